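#' Partition grids into IKWG staining levels
#'
#' Implements the level assignment of the IKWG manual scoring protocol:
#' the per-case LI range (max minus min over valid grids) is split in
#' thirds to give cutoffs `c1`, `c2`; grids with LI exactly 0 form the
#' `zero` level, the rest are `low` (`0 < LI <= c1`), `medium`
#' (`c1 < LI <= c2`) or `high` (`LI > c2`). Level proportions are counts
#' over all valid grids. When the range is 0, all non-zero grids form a
#' single level, labelled `high`.
#'
#' @param table A [grid_table()] (already QC-filtered if desired).
#' @param range_over Compute the range over `"all"` valid grids (default)
#'   or only the `"nonzero"`-LI grids.
#' @return An object of class `ikwg_partition`: list with `li_min`,
#'   `li_max`, `range_r`, `cutoff_c1`, `cutoff_c2`, `levels` (factor per
#'   valid grid, levels zero/low/medium/high), `proportions` (named, sums
#'   to 1), and the valid-grid data with LIs.
#' @export
partition_levels <- function(table, range_over = c("all", "nonzero")) {
  range_over <- match.arg(range_over)
  v <- li_of_valid(table)
  li_for_range <- if (range_over == "nonzero" && any(v$li > 0))
    v$li[v$li > 0] else v$li
  li_min <- min(li_for_range)
  li_max <- max(li_for_range)
  r <- li_max - li_min
  c1 <- li_min + r / 3
  c2 <- li_min + 2 * r / 3

  lv <- character(nrow(v))
  lv[v$li == 0] <- "zero"
  nz <- v$li > 0
  if (r == 0) {
    lv[nz] <- "high"
  } else {
    lv[nz & v$li <= c1] <- "low"
    lv[nz & v$li > c1 & v$li <= c2] <- "medium"
    lv[nz & v$li > c2] <- "high"
  }
  lv <- factor(lv, levels = c("zero", "low", "medium", "high"))
  props <- as.numeric(table(lv)) / nrow(v)
  names(props) <- levels(lv)

  structure(
    list(li_min = li_min, li_max = li_max, range_r = r,
         cutoff_c1 = c1, cutoff_c2 = c2,
         levels = lv, proportions = props, grids = v),
    class = "ikwg_partition")
}

#' Allocate and sample scoring fields across staining levels
#'
#' Distributes `n_fields` picks over the non-empty levels by
#' largest-remainder apportionment of the level proportions (ties in the
#' remainders broken by level order zero < low < medium < high), caps each
#' level at its grid count, redistributes unplaceable picks to the levels
#' with most spare grids, then samples without replacement within each
#' level using the current RNG state.
#'
#' @param partition An [partition_levels()] result.
#' @param n_fields Total number of grids to select (default 4, the IKWG
#'   field count).
#' @param strategy `"proportional"` (default) or `"one_per_level"` (one
#'   pick per non-empty level, extra picks by the proportional rule) for
#'   sensitivity analysis.
#' @return Character vector of selected `grid_id`s.
#' @export
select_fields <- function(partition, n_fields = 4,
                          strategy = c("proportional", "one_per_level")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(partition, "ikwg_partition"), n_fields >= 1)
  alloc <- allocate_fields(partition, n_fields, strategy)
  ids <- character(0)
  for (l in names(alloc)) {
    if (alloc[[l]] == 0L) next
    pool <- partition$grids$grid_id[partition$levels == l]
    ids <- c(ids, pool[sample.int(length(pool), alloc[[l]])])
  }
  ids
}

# deterministic apportionment (no RNG involved)
allocate_fields <- function(partition, n_fields, strategy = "proportional") {
  sizes <- as.integer(table(partition$levels))
  names(sizes) <- names(partition$proportions)
  total <- sum(sizes)
  if (total <= n_fields) return(sizes)  # fewer grids than fields: take all

  props <- partition$proportions
  alloc <- integer(length(props))
  names(alloc) <- names(props)
  if (strategy == "one_per_level") {
    alloc[sizes > 0] <- 1L
    alloc <- pmin(alloc, sizes)
  }
  remaining <- n_fields - sum(alloc)
  if (remaining > 0) {
    quota <- remaining * props / sum(props[sizes > 0])
    quota[sizes == 0] <- 0
    extra <- pmin(floor(quota), sizes - alloc)
    alloc <- alloc + as.integer(extra)
    rem <- quota - floor(quota)
    while (sum(alloc) < n_fields) {
      open <- which(sizes - alloc > 0)
      # largest remainder first; exhausted remainders fall back to spare size
      pick <- open[order(-rem[open], -(sizes - alloc)[open])][1]
      alloc[pick] <- alloc[pick] + 1L
      rem[pick] <- rem[pick] - 1
    }
  }
  alloc
}

#' IKWG global average over selected fields
#'
#' Total positive cells divided by total tumor cells of the selected grids.
#'
#' @param partition An [partition_levels()] result.
#' @param grid_ids Selected grid ids.
#' @return Percent.
#' @export
ikwg_global_average <- function(partition, grid_ids) {
  g <- partition$grids[match(grid_ids, partition$grids$grid_id), ,
                       drop = FALSE]
  if (nrow(g) == 0L || anyNA(g$grid_id))
    stop("empty or unknown field selection", call. = FALSE)
  100 * sum(g$positive_cells) / sum(g$tumor_cells)
}

#' IKWG weighted average over selected fields
#'
#' Per sampled level, the level score is the unweighted mean LI of its
#' selected grids; the weighted average sums level score times level
#' proportion. The zero level contributes 0 with its full proportion
#' whether or not it was sampled; when a non-zero level received no pick,
#' proportions are renormalized over the sampled levels (plus the zero
#' level) so that unsampled small levels do not bias the score downward.
#'
#' @inheritParams ikwg_global_average
#' @return Percent.
#' @export
ikwg_weighted_average <- function(partition, grid_ids) {
  idx <- match(grid_ids, partition$grids$grid_id)
  if (length(idx) == 0L || anyNA(idx))
    stop("empty or unknown field selection", call. = FALSE)
  lv <- partition$levels[idx]
  li <- partition$grids$li[idx]
  props <- partition$proportions

  sampled <- levels(lv)[levels(lv) %in% as.character(unique(lv))]
  keep <- union(sampled, if (props[["zero"]] > 0) "zero" else character(0))
  mass <- sum(props[keep])
  w <- 0
  for (l in setdiff(sampled, "zero")) {
    w <- w + mean(li[lv == l]) * props[[l]] / mass
  }
  w
}

#' Simulate the IKWG manual scoring protocol
#'
#' Monte-Carlo simulation of manual field selection: the slide's valid
#' grids are partitioned into staining levels once, then for each
#' replicate 4 fields are drawn by the level-proportional rule and the
#' global and weighted average scores computed. Replicates use one seeded
#' RNG stream sequentially; results are bit-identical for identical seeds.
#'
#' @param table A [grid_table()].
#' @param n_replicates Number of replicates (default 1000).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param n_fields Fields per replicate (default 4).
#' @param strategy Field-allocation strategy, see [select_fields()].
#' @param range_over Range convention, see [partition_levels()].
#' @param keep_replicates Keep the per-replicate scores (default `TRUE`).
#' @return An `ikwg_summary`: list with `case_id`, `n_replicates`, `seed`,
#'   `medians`, `ci_low`, `ci_high` (2.5th/97.5th percentiles), `range`
#'   (min/max per score) and optionally `replicates` (data.frame with
#'   `global_average`, `weighted_average`).
#' @export
run_ikwg_simulation <- function(table, n_replicates = 1000, seed = NULL,
                                n_fields = 4,
                                strategy = c("proportional", "one_per_level"),
                                range_over = c("all", "nonzero"),
                                keep_replicates = TRUE) {
  strategy <- match.arg(strategy)
  range_over <- match.arg(range_over)
  stopifnot(n_replicates >= 1)
  part <- partition_levels(table, range_over = range_over)
  alloc <- allocate_fields(part, n_fields, strategy)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  # per-level index pools into part$grids, fixed across replicates
  pools <- lapply(levels(part$levels), function(l) which(part$levels == l))
  names(pools) <- levels(part$levels)
  li <- part$grids$li
  n_cells <- part$grids$tumor_cells
  k_cells <- part$grids$positive_cells
  props <- part$proportions
  nz_levels <- setdiff(names(alloc)[alloc > 0], "zero")
  keep <- union(names(alloc)[alloc > 0],
                if (props[["zero"]] > 0) "zero" else character(0))
  mass <- sum(props[keep])

  G <- W <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sel <- integer(0)
    w <- 0
    for (l in names(alloc)) {
      if (alloc[[l]] == 0L) next
      pool <- pools[[l]]
      take <- if (length(pool) == alloc[[l]]) pool
              else pool[sample.int(length(pool), alloc[[l]])]
      sel <- c(sel, take)
      if (l != "zero") w <- w + mean(li[take]) * props[[l]] / mass
    }
    G[r] <- 100 * sum(k_cells[sel]) / sum(n_cells[sel])
    W[r] <- w
  }

  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  structure(
    list(case_id = table$case_id,
         n_replicates = n_replicates,
         seed = seed,
         allocation = alloc,
         medians = c(global_average = stats::median(G),
                     weighted_average = stats::median(W)),
         ci_low = c(global_average = q(G, 0.025),
                    weighted_average = q(W, 0.025)),
         ci_high = c(global_average = q(G, 0.975),
                     weighted_average = q(W, 0.975)),
         range = list(global_average = range(G),
                      weighted_average = range(W)),
         replicates = if (keep_replicates)
           data.frame(global_average = G, weighted_average = W) else NULL),
    class = "ikwg_summary")
}

#' @export
print.ikwg_summary <- function(x, ...) {
  cat(sprintf(
    "ikwg_summary '%s': %d replicates (seed %s)\n  global   median %.2f [%.2f, %.2f]\n  weighted median %.2f [%.2f, %.2f]\n",
    x$case_id, x$n_replicates,
    if (is.null(x$seed)) "none" else x$seed,
    x$medians[["global_average"]], x$ci_low[["global_average"]],
    x$ci_high[["global_average"]],
    x$medians[["weighted_average"]], x$ci_low[["weighted_average"]],
    x$ci_high[["weighted_average"]]))
  invisible(x)
}
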