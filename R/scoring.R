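#' Ki67 labeling index of a single grid
#'
#' @param tumor_cells Tumor cell count(s), must be positive.
#' @param positive_cells Ki67-positive tumor cell count(s).
#' @return Percent LI, `100 * positive_cells / tumor_cells` (vectorized).
#' @export
grid_li <- function(tumor_cells, positive_cells) {
  if (any(tumor_cells <= 0))
    stop("LI undefined: tumor_cells must be > 0", call. = FALSE)
  100 * positive_cells / tumor_cells
}

#' Apply the minimum-cell QC filter
#'
#' Grids with fewer than `min_cells` tumor cells are excluded
#' (`exclusion_reason = "too_few_cells"`); the boundary is strict, so a grid
#' with exactly `min_cells` cells is retained. Pre-existing manual
#' exclusions are preserved.
#'
#' @param table A [grid_table()].
#' @param min_cells Minimum tumor cells per grid (default 100).
#' @return A new `grid_table` with updated QC flags.
#' @export
apply_qc <- function(table, min_cells = 100) {
  stopifnot(inherits(table, "grid_table"), min_cells >= 0)
  g <- table$grids
  low <- g$tumor_cells < min_cells & g$exclusion_reason != "manual"
  g$exclusion_reason[low] <- "too_few_cells"
  g$exclusion_reason[!low & g$exclusion_reason == "too_few_cells"] <- "none"
  g$excluded <- g$exclusion_reason != "none"
  table$grids <- g
  table
}

li_of_valid <- function(table) {
  v <- valid_grids(table)
  if (nrow(v) == 0L)
    stop("empty slide: no valid grids after QC in '", table$case_id, "'",
         call. = FALSE)
  v$li <- grid_li(v$tumor_cells, v$positive_cells)
  v
}

#' Pooled (global) average score
#'
#' Sum of Ki67-positive tumor cells over sum of tumor cells across all valid
#' grids, times 100 — a cell-count-weighted mean, not the unweighted mean of
#' grid LIs.
#'
#' @param table A [grid_table()].
#' @return Percent in `[0, 100]`.
#' @export
average_score <- function(table) {
  v <- li_of_valid(table)
  100 * sum(v$positive_cells) / sum(v$tumor_cells)
}

#' Hottest-spot score
#'
#' The maximum grid LI over valid grids.
#'
#' @param table A [grid_table()].
#' @return Percent in `[0, 100]`.
#' @export
hottest_spot_score <- function(table) {
  max(li_of_valid(table)$li)
}

#' Hotspot score (top-k grid mean)
#'
#' Unweighted mean LI of the `k` highest-LI valid grids. Slides with fewer
#' than `k` valid grids are scored over all available grids (slides with as
#' few as 4 grids occur at coarse grid sizes), with the number actually
#' averaged reported as `k_used`. Ties at the k-th LI are broken by larger
#' tumor-cell count, then grid id; this affects only which grids are
#' reported, never the score.
#'
#' @param table A [grid_table()].
#' @param k Number of top grids to average (default 5).
#' @param method `"mean_li"` (default): unweighted mean of the top-k grid
#'   LIs; `"pooled"`: pooled counts over the top-k grids, for sensitivity
#'   analysis of the averaging convention.
#' @return List with `score` (percent), `k_used`, and `grid_ids` of the
#'   selected grids.
#' @export
hotspot_score <- function(table, k = 5, method = c("mean_li", "pooled")) {
  method <- match.arg(method)
  stopifnot(k >= 1)
  v <- li_of_valid(table)
  ord <- order(-v$li, -v$tumor_cells, v$grid_id)
  top <- v[ord[seq_len(min(k, nrow(v)))], , drop = FALSE]
  score <- if (method == "pooled")
    100 * sum(top$positive_cells) / sum(top$tumor_cells)
  else mean(top$li)
  list(score = score, k_used = nrow(top), grid_ids = top$grid_id)
}

#' Score one slide
#'
#' Applies the QC filter then computes the three whole-slide Ki67 scores:
#' pooled average, top-`k` hotspot, and hottest spot.
#'
#' @param table A [grid_table()].
#' @param min_cells QC threshold passed to [apply_qc()] (default 100).
#' @param k Hotspot top-k (default 5).
#' @return A `slide_scores` object: list with `case_id`, `grid_size_um`,
#'   `n_grids_total`, `n_grids_valid`, `average`, `hotspot`, `hottest_spot`,
#'   `k_used`.
#' @export
score_slide <- function(table, min_cells = 100, k = 5) {
  table <- apply_qc(table, min_cells = min_cells)
  hs <- hotspot_score(table, k = k)
  structure(
    list(case_id = table$case_id,
         grid_size_um = table$grid_size_um,
         n_grids_total = nrow(table$grids),
         n_grids_valid = sum(!table$grids$excluded),
         average = average_score(table),
         hotspot = hs$score,
         hottest_spot = hottest_spot_score(table),
         k_used = hs$k_used),
    class = "slide_scores")
}

#' @export
as.data.frame.slide_scores <- function(x, ...) {
  data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
print.slide_scores <- function(x, ...) {
  cat(sprintf(
    "slide_scores '%s' (%g um, %d/%d grids valid)\n  average %.2f  hotspot %.2f (k=%d)  hottest %.2f\n",
    x$case_id, x$grid_size_um, x$n_grids_valid, x$n_grids_total,
    x$average, x$hotspot, x$k_used, x$hottest_spot))
  invisible(x)
}

#' Score a list of slides
#'
#' @param tables List of [grid_table()] objects.
#' @inheritParams score_slide
#' @return data.frame with one row per slide.
#' @export
score_cohort <- function(tables, min_cells = 100, k = 5) {
  do.call(rbind, lapply(tables, function(t)
    as.data.frame(score_slide(t, min_cells = min_cells, k = k))))
}
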