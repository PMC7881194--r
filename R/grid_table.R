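#' @title Slide grid tables
#'
#' @description A `grid_table` holds the per-grid (tile) cell counts of one
#' slide at one grid size: for every square grid of the annotated invasive
#' tumor area, the number of tumor cells detected and the number of
#' Ki67-positive tumor cells among them. It is the unit on which all scoring
#' operates.
#'
#' @details Each grid row carries a QC state: `excluded` plus an
#' `exclusion_reason` in `"none"`, `"too_few_cells"` (set by [apply_qc()])
#' or `"manual"` (set upstream for grids with DCIS, lymphoid aggregates or
#' staining artifacts; this package never infers manual exclusions).
#' The invariants `positive_cells <= tumor_cells` and
#' `excluded == (exclusion_reason != "none")` are enforced at construction.
#'
#' @param case_id Slide/case identifier (length-1 character).
#' @param grids A data.frame with columns `grid_id`, `row_index`, `col_index`,
#'   `tumor_cells`, `positive_cells` and optionally `excluded`,
#'   `exclusion_reason`.
#' @param grid_size_um Grid edge length in micrometers (positive number;
#'   the study design uses 300, 400 or 500).
#' @return An object of class `grid_table`: a list with elements `case_id`,
#'   `grid_size_um` and `grids` (the validated data.frame).
#' @examples
#' gt <- grid_table("case1",
#'                  data.frame(grid_id = c("g1", "g2"),
#'                             tumor_cells = c(200L, 150L),
#'                             positive_cells = c(20L, 30L)))
#' average_score(gt)
#' @export
grid_table <- function(case_id, grids, grid_size_um = 300) {
  stopifnot(is.character(case_id) || is.factor(case_id), length(case_id) == 1L)
  if (!is.data.frame(grids) || nrow(grids) == 0L)
    stop("no grids: a grid_table needs at least one grid", call. = FALSE)
  if (!is.numeric(grid_size_um) || length(grid_size_um) != 1L ||
      is.na(grid_size_um) || grid_size_um <= 0)
    stop("grid_size_um must be a single positive number", call. = FALSE)

  need <- c("grid_id", "tumor_cells", "positive_cells")
  miss <- setdiff(need, names(grids))
  if (length(miss))
    stop("grids is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  grids$grid_id <- as.character(grids$grid_id)
  if (anyDuplicated(grids$grid_id))
    stop("duplicate grid_id within slide '", case_id, "'", call. = FALSE)

  # lattice coordinates: synthesized sequentially (one row) when unmapped
  if (is.null(grids$row_index)) grids$row_index <- 0L
  if (is.null(grids$col_index)) grids$col_index <- seq_len(nrow(grids)) - 1L
  grids$row_index <- check_count(grids$row_index, "row_index", grids$grid_id)
  grids$col_index <- check_count(grids$col_index, "col_index", grids$grid_id)
  if (anyDuplicated(grids[, c("row_index", "col_index")]))
    stop("duplicate (row_index, col_index) lattice position in slide '",
         case_id, "'", call. = FALSE)

  grids$tumor_cells <- check_count(grids$tumor_cells, "tumor_cells",
                                   grids$grid_id)
  grids$positive_cells <- check_count(grids$positive_cells, "positive_cells",
                                      grids$grid_id)
  bad <- grids$positive_cells > grids$tumor_cells
  if (any(bad))
    stop("positive_cells > tumor_cells for grid(s): ",
         paste(utils::head(grids$grid_id[bad], 5L), collapse = ", "),
         call. = FALSE)

  if (is.null(grids$exclusion_reason)) {
    grids$exclusion_reason <-
      if (is.null(grids$excluded)) "none"
      else ifelse(as.logical(grids$excluded), "manual", "none")
  }
  grids$exclusion_reason <- as.character(grids$exclusion_reason)
  ok <- grids$exclusion_reason %in% c("none", "too_few_cells", "manual")
  if (!all(ok))
    stop("invalid exclusion_reason: ",
         paste(unique(grids$exclusion_reason[!ok]), collapse = ", "),
         call. = FALSE)
  grids$excluded <- grids$exclusion_reason != "none"

  rownames(grids) <- NULL
  structure(
    list(case_id = as.character(case_id),
         grid_size_um = as.numeric(grid_size_um),
         grids = grids[, c("grid_id", "row_index", "col_index", "tumor_cells",
                           "positive_cells", "excluded", "exclusion_reason")]),
    class = "grid_table")
}

# validate a non-negative integer-valued column, naming offending grids
check_count <- function(x, what, grid_id) {
  x <- suppressWarnings(as.numeric(x))
  bad <- is.na(x) | x < 0 | x != floor(x)
  if (any(bad))
    stop(what, " must be a non-negative integer; offending grid(s): ",
         paste(utils::head(grid_id[bad], 5L), collapse = ", "), call. = FALSE)
  as.integer(x)
}

#' @export
print.grid_table <- function(x, ...) {
  g <- x$grids
  cat(sprintf("grid_table '%s' (%g um): %d grids, %d excluded\n",
              x$case_id, x$grid_size_um, nrow(g), sum(g$excluded)))
  invisible(x)
}

#' Non-excluded grids of a slide
#'
#' @param table A [grid_table()].
#' @return The data.frame of grids with `excluded == FALSE`.
#' @export
valid_grids <- function(table) {
  stopifnot(inherits(table, "grid_table"))
  table$grids[!table$grids$excluded, , drop = FALSE]
}

#' Validate case-level metadata
#'
#' Checks a data.frame of case metadata: `case_id` (unique), `age_years`
#' (positive), Nottingham `grade` (1, 2 or 3) and the 21-gene Recurrence
#' Score `rs` (integer 0-100).
#'
#' @param meta A data.frame with columns `case_id`, `age_years`, `grade`, `rs`.
#' @return The validated data.frame (invisibly the same content, normalized
#'   types).
#' @export
case_metadata <- function(meta) {
  need <- c("case_id", "age_years", "grade", "rs")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("case metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta$case_id <- as.character(meta$case_id)
  if (anyDuplicated(meta$case_id))
    stop("duplicate case_id: ",
         paste(unique(meta$case_id[duplicated(meta$case_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(meta$age_years) | meta$age_years <= 0))
    stop("age_years must be positive", call. = FALSE)
  if (any(!meta$grade %in% c(1, 2, 3)))
    stop("grade must be 1, 2 or 3", call. = FALSE)
  if (any(!is.finite(meta$rs) | meta$rs < 0 | meta$rs > 100 |
            meta$rs != floor(meta$rs)))
    stop("rs must be an integer in [0, 100]", call. = FALSE)
  meta$grade <- as.integer(meta$grade)
  meta$rs <- as.integer(meta$rs)
  rownames(meta) <- NULL
  meta
}
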