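#' Read a per-grid measurement table
#'
#' Ingests a delimited export of tile-level cell detections (one row per
#' square grid) into a [grid_table()]. The delimiter is auto-detected
#' between tab and comma by header inspection. Column names vary between
#' image-analysis exports, so a `column_map` translates file columns to the
#' internal fields; the default matches common tile-annotation exports.
#'
#' @param path Path to a TSV/CSV file.
#' @param case_id Case identifier for the slide; defaults to the file name
#'   without extension.
#' @param column_map Named character vector mapping internal fields
#'   (`grid_id`, `tumor_cells`, `positive_cells`, optionally `row_index`,
#'   `col_index`, `excluded`) to file column names. Required fields:
#'   `tumor_cells`, `positive_cells`. When `grid_id` is unmapped or absent,
#'   sequential ids `g1, g2, ...` are synthesized; the same holds for the
#'   lattice indices.
#' @param grid_size_um Grid edge length in micrometers.
#' @return A [grid_table()] with one grid per data row, in file order, all
#'   grids initially retained unless an `excluded` column is mapped.
#' @export
read_grid_table <- function(path,
                            case_id = NULL,
                            column_map = default_column_map(),
                            grid_size_um = 300) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(case_id))
    case_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- read_delimited(path)
  if (nrow(raw) == 0L)
    stop("no grids: '", path, "' has an empty data section", call. = FALSE)

  column_map <- utils::modifyList(as.list(default_column_map()),
                                  as.list(column_map))
  for (field in c("tumor_cells", "positive_cells")) {
    if (!column_map[[field]] %in% names(raw))
      stop("configuration error: mapped column '", column_map[[field]],
           "' (for ", field, ") not found in ", path, call. = FALSE)
  }

  grids <- data.frame(
    tumor_cells = raw[[column_map$tumor_cells]],
    positive_cells = raw[[column_map$positive_cells]],
    stringsAsFactors = FALSE)
  grids$grid_id <- pick_col(raw, column_map$grid_id,
                            paste0("g", seq_len(nrow(raw))))
  ri <- pick_col(raw, column_map$row_index, NULL)
  ci <- pick_col(raw, column_map$col_index, NULL)
  if (!is.null(ri)) grids$row_index <- ri
  if (!is.null(ci)) grids$col_index <- ci
  ex <- pick_col(raw, column_map$excluded, NULL)
  if (!is.null(ex)) grids$excluded <- parse_flag(ex)

  grid_table(case_id, grids, grid_size_um = grid_size_um)
}

#' Default column map for grid exports
#'
#' @return Named character vector of file column names keyed by internal
#'   field; override any entry via the `column_map` argument of
#'   [read_grid_table()].
#' @export
default_column_map <- function() {
  c(grid_id = "Name",
    tumor_cells = "Num Tumor",
    positive_cells = "Num Tumor Positive",
    row_index = "Row",
    col_index = "Column",
    excluded = "Excluded")
}

pick_col <- function(raw, name, default) {
  if (!is.null(name) && !is.na(name) && name %in% names(raw)) raw[[name]]
  else default
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "y")
}

# delimiter sniffing: tab wins if the header contains one, else comma
read_delimited <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

#' Read case-level metadata
#'
#' @param path TSV/CSV file with columns `case_id`, `age_years`, `grade`, `rs`.
#' @return A validated data.frame (see [case_metadata()]).
#' @export
read_case_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  case_metadata(read_delimited(path))
}

#' Write a per-case score table
#'
#' Writes one row per case with the three whole-slide scores, QC
#' bookkeeping, and (when supplied) the case metadata, as tab-separated
#' text. Scores are rendered with fixed decimal precision.
#'
#' @param scores A data.frame of slide scores as returned by
#'   [score_slide()] rows bound together (see [score_cohort()]), or a single
#'   `slide_scores` object.
#' @param path Output file path.
#' @param metadata Optional data.frame of [case_metadata()] merged by
#'   `case_id`; cases without metadata get `NA` fields.
#' @param digits Decimal places for the score columns (default 2).
#' @return Invisibly, the data.frame written.
#' @export
write_score_table <- function(scores, path, metadata = NULL, digits = 2) {
  if (inherits(scores, "slide_scores")) scores <- as.data.frame(scores)
  stopifnot(is.data.frame(scores))
  out <- scores
  if (!is.null(metadata)) {
    metadata <- case_metadata(metadata)
    out <- merge(out, metadata, by = "case_id", all.x = TRUE, sort = FALSE)
  }
  for (col in c("average", "hotspot", "hottest_spot"))
    if (col %in% names(out)) out[[col]] <- round(out[[col]], digits)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(out)
}

#' Read back a score table written by [write_score_table()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read_delimited(path)
}
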