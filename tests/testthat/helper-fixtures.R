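# in-code fixtures shared across test files

# grid table from parallel count vectors (all grids valid, equal ids g1..gn)
make_table <- function(tumor, positive, case_id = "t", grid_size_um = 300) {
  grid_table(case_id,
             data.frame(grid_id = paste0("g", seq_along(tumor)),
                        tumor_cells = tumor, positive_cells = positive),
             grid_size_um = grid_size_um)
}

# grid table whose grid LIs are exactly `li` percent (100 cells per grid)
make_li_table <- function(li, case_id = "t") {
  make_table(rep(100L, length(li)), as.integer(round(li)), case_id = case_id)
}

# randomized table for property tests (uses current RNG)
random_table <- function(n_grids = NULL) {
  if (is.null(n_grids)) n_grids <- sample(1:40, 1)
  tumor <- sample(100:1000, n_grids, replace = TRUE)
  positive <- rbinom(n_grids, tumor, runif(1, 0, 0.8))
  make_table(tumor, positive)
}

# two-loop Pearson chi-square oracle, independent of pearson_chi2()
chi2_oracle <- function(m) {
  n <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- rs[i] * cs[j] / n
      acc <- acc + (m[i, j] - e)^2 / e
    }
  }
  acc
}

# write a grid table in the default export schema; returns the path
write_export <- function(table, path = tempfile(fileext = ".tsv")) {
  g <- table$grids
  utils::write.table(
    data.frame(Name = g$grid_id, Row = g$row_index, Column = g$col_index,
               `Num Tumor` = g$tumor_cells,
               `Num Tumor Positive` = g$positive_cells, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
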