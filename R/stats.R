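#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square (no continuity correction): expected counts
#' `E[i,j] = row_i * col_j / N`, statistic `sum((O - E)^2 / E)`, p-value
#' from the upper tail of the chi-square distribution at
#' `df = (r - 1)(c - 1)`.
#'
#' @param observed Integer matrix of counts, at least 2x2, all entries
#'   non-negative, no zero row or column margin.
#' @return A `contingency_result`: list with `observed`, `expected`,
#'   `chi2`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(observed < 0) || anyNA(observed))
    stop("counts must be non-negative", call. = FALSE)
  n <- sum(observed)
  if (n <= 0) stop("grand total must be positive", call. = FALSE)
  rs <- rowSums(observed)
  cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate margin: a row or column sums to 0; drop it first",
         call. = FALSE)
  expected <- outer(rs, cs) / n
  chi2 <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  structure(
    list(observed = observed, expected = expected, chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE)),
    class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Median and quartiles
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention fixed for this package.
#'
#' @param values Numeric vector (>= 1 finite value).
#' @return Named list with `median`, `q1`, `q3`.
#' @export
quartile_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}
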