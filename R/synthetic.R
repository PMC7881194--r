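#' Parameters for a synthetic slide
#'
#' Describes the generative model for one slide: a lattice of square
#' grids, overdispersed tumor-cell counts per grid (negative binomial with
#' mean `cells_mean` and dispersion `cells_dispersion`; dispersion 0
#' degenerates to Poisson), and a Ki67-positivity field made of a uniform
#' baseline plus Gaussian proliferation bumps ("hotspots") whose centers
#' are placed uniformly at random over the lattice. Positive-cell counts
#' are binomial draws at the local positivity.
#'
#' Defaults reflect a 300 um tiling of a typical slide: about 650 grids
#' per slide with a mean of 268.4 tumor cells per grid.
#'
#' @param n_rows,n_cols Lattice dimensions (default 25 x 26, about the
#'   mean grid count of a 300 um tiling).
#' @param grid_size_um Grid edge length (default 300).
#' @param cells_mean Mean tumor cells per grid (default 268.4).
#' @param cells_dispersion Negative-binomial dispersion (variance =
#'   mean + dispersion * mean^2; default 0.3, CV about 0.55, matching the
#'   wide observed per-grid ranges).
#' @param baseline_li Baseline positive fraction p0 (default 0.06).
#' @param n_hotspots Number of Gaussian bumps (default 2).
#' @param hotspot_amplitude Added positive fraction at a bump center
#'   (default 0.35); the field is clamped to `[0, 1]`.
#' @param hotspot_sigma_grids Bump standard deviation in grid units
#'   (default 2).
#' @return A `slide_sim_params` list.
#' @export
slide_sim_params <- function(n_rows = 25, n_cols = 26, grid_size_um = 300,
                             cells_mean = 268.4, cells_dispersion = 0.3,
                             baseline_li = 0.06, n_hotspots = 2,
                             hotspot_amplitude = 0.35,
                             hotspot_sigma_grids = 2.0) {
  p <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            grid_size_um = grid_size_um, cells_mean = cells_mean,
            cells_dispersion = cells_dispersion, baseline_li = baseline_li,
            n_hotspots = as.integer(n_hotspots),
            hotspot_amplitude = hotspot_amplitude,
            hotspot_sigma_grids = hotspot_sigma_grids)
  with(p, {
    if (n_rows < 1 || n_cols < 1) stop("lattice dimensions must be >= 1",
                                       call. = FALSE)
    if (cells_mean <= 0) stop("cells_mean must be positive", call. = FALSE)
    if (cells_dispersion < 0) stop("cells_dispersion must be >= 0",
                                   call. = FALSE)
    if (baseline_li < 0 || baseline_li > 1)
      stop("baseline_li must be a fraction in [0, 1]", call. = FALSE)
    if (n_hotspots < 0 || hotspot_amplitude < 0)
      stop("n_hotspots and hotspot_amplitude must be >= 0", call. = FALSE)
    if (hotspot_sigma_grids <= 0) stop("hotspot_sigma_grids must be > 0",
                                       call. = FALSE)
  })
  structure(p, class = "slide_sim_params")
}

#' Simulate one slide's grid table
#'
#' Uses the current RNG state (seed with `set.seed()` for reproducibility).
#'
#' @param params A [slide_sim_params()].
#' @param case_id Case identifier for the generated slide.
#' @return A [grid_table()]; the true positivity field is attached as
#'   attribute `"p_field"` and bump centers as `"hotspot_centers"`.
#' @export
simulate_slide <- function(params = slide_sim_params(), case_id = "sim1") {
  stopifnot(inherits(params, "slide_sim_params"))
  nr <- params$n_rows; nc <- params$n_cols
  n <- nr * nc
  lattice <- expand.grid(row_index = seq_len(nr) - 1L,
                         col_index = seq_len(nc) - 1L)

  centers <- if (params$n_hotspots > 0)
    cbind(row = stats::runif(params$n_hotspots, 0, nr - 1),
          col = stats::runif(params$n_hotspots, 0, nc - 1))
  else matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col")))

  p <- rep(params$baseline_li, n)
  if (nrow(centers) > 0) {
    s2 <- 2 * params$hotspot_sigma_grids^2
    for (b in seq_len(nrow(centers))) {
      d2 <- (lattice$row_index - centers[b, "row"])^2 +
            (lattice$col_index - centers[b, "col"])^2
      p <- p + params$hotspot_amplitude * exp(-d2 / s2)
    }
  }
  p <- pmin(pmax(p, 0), 1)

  cells <- if (params$cells_dispersion == 0)
    stats::rpois(n, params$cells_mean)
  else
    stats::rnbinom(n, mu = params$cells_mean,
                   size = 1 / params$cells_dispersion)
  pos <- stats::rbinom(n, cells, p)

  gt <- grid_table(case_id,
                   data.frame(grid_id = sprintf("r%d_c%d", lattice$row_index,
                                                lattice$col_index),
                              row_index = lattice$row_index,
                              col_index = lattice$col_index,
                              tumor_cells = cells, positive_cells = pos),
                   grid_size_um = params$grid_size_um)
  attr(gt, "p_field") <- p
  attr(gt, "hotspot_centers") <- centers
  gt
}

#' Merge grids into coarser blocks
#'
#' Emulates re-tiling at a coarser grid size by pooling `factor x factor`
#' blocks: tumor and positive cell counts are summed and the grid size
#' scaled by `factor`. Operates on raw counts of all grids; QC flags are
#' reset (re-apply [apply_qc()] after regridding).
#'
#' @param table A [grid_table()].
#' @param factor Positive integer block edge; partial edge blocks are kept.
#' @return A new [grid_table()] at `factor`-times the grid size.
#' @export
regrid <- function(table, factor) {
  stopifnot(inherits(table, "grid_table"))
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != floor(factor))
    stop("factor must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(table)
  g <- table$grids
  br <- g$row_index %/% factor
  bc <- g$col_index %/% factor
  agg <- stats::aggregate(g[, c("tumor_cells", "positive_cells")],
                          by = list(row_index = br, col_index = bc), sum)
  grid_table(table$case_id,
             data.frame(grid_id = sprintf("r%d_c%d", agg$row_index,
                                          agg$col_index),
                        row_index = agg$row_index, col_index = agg$col_index,
                        tumor_cells = agg$tumor_cells,
                        positive_cells = agg$positive_cells),
             grid_size_um = table$grid_size_um * factor)
}

#' Parameters for a synthetic cohort
#'
#' Case-level generative model: age is a two-point mixture (under/over
#' 50), grade is categorical, each case gets its own baseline LI and
#' hotspot amplitude (log-normal across cases, producing the right-skewed
#' score distribution), and the Recurrence Score is linked to the slide's
#' pooled average score A through
#' `RS = round(clamp(beta0 + beta1 * sqrt(A) + beta2 * (grade - 2) + N(0, sigma), 0, 100))`.
#' The square-root transform gives the saturating, non-linear LI-RS
#' relation seen at low proliferation. Defaults are calibrated so that the
#' cohort Pearson correlation between A and RS lands near 0.5 and the
#' median hotspot score is about twice the median average score.
#'
#' @param n_cases Number of cases (default 240).
#' @param p_age_lt50 Probability of age < 50 (default 153/240).
#' @param grade_probs Probabilities of grades 1-3
#'   (default `c(0.212, 0.646, 0.142)`).
#' @param baseline_li_meanlog,baseline_li_sdlog Log-normal law of the
#'   per-case baseline fraction p0.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal law of the per-case
#'   hotspot amplitude.
#' @param rs_link List with `beta0`, `beta1`, `beta2`, `sigma`.
#' @param slide Base [slide_sim_params()]; per-case baseline and amplitude
#'   override its `baseline_li` / `hotspot_amplitude`.
#' @return A `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_cases = 240,
                              p_age_lt50 = 153 / 240,
                              grade_probs = c(0.212, 0.646, 0.142),
                              baseline_li_meanlog = log(0.09),
                              baseline_li_sdlog = 0.7,
                              amplitude_meanlog = log(0.10),
                              amplitude_sdlog = 0.5,
                              rs_link = list(beta0 = 2, beta1 = 4.4,
                                             beta2 = 4, sigma = 8),
                              slide = slide_sim_params()) {
  if (n_cases < 0) stop("n_cases must be >= 0", call. = FALSE)
  if (abs(sum(grade_probs) - 1) > 1e-8 || any(grade_probs < 0))
    stop("grade_probs must be non-negative and sum to 1", call. = FALSE)
  if (p_age_lt50 < 0 || p_age_lt50 > 1)
    stop("p_age_lt50 must be in [0, 1]", call. = FALSE)
  if (rs_link$sigma < 0) stop("rs_link$sigma must be >= 0", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases), p_age_lt50 = p_age_lt50,
                 grade_probs = grade_probs,
                 baseline_li_meanlog = baseline_li_meanlog,
                 baseline_li_sdlog = baseline_li_sdlog,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 rs_link = rs_link, slide = slide),
            class = "cohort_sim_params")
}

#' Simulate a scored cohort
#'
#' Draws case metadata and one slide per case, scores every slide
#' ([score_slide()] with the default QC and top-5 hotspot), and links the
#' Recurrence Score to the realized average score.
#'
#' @param params A [cohort_sim_params()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `cohort` (data.frame: `case_id`, `age_years`, `grade`,
#'   `rs`, `average`, `hotspot`, `hottest_spot`, `n_grids_valid`) and
#'   `slides` (named list of [grid_table()]s).
#' @export
simulate_cohort <- function(params = cohort_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_sim_params"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- params$n_cases
  if (n == 0L)
    return(list(cohort = data.frame(case_id = character(0),
                                    age_years = numeric(0),
                                    grade = integer(0), rs = integer(0),
                                    average = numeric(0),
                                    hotspot = numeric(0),
                                    hottest_spot = numeric(0),
                                    n_grids_valid = integer(0)),
                slides = list()))

  young <- stats::runif(n) < params$p_age_lt50
  age <- ifelse(young, stats::runif(n, 35, 49.9), stats::runif(n, 50, 75))
  grade <- sample.int(3L, n, replace = TRUE, prob = params$grade_probs)
  p0 <- pmin(stats::rlnorm(n, params$baseline_li_meanlog,
                           params$baseline_li_sdlog), 0.6)
  amp <- pmin(stats::rlnorm(n, params$amplitude_meanlog,
                            params$amplitude_sdlog), 0.9)

  slides <- vector("list", n)
  scores <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- params$slide
    sp$baseline_li <- p0[i]
    sp$hotspot_amplitude <- amp[i]
    slides[[i]] <- simulate_slide(sp, case_id = sprintf("case%03d", i))
    scores[[i]] <- as.data.frame(score_slide(slides[[i]]))
  }
  sc <- do.call(rbind, scores)
  names(slides) <- sc$case_id

  b <- params$rs_link
  rs <- round(b$beta0 + b$beta1 * sqrt(sc$average) + b$beta2 * (grade - 2) +
                stats::rnorm(n, 0, b$sigma))
  rs <- as.integer(pmin(pmax(rs, 0), 100))

  cohort <- data.frame(case_id = sc$case_id, age_years = age,
                       grade = as.integer(grade), rs = rs,
                       average = sc$average, hotspot = sc$hotspot,
                       hottest_spot = sc$hottest_spot,
                       n_grids_valid = sc$n_grids_valid,
                       stringsAsFactors = FALSE)
  list(cohort = cohort, slides = slides)
}
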