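#' Recurrence-score category
#'
#' Bins an OncotypeDx Recurrence Score into the four categories used for
#' concordance tables: 0-15, 16-19, 20-25, >25 (TAILORx-derived cut
#' points as used in the tabulations, not the introduction's prose
#' grouping).
#'
#' @param rs Integer vector, 0-100.
#' @return Factor with levels `RS0_15`, `RS16_19`, `RS20_25`, `RS_gt25`.
#' @export
rs_category <- function(rs) {
  if (any(!is.finite(rs) | rs < 0 | rs > 100))
    stop("rs must be in [0, 100]", call. = FALSE)
  cut(rs, breaks = c(-Inf, 15, 19, 25, Inf),
      labels = c("RS0_15", "RS16_19", "RS20_25", "RS_gt25"))
}

#' Ki67 decade bin
#'
#' Half-open decade bins `[0,10) [10,20) [20,30) [30,40) [40,100]`, the
#' row categories of the concordance tables.
#'
#' @param score Percent Ki67 LI, 0-100.
#' @return Factor with levels `lt10`, `lt20`, `lt30`, `lt40`, `ge40`.
#' @export
ki67_bin <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 100))
    stop("score must be a percent in [0, 100]", call. = FALSE)
  cut(score, breaks = c(-Inf, 10, 20, 30, 40, Inf), right = FALSE,
      labels = c("lt10", "lt20", "lt30", "lt40", "ge40"))
}

#' Combined grade/hotspot risk rule
#'
#' Low risk if Nottingham grade 1 OR hotspot score strictly below 20;
#' high risk otherwise.
#'
#' @param grade Integer vector in \{1, 2, 3\}.
#' @param hotspot Hotspot score (percent).
#' @return Factor with levels `low`, `high`.
#' @export
combined_risk <- function(grade, hotspot) {
  if (any(!grade %in% c(1, 2, 3)))
    stop("grade must be 1, 2 or 3", call. = FALSE)
  factor(ifelse(grade == 1 | hotspot < 20, "low", "high"),
         levels = c("low", "high"))
}

#' Chemotherapy indication by Recurrence Score
#'
#' Operationalizes the trial-derived rule: chemotherapy is indicated for
#' patients under 50 with RS above 20, or 50 and older with RS above 25.
#' Age exactly 50 falls in the older stratum.
#'
#' @param age_years Age in years.
#' @param rs Recurrence Score, 0-100.
#' @return Logical vector.
#' @export
chemo_by_rs <- function(age_years, rs) {
  (age_years < 50 & rs > 20) | (age_years >= 50 & rs > 25)
}

#' Contingency table of a Ki67/grade factor against RS categories
#'
#' @param cohort data.frame with columns `age_years`, `grade`, `rs` and the
#'   score columns named by `score` (`average`, `hotspot`, `hottest_spot`;
#'   `grade` and `combined` use the grade/hotspot columns directly).
#' @param score Row factor: one of `"average"`, `"hotspot"`,
#'   `"hottest_spot"` (decade-binned), `"grade"`, or `"combined"` (the
#'   grade-1-or-hotspot<20 rule).
#' @param age_filter `"all"`, `"lt50"` or `"ge50"`.
#' @return Integer matrix (rows = score levels present, columns = RS
#'   categories) with `row_totals`/`col_totals` attributes.
#' @export
build_contingency <- function(cohort,
                              score = c("hotspot", "average", "hottest_spot",
                                        "grade", "combined"),
                              age_filter = c("all", "lt50", "ge50")) {
  score <- match.arg(score)
  age_filter <- match.arg(age_filter)
  cohort <- switch(age_filter,
                   all = cohort,
                   lt50 = cohort[cohort$age_years < 50, , drop = FALSE],
                   ge50 = cohort[cohort$age_years >= 50, , drop = FALSE])
  if (nrow(cohort) == 0L)
    stop("empty cohort after age filter '", age_filter, "'", call. = FALSE)
  rowf <- switch(score,
                 grade = factor(cohort$grade, levels = 1:3),
                 combined = combined_risk(cohort$grade, cohort$hotspot),
                 ki67_bin(cohort[[score]]))
  tab <- table(rowf, rs_category(cohort$rs))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c(score, "rs_category")
  attr(m, "row_totals") <- rowSums(m)
  attr(m, "col_totals") <- colSums(m)
  m
}

#' Misclassification accounting for the low-risk rules
#'
#' For the combined grade/hotspot rule and for the pure hotspot<20 rule,
#' counts — overall and per age stratum — the cases called low risk, and
#' among them those whose Recurrence Score would indicate chemotherapy
#' ([chemo_by_rs()]), those with RS above 20, and those with RS above 25.
#'
#' @param cohort data.frame with columns `age_years`, `grade`, `rs`,
#'   `hotspot`.
#' @return Nested list `summary[[stratum]][[rule]]` for strata `overall`,
#'   `age_lt50`, `age_ge50` and rules `combined`, `hotspot_lt20`, each a
#'   named list of counts `n`, `n_low`, `n_low_chemo_by_rs`,
#'   `n_low_rs_gt20`, `n_low_rs_gt25`.
#' @export
misclassification_summary <- function(cohort) {
  strata <- list(overall = rep(TRUE, nrow(cohort)),
                 age_lt50 = cohort$age_years < 50,
                 age_ge50 = cohort$age_years >= 50)
  rules <- list(
    combined = if (nrow(cohort))
      combined_risk(cohort$grade, cohort$hotspot) == "low" else logical(0),
    hotspot_lt20 = cohort$hotspot < 20)
  lapply(strata, function(in_stratum) {
    lapply(rules, function(low) {
      sel <- in_stratum & low
      list(n = sum(in_stratum),
           n_low = sum(sel),
           n_low_chemo_by_rs = sum(sel & chemo_by_rs(cohort$age_years,
                                                     cohort$rs)),
           n_low_rs_gt20 = sum(sel & cohort$rs > 20),
           n_low_rs_gt25 = sum(sel & cohort$rs > 25))
    })
  })
}

#' Bundled reference concordance tables
#'
#' Loads the cell counts of the two published concordance tables shipped
#' with the package (age < 50 and age >= 50), one row per (layout, level)
#' with the four RS-category counts.
#'
#' @param which `"age_lt50"` or `"age_ge50"`.
#' @return data.frame with columns `layout`, `level`, `rs0_15`, `rs16_19`,
#'   `rs20_25`, `rs_gt25`.
#' @export
ki67_reference_tables <- function(which = c("age_lt50", "age_ge50")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("concordance_", which, ".tsv"),
                   package = "ki67grid", mustWork = TRUE)
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Reference table counts as a matrix for one layout
#'
#' @param which Table: `"age_lt50"` or `"age_ge50"`.
#' @param layout One of `"hotspot"`, `"average"`, `"hottest_spot"`,
#'   `"grade"`, `"combined"`.
#' @return Integer matrix, rows = levels, columns = RS categories.
#' @export
reference_counts <- function(which, layout) {
  tab <- ki67_reference_tables(which)
  tab <- tab[tab$layout == layout, , drop = FALSE]
  if (nrow(tab) == 0L) stop("unknown layout: ", layout, call. = FALSE)
  m <- as.matrix(tab[, c("rs0_15", "rs16_19", "rs20_25", "rs_gt25")])
  rownames(m) <- tab$level
  m
}

# representative within-bin values so that classifier logic, not table
# reading, reproduces the printed counts
bin_midpoint <- c(lt10 = 5, lt20 = 15, lt30 = 25, lt40 = 35, ge40 = 45)
rs_representative <- c(rs0_15 = 8, rs16_19 = 17, rs20_25 = 22, rs_gt25 = 30)

#' Expand printed table counts into per-case records
#'
#' Turns one layout of a reference concordance table into synthetic
#' per-case records carrying representative within-bin values (Ki67 bin
#' midpoints; RS categories mapped to 8, 17, 22, 30), so that the cohort
#' classifiers re-derive the printed counts. Fields not determined by the
#' layout get neutral values: grade 2 for score layouts, hotspot 25 for the
#' grade layout, and (grade 1, hotspot 25) / (grade 2, hotspot 25) for the
#' low/high rows of the combined layout.
#'
#' @param which Table: `"age_lt50"` or `"age_ge50"`.
#' @param layout Layout to expand (see [reference_counts()]).
#' @return data.frame of cases with columns `case_id`, `age_years`,
#'   `grade`, `rs`, `average`, `hotspot`, `hottest_spot`.
#' @export
expand_reference_table <- function(which, layout) {
  counts <- reference_counts(which, layout)
  age <- if (which == "age_lt50") 45 else 60
  rows <- expand.grid(level = rownames(counts),
                      rs_cat = colnames(counts),
                      stringsAsFactors = FALSE)
  rows$n <- as.vector(counts)
  rows <- rows[rows$n > 0, , drop = FALSE]
  rec <- rows[rep(seq_len(nrow(rows)), rows$n), c("level", "rs_cat")]
  out <- data.frame(
    case_id = sprintf("%s_%s_%03d", which, layout, seq_len(nrow(rec))),
    age_years = age,
    grade = 2L,
    rs = unname(rs_representative[rec$rs_cat]),
    average = 15, hotspot = 25, hottest_spot = 25,
    stringsAsFactors = FALSE)
  if (layout %in% c("average", "hotspot", "hottest_spot")) {
    out[[layout]] <- unname(bin_midpoint[rec$level])
  } else if (layout == "grade") {
    out$grade <- as.integer(rec$level)
  } else if (layout == "combined") {
    out$grade <- ifelse(rec$level == "low", 1L, 2L)
  }
  rownames(out) <- NULL
  out
}
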