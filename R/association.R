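#' Validate a cohort table
#'
#' A cohort table carries, per sample: `sample_id`, `vd_z` (Z-scored serum
#' 25(OH)D), `supplementing` (logical), `dose` (IU/day, 0 when not
#' supplementing), `bmi` (kg/m2), `age` (years), `sex` (factor or 0/1,
#' female = 1 in generated data), `ms_status` (logical), and optionally
#' `grs_z`.
#'
#' @param cohort A data frame.
#' @return The cohort, invisibly, after validation.
#' @export
validate_cohort <- function(cohort) {
  required <- c("sample_id", "vd_z", "supplementing", "dose", "bmi", "age",
                "sex", "ms_status")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$sample_id)) {
    stop("duplicate sample_id in cohort table", call. = FALSE)
  }
  bad_dose <- !is.na(cohort$dose) & cohort$dose > 0 & !cohort$supplementing
  if (any(bad_dose)) {
    stop(sum(bad_dose), " sample(s) have dose > 0 but supplementing = FALSE",
         call. = FALSE)
  }
  invisible(cohort)
}

#' Fit an ordinary least squares model and tidy its terms
#'
#' Complete-case OLS with intercept; two-sided t-test p-values. The number
#' of excluded incomplete cases is reported via a message and recorded in
#' the `n_excluded` attribute.
#'
#' @param cohort A validated cohort table.
#' @param response Response column name.
#' @param terms Character vector of predictor column names.
#' @param stratum Label recorded on each output row.
#' @return A tibble: `term`, `stratum`, `estimate`, `se`, `p`, `n`,
#'   `covariates`, with attributes `fit` (the `lm` object), `adj_r2`, and
#'   `n_excluded`.
#' @export
fit_linear_model <- function(cohort, response, terms, stratum = "all") {
  stopifnot(all(c(response, terms) %in% names(cohort)))
  dat <- cohort[, c(response, terms), drop = FALSE]
  cc <- stats::complete.cases(dat)
  n_excluded <- sum(!cc)
  if (n_excluded > 0) {
    message("fit_linear_model: excluding ", n_excluded, " incomplete case(s)")
  }
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < length(terms) + 2L) {
    stop("too few complete cases (", nrow(dat), ") for ", length(terms),
         " term(s)", call. = FALSE)
  }
  fml <- stats::reformulate(terms, response = response)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design: collinear term(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  out <- tibble::tibble(
    term = rownames(co), stratum = stratum,
    estimate = unname(co[, "Estimate"]), se = unname(co[, "Std. Error"]),
    p = unname(co[, "Pr(>|t|)"]), n = nrow(dat),
    covariates = paste(terms, collapse = "+")
  )
  attr(out, "fit") <- fit
  attr(out, "adj_r2") <- sm$adj.r.squared
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Screen candidate predictors of vitamin D with an FDR correction
#'
#' Each candidate is tested in its own age- and sex-adjusted linear model of
#' `vd_z`; the candidate-term p-values are then corrected across candidates
#' by the Benjamini-Hochberg step-up procedure, and candidates with
#' q < `fdr` are flagged. The special candidate `"dose"` enters as
#' `log(dose + 1)` and is assessed among supplementers only, since dose is
#' undefined off supplement.
#'
#' @param cohort A validated cohort table.
#' @param candidates Character vector of candidate predictor columns
#'   (default: supplementation, dose, BMI, MS status, and `grs_z` if
#'   present).
#' @param fdr False-discovery-rate threshold for the `significant` flag.
#' @return A tibble with one row per candidate: `term`, `estimate`, `se`,
#'   `p`, `q`, `n`, `significant`.
#' @export
screen_predictors <- function(cohort, candidates = NULL, fdr = 0.05) {
  validate_cohort(cohort)
  if (is.null(candidates)) {
    candidates <- c("supplementing", "dose", "bmi", "ms_status")
    if ("grs_z" %in% names(cohort)) candidates <- c("grs_z", candidates)
  }
  rows <- lapply(candidates, function(cand) {
    dat <- cohort
    # lm() renames logical terms (e.g. supplementingTRUE); fit on 0/1 instead
    for (col in candidates) {
      if (is.logical(dat[[col]])) dat[[col]] <- as.integer(dat[[col]])
    }
    term_name <- cand
    if (cand == "dose") {
      dat <- dat[dat$supplementing %in% TRUE, , drop = FALSE]
      dat$log_dose <- log(dat$dose + 1)
      term_name <- "log_dose"
    }
    fit <- fit_linear_model(dat, "vd_z", c(term_name, "age", "sex"))
    row <- fit[fit$term == term_name, c("estimate", "se", "p", "n")]
    tibble::tibble(term = cand, estimate = row$estimate, se = row$se,
                   p = row$p, n = row$n)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out[order(out$p), ]
}

#' Multivariable and supplementation-stratified GRS association models
#'
#' Fits the covariate-adjusted model
#' `vd_z ~ grs_z + age + sex + bmi + supplementing + ms_status` on the full
#' cohort, and `vd_z ~ grs_z + age + sex + bmi (+ ms_status)` separately
#' within supplementers and non-supplementers (the supplementation
#' indicator is constant within a stratum and is dropped there; `ms_status`
#' is retained unless constant). Strata with too few samples are skipped
#' with a warning.
#'
#' @param cohort A validated cohort table with `grs_z` populated.
#' @param min_n Minimum stratum size to attempt a fit.
#' @return A tibble of model terms from all fitted strata, with `stratum`
#'   in `"all"`, `"supplementers"`, `"non-supplementers"`.
#' @export
grs_association <- function(cohort, min_n = 20) {
  validate_cohort(cohort)
  if (!"grs_z" %in% names(cohort)) {
    stop("cohort table lacks grs_z; score the cohort first", call. = FALSE)
  }
  base_terms <- c("grs_z", "age", "sex", "bmi")
  # constant columns (e.g. ms_status in a control-only cohort) are dropped
  varying <- Filter(function(tm) length(unique(cohort[[tm]])) > 1L,
                    c("supplementing", "ms_status"))
  full <- fit_linear_model(cohort, "vd_z", c(base_terms, varying),
                           stratum = "all")
  pieces <- list(full)
  strata <- list(supplementers = cohort[cohort$supplementing %in% TRUE, ],
                 `non-supplementers` = cohort[!(cohort$supplementing %in% TRUE), ])
  for (nm in names(strata)) {
    sub <- strata[[nm]]
    if (nrow(sub) < min_n) {
      warning("stratum '", nm, "' skipped: only ", nrow(sub), " sample(s)",
              call. = FALSE)
      next
    }
    terms <- base_terms
    if (length(unique(sub$ms_status)) > 1L) terms <- c(terms, "ms_status")
    pieces <- c(pieces, list(fit_linear_model(sub, "vd_z", terms, stratum = nm)))
  }
  do.call(rbind, pieces)
}

#' Adjusted R-squared gain from adding the GRS to the covariate model
#'
#' Compares `vd_z ~ age + sex + bmi + supplementing + ms_status` with the
#' same model plus `grs_z`, using the usual `(n - 1) / (n - p - 1)`
#' adjustment.
#'
#' @param cohort A validated cohort table with `grs_z`.
#' @return A list: `r2_base`, `r2_full`, `delta`.
#' @export
adjusted_r2_delta <- function(cohort) {
  validate_cohort(cohort)
  base_terms <- c("age", "sex", "bmi",
                  Filter(function(tm) length(unique(cohort[[tm]])) > 1L,
                         c("supplementing", "ms_status")))
  base <- fit_linear_model(cohort, "vd_z", base_terms)
  full <- fit_linear_model(cohort, "vd_z", c(base_terms, "grs_z"))
  r2b <- attr(base, "adj_r2"); r2f <- attr(full, "adj_r2")
  list(r2_base = r2b, r2_full = r2f, delta = r2f - r2b)
}

#' Case-control genotype distribution chi-square test
#'
#' Pearson chi-square on the 2 x 3 (case/control by genotype) contingency
#' table, without continuity correction. Genotype classes absent from both
#' groups are collapsed, reducing the degrees of freedom accordingly.
#'
#' @param case_counts,control_counts Length-3 non-negative genotype counts
#'   (0, 1, 2 copies of the effect allele).
#' @return A list: `statistic`, `df`, `p`.
#' @export
genotype_distribution_test <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == 3L, length(control_counts) == 3L)
  tab <- rbind(case = as.numeric(case_counts),
               control = as.numeric(control_counts))
  if (any(tab < 0)) stop("genotype counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("all genotype counts are zero", call. = FALSE)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0)) {
    # no heterogeneity is testable with a single genotype class or empty group
    return(list(statistic = 0, df = 0L, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Plot the supplementation-stratified GRS association
#'
#' Scatter of covariate-adjusted, Z-scored vitamin D against the GRS
#' Z-score, with an OLS fit line, panelled by supplementation stratum.
#' Vitamin D is residualized on BMI, age, sex and MS status before
#' plotting so the panels show the adjusted relationship.
#'
#' @param cohort A validated cohort table with `grs_z`.
#' @return A ggplot object.
#' @export
plot_stratified_association <- function(cohort) {
  validate_cohort(cohort)
  covars <- c("bmi", "age", "sex")
  if (length(unique(cohort$ms_status)) > 1L) covars <- c(covars, "ms_status")
  fml <- stats::reformulate(covars, response = "vd_z")
  cohort$vd_adj <- stats::residuals(stats::lm(fml, data = cohort))
  cohort$stratum <- ifelse(cohort$supplementing %in% TRUE,
                           "supplementers", "non-supplementers")
  ggplot2::ggplot(cohort, ggplot2::aes(x = grs_z, y = vd_adj)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "#2166ac") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "GRS (Z-score)",
                  y = "Serum 25(OH)D (Z-score, covariate-adjusted)") +
    ggplot2::theme_bw()
}
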