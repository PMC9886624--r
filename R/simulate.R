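#' Default effect-allele frequencies for the six-variant panel
#'
#' Approximate European-ancestry effect-allele frequencies for the packaged
#' panel, chosen from public reference-panel ranges and documented in the
#' methods vignette. They are the generator's defaults, not estimates from
#' any study cohort.
#'
#' @return Named numeric vector of effect-allele frequencies.
#' @export
default_allele_freqs <- function() {
  c(rs10745742 = 0.40, rs12785878 = 0.75, rs10741657 = 0.40,
    rs17216707 = 0.79, rs8018720 = 0.82, rs2282679 = 0.72)
}

#' Expected phenotypic variance explained by the score
#'
#' Under Hardy-Weinberg and linkage equilibrium, a variant with effect-allele
#' frequency p and per-allele effect beta (on a phenotype of unit variance)
#' contributes additive genetic variance 2 p (1 - p) beta^2; the score's
#' expected variance explained is the sum over variants.
#'
#' @param freqs Effect-allele frequencies in (0, 1) (boundary values allowed
#'   for degenerate test cases).
#' @param betas Per-allele effects on the Z-score scale, same length/order.
#' @return Fraction of phenotypic variance explained.
#' @export
expected_variance_explained <- function(freqs = default_allele_freqs(),
                                        betas = NULL) {
  if (is.null(betas)) {
    wt <- default_weight_table()
    betas <- vapply(wt$entries, `[[`, numeric(1), "beta")[match(names(freqs), weight_rsids(wt))]
  }
  stopifnot(length(freqs) == length(betas), all(freqs >= 0 & freqs <= 1))
  sum(2 * freqs * (1 - freqs) * betas^2)
}

score_moments <- function(freqs, betas) {
  list(mean = sum(2 * freqs * betas),
       sd = sqrt(sum(2 * freqs * (1 - freqs) * betas^2)))
}

#' Build and validate a simulation configuration
#'
#' Defines the generative model for a synthetic cohort: Hardy-Weinberg
#' genotypes at the panel loci; supplementation drawn with MS- and
#' control-specific prevalence; log-normal doses with group-specific
#' medians; Gaussian BMI and age, Bernoulli sex; and a vitamin D phenotype
#' assembled in one of two modes.
#'
#' In `"additive"` mode every sample receives
#' `genetic + dose_effect * log(dose + 1) * supplementing + covariates +
#' noise`. In `"titration"` mode supplementers instead receive
#' `titration_target + titration_genetic_attenuation * genetic + noise`,
#' emulating dosing toward a target level that masks genetic and covariate
#' determinants; non-supplementers follow the additive form without the
#' dose term. The phenotype is finally Z-scored cohort-wide.
#'
#' The genetic term is the raw weighted score `g = sum_j X_j beta_j` when
#' `grs_effect_sd` is `NULL`; otherwise `g` is standardized by its analytic
#' Hardy-Weinberg moments and scaled to `grs_effect_sd`, so the true effect
#' per SD of the score is set directly.
#'
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param n_ms,n_control Cohort sizes by MS status.
#' @param allele_freqs Named effect-allele frequencies for the panel.
#' @param betas Per-allele weights aligned with `allele_freqs` (default:
#'   the packaged weight table).
#' @param supp_prob_ms,supp_prob_control Supplementation prevalence by group.
#' @param dose_median_ms,dose_median_control Median dose (IU/day) among
#'   supplementers, by group; doses are log-normal, so the median equals
#'   `exp(meanlog)`.
#' @param dose_log_sd Log-scale SD of the dose distribution.
#' @param mode `"additive"` or `"titration"`.
#' @param grs_effect_sd True phenotype effect (in SD) per SD of the score,
#'   or `NULL` to use the raw weighted score.
#' @param covariate_effects Named list with elements `bmi` (per kg/m2),
#'   `age` (per year), `sex` (female vs male), `ms` (MS vs control), each
#'   on the vitamin D Z-score scale; covariates enter centered at their
#'   generative means.
#' @param dose_effect Z-score per unit `log(dose + 1)` (additive mode).
#' @param noise_sd Residual SD; must be positive.
#' @param titration_target Level (Z-score scale) supplementers titrate
#'   toward.
#' @param titration_genetic_attenuation Multiplier in \[0, 1\] on the
#'   genetic term among supplementers in titration mode (0 = fully masked).
#' @param bmi_mean,bmi_sd,age_mean,age_sd Covariate distributions.
#' @param female_prob_ms,female_prob_control Probability of female sex.
#' @param vd_mean_nmol,vd_sd_nmol Back-transform used only to write a
#'   nmol/L column alongside the modelled Z-scores.
#' @return A validated list of class `vd_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ms = 315L, n_control = 232L,
                       allele_freqs = default_allele_freqs(),
                       betas = NULL,
                       supp_prob_ms = 0.711, supp_prob_control = 0.267,
                       dose_median_ms = 1200, dose_median_control = 571,
                       dose_log_sd = 0.5,
                       mode = c("titration", "additive"),
                       grs_effect_sd = 0.17,
                       covariate_effects = list(bmi = -0.03, age = 0.01,
                                                sex = 0.05, ms = 0),
                       dose_effect = 0.05,
                       noise_sd = 0.6,
                       titration_target = 0.97,
                       titration_genetic_attenuation = 0,
                       bmi_mean = 27, bmi_sd = 4.5,
                       age_mean = 55, age_sd = 12,
                       female_prob_ms = 0.74, female_prob_control = 0.75,
                       vd_mean_nmol = 50, vd_sd_nmol = 20) {
  mode <- match.arg(mode)
  if (is.null(betas)) {
    wt <- default_weight_table()
    betas <- stats::setNames(vapply(wt$entries, `[[`, numeric(1), "beta"),
                             weight_rsids(wt))[names(allele_freqs)]
    if (anyNA(betas)) {
      stop("allele_freqs names must match the packaged panel when betas ",
           "are not supplied", call. = FALSE)
    }
  }
  probs <- c(supp_prob_ms, supp_prob_control, female_prob_ms,
             female_prob_control)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    stop("allele frequencies must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (titration_genetic_attenuation < 0 || titration_genetic_attenuation > 1) {
    stop("titration_genetic_attenuation must lie in [0, 1]", call. = FALSE)
  }
  if (n_ms + n_control < 1) stop("cohort size must be at least 1", call. = FALSE)
  stopifnot(length(betas) == length(allele_freqs))
  cfg <- list(seed = as.integer(seed), n_ms = as.integer(n_ms),
              n_control = as.integer(n_control),
              allele_freqs = allele_freqs, betas = betas,
              supp_prob_ms = supp_prob_ms,
              supp_prob_control = supp_prob_control,
              dose_median_ms = dose_median_ms,
              dose_median_control = dose_median_control,
              dose_log_sd = dose_log_sd, mode = mode,
              grs_effect_sd = grs_effect_sd,
              covariate_effects = covariate_effects,
              dose_effect = dose_effect, noise_sd = noise_sd,
              titration_target = titration_target,
              titration_genetic_attenuation = titration_genetic_attenuation,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              age_mean = age_mean, age_sd = age_sd,
              female_prob_ms = female_prob_ms,
              female_prob_control = female_prob_control,
              vd_mean_nmol = vd_mean_nmol, vd_sd_nmol = vd_sd_nmol)
  structure(cfg, class = "vd_sim_config")
}

#' Study-like cohort preset
#'
#' Emulates a multiple-sclerosis case-control study of 315 cases and 232
#' matched controls: supplementation prevalence 71.1% (MS) vs 26.7%
#' (control), median doses 1200 vs 571 IU/day, titration-mode phenotype
#' with calibrated covariate effects and noise. The calibration (see the
#' methods vignette and `scripts/calibrate_study_preset.R`) sets the
#' supplementer target level and residual SD so the covariate-only model
#' explains about 37% of adjusted variance and the score adds roughly
#' 0.01-0.02, with a full-cohort multivariable score coefficient near
#' 0.1 SD per SD.
#'
#' @param seed Integer seed.
#' @param n_ms,n_control Cohort sizes (defaults as in the emulated study).
#' @param ... Overrides passed to [sim_config()].
#' @return A `vd_sim_config`.
#' @export
study_preset <- function(seed = 1L, n_ms = 315L, n_control = 232L, ...) {
  sim_config(seed = seed, n_ms = n_ms, n_control = n_control,
             mode = "titration", ...)
}

#' Biobank-like cohort preset
#'
#' Emulates a large population cohort without MS: supplementation
#' prevalence 5.1%, no dose information (dose effect 0), additive-mode
#' phenotype with the true per-SD score effect set directly and residual
#' noise chosen so the phenotype has unit variance (the validation
#' regression is unadjusted, so non-genetic structure is absorbed into the
#' residual).
#'
#' @param seed Integer seed.
#' @param n Cohort size (all controls); the emulated cohort is two orders
#'   of magnitude larger, scaled down for desk runs.
#' @param grs_effect_sd True phenotype SD per score SD.
#' @param supp_prob Supplementation prevalence.
#' @param ... Overrides passed to [sim_config()].
#' @return A `vd_sim_config`.
#' @export
ukb_preset <- function(seed = 1L, n = 50000L, grs_effect_sd = 0.14,
                       supp_prob = 0.051, ...) {
  sim_config(seed = seed, n_ms = 0L, n_control = n,
             mode = "additive", grs_effect_sd = grs_effect_sd,
             supp_prob_ms = supp_prob, supp_prob_control = supp_prob,
             covariate_effects = list(bmi = 0, age = 0, sex = 0, ms = 0),
             dose_effect = 0,
             noise_sd = sqrt(1 - grs_effect_sd^2),
             age_mean = 58, age_sd = 9,
             female_prob_ms = 0.533, female_prob_control = 0.533, ...)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each variant is drawn independently; per-sample dosages are
#' Binomial(2, freq) effect-allele counts.
#'
#' @param n Number of samples.
#' @param freqs Named effect-allele frequencies in \[0, 1\].
#' @param seed Optional integer seed (omit when called inside a seeded
#'   simulation).
#' @param weights Optional [weight_table()] supplying REF/ALT alleles for
#'   the variant metadata; defaults to the packaged table when the names
#'   match, otherwise synthetic A/G pairs are recorded.
#' @return An oriented [dosage_matrix()] of hard calls.
#' @export
simulate_genotypes <- function(n, freqs, seed = NULL, weights = NULL) {
  stopifnot(n >= 1, all(freqs >= 0 & freqs <= 1))
  if (!is.null(seed)) set.seed(seed)
  rsids <- names(freqs)
  if (is.null(rsids)) rsids <- paste0("snp", seq_along(freqs))
  dm <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  if (n == 1L) dm <- matrix(dm, nrow = 1L)
  dimnames(dm) <- list(sprintf("S%05d", seq_len(n)), rsids)
  ref <- rep("A", length(rsids)); alt <- rep("G", length(rsids))
  if (is.null(weights)) {
    wt <- tryCatch(default_weight_table(), error = function(e) NULL)
    if (!is.null(wt) && all(rsids %in% weight_rsids(wt))) weights <- wt
  }
  if (!is.null(weights)) {
    idx <- match(rsids, weight_rsids(weights))
    ok <- !is.na(idx)
    ref[ok] <- vapply(weights$entries[idx[ok]], `[[`, character(1), "other_allele")
    alt[ok] <- vapply(weights$entries[idx[ok]], `[[`, character(1), "effect_allele")
  }
  meta <- data.frame(rsid = rsids, ref = ref, alt = alt, info = NA_real_,
                     stringsAsFactors = FALSE)
  dosage_matrix(dm, meta, oriented = TRUE)
}

#' Simulate a full cohort: genotypes plus phenotype table
#'
#' See [sim_config()] for the generative model. The returned phenotype
#' table contains the cohort-wide Z-scored vitamin D (`vd_z`), a nmol/L
#' back-transform (`vd_nmol`), supplementation, dose, BMI, age, sex
#' (1 = female), and MS status. The raw genetic value and the generative
#' truth are attached for parameter-recovery checks.
#'
#' @param config A `vd_sim_config` from [sim_config()] or a preset.
#' @return A list: `genotypes` (a [dosage_matrix()]), `cohort` (a tibble),
#'   `truth` (list of generative parameters, including the genetic values).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "vd_sim_config"))
  set.seed(config$seed)
  n <- config$n_ms + config$n_control
  ms <- c(rep(TRUE, config$n_ms), rep(FALSE, config$n_control))

  genotypes <- simulate_genotypes(n, config$allele_freqs, seed = NULL)
  g_raw <- as.numeric(genotypes$dosages %*% config$betas)
  if (!is.null(config$grs_effect_sd)) {
    mom <- score_moments(config$allele_freqs, config$betas)
    genetic <- config$grs_effect_sd * (g_raw - mom$mean) / mom$sd
  } else {
    genetic <- g_raw
  }

  supp_prob <- ifelse(ms, config$supp_prob_ms, config$supp_prob_control)
  supplementing <- stats::runif(n) < supp_prob
  dose <- numeric(n)
  meanlog <- ifelse(ms, log(config$dose_median_ms),
                    log(config$dose_median_control))
  dose[supplementing] <- stats::rlnorm(sum(supplementing),
                                       meanlog = meanlog[supplementing],
                                       sdlog = config$dose_log_sd)
  dose <- round(dose)

  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  female_prob <- ifelse(ms, config$female_prob_ms, config$female_prob_control)
  sex <- as.integer(stats::runif(n) < female_prob) # 1 = female

  ce <- config$covariate_effects
  cov_term <- ce$bmi * (bmi - config$bmi_mean) +
    ce$age * (age - config$age_mean) +
    ce$sex * sex + ce$ms * ms
  noise <- stats::rnorm(n, 0, config$noise_sd)

  if (config$mode == "additive") {
    vd <- genetic + config$dose_effect * log(dose + 1) * supplementing +
      cov_term + noise
  } else {
    vd <- ifelse(
      supplementing,
      config$titration_target +
        config$titration_genetic_attenuation * genetic + noise,
      genetic + cov_term + noise
    )
  }
  vd_z <- zscore(vd)

  cohort <- tibble::tibble(
    sample_id = sample_ids(genotypes),
    vd_z = vd_z,
    vd_nmol = config$vd_mean_nmol + config$vd_sd_nmol * vd_z,
    supplementing = supplementing,
    dose = dose,
    bmi = bmi, age = age, sex = sex,
    ms_status = ms
  )
  list(genotypes = genotypes, cohort = cohort,
       truth = list(genetic = genetic, g_raw = g_raw,
                    grs_effect_sd = config$grs_effect_sd,
                    vd_raw_sd = stats::sd(vd),
                    mode = config$mode, config = config))
}
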