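#' Flip negative weights to the non-effect allele
#'
#' For entries with a negative beta, the non-effect allele's copy number is
#' counted instead so that all effect sizes are positive: effect and other
#' alleles are swapped and beta is negated. On complete genotypes the two
#' parameterizations give raw scores differing only by the constant
#' 2 * sum(|beta|) over the flipped entries, so Z-scored results are
#' identical.
#'
#' @param weights A [weight_table()].
#' @return A [weight_table()] with all betas positive.
#' @export
flip_negative_weights <- function(weights) {
  stopifnot(inherits(weights, "weight_table"))
  entries <- lapply(weights$entries, function(w) {
    if (w$beta >= 0) return(w)
    variant_weight(w$rsid, effect_allele = w$other_allele,
                   other_allele = w$effect_allele, beta = -w$beta,
                   gene_label = w$gene_label, proxy = w$proxy)
  })
  weight_table(entries)
}

#' Z-score a numeric vector
#'
#' Centers and scales by the sample (n - 1) standard deviation; `NA`s
#' propagate and are excluded from the reference mean and SD.
#'
#' @param values Numeric vector with at least two non-missing values.
#' @return Numeric vector with mean 0 and SD 1 over the non-missing entries.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    stop("zscore needs at least two non-missing values", call. = FALSE)
  }
  s <- stats::sd(values[ok])
  if (s == 0) stop("zscore undefined: zero variance", call. = FALSE)
  (values - mean(values[ok])) / s
}

#' Compute per-sample weighted genetic risk scores
#'
#' Raw score of sample i is `sum_j X_ij * beta_j` over the panel variants,
#' with `X` the effect-allele dosage. Missing dosages are handled per
#' `missing_policy`:
#' \describe{
#'   \item{`"mean"`}{(default) impute 2 x effect-allele frequency, the
#'     frequency estimated from non-missing samples;}
#'   \item{`"exclude"`}{drop the variant from that sample's sum
#'     (equivalent to imputing dosage 0);}
#'   \item{`"drop"`}{samples with any missing dosage get an `NA` score.}
#' }
#' Samples with every dosage missing are flagged absent (`NA` score) under
#' all policies.
#'
#' @param matrix An oriented [dosage_matrix()] whose columns match the
#'   weight table after proxy resolution.
#' @param weights A [weight_table()].
#' @param missing_policy One of `"mean"`, `"exclude"`, `"drop"`.
#' @return A tibble: `sample_id`, `raw_grs`, `n_variants_used`, `n_imputed`.
#' @export
compute_raw_score <- function(matrix, weights,
                              missing_policy = c("mean", "exclude", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(matrix, "dosage_matrix"), inherits(weights, "weight_table"))
  if (!matrix$oriented) {
    stop("dosage matrix must be oriented to effect alleles first ",
         "(see orient_dosages())", call. = FALSE)
  }
  resolved <- resolve_proxies(weights, variant_ids(matrix))
  rsids <- weight_rsids(resolved)
  absent <- setdiff(rsids, variant_ids(matrix))
  if (length(absent)) {
    stop("panel variant(s) absent from dosage matrix after proxy ",
         "resolution: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  dm <- matrix$dosages[, rsids, drop = FALSE]
  beta <- vapply(resolved$entries, `[[`, numeric(1), "beta")

  miss <- is.na(dm)
  all_missing <- rowSums(!miss) == 0L
  n_used <- rowSums(!miss)
  n_imputed <- integer(nrow(dm))

  filled <- dm
  if (missing_policy == "mean") {
    eaf2 <- colMeans(dm, na.rm = TRUE) # = 2 * effect-allele frequency
    for (j in seq_len(ncol(dm))) {
      mj <- miss[, j]
      if (any(mj)) filled[mj, j] <- eaf2[j]
    }
    n_imputed <- rowSums(miss)
    n_used <- rep.int(ncol(dm), nrow(dm))
  } else if (missing_policy == "exclude") {
    filled[miss] <- 0
  } # "drop": leave NAs so the sum propagates

  raw <- as.numeric(filled %*% beta)
  raw[all_missing] <- NA_real_
  if (missing_policy == "mean") n_used[all_missing] <- 0L

  tibble::tibble(sample_id = sample_ids(matrix), raw_grs = raw,
                 n_variants_used = as.integer(n_used),
                 n_imputed = as.integer(n_imputed))
}

#' Compute raw and Z-scored genetic risk scores
#'
#' Convenience wrapper: [compute_raw_score()] followed by [zscore()] of the
#' raw scores within the scored cohort. The Z-score reference is the cohort
#' being scored — strata analysed later reuse these whole-cohort Z-scores.
#'
#' @inheritParams compute_raw_score
#' @return A tibble: `sample_id`, `raw_grs`, `grs_z`, `n_variants_used`,
#'   `n_imputed`.
#' @export
compute_grs <- function(matrix, weights,
                        missing_policy = c("mean", "exclude", "drop")) {
  res <- compute_raw_score(matrix, weights, missing_policy = missing_policy)
  res$grs_z <- zscore(res$raw_grs)
  res[, c("sample_id", "raw_grs", "grs_z", "n_variants_used", "n_imputed")]
}
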