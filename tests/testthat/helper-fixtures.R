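# Shared builders for small in-code fixtures.

# A dosage matrix with explicit values; variants default to the packaged
# panel's allele pairs when rsids match, A/G otherwise.
make_matrix <- function(dosages, rsids = colnames(dosages),
                        ref = NULL, alt = NULL, info = NA_real_,
                        oriented = TRUE) {
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- rsids
  wt <- default_weight_table()
  wt_df <- as.data.frame(wt)
  idx <- match(rsids, wt_df$rsid)
  if (is.null(ref)) ref <- ifelse(is.na(idx), "A", wt_df$other_allele[idx])
  if (is.null(alt)) alt <- ifelse(is.na(idx), "G", wt_df$effect_allele[idx])
  meta <- data.frame(rsid = rsids, ref = ref, alt = alt,
                     info = rep_len(info, length(rsids)),
                     stringsAsFactors = FALSE)
  dosage_matrix(dosages, meta, oriented = oriented)
}

# Write a tiny hard-call VCF; genotypes is a samples x variants matrix of
# ALT dosages (NA = missing call).
write_tiny_vcf <- function(genotypes, rsids, ref, alt, path = tempfile(fileext = ".vcf"),
                           info = rep(NA_real_, length(rsids))) {
  meta <- data.frame(rsid = rsids, ref = ref, alt = alt, info = info,
                     stringsAsFactors = FALSE)
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("S%03d", seq_len(nrow(genotypes)))
  }
  colnames(genotypes) <- rsids
  write_vcf(dosage_matrix(genotypes, meta, oriented = FALSE), path)
  path
}

# A small complete cohort table with known structure for model tests.
make_cohort <- function(n = 200, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    grs_z = rnorm(n),
    supplementing = runif(n) < 0.5,
    bmi = rnorm(n, 27, 4),
    age = rnorm(n, 55, 10),
    sex = rbinom(n, 1, 0.5),
    ms_status = runif(n) < 0.5,
    dose = 0,
    vd_z = NA_real_
  )
}

table1_betas <- c(rs10745742 = 0.017, rs12785878 = 0.036, rs10741657 = 0.031,
                  rs17216707 = 0.026, rs8018720 = -0.017, rs2282679 = -0.089)
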