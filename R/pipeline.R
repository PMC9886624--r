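#' Write a dosage matrix as a minimal VCF
#'
#' Serializes hard-call matrices with a `GT` FORMAT field and fractional
#' (imputed-style) matrices with `DS`. Variant REF/ALT come from the
#' matrix metadata; for oriented matrices ALT is the effect allele.
#' Positions are synthetic placeholders (the pipeline matches variants by
#' ID, not position).
#'
#' @param matrix A [dosage_matrix()].
#' @param path Output `.vcf` path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "dosage_matrix"))
  dm <- matrix$dosages
  meta <- matrix$variant_meta
  hard <- all(dm[!is.na(dm)] %in% c(0, 1, 2))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vdgrs",
    if (hard) '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
    else '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated ALT dose">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dm)), collapse = "\t")
  )
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(dm)), function(j) {
    x <- dm[, j]
    calls <- if (hard) {
      out <- gt_code[as.character(x)]
      out[is.na(x)] <- "./."
      out
    } else {
      out <- formatC(x, digits = 3, format = "f")
      out[is.na(x)] <- "."
      out
    }
    info <- if (!is.na(meta$info[j])) sprintf("INFO=%g", meta$info[j]) else "."
    paste(c("1", as.character(j * 1000L), meta$rsid[j], meta$ref[j],
            meta$alt[j], ".", "PASS", info, if (hard) "GT" else "DS", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(dir, stage, seed = NA, inputs = character(),
                           counts = list(), extra = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(stage = stage,
                     package = "vdgrs",
                     version = as.character(utils::packageVersion("vdgrs")),
                     seed = seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     input_md5 = digests,
                     counts = counts),
                extra)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a synthetic cohort and write it to disk
#'
#' Writes `genotypes.vcf` (hard calls), `phenotypes.tsv`, a config
#' snapshot, and a run manifest with row/variant counts.
#'
#' @param config A `vd_sim_config` (see [sim_config()] and presets), or a
#'   path to a YAML file of [sim_config()] arguments.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list from [simulate_cohort()].
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- load_sim_config(config)
  stopifnot(inherits(config, "vd_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  phe_path <- file.path(out_dir, "phenotypes.tsv")
  write_vcf(sim$genotypes, vcf_path)
  write_tsv(sim$cohort, phe_path)
  cfg <- unclass(config)
  cfg$allele_freqs <- as.list(cfg$allele_freqs)
  cfg$betas <- as.list(cfg$betas)
  yaml::write_yaml(cfg, file.path(out_dir, "sim_config.yaml"))
  write_manifest(out_dir, "simulate", seed = config$seed,
                 inputs = c(vcf_path, phe_path),
                 counts = list(samples = nrow(sim$cohort),
                               variants = ncol(sim$genotypes$dosages)))
  message("simulate: wrote ", nrow(sim$cohort), " samples x ",
          ncol(sim$genotypes$dosages), " variants to ", out_dir)
  invisible(sim)
}

#' Load a simulation config from YAML
#'
#' The YAML holds named [sim_config()] arguments; `allele_freqs`, `betas`
#' and `covariate_effects` may be nested maps. A `preset` key of
#' `"study"` or `"ukb"` selects [study_preset()] / [ukb_preset()] with the
#' remaining keys as overrides.
#'
#' @param path YAML file path.
#' @return A `vd_sim_config`.
#' @export
load_sim_config <- function(path) {
  args <- yaml::read_yaml(path)
  preset <- args$preset
  args$preset <- NULL
  for (nm in c("allele_freqs", "betas")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  fn <- switch(preset %||% "none",
               study = study_preset, ukb = ukb_preset, sim_config)
  do.call(fn, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a genotype file: QC, harmonization, GRS, Z-score
#'
#' Reads the genotypes, applies variant- and sample-level QC at the
#' standard thresholds, computes raw and Z-scored genetic risk scores, and
#' writes `scores.tsv`, `variant_qc.tsv`, `sample_qc.tsv` and a manifest.
#'
#' @param vcf Path to a VCF (or dosage TSV) file.
#' @param out_dir Output directory.
#' @param weights A [weight_table()] (default: the packaged panel).
#' @param allow_palindromic rsids whose strand-ambiguous weights are
#'   accepted; defaults to the packaged panel's assay-genotyped C/G variant
#'   rs8018720 (see the methods vignette).
#' @param missing_policy Passed to [compute_grs()].
#' @param qc Named list of QC threshold overrides for [apply_qc()].
#' @return Invisibly, a list with `scores`, `variant_report`,
#'   `sample_report`, and the filtered `matrix`.
#' @export
run_score <- function(vcf, out_dir, weights = default_weight_table(),
                      allow_palindromic = "rs8018720",
                      missing_policy = "mean", qc = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  matrix <- read_genotypes(vcf, weights, allow_palindromic = allow_palindromic)
  n0 <- dim(matrix)
  qc_res <- do.call(apply_qc, c(list(matrix), qc))
  n1 <- dim(qc_res$matrix)
  message("score: QC kept ", n1[1], "/", n0[1], " samples and ",
          n1[2], "/", n0[2], " variants")
  scores <- compute_grs(qc_res$matrix, weights, missing_policy = missing_policy)
  write_tsv(scores, file.path(out_dir, "scores.tsv"))
  write_tsv(qc_res$variant_report, file.path(out_dir, "variant_qc.tsv"))
  write_tsv(qc_res$sample_report, file.path(out_dir, "sample_qc.tsv"))
  write_manifest(out_dir, "score", inputs = vcf,
                 counts = list(samples_in = n0[1], samples_out = n1[1],
                               variants_in = n0[2], variants_out = n1[2]))
  invisible(list(scores = scores, variant_report = qc_res$variant_report,
                 sample_report = qc_res$sample_report,
                 matrix = qc_res$matrix))
}

#' Association stage: screen, multivariable models, stratified estimates
#'
#' Joins scores to phenotypes by `sample_id`, runs the age/sex-adjusted
#' predictor screen with BH-FDR, the multivariable and
#' supplementation-stratified score models, the adjusted R-squared
#' comparison, and (when genotypes are supplied) per-variant case/control
#' genotype-distribution chi-square tests. Writes result TSVs and a
#' stratified association figure.
#'
#' @param scores Path to a scores TSV (from [run_score()]) or a tibble.
#' @param phenotypes Path to a phenotype TSV (from [run_simulate()]) or a
#'   tibble.
#' @param out_dir Output directory.
#' @param genotypes Optional [dosage_matrix()] or VCF path for the
#'   genotype-distribution tests.
#' @param min_n Minimum joined sample count to proceed.
#' @return Invisibly, a list with `screen`, `models`, `r2`, and optionally
#'   `genotype_tests`.
#' @export
run_assoc <- function(scores, phenotypes, out_dir, genotypes = NULL,
                      min_n = 30) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(scores)) scores <- utils::read.delim(scores)
  if (is.character(phenotypes)) phenotypes <- utils::read.delim(phenotypes)
  cohort <- merge(phenotypes, scores[, c("sample_id", "grs_z")],
                  by = "sample_id")
  if (nrow(cohort) < min_n) {
    stop("joined cohort has only ", nrow(cohort), " samples (minimum ",
         min_n, ")", call. = FALSE)
  }
  cohort <- tibble::as_tibble(cohort)
  validate_cohort(cohort)

  screen <- screen_predictors(cohort)
  models <- grs_association(cohort)
  r2 <- adjusted_r2_delta(cohort)
  write_tsv(screen, file.path(out_dir, "predictor_screen.tsv"))
  write_tsv(models, file.path(out_dir, "grs_models.tsv"))
  write_tsv(tibble::tibble(model = c("covariates", "covariates+grs"),
                           adj_r2 = c(r2$r2_base, r2$r2_full)),
            file.path(out_dir, "adjusted_r2.tsv"))

  gtests <- NULL
  if (!is.null(genotypes)) {
    if (is.character(genotypes)) {
      genotypes <- read_genotypes(genotypes, default_weight_table(),
                                  allow_palindromic = "rs8018720")
    }
    dm <- genotypes$dosages[match(cohort$sample_id, rownames(genotypes$dosages)), ,
                            drop = FALSE]
    is_case <- cohort$ms_status %in% TRUE
    gtests <- do.call(rbind, lapply(colnames(dm), function(v) {
      cnt <- function(rows) {
        x <- dm[rows, v]; x <- x[!is.na(x)]
        c(sum(x == 0), sum(x == 1), sum(x == 2))
      }
      res <- genotype_distribution_test(cnt(is_case), cnt(!is_case))
      tibble::tibble(rsid = v, statistic = res$statistic, df = res$df,
                     p = res$p)
    }))
    write_tsv(gtests, file.path(out_dir, "genotype_distribution.tsv"))
  }

  fig <- plot_stratified_association(cohort)
  ggplot2::ggsave(file.path(out_dir, "stratified_association.png"), fig,
                  width = 7, height = 4, dpi = 150)
  write_manifest(out_dir, "assoc",
                 counts = list(samples = nrow(cohort)))
  message("assoc: ", nrow(cohort), " samples analysed; results in ", out_dir)
  invisible(list(screen = screen, models = models, r2 = r2,
                 genotype_tests = gtests, cohort = cohort))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate, score, and analyse in one call; each stage writes its own
#' outputs and manifest under `out_dir`.
#'
#' @param config A `vd_sim_config` or YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, the list from [run_assoc()].
#' @export
run_pipeline <- function(config, out_dir) {
  sim <- run_simulate(config, out_dir)
  sc <- run_score(file.path(out_dir, "genotypes.vcf"), out_dir)
  res <- run_assoc(sc$scores, file.path(out_dir, "phenotypes.tsv"), out_dir,
                   genotypes = sc$matrix)
  invisible(res)
}
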