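#' Construct a dosage matrix
#'
#' Samples-by-variants effect-allele (or ALT-allele, before orientation)
#' dosages in \[0, 2\], possibly fractional for imputed data, with `NA` for
#' missing calls. Per-variant metadata records the genotyped REF/ALT pair
#' and, when available, the imputation info score.
#'
#' @param dosages Numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = rsids).
#' @param variant_meta Data frame with columns `rsid`, `ref`, `alt` and
#'   optionally `info` (imputation quality in \[0, 1\]); one row per column
#'   of `dosages`, in the same order.
#' @param oriented Logical; `TRUE` once dosages count effect alleles (after
#'   [harmonize_alleles()]), `FALSE` while they still count ALT alleles.
#' @return A list of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variant_meta, oriented = FALSE) {
  stopifnot(is.matrix(dosages), is.numeric(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    stop("dosages must carry sample ids as rownames and rsids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(dosages))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(dosages))) stop("duplicate variant ids", call. = FALSE)
  rng <- range(dosages, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  stopifnot(is.data.frame(variant_meta),
            all(c("rsid", "ref", "alt") %in% names(variant_meta)),
            nrow(variant_meta) == ncol(dosages),
            identical(variant_meta$rsid, colnames(dosages)))
  if (is.null(variant_meta$info)) variant_meta$info <- NA_real_
  structure(list(dosages = dosages, variant_meta = variant_meta,
                 oriented = oriented),
            class = "dosage_matrix")
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("<dosage_matrix> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " variants (", if (x$oriented) "effect-allele" else "ALT-allele",
      " dosages)\n", sep = "")
  invisible(x)
}

sample_ids <- function(x) rownames(x$dosages)
variant_ids <- function(x) colnames(x$dosages)

#' Orient ALT-allele dosages to effect-allele dosages
#'
#' Resolves each weight against the genotyped variants (via proxies where
#' needed), harmonizes alleles against the stored REF/ALT pair, and rewrites
#' the matrix as effect-allele dosages in weight-table order.
#'
#' @param matrix A [dosage_matrix()] with `oriented = FALSE`.
#' @param weights A [weight_table()].
#' @param allow_palindromic Character vector of rsids whose strand-ambiguous
#'   weights may be used (see [harmonize_alleles()]).
#' @param strict If `TRUE`, a weight with neither target nor proxy genotyped
#'   is an error; if `FALSE` (the reading default) such weights are dropped
#'   with a warning and scoring fails later only if the panel stays
#'   incomplete.
#' @return A [dosage_matrix()] restricted to the panel variants, oriented.
#' @export
orient_dosages <- function(matrix, weights, allow_palindromic = character(),
                           strict = TRUE) {
  stopifnot(inherits(matrix, "dosage_matrix"), inherits(weights, "weight_table"))
  if (strict) {
    resolved <- resolve_proxies(weights, variant_ids(matrix))
  } else {
    entries <- list(); dropped <- character()
    for (w in weights$entries) {
      r <- tryCatch(resolve_proxy(w, variant_ids(matrix)),
                    error = function(e) NULL)
      if (is.null(r)) dropped <- c(dropped, w$rsid) else entries <- c(entries, list(r))
    }
    if (length(entries) == 0L) {
      stop("no panel variants (or proxies) genotyped", call. = FALSE)
    }
    if (length(dropped)) {
      warning("panel variant(s) not genotyped (no proxy either): ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    resolved <- weight_table(entries)
  }
  rsids <- weight_rsids(resolved)
  meta <- matrix$variant_meta
  cols <- lapply(seq_along(rsids), function(j) {
    rsid <- rsids[j]
    k <- match(rsid, meta$rsid)
    ori <- harmonize_alleles(resolved$entries[[j]], meta$ref[k], meta$alt[k],
                             allow_palindromic = allow_palindromic)
    if (ori$status %in% c("mismatch", "ambiguous_palindromic")) {
      stop("allele harmonization failed for ", rsid, ": status ", ori$status,
           " (weight ", resolved$entries[[j]]$effect_allele, "/",
           resolved$entries[[j]]$other_allele, " vs genotyped ",
           meta$ref[k], "/", meta$alt[k], ")", call. = FALSE)
    }
    apply_orientation(ori, matrix$dosages[, k], rsid)
  })
  dm <- do.call(cbind, cols)
  dimnames(dm) <- list(sample_ids(matrix), rsids)
  new_meta <- meta[match(rsids, meta$rsid), , drop = FALSE]
  rownames(new_meta) <- NULL
  out <- dosage_matrix(dm, new_meta, oriented = TRUE)
  attr(out, "resolved_weights") <- resolved
  out
}

parse_gt_dosage <- function(gt) {
  # "0/0" -> 0, "0|1" -> 1, "1/1" -> 2, "./." or NA -> NA
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || any(a == "." | is.na(a))) return(NA_real_)
    sum(as.numeric(a))
  }, numeric(1))
}

#' Read panel genotypes from a VCF or dosage TSV
#'
#' For VCF input, variants are matched to the weight table (or its proxies)
#' by ID; multi-allelic records are excluded with a warning; the `DS` FORMAT
#' field is preferred when present, otherwise hard `GT` calls are counted;
#' an imputation info score is read from the INFO column under `info_key`.
#' For TSV input (detected by file extension `.tsv`/`.txt`), the file must
#' be samples x variants with a `sample_id` column and rsid-named dosage
#' columns; allele orientation is then taken on trust as effect-allele
#' dosage and QC skips allele harmonization.
#'
#' Returned dosages are effect-allele counts (the VCF path applies
#' [orient_dosages()]).
#'
#' @param source Path to a `.vcf`/`.vcf.gz` or dosage `.tsv` file.
#' @param weights A [weight_table()].
#' @param allow_palindromic Passed to [orient_dosages()].
#' @param info_key INFO field key holding the imputation quality score;
#'   the first of the given keys found is used.
#' @return An oriented [dosage_matrix()].
#' @export
read_genotypes <- function(source, weights, allow_palindromic = character(),
                           info_key = c("INFO", "R2", "DR2")) {
  stopifnot(inherits(weights, "weight_table"))
  if (!file.exists(source)) stop("genotype file not found: ", source, call. = FALSE)
  if (grepl("\\.(tsv|txt)$", source, ignore.case = TRUE)) {
    return(read_dosage_tsv(source, weights))
  }
  vcf <- vcfR::read.vcfR(source, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", source, call. = FALSE)

  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning("excluding ", sum(multi), " multi-allelic record(s): ",
            paste(fix$ID[multi], collapse = ", "), call. = FALSE)
  }
  wanted <- unique(c(weight_rsids(weights),
                     unlist(lapply(weights$entries, function(w)
                       if (!is.null(w$proxy)) w$proxy$proxy_rsid))))
  keep <- !multi & fix$ID %in% wanted
  if (!any(keep)) {
    stop("no panel variants (or proxies) found in ", source, call. = FALSE)
  }

  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)
  if (is.null(ds) && is.null(gt)) {
    stop("VCF has neither DS nor GT FORMAT fields: ", source, call. = FALSE)
  }

  ids <- fix$ID[keep]
  n_samp <- ncol(vcf@gt) - 1L
  samp <- colnames(vcf@gt)[-1]
  dm <- matrix(NA_real_, nrow = n_samp, ncol = sum(keep),
               dimnames = list(samp, ids))
  rows <- which(keep)
  for (j in seq_along(rows)) {
    i <- rows[j]
    if (!is.null(ds) && !all(is.na(ds[i, ]))) {
      dm[, j] <- as.numeric(ds[i, ])
    } else if (!is.null(gt)) {
      dm[, j] <- parse_gt_dosage(gt[i, ])
    }
  }

  info <- rep(NA_real_, length(rows))
  for (key in info_key) {
    vals <- suppressWarnings(vcfR::extract.info(vcf, element = key,
                                                as.numeric = TRUE))
    if (!is.null(vals) && !all(is.na(vals[rows]))) {
      info <- as.numeric(vals[rows])
      break
    }
  }

  meta <- data.frame(rsid = ids, ref = fix$REF[keep], alt = fix$ALT[keep],
                     info = info, stringsAsFactors = FALSE)
  raw <- dosage_matrix(dm, meta, oriented = FALSE)
  orient_dosages(raw, weights, allow_palindromic = allow_palindromic,
                 strict = FALSE)
}

#' Read a dosage TSV (samples x variants, effect-allele dosages)
#'
#' @param path TSV with a `sample_id` column and one rsid-named numeric
#'   column per variant; empty cells or `NA` mark missing dosages.
#' @param weights A [weight_table()]; columns are matched by rsid (or proxy).
#' @return An oriented [dosage_matrix()] (orientation taken on trust; the
#'   per-variant alleles are recorded as the weight's other/effect pair).
#' @export
read_dosage_tsv <- function(path, weights) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("dosage TSV must have a sample_id column", call. = FALSE)
  }
  resolved <- resolve_proxies(weights, setdiff(names(df), "sample_id"))
  rsids <- weight_rsids(resolved)
  missing_v <- setdiff(rsids, names(df))
  if (length(missing_v)) {
    stop("dosage TSV lacks panel variant(s): ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  dm <- as.matrix(df[, rsids, drop = FALSE])
  storage.mode(dm) <- "double"
  rownames(dm) <- as.character(df$sample_id)
  meta <- data.frame(
    rsid = rsids,
    ref = vapply(resolved$entries, `[[`, character(1), "other_allele"),
    alt = vapply(resolved$entries, `[[`, character(1), "effect_allele"),
    info = NA_real_, stringsAsFactors = FALSE
  )
  out <- dosage_matrix(dm, meta, oriented = TRUE)
  attr(out, "resolved_weights") <- resolved
  out
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the Hardy-Weinberg expectations computed from the sample allele
#' frequency. Monomorphic samples (allele frequency 0 or 1) fit their
#' expectations exactly and return p = 1.
#'
#' @param n_hom_effect,n_het,n_hom_other Non-negative genotype counts
#'   (effect-allele homozygotes, heterozygotes, other-allele homozygotes).
#' @return List with `statistic` (chi-square), `p` (upper-tail p-value on
#'   1 df), and `freq` (sample effect-allele frequency).
#' @export
hwe_test <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero", call. = FALSE)
  p <- (2 * n_hom_effect + n_het) / (2 * n)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  nonzero <- expected > 0
  stat <- sum((counts[nonzero] - expected[nonzero])^2 / expected[nonzero])
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       freq = p)
}

is_hard_call <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0 && all(x %in% c(0, 1, 2))
}

#' Per-variant quality-control report
#'
#' Flags each variant against the standard panel thresholds: minor allele
#' frequency >= `maf_min`, Hardy-Weinberg p >= `hwe_p_min`, call rate
#' >= `call_rate_min`, and (when an info score is recorded) imputation
#' quality >= `info_min`. MAF is computed from the mean dosage / 2 and
#' folded to <= 0.5, so it is invariant under effect/other relabelling.
#' The HWE test needs hard calls and is skipped (recorded as `NA`) for
#' fractional dosage data.
#'
#' @param matrix A [dosage_matrix()].
#' @param maf_min,hwe_p_min,call_rate_min,info_min Thresholds; the defaults
#'   are the conventional biobank filters (MAF < 0.01, HWE p < 1e-5,
#'   missingness > 10%, info < 0.3 are excluded).
#' @return A tibble with one row per variant: `rsid`, `eaf` (effect-allele
#'   frequency), `maf`, `hwe_p`, `call_rate`, `info`, `pass`, `reasons`.
#' @export
variant_qc <- function(matrix, maf_min = 0.01, hwe_p_min = 1e-5,
                       call_rate_min = 0.90, info_min = 0.3) {
  stopifnot(inherits(matrix, "dosage_matrix"))
  dm <- matrix$dosages
  if (nrow(dm) == 0L) stop("empty dosage matrix", call. = FALSE)
  res <- lapply(seq_len(ncol(dm)), function(j) {
    x <- dm[, j]
    call_rate <- mean(!is.na(x))
    eaf <- if (call_rate > 0) mean(x, na.rm = TRUE) / 2 else NA_real_
    maf <- if (is.na(eaf)) NA_real_ else min(eaf, 1 - eaf)
    hwe_p <- NA_real_
    if (is_hard_call(x)) {
      xc <- x[!is.na(x)]
      hwe_p <- hwe_test(sum(xc == 2), sum(xc == 1), sum(xc == 0))$p
    }
    info <- matrix$variant_meta$info[j]
    reasons <- character()
    if (!is.na(maf) && maf < maf_min) reasons <- c(reasons, sprintf("MAF < %g", maf_min))
    if (!is.na(hwe_p) && hwe_p < hwe_p_min) reasons <- c(reasons, sprintf("HWE p < %g", hwe_p_min))
    if (call_rate < call_rate_min) {
      reasons <- c(reasons, sprintf("missingness > %g%%", 100 * (1 - call_rate_min)))
    }
    if (!is.na(info) && info < info_min) reasons <- c(reasons, sprintf("info < %g", info_min))
    if (is.na(maf)) reasons <- c(reasons, "no calls")
    tibble::tibble(rsid = colnames(dm)[j], eaf = eaf, maf = maf,
                   hwe_p = hwe_p, call_rate = call_rate, info = info,
                   pass = length(reasons) == 0L,
                   reasons = paste(reasons, collapse = "; "))
  })
  do.call(rbind, res)
}

#' Per-sample quality-control report
#'
#' A sample fails when the fraction of missing panel variants exceeds
#' `max_missing` (default 10%).
#'
#' @param matrix A [dosage_matrix()].
#' @param max_missing Maximum tolerated missing fraction.
#' @return A tibble: `sample_id`, `missingness`, `pass`.
#' @export
sample_qc <- function(matrix, max_missing = 0.10) {
  stopifnot(inherits(matrix, "dosage_matrix"))
  dm <- matrix$dosages
  if (ncol(dm) == 0L) stop("empty dosage matrix", call. = FALSE)
  miss <- rowMeans(is.na(dm))
  tibble::tibble(sample_id = rownames(dm), missingness = unname(miss),
                 pass = unname(miss <= max_missing))
}

#' Drop variants and samples failing QC
#'
#' Applies [variant_qc()] then [sample_qc()] and subsets the matrix to
#' passing entries. Idempotent: a filtered matrix passes unchanged.
#'
#' @param matrix A [dosage_matrix()].
#' @param ... Thresholds forwarded to [variant_qc()] and [sample_qc()]
#'   (`maf_min`, `hwe_p_min`, `call_rate_min`, `info_min`, `max_missing`).
#' @return List with the filtered `matrix`, `variant_report`, `sample_report`.
#' @export
apply_qc <- function(matrix, maf_min = 0.01, hwe_p_min = 1e-5,
                     call_rate_min = 0.90, info_min = 0.3,
                     max_missing = 0.10) {
  vrep <- variant_qc(matrix, maf_min = maf_min, hwe_p_min = hwe_p_min,
                     call_rate_min = call_rate_min, info_min = info_min)
  keep_v <- which(vrep$pass)
  dm <- matrix$dosages[, keep_v, drop = FALSE]
  meta <- matrix$variant_meta[keep_v, , drop = FALSE]
  rownames(meta) <- NULL
  sub <- dosage_matrix(dm, meta, oriented = matrix$oriented)
  srep <- sample_qc(sub, max_missing = max_missing)
  keep_s <- which(srep$pass)
  out <- dosage_matrix(dm[keep_s, , drop = FALSE], meta,
                       oriented = matrix$oriented)
  attr(out, "resolved_weights") <- attr(matrix, "resolved_weights")
  list(matrix = out, variant_report = vrep, sample_report = srep)
}
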