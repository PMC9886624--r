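VALID_BASES <- c("A", "C", "G", "T")

#' Construct a single variant weight
#'
#' A variant weight ties an rsid to an effect allele, the other (reference)
#' allele, and a per-allele beta on the vitamin D Z-score scale. Optionally
#' carries a proxy map describing a substitute variant in high linkage
#' disequilibrium, with the allele correspondence between the two.
#'
#' @param rsid Variant identifier (e.g. `"rs2282679"`).
#' @param effect_allele Single base in A/C/G/T whose dosage is weighted.
#' @param other_allele The non-effect allele; must differ from `effect_allele`.
#' @param beta Per-allele change in vitamin D Z-score; finite and nonzero.
#' @param gene_label Optional gene annotation (informational).
#' @param proxy Optional proxy map built by [proxy_map()].
#' @return A list of class `variant_weight`.
#' @export
variant_weight <- function(rsid, effect_allele, other_allele, beta,
                           gene_label = NA_character_, proxy = NULL) {
  stopifnot(is.character(rsid), length(rsid) == 1L, nzchar(rsid))
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (!effect_allele %in% VALID_BASES || !other_allele %in% VALID_BASES) {
    stop("alleles for ", rsid, " must be single bases in A/C/G/T, got ",
         effect_allele, "/", other_allele, call. = FALSE)
  }
  if (effect_allele == other_allele) {
    stop("effect and other allele are identical for ", rsid, call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta == 0) {
    stop("beta for ", rsid, " must be finite and nonzero", call. = FALSE)
  }
  if (!is.null(proxy) && !inherits(proxy, "proxy_map")) {
    stop("proxy must be built with proxy_map()", call. = FALSE)
  }
  structure(
    list(rsid = rsid, effect_allele = effect_allele,
         other_allele = other_allele, beta = as.numeric(beta),
         gene_label = gene_label, proxy = proxy),
    class = "variant_weight"
  )
}

#' Construct a proxy map
#'
#' Describes a substitute variant genotyped in place of a target variant,
#' with a bijective allele correspondence from the *target's* alleles to the
#' proxy's alleles. The squared LD correlation is informational only; no LD
#' is computed by this package.
#'
#' @param proxy_rsid Identifier of the genotyped proxy variant.
#' @param allele_map Named character vector of length 2 mapping target
#'   alleles (names) to proxy alleles (values), e.g. `c(C = "T", T = "G")`.
#' @param r2 Squared LD correlation between target and proxy (informational).
#' @return A list of class `proxy_map`.
#' @export
proxy_map <- function(proxy_rsid, allele_map, r2 = NA_real_) {
  stopifnot(is.character(proxy_rsid), length(proxy_rsid) == 1L)
  allele_map <- toupper(structure(as.character(allele_map),
                                  names = toupper(names(allele_map))))
  if (length(allele_map) != 2L ||
      anyDuplicated(names(allele_map)) || anyDuplicated(allele_map) ||
      !all(names(allele_map) %in% VALID_BASES) ||
      !all(allele_map %in% VALID_BASES)) {
    stop("allele_map must be a bijection over exactly two A/C/G/T alleles",
         call. = FALSE)
  }
  structure(list(proxy_rsid = proxy_rsid, allele_map = allele_map, r2 = r2),
            class = "proxy_map")
}

#' Construct a weight table
#'
#' @param entries List of [variant_weight()] objects with unique rsids.
#' @return A list of class `weight_table`.
#' @export
weight_table <- function(entries) {
  if (length(entries) < 1L) {
    stop("weight table has zero entries; at least one variant is required",
         call. = FALSE)
  }
  ok <- vapply(entries, inherits, logical(1), what = "variant_weight")
  stopifnot(all(ok))
  rsids <- vapply(entries, `[[`, character(1), "rsid")
  if (anyDuplicated(rsids)) {
    stop("duplicate rsid(s) in weight table: ",
         paste(unique(rsids[duplicated(rsids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = entries), class = "weight_table")
}

#' @export
length.weight_table <- function(x) length(x$entries)

#' @export
print.weight_table <- function(x, ...) {
  cat("<weight_table> ", length(x), " variants\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.weight_table <- function(x, ...) {
  data.frame(
    rsid = vapply(x$entries, `[[`, character(1), "rsid"),
    effect_allele = vapply(x$entries, `[[`, character(1), "effect_allele"),
    other_allele = vapply(x$entries, `[[`, character(1), "other_allele"),
    beta = vapply(x$entries, `[[`, numeric(1), "beta"),
    gene_label = vapply(x$entries, `[[`, character(1), "gene_label"),
    stringsAsFactors = FALSE
  )
}

weight_rsids <- function(weights) {
  vapply(weights$entries, `[[`, character(1), "rsid")
}

#' Load a weight table from a TSV file
#'
#' Expects a tab-separated file with header columns `rsid`, `effect_allele`,
#' `other_allele`, `beta`, and optionally `gene_label`, `proxy_rsid`,
#' `proxy_allele_map` (format `"C=T,T=G"`, target allele on the left), and
#' `proxy_r2`.
#'
#' @param path Path to the weight TSV.
#' @return A validated [weight_table()].
#' @seealso [default_weight_table()] for the packaged six-variant score.
#' @export
load_weight_table <- function(path) {
  if (!file.exists(path)) stop("weight file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("rsid", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("weight file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("weight file contains zero entries", call. = FALSE)
  }
  entries <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    proxy <- NULL
    if (!is.null(row$proxy_rsid) && !is.na(row$proxy_rsid) &&
        nzchar(row$proxy_rsid)) {
      pairs <- strsplit(strsplit(row$proxy_allele_map, ",")[[1]], "=")
      am <- vapply(pairs, function(p) trimws(p[2]), character(1))
      names(am) <- vapply(pairs, function(p) trimws(p[1]), character(1))
      r2 <- if (!is.null(row$proxy_r2)) as.numeric(row$proxy_r2) else NA_real_
      proxy <- proxy_map(row$proxy_rsid, am, r2)
    }
    gene <- if (!is.null(row$gene_label)) row$gene_label else NA_character_
    variant_weight(row$rsid, row$effect_allele, row$other_allele,
                   as.numeric(row$beta), gene_label = gene, proxy = proxy)
  })
  weight_table(entries)
}

#' The packaged six-variant vitamin D weight table
#'
#' Six SNPs from GWAS-significant vitamin D loci (AMDHD1, DHCR7, CYP2R1,
#' CYP24A1, SEC23A, GC) with per-allele betas on the serum 25(OH)D Z-score
#' scale. One entry carries a proxy map: rs10745742 can be substituted by
#' rs6538691 (T alleles corresponding, R2 > 0.99). The GC entry is keyed on
#' rs2282679, which is itself the genotyped stand-in for rs3755967
#' (correlated alleles C=T, T=G, R2 = 0.9719); [rs3755967_weight()] returns
#' the rs3755967-keyed form whose proxy map resolves back to rs2282679.
#'
#' @return A [weight_table()] with six entries.
#' @export
default_weight_table <- function() {
  load_weight_table(system.file("extdata", "grs_weights_6snp.tsv",
                                package = "vdgrs", mustWork = TRUE))
}

#' The GC-locus weight keyed on rs3755967
#'
#' The GC signal is tabulated for rs3755967, but rs2282679 — in near-complete
#' LD with it (R2 = 0.9719, correlated alleles C=T, T=G) — is what assay
#' panels typically genotype. This returns the rs3755967-keyed weight whose
#' proxy map resolves to rs2282679: effect allele C (beta -0.089) translates
#' to rs2282679's T.
#'
#' @return A [variant_weight()].
#' @export
rs3755967_weight <- function() {
  variant_weight(
    rsid = "rs3755967", effect_allele = "C", other_allele = "T",
    beta = -0.089, gene_label = "GC",
    proxy = proxy_map("rs2282679", c(C = "T", T = "G"), r2 = 0.9719)
  )
}

#' Resolve a weight against available variants via its proxy
#'
#' If the weight's target rsid is genotyped, it is returned unchanged. If it
#' is absent but a proxy map is present and the proxy is genotyped, the
#' weight is re-keyed to the proxy with its alleles translated through the
#' allele map; beta is never changed. If neither is available an error names
#' the missing rsid.
#'
#' @param weight A [variant_weight()].
#' @param available_rsids Character vector of genotyped variant identifiers.
#' @return A [variant_weight()], possibly re-keyed to the proxy.
#' @export
resolve_proxy <- function(weight, available_rsids) {
  stopifnot(inherits(weight, "variant_weight"))
  if (weight$rsid %in% available_rsids) {
    return(weight)
  }
  px <- weight$proxy
  if (!is.null(px) && px$proxy_rsid %in% available_rsids) {
    am <- px$allele_map
    if (!all(c(weight$effect_allele, weight$other_allele) %in% names(am))) {
      stop("proxy allele map for ", weight$rsid,
           " does not cover alleles ", weight$effect_allele, "/",
           weight$other_allele, call. = FALSE)
    }
    return(variant_weight(
      rsid = px$proxy_rsid,
      effect_allele = unname(am[weight$effect_allele]),
      other_allele = unname(am[weight$other_allele]),
      beta = weight$beta,
      gene_label = weight$gene_label,
      proxy = NULL
    ))
  }
  stop("variant ", weight$rsid, " not genotyped and no genotyped proxy ",
       "available", call. = FALSE)
}

#' Resolve every entry of a weight table against available variants
#'
#' @param weights A [weight_table()].
#' @param available_rsids Character vector of genotyped variant identifiers.
#' @return A [weight_table()] with each entry resolved via [resolve_proxy()].
#' @export
resolve_proxies <- function(weights, available_rsids) {
  weight_table(lapply(weights$entries, resolve_proxy, available_rsids))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement one or more single-base alleles
#' @param allele Character vector of bases in A/C/G/T.
#' @return The complementary base(s).
#' @export
complement_allele <- function(allele) {
  unname(COMPLEMENT[toupper(allele)])
}

is_palindromic <- function(weight) {
  complement_allele(weight$effect_allele) == weight$other_allele
}

#' Harmonize a weight's alleles against a genotyped REF/ALT pair
#'
#' Determines how to obtain effect-allele dosage from stored ALT dosage for
#' an arbitrary genotype-file orientation. Direct matches are preferred;
#' failing that, a reverse-complement (strand-flip) match is attempted.
#' Weights whose two alleles are complementary (A/T or C/G) are strand
#' ambiguous: flips cannot be detected from alleles alone, so they are
#' refused unless the rsid is explicitly whitelisted, in which case the
#' direct-match orientation is assumed (appropriate when strand is known,
#' e.g. assay-based genotyping).
#'
#' @param weight A [variant_weight()].
#' @param genotyped_ref,genotyped_alt Single REF/ALT bases from the
#'   genotype file.
#' @param allow_palindromic Character vector of rsids for which
#'   strand-ambiguous weights may be used under the direct-match assumption.
#' @return A list of class `allele_orientation` with fields `status` (one of
#'   `effect_is_alt`, `effect_is_ref`, `strand_flipped_alt`,
#'   `strand_flipped_ref`, `ambiguous_palindromic`, `mismatch`) and
#'   `dosage_transform` (`"identity"`, `"2 - x"`, or `NA`).
#' @export
harmonize_alleles <- function(weight, genotyped_ref, genotyped_alt,
                              allow_palindromic = character()) {
  stopifnot(inherits(weight, "variant_weight"))
  ref <- toupper(genotyped_ref); alt <- toupper(genotyped_alt)
  if (!ref %in% VALID_BASES || !alt %in% VALID_BASES) {
    stop("genotyped alleles must be single bases in A/C/G/T, got ",
         ref, "/", alt, call. = FALSE)
  }
  eff <- weight$effect_allele; oth <- weight$other_allele

  orientation <- function(status, transform) {
    structure(list(status = status, dosage_transform = transform),
              class = "allele_orientation")
  }

  if (is_palindromic(weight)) {
    if (eff == alt && oth == ref) {
      if (weight$rsid %in% allow_palindromic) {
        return(orientation("effect_is_alt", "identity"))
      }
      return(orientation("ambiguous_palindromic", NA_character_))
    }
    if (eff == ref && oth == alt) {
      if (weight$rsid %in% allow_palindromic) {
        return(orientation("effect_is_ref", "2 - x"))
      }
      return(orientation("ambiguous_palindromic", NA_character_))
    }
    return(orientation("mismatch", NA_character_))
  }

  if (eff == alt && oth == ref) return(orientation("effect_is_alt", "identity"))
  if (eff == ref && oth == alt) return(orientation("effect_is_ref", "2 - x"))

  ceff <- complement_allele(eff); coth <- complement_allele(oth)
  if (ceff == alt && coth == ref) return(orientation("strand_flipped_alt", "identity"))
  if (ceff == ref && coth == alt) return(orientation("strand_flipped_ref", "2 - x"))

  orientation("mismatch", NA_character_)
}

#' Apply an orientation's dosage transform to ALT dosages
#'
#' @param orientation An `allele_orientation` from [harmonize_alleles()].
#' @param alt_dosage Numeric vector of ALT-allele dosages in \[0, 2\].
#' @param rsid Variant name used in error messages.
#' @return Effect-allele dosages.
#' @export
apply_orientation <- function(orientation, alt_dosage, rsid = "variant") {
  status <- orientation$status
  if (status %in% c("mismatch", "ambiguous_palindromic")) {
    stop("cannot orient dosages for ", rsid, ": status ", status, call. = FALSE)
  }
  if (identical(orientation$dosage_transform, "identity")) alt_dosage
  else 2 - alt_dosage
}
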