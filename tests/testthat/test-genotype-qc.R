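test_that("VCF hard calls become effect-allele dosages after orientation", {
  wt <- default_weight_table()
  # rs12785878 weight T/G; write genotyped REF=G ALT=T so effect_is_alt,
  # and rs10741657 weight A/G genotyped REF=A ALT=G so effect_is_ref.
  gt <- rbind(c(1, 2), c(0, 0), c(2, NA))
  path <- write_tiny_vcf(gt, rsids = c("rs12785878", "rs10741657"),
                         ref = c("G", "A"), alt = c("T", "G"))
  sub <- weight_table(wt$entries[2:3])
  m <- read_genotypes(path, sub)
  expect_true(m$oriented)
  # effect_is_alt: identity; effect_is_ref: 2 - x
  expect_equal(unname(m$dosages[, "rs12785878"]), c(1, 0, 2))
  expect_equal(unname(m$dosages[, "rs10741657"]), c(0, 2, NA))
})

test_that("missing calls, palindromic whitelisting and proxies flow through VCF reading", {
  wt <- default_weight_table()
  gt <- rbind(c(0, 1), c(NA, 2))
  # rs8018720 is C/G: refused without whitelist
  path <- write_tiny_vcf(gt, rsids = c("rs8018720", "rs6538691"),
                         ref = c("G", "C"), alt = c("C", "T"))
  sub <- weight_table(wt$entries[c(5, 1)]) # rs8018720 + rs10745742 (proxy rs6538691)
  expect_error(read_genotypes(path, sub), "ambiguous_palindromic")
  m <- read_genotypes(path, sub, allow_palindromic = "rs8018720")
  expect_setequal(colnames(m$dosages), c("rs8018720", "rs6538691"))
  expect_equal(unname(m$dosages[, "rs6538691"]), c(1, 2))
  expect_equal(unname(m$dosages[2, "rs8018720"]), NA_real_)
})

test_that("multi-allelic records are excluded and absent panels are fatal", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("1", "100", "rs12785878", "G", "T,A", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t"),
    paste(c("1", "200", "rs10741657", "A", "G", ".", "PASS", ".", "GT", "1/1"),
          collapse = "\t")
  ), path)
  wt <- default_weight_table()
  expect_warning(m <- read_genotypes(path, weight_table(wt$entries[2:3])),
                 "multi-allelic")
  expect_equal(colnames(m$dosages), "rs10741657")

  expect_error(
    suppressWarnings(read_genotypes(path, weight_table(wt$entries[4]))),
    "no panel variants"
  )
})

test_that("dosage TSV input is accepted with missing values", {
  wt <- default_weight_table()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs12785878\trs10741657",
               "A\t0.5\t2", "B\tNA\t1"), path)
  m <- read_genotypes(path, weight_table(wt$entries[2:3]))
  expect_true(m$oriented)
  expect_equal(unname(m$dosages["B", ]), c(NA, 1))
  expect_equal(unname(m$dosages["A", "rs12785878"]), 0.5)
})

test_that("HWE chi-square matches hand-computed tables", {
  # counts exactly at HWE for p = 0.5: statistic 0, p = 1
  r <- hwe_test(25, 50, 25)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # all homozygotes, p = 0.5: expectations 25/50/25 for n = 100, stat = 100
  r2 <- hwe_test(50, 0, 50)
  expect_equal(r2$statistic, 100)
  expect_lt(r2$p, 1e-5)
  expect_equal(r2$p, pchisq(100, 1, lower.tail = FALSE))
  # monomorphic: fits exactly
  r3 <- hwe_test(100, 0, 0)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
  expect_error(hwe_test(0, 0, 0), "zero")
})

test_that("hwe_test equals the 1-df chi-square survival function on random counts", {
  set.seed(5)
  for (i in 1:20) {
    cnt <- rmultinom(1, 200, c(0.3, 0.5, 0.2))[, 1]
    r <- hwe_test(cnt[1], cnt[2], cnt[3])
    p <- (2 * cnt[1] + cnt[2]) / (2 * sum(cnt))
    e <- sum(cnt) * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((cnt - e)^2 / e)
    expect_equal(r$statistic, stat)
    expect_equal(r$p, pchisq(stat, 1, lower.tail = FALSE))
  }
})

test_that("variant QC applies the panel thresholds", {
  set.seed(1)
  n <- 1000
  # v1: rare (freq 0.005); v2: HWE violation; v3: high missingness;
  # v4: clean; v5: low info score
  v1 <- rbinom(n, 2, 0.005)
  v2 <- sample(c(0, 2), n, replace = TRUE) # no hets at freq ~0.5
  v3 <- rbinom(n, 2, 0.3); v3[1:150] <- NA # call rate 0.85
  v4 <- rbinom(n, 2, 0.3)
  v5 <- rbinom(n, 2, 0.3)
  m <- make_matrix(cbind(v1, v2, v3, v4, v5),
                   rsids = paste0("v", 1:5),
                   info = c(NA, NA, NA, 0.99, 0.1))
  rep <- variant_qc(m)
  expect_false(rep$pass[1]); expect_match(rep$reasons[1], "MAF")
  expect_false(rep$pass[2]); expect_match(rep$reasons[2], "HWE")
  expect_false(rep$pass[3]); expect_match(rep$reasons[3], "missingness")
  expect_true(rep$pass[4])
  expect_false(rep$pass[5]); expect_match(rep$reasons[5], "info")
})

test_that("MAF is folded and invariant under allele relabelling", {
  set.seed(2)
  x <- rbinom(500, 2, 0.8)
  m1 <- make_matrix(cbind(v = x), rsids = "v")
  m2 <- make_matrix(cbind(v = 2 - x), rsids = "v")
  r1 <- variant_qc(m1); r2 <- variant_qc(m2)
  expect_equal(r1$maf, r2$maf)
  expect_equal(r1$eaf, 1 - r2$eaf)
  expect_lte(r1$maf, 0.5)
})

test_that("fractional dosages skip the HWE test", {
  m <- make_matrix(cbind(v = runif(50, 0, 2)), rsids = "v")
  rep <- variant_qc(m)
  expect_true(is.na(rep$hwe_p))
})

test_that("sample QC fails samples missing more than 10% of the panel", {
  dm <- matrix(1, nrow = 3, ncol = 6,
               dimnames = list(NULL, paste0("v", 1:6)))
  dm[2, 1] <- NA            # 1/6 = 0.167 > 0.10
  m <- make_matrix(dm, rsids = paste0("v", 1:6))
  rep <- sample_qc(m)
  expect_equal(rep$pass, c(TRUE, FALSE, TRUE))
  # vacuous threshold keeps everyone
  expect_true(all(sample_qc(m, max_missing = 1)$pass))
})

test_that("QC filtering is idempotent", {
  set.seed(3)
  dm <- cbind(a = rbinom(300, 2, 0.004), b = rbinom(300, 2, 0.4),
              c = rbinom(300, 2, 0.25))
  dm[1:40, "b"] <- NA
  dm[1, c("b", "c")] <- NA
  m <- make_matrix(dm, rsids = c("a", "b", "c"))
  once <- apply_qc(m)
  twice <- apply_qc(once$matrix)
  expect_identical(once$matrix$dosages, twice$matrix$dosages)
  expect_true(all(twice$variant_report$pass))
  expect_true(all(twice$sample_report$pass))
})
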