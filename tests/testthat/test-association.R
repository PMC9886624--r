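test_that("noise-free responses are fitted exactly", {
  co <- make_cohort(100)
  co$vd_z <- 2 * co$grs_z
  fit <- fit_linear_model(co, "vd_z", "grs_z")
  expect_equal(fit$estimate[fit$term == "grs_z"], 2, tolerance = 1e-10)
  expect_equal(attr(fit, "adj_r2"), 1, tolerance = 1e-10)
})

test_that("an orthogonal covariate leaves an estimate unchanged", {
  set.seed(21)
  n <- 400
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x)) # exactly orthogonal to x (and to the intercept)
  co <- tibble::tibble(sample_id = as.character(1:n), x = x, z = z,
                       y = 1.5 * x + rnorm(n))
  f1 <- fit_linear_model(co, "y", "x")
  f2 <- fit_linear_model(co, "y", c("x", "z"))
  expect_equal(f1$estimate[f1$term == "x"], f2$estimate[f2$term == "x"],
               tolerance = 1e-10)
})

test_that("OLS matches a brute-force normal-equations solution", {
  set.seed(22)
  for (i in 1:10) {
    n <- 50; k <- 3
    X <- cbind(1, matrix(rnorm(n * k), n, k))
    y <- X %*% runif(k + 1, -1, 1) + rnorm(n)
    co <- tibble::tibble(sample_id = as.character(1:n), y = as.numeric(y),
                         a = X[, 2], b = X[, 3], c = X[, 4])
    fit <- fit_linear_model(co, "y", c("a", "b", "c"))
    beta_hat <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$estimate, as.numeric(beta_hat), tolerance = 1e-8)
  }
})

test_that("rank deficiency and small samples raise informative errors", {
  co <- make_cohort(50)
  co$vd_z <- rnorm(50)
  co$dup <- co$grs_z
  expect_error(fit_linear_model(co, "vd_z", c("grs_z", "dup")), "singular|collinear")
  expect_error(fit_linear_model(co[1:3, ], "vd_z", c("grs_z", "bmi", "age")),
               "too few")
})

test_that("complete-case exclusions are counted", {
  co <- make_cohort(60)
  co$vd_z <- rnorm(60)
  co$bmi[1:5] <- NA
  expect_message(fit <- fit_linear_model(co, "vd_z", c("grs_z", "bmi")),
                 "excluding 5")
  expect_equal(fit$n[1], 55L)
})

test_that("BH q-values follow the step-up procedure", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.8)
  expect_equal(p.adjust(p, "BH"), c(0.005, 0.025, 0.02 * 5 / 3, 0.05, 0.8))
  # screen output reproduces this ordering and the q >= p invariant
  set.seed(23)
  co <- make_cohort(500)
  co$vd_z <- 0.4 * co$supplementing + 0.05 * co$grs_z + rnorm(500, 0, 0.8)
  co$dose[co$supplementing] <- exp(rnorm(sum(co$supplementing), log(800), 0.5))
  sc <- screen_predictors(co)
  expect_true(all(sc$q >= sc$p - 1e-15))
  expect_true(all(diff(sc$q[order(sc$p)]) >= -1e-15))
  expect_true(all(sc$q <= 1))
  expect_equal(nrow(sc), 5L) # grs_z, supplementing, dose, bmi, ms_status
  expect_true(sc$significant[sc$term == "supplementing"])
})

test_that("single-candidate screens leave p unchanged", {
  set.seed(24)
  co <- make_cohort(200)
  co$vd_z <- 0.3 * co$grs_z + rnorm(200)
  sc <- screen_predictors(co, candidates = "grs_z")
  expect_equal(sc$q, sc$p)
})

test_that("stratified models recover additive-mode generative effects", {
  sim <- simulate_cohort(ukb_preset(seed = 31, n = 8000L, grs_effect_sd = 0.15,
                                    supp_prob = 0.5))
  sc <- compute_grs(sim$genotypes, default_weight_table())
  co <- merge(sim$cohort, sc[, c("sample_id", "grs_z")], by = "sample_id")
  fit <- grs_association(tibble::as_tibble(co))
  for (st in c("supplementers", "non-supplementers")) {
    row <- fit[fit$term == "grs_z" & fit$stratum == st, ]
    expect_lt(abs(row$estimate - 0.15), 3 * row$se)
  }
})

test_that("titration-mode supplementers show no GRS effect", {
  sim <- simulate_cohort(study_preset(seed = 32, n_ms = 3000L, n_control = 2000L))
  sc <- compute_grs(sim$genotypes, default_weight_table())
  co <- merge(sim$cohort, sc[, c("sample_id", "grs_z")], by = "sample_id")
  fit <- grs_association(tibble::as_tibble(co))
  supp <- fit[fit$term == "grs_z" & fit$stratum == "supplementers", ]
  nons <- fit[fit$term == "grs_z" & fit$stratum == "non-supplementers", ]
  expect_lt(abs(supp$estimate), 3 * supp$se)
  expect_gt(nons$estimate / nons$se, 4)
})

test_that("empty strata are skipped with a warning", {
  set.seed(33)
  co <- make_cohort(100)
  co$vd_z <- rnorm(100)
  co$supplementing <- FALSE
  expect_warning(fit <- grs_association(co), "supplementers")
  expect_false("supplementers" %in% fit$stratum)
  expect_true("non-supplementers" %in% fit$stratum)
})

test_that("adjusted R-squared delta is zero for irrelevant scores and positive for real ones", {
  set.seed(34)
  co <- make_cohort(3000)
  co$vd_z <- 0.3 * co$grs_z - 0.03 * (co$bmi - 27) + rnorm(3000, 0, 0.9)
  r2 <- adjusted_r2_delta(co)
  expect_gt(r2$delta, 0.05)
  expect_equal(r2$r2_full - r2$r2_base, r2$delta)

  # a pure-noise score adds nothing in expectation: deltas straddle zero
  deltas <- vapply(1:30, function(i) {
    set.seed(100 + i)
    co$grs_z <- rnorm(nrow(co))
    adjusted_r2_delta(co)$delta
  }, numeric(1))
  expect_lt(mean(deltas), 0.002)
})

test_that("genotype distribution chi-square matches a hand oracle", {
  # identical distributions
  r <- genotype_distribution_test(c(10, 20, 10), c(10, 20, 10))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  # proportional distributions
  r2 <- genotype_distribution_test(c(10, 20, 10), c(20, 40, 20))
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  # hand-computed 2x3 Pearson statistic
  cases <- c(30, 10, 0); controls <- c(10, 10, 20)
  tab <- rbind(cases, controls)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  r3 <- genotype_distribution_test(cases, controls)
  expect_equal(r3$statistic, stat)
  expect_equal(r3$df, 2L)
  expect_equal(r3$p, pchisq(stat, 2, lower.tail = FALSE))
  # zero-total genotype classes collapse with reduced df
  r4 <- genotype_distribution_test(c(30, 10, 0), c(10, 30, 0))
  expect_equal(r4$df, 1L)
  expect_error(genotype_distribution_test(c(0, 0, 0), c(0, 0, 0)), "zero")
})

test_that("cohort validation enforces the dose/supplementation invariant", {
  co <- make_cohort(10)
  co$vd_z <- rnorm(10)
  co$dose[!co$supplementing][1] <- 400
  expect_error(validate_cohort(co), "dose > 0")
  co2 <- make_cohort(10)
  co2$sample_id[2] <- co2$sample_id[1]
  expect_error(validate_cohort(co2), "duplicate")
})
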