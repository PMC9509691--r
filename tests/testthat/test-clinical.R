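test_that("diff pH is rest minus drop with missing propagation", {
  expect_equal(diff_ph(7.0, 5.5), 1.5)
  expect_equal(diff_ph(6.0, 6.0), 0)
  expect_equal(diff_ph(6.0, 6.4), -0.4)
  expect_true(is.na(diff_ph(NA, 6.0)))
  expect_true(is.na(diff_ph(6.0, NA)))
})

test_that("saliva normalisation divides by default and can subtract", {
  expect_equal(normalize_by_saliva(7.0, 7.0), 1.0)
  expect_equal(normalize_by_saliva(6.3, 7.0), 0.9)
  expect_true(is.na(normalize_by_saliva(6.3, NA)))
  expect_equal(normalize_by_saliva(6.3, 7.0, method = "subtract"), -0.7)
  expect_error(normalize_by_saliva(6.3, 0), "positive")
})

test_that("Welch's test matches the textbook formulas and is antisymmetric", {
  same <- welch_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # frozen oracle: Welch formulas evaluated by hand / stats::t.test
  w <- welch_t_test(c(1, 2, 3), c(1, 2, 3, 4, 5))
  expect_equal(w$t, -1.0954451150, tolerance = 1e-9)
  expect_equal(w$df, 5.8823529412, tolerance = 1e-9)
  expect_equal(w$p, 0.3161334219, tolerance = 1e-9)
  # swapping groups flips the statistic, not the p-value
  set.seed(4)
  a <- rnorm(8, 6.5, 0.3); b <- rnorm(12, 6.2, 0.5)
  expect_equal(welch_t_test(a, b)$t, -welch_t_test(b, a)$t)
  expect_equal(welch_t_test(a, b)$p, welch_t_test(b, a)$p)
  # equal-variance equal-n case collapses to pooled Student's t
  a2 <- c(1, 2, 3, 4); b2 <- c(2, 3, 4, 5)
  pooled <- t.test(a2, b2, var.equal = TRUE)
  expect_equal(welch_t_test(a2, b2)$t, unname(pooled$statistic))
  expect_equal(welch_t_test(a2, b2)$p, pooled$p.value)
  expect_error(welch_t_test(1, c(1, 2)))
})

test_that("exhaustive permutation p equals explicit enumeration", {
  r <- permutation_test(c(1, 2), c(10, 11))
  expect_identical(r$mode, "exhaustive")
  expect_equal(r$p, 1 / 3)
  expect_equal(r$p, bf_permutation_p(c(1, 2), c(10, 11)))
  # constant identical groups: every assignment ties the observed statistic
  expect_equal(permutation_test(c(2, 2, 2), c(2, 2))$p, 1)
  # random small cases against the bitmask oracle
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(sample(2:4, 1), 6.5, 0.5)
    b <- rnorm(sample(2:5, 1), 6.0, 0.5)
    expect_equal(permutation_test(a, b)$p, bf_permutation_p(a, b))
  }
  expect_error(permutation_test(numeric(0), 1:3))
})

test_that("sampled permutation p converges to the exhaustive value", {
  set.seed(2)
  a <- rnorm(6, 6.6, 0.3)
  b <- rnorm(7, 6.2, 0.3)
  exact <- permutation_test(a, b)   # C(13,6) = 1716: exhaustive
  expect_identical(exact$mode, "exhaustive")
  sampled <- permutation_test(a, b, n_perm = 10000, seed = 99,
                              exhaustive_limit = 10)
  expect_identical(sampled$mode, "sampled")
  se <- sqrt(exact$p * (1 - exact$p) / 10000)
  expect_lt(abs(sampled$p - exact$p), 3 * se + 2 / 10000)
  # seeded draws are reproducible
  again <- permutation_test(a, b, n_perm = 500, seed = 99,
                            exhaustive_limit = 10)
  once <- permutation_test(a, b, n_perm = 500, seed = 99,
                           exhaustive_limit = 10)
  expect_identical(again$p, once$p)
})

test_that("the synthetic cohort is seeded, clipped and faithful to its parameters", {
  c1 <- synth_cohort(seed = 5)
  c2 <- synth_cohort(seed = 5)
  expect_identical(c1$surfaces, c2$surfaces)
  expect_identical(c1$readings, c2$readings)
  expect_identical(c1$subjects, c2$subjects)
  expect_equal(nrow(c1$surfaces), 85)
  expect_true(all(c1$readings$ph >= 4 & c1$readings$ph <= 7.5))
  expect_true(all(c1$subjects$saliva_ph >= 5.5 & c1$subjects$saliva_ph <= 8.5))
  expect_true(all(c1$surfaces$rank %in% 0:1))
  # zero replicate noise: every replicate equals its surface's value
  quiet <- synth_cohort(cohort_params(replicate_sd = 0), seed = 8)
  rest <- quiet$readings[quiet$readings$phase == "rest", ]
  per_surface <- tapply(rest$ph, rest$surface_id, function(x)
    max(x) - min(x))
  expect_equal(max(per_surface), 0)
  merged <- merge(rest, quiet$surfaces[, c("surface_id", "rest_ph")],
                  by = "surface_id")
  expect_equal(merged$ph, merged$rest_ph, tolerance = 1e-12)
})

test_that("a large default cohort reproduces the rank-0 resting pH", {
  big <- cohort_params(n_surfaces = c(pre = 235, post = 265),
                       n_subjects = c(pre = 41, post = 106))
  coh <- synth_cohort(big, seed = 17)
  s <- coh$surfaces
  m <- mean(s$rest_ph[s$rank == 0])
  expect_lt(abs(m - 6.73), 0.1)
})

test_that("analyze_cohort emits a deterministic comparison grid", {
  coh <- synth_cohort(seed = 2)
  res <- suppressWarnings(analyze_cohort(coh, n_perm = 200, seed = 3))
  # one row per metric x normalisation x comparison cell
  expect_equal(nrow(res), 3 * 2 * (1 + 2 + 2))
  expect_identical(unique(res$metric), c("rest", "drop", "diff"))
  expect_true(all(res$perm_p >= 0 & res$perm_p <= 1, na.rm = TRUE))
  expect_true(all(res$significant == (res$perm_p < res$alpha), na.rm = TRUE))
  # Welch is reported only where both samples pass the normality gate
  expect_true(all(is.na(res$welch_p[!res$normal %in% TRUE])))
  res2 <- suppressWarnings(analyze_cohort(coh, n_perm = 200, seed = 3))
  expect_identical(res, res2)
})

test_that("single-group cohorts keep within-group rank comparisons only", {
  params <- cohort_params(n_subjects = c(pre = 7), n_surfaces = c(pre = 40),
                          rest_mean = c(pre = 6.65),
                          diff_mean = c(pre = 0.84))
  coh <- synth_cohort(params, seed = 4)
  res <- suppressWarnings(analyze_cohort(coh, n_perm = 200, seed = 1,
                                         normalized = FALSE))
  expect_true(all(res$comparison == "rank_within"))
  expect_true(any(is.finite(res$perm_p)))
})
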