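test_that("the normalised ratio behaves as a bounded antisymmetric contrast", {
  expect_equal(compute_ratio(2, 2), 0)
  expect_equal(compute_ratio(3, 1), 0.5)
  expect_equal(compute_ratio(1, 0), 1)
  expect_equal(compute_ratio(0, 1), -1)
  expect_equal(compute_ratio(1, 3), -compute_ratio(3, 1))
  expect_error(compute_ratio(0, 0), "undefined ratio")
  expect_error(compute_ratio(-1, 2))
})

test_that("the default calibration applies the device's published line", {
  cal <- calibration()
  expect_identical(predict_ph(0, cal), 3.42)
  expect_equal(predict_ph(1, cal), 13.76)
  expect_equal(predict_ph(0.2, cal), 5.488)
  expect_error(predict_ph(1.5, cal), "\\[-1, 1\\]")
})

test_that("calibration fitting recovers exact lines and is order-invariant", {
  r <- c(0.056, 0.2, 0.3, 0.3946)
  cal <- fit_calibration(r, 10.34 * r + 3.42)
  expect_equal(cal$slope, 10.34, tolerance = 1e-10)
  expect_equal(cal$intercept, 3.42, tolerance = 1e-10)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-10)
  # two points define the interpolating line
  cal2 <- fit_calibration(c(0.1, 0.5), c(5, 7))
  expect_equal(cal2$slope, 5)
  expect_equal(cal2$intercept, 4.5)
  # permuting the pairs changes nothing
  set.seed(1)
  ph <- 10.34 * r + 3.42 + rnorm(4, 0, 0.1)
  o <- c(3, 1, 4, 2)
  calA <- fit_calibration(r, ph)
  calB <- fit_calibration(r[o], ph[o])
  expect_equal(calA$slope, calB$slope)
  expect_equal(calA$intercept, calB$intercept)
  expect_equal(calA$pearson_r, calB$pearson_r)
  expect_error(fit_calibration(c(0.2, 0.2, 0.2), c(4, 5, 6)), "degenerate")
})

test_that("quality gating rejects in the fixed precedence order", {
  cal <- calibration(af_threshold = 1, min_signal = 0.5)
  mk <- function(f520, f550, af = 0, pp = 0)
    channel_amplitudes(f520, f550, af, pp)
  high_af <- qc_evaluate(mk(5, 2, af = 2), cal)
  expect_identical(high_af$status, "rejected")
  expect_identical(high_af$reject_reason, "high_af")
  # AF outranks low signal when both fail
  both <- qc_evaluate(mk(0.1, 0.1, af = 2), cal)
  expect_identical(both$reject_reason, "high_af")
  low <- qc_evaluate(mk(0.1, 0.1), cal)
  expect_identical(low$reject_reason, "low_signal")
  # ratio 1 maps to pH 13.76 under the default line: out of range
  oor <- qc_evaluate(mk(5, 0), cal)
  expect_identical(oor$reject_reason, "out_of_range")
  expect_equal(oor$ph, 13.76)
  ok <- qc_evaluate(mk(3, 2), cal)   # ratio 0.2 -> pH 5.488
  expect_identical(ok$status, "accepted")
  expect_equal(ok$ph, 5.488)
})

test_that("accepted readings always lie inside the calibration range", {
  cal <- calibration(af_threshold = 0.3, min_signal = 0.2)
  set.seed(21)
  for (i in 1:200) {
    amps <- channel_amplitudes(runif(1, 0, 5), runif(1, 0, 5),
                               runif(1, 0, 0.6), runif(1, 0, 1))
    rd <- qc_evaluate(amps, cal)
    if (rd$status == "accepted") {
      expect_gte(rd$ph, cal$ph_min)
      expect_lte(rd$ph, cal$ph_max)
    } else {
      expect_true(rd$reject_reason %in%
                    c("high_af", "low_signal", "out_of_range"))
    }
  }
})

test_that("replicate aggregation uses the sample SD and tolerates singletons", {
  agg <- aggregate_replicates(c(6, 6, 6))
  expect_equal(agg$mean, 6)
  expect_equal(agg$sd, 0)
  agg2 <- aggregate_replicates(c(6.0, 6.5))
  expect_equal(agg2$mean, 6.25)
  expect_equal(agg2$sd, sqrt(0.125), tolerance = 1e-12)
  single <- aggregate_replicates(6.8)
  expect_equal(single$mean, 6.8)
  expect_identical(single$n, 1L)
  expect_true(is.na(single$sd))
  expect_error(aggregate_replicates(numeric(0)), "no accepted")
})

test_that("pooled SD matches its defining sum and handles edge cases", {
  expect_equal(pooled_sd(list(c(6, 6, 6), c(5, 5))), 0)
  expect_equal(pooled_sd(list(c(0, 0.2, 0.4) + 6, c(5, 5.3, 5.6))),
               sqrt((2 * 0.04 + 2 * 0.09) / 4), tolerance = 1e-12)
  expect_equal(round(pooled_sd(list(c(6, 6.2, 6.4), c(5, 5.3, 5.6))), 4),
               0.2550)
  expect_equal(pooled_sd(list(c(4, 5, 7))), sd(c(4, 5, 7)))
  # singletons are excluded, not counted
  expect_equal(pooled_sd(list(c(6, 6.4), 5.2)), sd(c(6, 6.4)))
  expect_error(pooled_sd(list(6.1, 5.9)), "n >= 2")
  # brute-force oracle on random replicate groups
  set.seed(9)
  for (i in 1:20) {
    groups <- lapply(seq_len(sample(2:8, 1)),
                     function(j) rnorm(sample(2:5, 1), 6, 0.3))
    num <- sum(vapply(groups, function(g) (length(g) - 1) * var(g),
                      numeric(1)))
    den <- sum(vapply(groups, length, numeric(1)) - 1)
    expect_equal(pooled_sd(groups), sqrt(num / den), tolerance = 1e-12)
  }
})

test_that("the noiseless simulated pipeline reproduces the acid-end bias pattern", {
  cal <- simulated_calibration()
  grid <- seq(4, 7.5, by = 0.25)
  pred <- vapply(grid, function(p) predict_ph(simulated_ratio(p), cal),
                 numeric(1))
  err <- abs(pred - grid)
  expect_lte(mean(err), 0.25)
  acid <- mean(err[grid <= 4.5])
  others <- c(mean(err[grid > 4.5 & grid <= 5.5]),
              mean(err[grid > 5.5 & grid <= 6.5]),
              mean(err[grid > 6.5]))
  expect_true(all(acid > others))
})
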