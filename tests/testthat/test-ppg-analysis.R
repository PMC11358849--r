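# Pulse-oximetry metrics and curve comparisons.

test_that("AC, PI and R follow their definitions", {
  expect_equal(ac_component(0.05, 0.045), 0.005)
  expect_equal(ac_component(0.3, 0.3), 0)
  expect_warning(ac <- ac_component(0.04, 0.045), "negative AC")
  expect_equal(ac, -0.005)

  expect_equal(perfusion_index(0.05, 0.045), 0.1)
  expect_error(perfusion_index(0, 0), "dc_diastole is 0")

  expect_equal(ratio_of_ratios(0.041, 0.065), 0.041 / 0.065)
  expect_equal(ratio_of_ratios(0.2, 0.2), 1)
  expect_equal(ratio_of_ratios(0, 0.3), 0)
  expect_error(ratio_of_ratios(0.1, 0), "pi_ir is 0")

  m <- ppg_metrics(0.05, 0.045, 660)
  expect_equal(m$ac, 0.005)
  expect_equal(m$pi, 0.1)
})

test_that("attenuation fractions compare dark against light intensities", {
  expect_equal(attenuation_fraction(0.011, 0.1), 0.89)
  expect_equal(attenuation_fraction(0.2, 0.2), 0)
  expect_error(attenuation_fraction(0.1, 0), "intensity_light is 0")
})

test_that("curve distance is Euclidean", {
  expect_equal(curve_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(curve_distance(1:5, 1:5), 0)
  expect_error(curve_distance(1:4, 1:5), "equal length")
})

test_that("path statistics summarize detected photons with median and IQR", {
  rec <- data.frame(weight = rep(1, 20), opl = rep(2, 20),
                    max_depth = seq(0.01, 0.2, by = 0.01))
  s <- path_statistics(rec, "opl")
  expect_equal(s$median, 2)
  expect_equal(s$iqr, 0)
  expect_equal(s$n, 20)
  pd <- path_statistics(rec, "pd")
  expect_equal(pd$median, median(rec$max_depth))
  expect_error(path_statistics(rec[0, ], "opl"), "no detected")
})

test_that("path statistics cap the sample and flag non-normal data", {
  set.seed(1)
  rec <- data.frame(weight = 1, opl = rexp(20000), max_depth = 0.1)
  s <- path_statistics(rec, "opl")
  expect_equal(s$n, 10000)
  # exponential path lengths are decisively non-normal
  expect_lt(s$normality_p, 0.05)
  # near-normal data is not flagged
  recn <- data.frame(weight = 1, opl = rnorm(5000, 2, 0.3), max_depth = 0.1)
  expect_gt(path_statistics(recn, "opl")$normality_p, 0.01)
})

test_that("signed-rank comparison matches exact enumeration and wilcox.test", {
  # six all-positive unit differences: only the all-positive and
  # all-negative sign patterns reach the observed rank-sum deviation,
  # p = 2/2^6
  x <- rep(2, 6); y <- rep(1, 6)
  expect_equal(compare_curves_wilcoxon(x, y), 0.03125)

  # tie-free data: agree with the exact signed-rank distribution of
  # stats::wilcox.test (independent implementation)
  set.seed(42)
  for (i in 1:5) {
    a <- rnorm(8)
    b <- rnorm(8, 0.5)
    ours <- compare_curves_wilcoxon(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }

  # degenerate: identical samples
  expect_warning(p <- compare_curves_wilcoxon(1:6, 1:6), "degenerate")
  expect_equal(p, 1)
  expect_error(compare_curves_wilcoxon(1:3, 2:4), "at least 5")
})

test_that("SpO2 estimation reads the calibration curve and flags extrapolation", {
  cal <- data.frame(sao2 = seq(0.6, 1.0, by = 0.1),
                    r = c(1.4, 1.1, 0.85, 0.63, 0.45))  # falling in SaO2
  est <- estimate_spo2(0.63, cal)
  expect_equal(est$spo2, 0.9)
  expect_false(est$extrapolated)
  # a lower R than the light-skin curve at 0.9 reads as higher SpO2
  est2 <- estimate_spo2(0.55, cal)
  expect_gt(est2$spo2, 0.9)
  # outside the calibrated range
  expect_warning(est3 <- estimate_spo2(0.2, cal), "extrapolated")
  expect_true(est3$extrapolated)
  expect_gt(est3$spo2, 1.0)
  # non-monotone calibration is rejected
  bad <- cal; bad$r[2] <- 0.1
  expect_error(estimate_spo2(0.63, bad), "monotone")
})

test_that("weighted path statistics follow the weighted distribution", {
  # equal weights reduce to (approximately) the unweighted quantiles
  x <- c(1, 2, 3, 4, 5)
  expect_equal(weighted_quantile(x, rep(1, 5), 0.5), 3)
  # mass concentrated on one value pulls the median there
  expect_equal(weighted_quantile(c(1, 2, 10), c(1, 1, 100), 0.5), 10,
               tolerance = 0.05)
  rec <- data.frame(weight = c(rep(1, 50), rep(1e-6, 50)),
                    opl = c(rep(1, 50), rep(9, 50)),
                    max_depth = 0.1)
  sw <- path_statistics(rec, "opl", weighted = TRUE)
  su <- path_statistics(rec, "opl", weighted = FALSE)
  expect_equal(sw$median, 1, tolerance = 0.02)
  expect_equal(su$median, 5)
})
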