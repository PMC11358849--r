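# Transport-engine physics oracles: analytic limits, conservation,
# determinism, sampler distributions.

test_that("Henyey-Greenstein sampler has mean cosine g and isotropic limit", {
  for (g in c(0.5, 0.9)) {
    ct <- sample_hg(1e6, g, seed = 42)
    expect_lt(abs(mean(ct) - g), 0.003)
    expect_true(all(ct >= -1 & ct <= 1))
  }
  ct0 <- sample_hg(2e5, 0, seed = 7)
  # isotropic: uniform on [-1, 1] -> mean 0, variance 1/3
  expect_lt(abs(mean(ct0)), 0.005)
  expect_lt(abs(var(ct0) - 1 / 3), 0.005)
})

test_that("Gaussian beam radii follow the 1/e^2 intensity profile", {
  r <- sample_beam_radius(5e5, 0.2, seed = 9)
  expect_lt(abs(mean(r < 0.2) - (1 - exp(-2))), 0.003)
  # radial intensity ~ exp(-2 r^2 / w^2): r^2 is exponential with
  # mean w^2/2
  expect_lt(abs(mean(r^2) - 0.02) / 0.02, 0.01)
  expect_true(all(sample_beam_radius(100, 0, seed = 1) == 0))
})

test_that("ballistic transmission matches Beer-Lambert across optical depths", {
  n <- 2e5
  for (mua_l in c(0.1, 0.41, 1, 3)) {
    mua <- mua_l / 0.41
    ph <- homogeneous_phantom(mu_a = mua, mu_s = 0)
    res <- suppressWarnings(
      simulate_photons(ph, source_spec(beam_waist = 0), full_face_detector(),
                       n_photons = n, seed = 11))
    p <- exp(-mua_l)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(res$detected_dc - p), 3 * se)
    # survivors are unscattered: every optical path equals the thickness
    expect_equal(range(res$records$opl), c(0.41, 0.41), tolerance = 1e-12)
    expect_equal(max(res$records$max_depth), 0.41, tolerance = 1e-12)
  }
})

test_that("vacuum transport is lossless", {
  ph <- homogeneous_phantom(mu_a = 0, mu_s = 0)
  res <- simulate_photons(ph, source_spec(beam_waist = 0),
                          full_face_detector(), n_photons = 1e4, seed = 2)
  expect_equal(res$detected_dc, 1.0)
  expect_equal(res$absorbed, 0)
})

test_that("energy is conserved in a scattering heterogeneous phantom", {
  st <- physio_state(0.9, "diastole", "light")
  ph <- cached_phantom(0.9, "diastole", "light", 660)
  res <- suppressWarnings(
    simulate_photons(ph, source_spec(), full_face_detector(),
                     n_photons = 2e4, seed = 5))
  total <- res$absorbed + res$exit_top + res$exit_bottom + res$exit_lateral
  expect_lt(abs(total / res$n_photons - 1), 1e-3)
})

test_that("identical seeds reproduce results bit for bit, different seeds differ", {
  ph <- homogeneous_phantom(mu_a = 0.5, mu_s = 50)
  run <- function(seed) simulate_photons(ph, source_spec(),
                                         full_face_detector(), 5e3, seed)
  a <- run(123); b <- run(123); c <- run(124)
  expect_identical(a$detected_dc, b$detected_dc)
  expect_identical(a$records, b$records)
  expect_identical(a$absorbed, b$absorbed)
  expect_false(identical(a$detected_dc, c$detected_dc))
})

test_that("fluence decays with depth along the axis of an absorbing medium", {
  ph <- homogeneous_phantom(mu_a = 2, mu_s = 20,
                            bins = c(21L, 21L, 41L))
  res <- simulate_photons(ph, source_spec(beam_waist = 0.05),
                          full_face_detector(), n_photons = 2e4, seed = 8,
                          fluence = TRUE)
  axis_profile <- res$fluence[11, 11, ]
  expect_gt(axis_profile[1], axis_profile[21])
  expect_gt(axis_profile[1], axis_profile[41])
  # smoothed profile is monotone decreasing
  sm <- stats::filter(axis_profile, rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0))
  expect_true(all(res$fluence >= 0))
})

test_that("roulette preserves expected weight and passes trivial cases", {
  expect_equal(roulette(0.5, 1e-4, 0.1, u = 0.99), 0.5)
  expect_equal(roulette(1e-5, 1e-4, 0.1, u = 0.05), 1e-4)
  expect_equal(roulette(1e-5, 1e-4, 0.1, u = 0.5), 0)
  expect_error(roulette(1e-5, 1e-4, 0), "survival_prob")
  set.seed(99)
  w <- 1e-5
  out <- replicate(20000, roulette(w, 1e-4, 0.1))
  expect_lt(abs(mean(out) - w) / w, 0.05)
})

test_that("aperture detection accepts by face and lateral distance only", {
  det <- detector_spec("bottom", center = c(0, 0), diameter = 0.3)
  expect_true(detect_hit(0.1, 0, "bottom", det))
  expect_false(detect_hit(0.2, 0, "bottom", det))
  expect_false(detect_hit(0, 0, "top", det))
  expect_true(detect_hit(0.15, 0, "bottom", det))  # boundary inclusive
})

test_that("photon records respect their invariants", {
  ph <- cached_phantom(0.9, "diastole", "light", 940)
  res <- suppressWarnings(
    simulate_photons(ph, source_spec(), detector_spec("bottom"),
                     n_photons = 3e4, seed = 21))
  rec <- res$records
  expect_gt(nrow(rec), 50)
  expect_true(all(rec$weight > 0 & rec$weight <= 1))
  # detected photons crossed the slab: OPL at least the thickness,
  # maximum depth equals it
  expect_true(all(rec$opl >= 0.41))
  expect_true(all(abs(rec$max_depth - 0.41) < 1e-9))
  expect_equal(res$detected_dc, sum(rec$weight) / res$n_photons)
})

test_that("simulation outputs round-trip through the disk container", {
  ph <- homogeneous_phantom(mu_a = 1, mu_s = 5, bins = c(9L, 9L, 11L))
  res <- suppressWarnings(
    simulate_photons(ph, source_spec(), full_face_detector(), 2e3, seed = 31,
                     fluence = TRUE))
  prefix <- file.path(withr::local_tempdir(), "run")
  write_mc_result(res, prefix)
  flu <- readBin(paste0(prefix, ".fluence.bin"), "double",
                 n = length(res$fluence))
  expect_equal(array(flu, dim = dim(res$fluence)), res$fluence)
  rec <- read.delim(paste0(prefix, ".records.tsv"))
  expect_equal(nrow(rec), nrow(res$records))
  expect_equal(rec$opl, res$records$opl, tolerance = 1e-6)
  summ <- readLines(paste0(prefix, ".summary.txt"))
  expect_true(any(grepl("^seed: 31", summ)))
})
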