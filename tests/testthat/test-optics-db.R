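# Optical-property database: chromophore mixing, baseline power law,
# Rayleigh+Mie scattering, and reconstruction of the published layer table.

test_that("baseline absorption follows the power law", {
  # frozen from direct evaluation of 7.84e8 * lambda^-3.255
  expect_equal(baseline_absorption(660), 0.5208352, tolerance = 1e-6)
  expect_equal(baseline_absorption(940), 0.1647346, tolerance = 1e-6)
  expect_equal(baseline_absorption(500), 1.2857858, tolerance = 1e-6)
  expect_error(baseline_absorption(-1), "positive")
  expect_error(baseline_absorption(0), "positive")
})

test_that("blood absorption is the saturation-weighted hemoglobin mix", {
  tab <- chromophore_table()
  expect_equal(blood_absorption(1.0, 660, tab), 1.71)
  expect_equal(blood_absorption(0.0, 940, tab), 3.71)
  expect_equal(blood_absorption(0.9, 660, tab), 0.9 * 1.71 + 0.1 * 17.27)
  expect_error(blood_absorption(1.2, 660, tab), "\\[0, 1\\]")
  expect_error(blood_absorption(0.9, 800, tab), "not present")
})

test_that("blood absorption is monotone in SO2, falling at red, rising at IR", {
  tab <- chromophore_table()
  so2 <- seq(0, 1, by = 0.1)
  red <- blood_absorption(so2, 660, tab)
  ir <- blood_absorption(so2, 940, tab)
  expect_true(all(diff(red) < 0))
  expect_true(all(diff(ir) > 0))
})

test_that("epidermis absorption reconstructs the published values", {
  # printed table: 13.86 / 67.65 at 660 nm, 4.32 / 20.89 at 940 nm;
  # tolerance covers one unit in the table's last printed digit
  st_l <- physio_state(0.9, "diastole", "light")
  st_d <- physio_state(0.9, "diastole", "dark")
  epi <- function(st) oxisim:::.composition_for("epidermis", st, tissue_config())
  expect_equal(layer_absorption(epi(st_l), st_l, 660), 13.86, tolerance = 0.015 / 13.86)
  expect_equal(layer_absorption(epi(st_d), st_d, 660), 67.65, tolerance = 0.015 / 67.65)
  expect_equal(layer_absorption(epi(st_l), st_l, 940), 4.32, tolerance = 0.015 / 4.32)
  expect_equal(layer_absorption(epi(st_d), st_d, 940), 20.89, tolerance = 0.015 / 20.89)
})

test_that("layer absorption is linear in each fraction and reduces to baseline", {
  st <- physio_state(0.8, "diastole", "light")
  tab <- chromophore_table()
  zero <- list(V_w = 0, V_m = 0, V_a = 0, V_v = 0)
  expect_equal(layer_absorption(zero, st, 660), baseline_absorption(660))
  # linearity: mu_a(comp) - mu_a(0) is proportional to each fraction
  for (nm in c("V_w", "V_m", "V_a", "V_v")) {
    c1 <- zero; c1[[nm]] <- 0.1
    c2 <- zero; c2[[nm]] <- 0.2
    d1 <- layer_absorption(c1, st, 660) - layer_absorption(zero, st, 660)
    d2 <- layer_absorption(c2, st, 660) - layer_absorption(zero, st, 660)
    expect_equal(d2, 2 * d1, tolerance = 1e-12)
  }
})

test_that("over-full artery composition warns once and applies the negative residual", {
  pkg_env <- oxisim:::.oxisim_env
  pkg_env$warned_residual <- NULL
  st <- physio_state(0.9, "diastole", "light")
  comp <- list(V_w = 0.6, V_m = 0, V_a = 0.3, V_v = 0.3)
  expect_warning(v <- layer_absorption(comp, st, 660), "residual")
  # frozen from hand evaluation: 0.3*muaA(0.9) + 0.3*muaV(0.8) +
  # 0.6*muaw - 0.2*baseline
  expect_equal(v, 2.324393, tolerance = 1e-6)
  # second call does not warn again
  expect_no_warning(layer_absorption(comp, st, 660))
  pkg_env$warned_residual <- NULL
})

test_that("reduced scattering and the 1/(1-g) scaling reconstruct published mu_s", {
  cfg <- tissue_config()
  der <- reduced_scattering(cfg$scattering_models$dermis, c(660, 940))
  art <- reduced_scattering(cfg$scattering_models$artery, c(660, 940))
  expect_equal(der[1], 27.896, tolerance = 1e-4)
  expect_equal(scattering_coefficient(der, 0.9), c(279, 194.7),
               tolerance = 5e-4)
  expect_equal(scattering_coefficient(art, 0.9), c(75.76, 53.19),
               tolerance = 1e-4)
  # artery model is pure Mie: a' * (500/lambda)
  expect_equal(art, 10 * 500 / c(660, 940))
  # unlisted f_ray treated as zero
  expect_equal(reduced_scattering(list(a_prime = 10, f_ray = NULL, b_mie = 1), 660),
               reduced_scattering(list(a_prime = 10, f_ray = 0, b_mie = 1), 660))
  expect_equal(scattering_coefficient(5, 0), 5)
  expect_error(scattering_coefficient(5, 1), "g must be")
})

test_that("assemble_media produces the four study media", {
  st <- physio_state(0.9, "diastole", "light")
  m <- suppressWarnings(assemble_media(st, 660))
  expect_equal(m$medium, c("epidermis", "dermis", "artery", "bone"))
  expect_equal(m$mu_a[1], 13.86, tolerance = 1e-3)
  expect_equal(m$mu_s[1], 250)
  expect_equal(m$mu_a[4], 0.351)
  expect_equal(m$mu_s[4], 344.5)
  expect_true(all(m$g == 0.9))
  expect_true(all(m$n == 1.43))
  # artery absorption at SaO2 0.9, diastole, 660 nm
  expect_equal(m$mu_a[3], 2.3244, tolerance = 1e-4)

  std <- physio_state(0.9, "diastole", "dark")
  md <- suppressWarnings(assemble_media(std, 660))
  expect_equal(md$mu_a[1], 67.65, tolerance = 3e-4)
  expect_equal(md$mu_s[1], 300)
  # dark epidermis differs only in the epidermis row
  expect_equal(md[-1, ], m[-1, ])

  # systole doubles arterial blood volume -> artery mu_a rises
  sts <- physio_state(0.9, "systole", "light")
  ms <- suppressWarnings(assemble_media(sts, 660))
  expect_gt(ms$mu_a[3], m$mu_a[3])
  expect_equal(ms$mu_a[-3], m$mu_a[-3])

  expect_error(suppressWarnings(assemble_media(st, 800)), "not")
})

test_that("physiological states enforce the venous-offset rule", {
  st <- physio_state(0.6, "systole", "dark")
  expect_equal(st$svo2, 0.5)
  expect_error(physio_state(0.05), "venous")
  expect_error(physio_state(1.2), "\\[0, 1\\]")
})

test_that("a user configuration file overrides the built-in tables", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- tissue_config()
  cfg$chromophores$melanin <- c(100, 50)
  yaml::write_yaml(cfg, cfg_path)
  custom <- tissue_config(cfg_path)
  expect_equal(chromophore_table(custom)$melanin, c(100, 50))
  # built-in remains untouched
  expect_equal(chromophore_table()$melanin, c(269.43, 82.99))
})
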