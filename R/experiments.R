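# End-to-end experiment orchestration: optode placement, seeded study
# runs over the (tone, SaO2, phase, wavelength, repeat) grid, and the
# summary comparisons between skin tones.

#' Experiment configuration
#'
#' Describes one experiment family: the optode geometry (transmission,
#' central reflection, or reflection at a finite source-detector
#' separation), the physiological sweep, and the Monte Carlo budget.
#'
#' @param geometry_mode `"transmission"`, `"reflection_central"` or
#'   `"reflection_sd"`.
#' @param sd_separation Source-detector separation in cm
#'   (`reflection_sd` only; the study uses 0.1, 0.25, 0.45).
#' @param sao2_grid Arterial saturations to sweep.
#' @param tones Skin tones to simulate.
#' @param wavelengths Wavelengths, nm.
#' @param n_photons Photon packets per simulation.
#' @param n_repeats Independent repeats (distinct seeds) per configuration.
#' @param base_seed Base integer seed; every simulation's seed is derived
#'   from it deterministically.
#' @param spec Phantom [geometry_spec()].
#' @param tissue Tissue parameter configuration from [tissue_config()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(geometry_mode = c("transmission",
                                                "reflection_central",
                                                "reflection_sd"),
                              sd_separation = NULL,
                              sao2_grid = seq(0.6, 1.0, by = 0.1),
                              tones = c("light", "dark"),
                              wavelengths = c(660, 940),
                              n_photons = 1e6,
                              n_repeats = 3,
                              base_seed = 1,
                              spec = geometry_spec(),
                              tissue = tissue_config()) {
  geometry_mode <- match.arg(geometry_mode)
  if (geometry_mode == "reflection_sd") {
    if (is.null(sd_separation)) {
      stop("reflection_sd requires sd_separation")
    }
  } else {
    sd_separation <- 0
  }
  stopifnot(n_repeats >= 1, n_photons >= 1)
  structure(
    list(geometry_mode = geometry_mode, sd_separation = sd_separation,
         sao2_grid = sao2_grid, tones = tones, wavelengths = wavelengths,
         n_photons = n_photons, n_repeats = n_repeats,
         base_seed = as.integer(base_seed), spec = spec, tissue = tissue),
    class = "experiment_config"
  )
}

#' Place the source and detector for a geometry mode
#'
#' Transmission: source at the top-face center, detector at the
#' bottom-face center. Central reflection: source and detector both at the
#' top-face center. Finite separation: the separation is split
#' symmetrically about the origin, source at (-s/2, 0) and detector at
#' (+s/2, 0) on the top face, keeping the aperture within the face at the
#' largest study separation.
#'
#' @param config An [experiment_config()].
#' @return A list with elements `source` and `detector`.
#' @export
place_optodes <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ext <- config$spec$extent
  det_d <- 0.3
  if (config$geometry_mode == "transmission") {
    src <- source_spec(center = c(0, 0))
    det <- detector_spec(face = "bottom", center = c(0, 0), diameter = det_d)
  } else if (config$geometry_mode == "reflection_central") {
    src <- source_spec(center = c(0, 0))
    det <- detector_spec(face = "top", center = c(0, 0), diameter = det_d)
  } else {
    s <- config$sd_separation
    if (s / 2 + det_d / 2 > ext[1] / 2) {
      stop("source-detector separation ", s,
           " cm places the aperture outside the domain")
    }
    src <- source_spec(center = c(-s / 2, 0))
    det <- detector_spec(face = "top", center = c(s / 2, 0), diameter = det_d)
  }
  list(source = src, detector = det)
}

#' Derive a per-run seed from the base seed
#'
#' Deterministic integer mixing (kept below 2^31) so that every simulation
#' in a study has its own reproducible random stream.
#'
#' @param base_seed Base integer seed.
#' @param index Run index (>= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647
  s <- (as.double(base_seed) %% m) * 48271 %% m
  as.integer((s + index * 104729) %% m + 1)
}

#' Run a full experiment family
#'
#' For every (skin tone, SaO2, wavelength, repeat): assembles media for
#' both cardiac phases, simulates diastole and systole with a shared
#' derived seed (a paired-phase design: common random numbers cancel most
#' of the Monte Carlo noise in the small diastole-systole difference), and
#' computes the PPG metrics. Runs are deterministic given `base_seed`.
#'
#' @param config An [experiment_config()].
#' @param keep_records If `TRUE`, keep per-detected-photon records of the
#'   diastolic runs (for path-length/penetration-depth statistics).
#' @param progress If `TRUE`, print one line per simulation pair.
#' @return An object of class `oxi_study`: `metrics` (one row per tone,
#'   SaO2, wavelength, repeat), `r` (ratio of ratios per tone, SaO2,
#'   repeat), `records` (named list, if kept), `config`.
#' @export
run_study <- function(config, keep_records = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  optodes <- place_optodes(config)
  phantom <- build_phantom(config$spec, media = NULL)

  grid <- expand.grid(
    rep = seq_len(config$n_repeats),
    wavelength = config$wavelengths,
    sao2 = config$sao2_grid,
    tone = config$tones,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  rows <- vector("list", nrow(grid))
  records <- if (keep_records) vector("list", nrow(grid)) else NULL
  rec_names <- character(nrow(grid))

  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    seed_i <- derive_seed(config$base_seed, i)
    dc <- numeric(2); ndet <- numeric(2)
    for (p in 1:2) {
      phase <- c("diastole", "systole")[p]
      st <- physio_state(gi$sao2, phase = phase, skin_tone = gi$tone)
      ph <- phantom
      ph$media <- assemble_media(st, gi$wavelength, config$tissue)
      ph$provenance <- list(state = st, wavelength = gi$wavelength)
      res <- withCallingHandlers(
        simulate_photons(ph, optodes$source, optodes$detector,
                         n_photons = config$n_photons, seed = seed_i),
        warning = function(w) {
          if (grepl("no photons detected", conditionMessage(w))) {
            warning("zero detected photons for ", gi$tone, " SaO2=",
                    gi$sao2, " ", phase, " ", gi$wavelength,
                    " nm; recorded as missing", call. = FALSE)
            invokeRestart("muffleWarning")
          }
        }
      )
      dc[p] <- res$detected_dc
      ndet[p] <- res$n_detected
      if (keep_records && phase == "diastole") {
        records[[i]] <- res$records
        rec_names[i] <- paste(gi$tone, gi$sao2, gi$wavelength, gi$rep,
                              sep = "_")
      }
    }
    rows[[i]] <- data.frame(
      geometry = config$geometry_mode,
      sd_separation = config$sd_separation,
      tone = gi$tone, sao2 = gi$sao2, wavelength = gi$wavelength,
      rep = gi$rep, seed = seed_i,
      dc_diastole = dc[1], dc_systole = dc[2],
      ac = dc[1] - dc[2],
      pi = if (dc[1] > 0) (dc[1] - dc[2]) / dc[1] else NA_real_,
      n_detected_diastole = ndet[1], n_detected_systole = ndet[2]
    )
    if (progress) {
      cat(sprintf("[%d/%d] %s SaO2=%.2f %g nm rep %d: PI = %.4g\n",
                  i, nrow(grid), gi$tone, gi$sao2, gi$wavelength, gi$rep,
                  rows[[i]]$pi))
    }
  }
  metrics <- do.call(rbind, rows)
  if (keep_records) names(records) <- rec_names

  # ratio of ratios per (tone, sao2, rep), red / infrared
  red <- metrics[metrics$wavelength == min(config$wavelengths), ]
  ir <- metrics[metrics$wavelength == max(config$wavelengths), ]
  key <- function(d) paste(d$tone, d$sao2, d$rep)
  ir <- ir[match(key(red), key(ir)), ]
  r_tab <- data.frame(
    geometry = config$geometry_mode,
    sd_separation = config$sd_separation,
    tone = red$tone, sao2 = red$sao2, rep = red$rep,
    pi_red = red$pi, pi_ir = ir$pi,
    r = ratio_of_ratios(red$pi, ir$pi)
  )

  structure(list(metrics = metrics, r = r_tab, records = records,
                 config = config),
            class = "oxi_study")
}

#' @export
print.oxi_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "oxi_study: %s%s, %d SaO2 levels x %d tones x %d repeats, %g photons\n",
    cfg$geometry_mode,
    if (cfg$geometry_mode == "reflection_sd")
      sprintf(" (s = %g cm)", cfg$sd_separation) else "",
    length(cfg$sao2_grid), length(cfg$tones), cfg$n_repeats, cfg$n_photons))
  invisible(x)
}

#' AC/DC attenuation factors of dark relative to light skin
#'
#' The four fractional attenuations at one saturation level: a (AC red),
#' b (DC red), c (AC infrared), d (DC infrared), each computed per repeat
#' (paired by repeat index) and summarized as mean and standard deviation
#' over repeats.
#'
#' @param study An `oxi_study` containing both tones.
#' @param at_sao2 Saturation level at which to evaluate (default 0.9).
#' @return A data frame with columns `factor`, `component`, `wavelength`,
#'   `mean`, `sd`.
#' @export
attenuation_factors <- function(study, at_sao2 = 0.9) {
  m <- study$metrics
  m <- m[abs(m$sao2 - at_sao2) < 1e-9, ]
  if (!all(c("light", "dark") %in% m$tone)) {
    stop("study must contain both skin tones")
  }
  wl <- sort(unique(m$wavelength))
  out <- list()
  specs <- list(
    a = list(comp = "ac", wavelength = wl[1]),
    b = list(comp = "dc_diastole", wavelength = wl[1]),
    c = list(comp = "ac", wavelength = wl[2]),
    d = list(comp = "dc_diastole", wavelength = wl[2])
  )
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    li <- m[m$tone == "light" & m$wavelength == sp$wavelength, ]
    da <- m[m$tone == "dark" & m$wavelength == sp$wavelength, ]
    da <- da[match(li$rep, da$rep), ]
    f <- attenuation_fraction(da[[sp$comp]], li[[sp$comp]])
    out[[nm]] <- data.frame(
      factor = nm,
      component = if (sp$comp == "ac") "AC" else "DC",
      wavelength = sp$wavelength,
      mean = mean(f),
      sd = if (length(f) > 1) stats::sd(f) else 0
    )
  }
  do.call(rbind, out)
}

#' Compare SpO2-R curves (and PI curves) between skin tones
#'
#' Pairs the ratio-of-ratios samples of the two tones by (SaO2 level,
#' repeat index) and applies the two-sided Wilcoxon signed-rank test;
#' also reports Euclidean distances between the repeat-averaged PI-vs-SaO2
#' curves at each wavelength and between the repeat-averaged R curves.
#'
#' @param study An `oxi_study` containing both tones.
#' @return A list: `wilcoxon_p`, `pi_distance` (named by wavelength),
#'   `r_distance`, `mean_r_gap` (mean over the SaO2 grid of
#'   R_light - R_dark), `r_curves` (repeat-averaged R per tone and SaO2).
#' @export
compare_tones <- function(study) {
  r <- study$r
  li <- r[r$tone == "light", ]
  da <- r[r$tone == "dark", ]
  key <- function(d) paste(d$sao2, d$rep)
  da <- da[match(key(li), key(da)), ]
  p <- compare_curves_wilcoxon(li$r, da$r)

  m <- study$metrics
  wl <- sort(unique(m$wavelength))
  pi_dist <- vapply(wl, function(w) {
    avg <- function(tone) {
      sub <- m[m$tone == tone & m$wavelength == w, ]
      tapply(sub$pi, sub$sao2, mean)
    }
    curve_distance(avg("light"), avg("dark"))
  }, numeric(1))
  names(pi_dist) <- paste0(wl, "nm")

  ravg <- function(tone) {
    sub <- r[r$tone == tone, ]
    tapply(sub$r, sub$sao2, mean)
  }
  rl <- ravg("light"); rd <- ravg("dark")
  curves <- data.frame(
    sao2 = as.numeric(names(rl)),
    r_light = as.numeric(rl),
    r_dark = as.numeric(rd)
  )
  list(
    wilcoxon_p = p,
    pi_distance = pi_dist,
    r_distance = curve_distance(rl, rd),
    mean_r_gap = mean(rl - rd),
    r_curves = curves
  )
}

#' Repeat-averaged light-skin calibration curve from a study
#'
#' @param study An `oxi_study`.
#' @param tone Tone whose curve to extract (default `"light"`).
#' @return A data frame with columns `sao2`, `r`, usable with
#'   [estimate_spo2()].
#' @export
calibration_curve <- function(study, tone = "light") {
  r <- study$r[study$r$tone == tone, ]
  agg <- tapply(r$r, r$sao2, mean)
  data.frame(sao2 = as.numeric(names(agg)), r = as.numeric(agg))
}
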