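# Pulse-oximetry analysis: AC/PI/R, attenuation decomposition, path-length
# and penetration-depth statistics, curve comparisons.

#' Pulsatile (AC) component of the detected intensity
#'
#' Difference between the diastolic and systolic detected DC intensities.
#' In this model systole adds absorber (arterial blood volume doubles), so
#' the true AC is non-negative; a negative value can only arise from Monte
#' Carlo noise and is returned unclipped with a warning so that downstream
#' error bars remain unbiased.
#'
#' @param dc_diastole,dc_systole Detected DC intensities (>= 0).
#' @return AC intensity (dimensionless).
#' @export
ac_component <- function(dc_diastole, dc_systole) {
  stopifnot(all(dc_diastole >= 0), all(dc_systole >= 0))
  ac <- dc_diastole - dc_systole
  if (any(ac < 0)) {
    warning("negative AC component (Monte Carlo noise); value retained",
            call. = FALSE)
  }
  ac
}

#' Perfusion index
#'
#' Ratio of the AC pulsatile intensity to the DC diastolic intensity.
#'
#' @param dc_diastole,dc_systole Detected DC intensities; alternatively
#'   pass a list with elements `dc_diastole` and `dc_systole`.
#' @return PI (dimensionless).
#' @export
perfusion_index <- function(dc_diastole, dc_systole = NULL) {
  if (is.list(dc_diastole)) {
    m <- dc_diastole
    dc_diastole <- m$dc_diastole
    dc_systole <- m$dc_systole
  }
  if (any(dc_diastole == 0)) {
    stop("undefined perfusion index: dc_diastole is 0")
  }
  ac_component(dc_diastole, dc_systole) / dc_diastole
}

#' Combine paired diastole/systole intensities into PPG metrics
#'
#' @param dc_diastole,dc_systole Detected DC intensities.
#' @param wavelength Wavelength, nm.
#' @return A one-row data frame with `wavelength`, `dc_diastole`,
#'   `dc_systole`, `ac`, `pi`.
#' @export
ppg_metrics <- function(dc_diastole, dc_systole, wavelength = NA_real_) {
  data.frame(
    wavelength = wavelength,
    dc_diastole = dc_diastole,
    dc_systole = dc_systole,
    ac = ac_component(dc_diastole, dc_systole),
    pi = perfusion_index(dc_diastole, dc_systole)
  )
}

#' Ratio of ratios
#'
#' `R = PI(red) / PI(infrared)`; inversely related to SpO2.
#'
#' @param pi_red,pi_ir Perfusion indices at the red and infrared
#'   wavelengths.
#' @return R (dimensionless).
#' @export
ratio_of_ratios <- function(pi_red, pi_ir) {
  if (any(pi_ir == 0)) stop("undefined ratio of ratios: pi_ir is 0")
  pi_red / pi_ir
}

#' Fractional attenuation of dark skin relative to light skin
#'
#' `1 - I_dark / I_light` for any intensity component (AC or DC).
#'
#' @param intensity_dark,intensity_light Intensities of the same component
#'   in the two skin-tone models.
#' @return Fractional decrease (dimensionless; in \[0, 1\] when dark is
#'   dimmer than light).
#' @export
attenuation_fraction <- function(intensity_dark, intensity_light) {
  if (any(intensity_light == 0)) {
    stop("undefined attenuation fraction: intensity_light is 0")
  }
  1 - intensity_dark / intensity_light
}

#' Path-length / penetration-depth statistics of detected photons
#'
#' Median and interquartile range of the optical path length (total
#' distance traveled) or penetration depth (maximum z reached) over
#' detected photons, with a normality p-value from a Kolmogorov-Smirnov
#' test against a normal with sample-estimated moments (Lilliefors). The
#' sample is capped at `max_n` detected photons (the first `max_n` in
#' arrival order, itself a random subset).
#'
#' By default every detected photon counts equally (a histogram of
#' detected photons). With `weighted = TRUE` the quantiles weight each
#' record by its exit weight, which under implicit-capture transport is
#' the physical distribution of detected light; the normality test always
#' uses the unweighted values.
#'
#' @param records Data frame of per-photon records with columns `weight`,
#'   `opl` and `max_depth` (as in an `mc_result`).
#' @param quantity `"opl"` or `"pd"`.
#' @param max_n Sampling cap (default 10000).
#' @param weighted Weight records by exit weight?
#' @return A list of class `path_stats`: `median`, `iqr`, `n`, `quantity`,
#'   `normality_p`.
#' @export
path_statistics <- function(records, quantity = c("opl", "pd"),
                            max_n = 10000, weighted = FALSE) {
  quantity <- match.arg(quantity)
  if (is.null(records) || nrow(records) == 0) {
    stop("no detected-photon records")
  }
  if (nrow(records) > max_n) records <- records[seq_len(max_n), ]
  x <- if (quantity == "opl") records$opl else records$max_depth
  if (isTRUE(weighted)) {
    qs <- weighted_quantile(x, records$weight, c(0.25, 0.5, 0.75))
    med <- qs[2]; iqr <- qs[3] - qs[1]
  } else {
    med <- stats::median(x)
    iqr <- unname(stats::IQR(x))
  }
  p <- if (length(x) >= 5 && stats::sd(x) > 0) {
    unname(nortest::lillie.test(x)$p.value)
  } else {
    NA_real_
  }
  structure(
    list(median = unname(med),
         iqr = unname(iqr),
         n = length(x),
         quantity = quantity,
         normality_p = p),
    class = "path_stats"
  )
}

#' Weighted sample quantiles
#'
#' Quantiles of a weighted sample by linear interpolation of the
#' cumulative weight distribution.
#'
#' @param x Numeric values.
#' @param w Non-negative weights.
#' @param probs Probabilities in \[0, 1\].
#' @return Quantile values.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' @export
print.path_stats <- function(x, ...) {
  cat(sprintf("%s over %d detected photons: median %.3g cm (IQR %.3g)",
              toupper(x$quantity), x$n, x$median, x$iqr))
  if (!is.na(x$normality_p)) {
    cat(sprintf("; KS normality p = %.3g", x$normality_p))
  }
  cat("\n")
  invisible(x)
}

#' Euclidean distance between two response curves
#'
#' Applied to PI-vs-SaO2 (or R-vs-SaO2) vectors sampled at the same
#' saturation grid.
#'
#' @param curve_a,curve_b Numeric vectors of equal length.
#' @return The Euclidean distance.
#' @export
curve_distance <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b)) {
    stop("curves must have equal length")
  }
  sqrt(sum((curve_a - curve_b)^2))
}

#' Paired Wilcoxon signed-rank comparison of two R curves
#'
#' Two-sided signed-rank test on paired samples (paired by saturation
#' level and repeat index). Zero differences are dropped; if all
#' differences are zero the test is degenerate and p = 1 is returned with
#' a warning. For up to `exact_max` non-zero pairs, the exact permutation
#' distribution over all sign assignments is enumerated (average ranks for
#' tied magnitudes), and the two-sided p-value is the probability of a
#' rank-sum deviation from its null mean at least as large as observed;
#' beyond that, the normal approximation of [stats::wilcox.test()] is used.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest number of pairs for exact enumeration.
#' @return Two-sided p-value.
#' @export
compare_curves_wilcoxon <- function(x, y, exact_max = 20) {
  if (length(x) != length(y)) stop("samples must be paired (equal length)")
  if (length(x) < 5) stop("need at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; degenerate test, p = 1",
            call. = FALSE)
    return(1)
  }
  if (n <= exact_max) {
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    mu <- sum(r) / 2
    dev_obs <- abs(w_obs - mu)
    # enumerate all 2^n sign assignments
    p_count <- 0L
    total <- 2L^n
    for (k in 0:(total - 1L)) {
      signs <- bitwAnd(k, bitwShiftL(1L, 0:(n - 1L))) != 0L
      w <- sum(r[signs])
      if (abs(w - mu) >= dev_obs - 1e-12) p_count <- p_count + 1L
    }
    return(p_count / total)
  }
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
  )
}

#' Estimate SpO2 from a ratio-of-ratios via a calibration curve
#'
#' Formalizes the clinical reading error: a measured R (for example from a
#' dark-skin model) is converted to SpO2 by linear interpolation of a
#' calibration curve derived from another model (typically light skin).
#' The calibration must be monotone in R; readings outside the calibrated
#' R range are linearly extrapolated and flagged.
#'
#' @param r Measured ratio(s) of ratios.
#' @param calibration Data frame with columns `sao2` and `r` (one row per
#'   saturation level of the calibration curve).
#' @return A list: `spo2` (estimates) and `extrapolated` (logical flags).
#' @export
estimate_spo2 <- function(r, calibration) {
  stopifnot(is.data.frame(calibration),
            all(c("sao2", "r") %in% names(calibration)))
  rs <- calibration$r[order(calibration$sao2)]
  if (!(all(diff(rs) < 0) || all(diff(rs) > 0))) {
    stop("calibration curve is not monotone in R")
  }
  cal <- calibration[order(calibration$r), ]
  extrapolated <- r < min(cal$r) | r > max(cal$r)
  fit <- stats::approx(cal$r, cal$sao2, xout = r, rule = 2)
  spo2 <- fit$y
  if (any(extrapolated)) {
    # linear extrapolation from the end segments
    lo <- cal[1:2, ]; hi <- cal[(nrow(cal) - 1):nrow(cal), ]
    slope_lo <- (lo$sao2[2] - lo$sao2[1]) / (lo$r[2] - lo$r[1])
    slope_hi <- (hi$sao2[2] - hi$sao2[1]) / (hi$r[2] - hi$r[1])
    below <- extrapolated & r < min(cal$r)
    above <- extrapolated & r > max(cal$r)
    spo2[below] <- lo$sao2[1] + slope_lo * (r[below] - lo$r[1])
    spo2[above] <- hi$sao2[2] + slope_hi * (r[above] - hi$r[2])
    warning("R outside the calibrated range; estimate extrapolated",
            call. = FALSE)
  }
  list(spo2 = spo2, extrapolated = extrapolated)
}
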