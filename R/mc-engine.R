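# R surface of the Monte Carlo transport engine.

#' Photon source specification
#'
#' A collimated (+z) Gaussian beam incident on the top face. The beam's
#' "radial width" is its 1/e^2 intensity radius; samples falling outside
#' the domain cross-section are redrawn.
#'
#' @param center Numeric length-2, beam center (x, y) on the top face, cm.
#' @param beam_waist 1/e^2 intensity radius, cm (0 gives a point source).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(center = c(0, 0), beam_waist = 0.2) {
  stopifnot(length(center) == 2, beam_waist >= 0)
  structure(list(center = as.numeric(center), beam_waist = beam_waist),
            class = "source_spec")
}

#' Photon detector specification
#'
#' A circular aperture on the top or bottom face. By default any photon
#' exiting through the aperture disc is collected regardless of angle; an
#' optional numerical-aperture angular cut is available.
#'
#' @param face `"top"` or `"bottom"`.
#' @param center Numeric length-2, aperture center (x, y), cm.
#' @param diameter Aperture diameter, cm.
#' @param numerical_aperture Dimensionless fiber NA. By default no angular
#'   cut is applied (NA = 1 is read as accept-all: the model has uniform
#'   refractive index and no exterior medium). Setting
#'   `angular_cut = TRUE` instead restricts acceptance to the half-angle
#'   `asin(NA / medium_n)` inside the tissue (about 44 degrees for NA = 1
#'   in the n = 1.43 medium).
#' @param medium_n Refractive index of the medium the collector faces.
#' @param angular_cut Apply the NA-derived angular acceptance cut?
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(face = c("bottom", "top"), center = c(0, 0),
                          diameter = 0.3, numerical_aperture = 1,
                          medium_n = 1.43, angular_cut = FALSE) {
  face <- match.arg(face)
  stopifnot(length(center) == 2, diameter > 0,
            numerical_aperture > 0, medium_n >= 1)
  cos_min <- if (!isTRUE(angular_cut) || numerical_aperture >= medium_n) {
    0
  } else {
    sqrt(1 - (numerical_aperture / medium_n)^2)
  }
  structure(list(face = face, center = as.numeric(center),
                 diameter = diameter,
                 numerical_aperture = numerical_aperture,
                 medium_n = medium_n, angular_cut = isTRUE(angular_cut),
                 cos_min = cos_min),
            class = "detector_spec")
}

#' Run the voxel Monte Carlo simulation
#'
#' Transports `n_photons` weighted photon packets through the phantom:
#' Gaussian-beam launch, dimensionless step lengths converted through the
#' local interaction coefficient with carry-over at voxel boundaries,
#' implicit-capture absorption weighting, Henyey-Greenstein scattering,
#' Russian roulette termination, and aperture detection. Results are
#' deterministic given the seed.
#'
#' @param phantom A `tissue_phantom` carrying media (see
#'   [phantom_for_state()]).
#' @param source A [source_spec()].
#' @param detector A [detector_spec()].
#' @param n_photons Number of photon packets to launch.
#' @param seed Integer seed for the simulation's random stream.
#' @param fluence If `TRUE`, accumulate the 3-d fluence volume
#'   (path-length estimator, W/cm^2 per W incident).
#' @param lateral `"infinite"` (default): the tissue continues unchanged
#'   beyond the lateral grid edges (the finger model is laterally
#'   unbounded; photons may wander outside the voxel grid and return, with
#'   fluence recorded only inside). `"escape"`: photons are terminated at
#'   the side walls.
#' @param roulette_threshold Weight below which roulette is played.
#' @param survival_prob Roulette survival probability.
#' @return An object of class `mc_result`: `detected_dc` (sum of detected
#'   weights / photons launched), `n_detected`, `records` (data frame with
#'   `weight`, `opl`, `max_depth` per detected photon), energy tallies
#'   (`absorbed`, `exit_top`, `exit_bottom`, `exit_lateral`,
#'   `roulette_lost`, `roulette_gain`), optional `fluence` array,
#'   `n_photons` and `seed`.
#' @export
simulate_photons <- function(phantom, source, detector, n_photons, seed,
                             fluence = FALSE,
                             lateral = c("infinite", "escape"),
                             roulette_threshold = 1e-4,
                             survival_prob = 0.1) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(source, "source_spec"),
            inherits(detector, "detector_spec"),
            n_photons >= 1)
  if (is.null(phantom$media)) {
    stop("phantom carries no media; build it with phantom_for_state() or ",
         "pass media to build_phantom()")
  }
  if (survival_prob <= 0 || survival_prob > 1) {
    stop("survival_prob must lie in (0, 1]")
  }
  med <- phantom$media
  ext <- phantom$extent
  det_r <- detector$diameter / 2
  if (lateral == "escape" &&
      (abs(detector$center[1]) > ext[1] / 2 ||
       abs(detector$center[2]) > ext[2] / 2)) {
    stop("detector center lies outside the domain face ",
         "(photons escape at the side walls)")
  }
  res <- mc_simulate_cpp(
    labels = phantom$labels,
    bins = dim(phantom$labels),
    extent = ext,
    mua = med$mu_a, mus = med$mu_s, g = med$g,
    src_x = source$center[1], src_y = source$center[2],
    waist = source$beam_waist,
    det_face = if (detector$face == "top") 0L else 1L,
    det_x = detector$center[1], det_y = detector$center[2],
    det_radius = det_r,
    det_cos_min = detector$cos_min,
    n_photons = as.double(n_photons), seed = as.double(seed),
    do_fluence = isTRUE(fluence),
    lateral_infinite = (lateral == "infinite"),
    roulette_threshold = roulette_threshold,
    survival_prob = survival_prob
  )
  if (res$n_detected == 0) {
    warning("no photons detected; detected_dc = 0 and records are empty",
            call. = FALSE)
  }
  structure(
    list(
      detected_dc = res$detected_dc,
      n_detected = res$n_detected,
      records = data.frame(weight = res$weight, opl = res$opl,
                           max_depth = res$max_depth),
      absorbed = res$absorbed,
      exit_top = res$exit_top,
      exit_bottom = res$exit_bottom,
      exit_lateral = res$exit_lateral,
      roulette_lost = res$roulette_lost,
      roulette_gain = res$roulette_gain,
      fluence = res$fluence,
      n_photons = n_photons,
      seed = seed,
      source = source,
      detector = detector
    ),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "mc_result: %g photons (seed %s), detected DC %.4g (%g photons)\n",
    x$n_photons, format(x$seed), x$detected_dc, x$n_detected))
  invisible(x)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Draws from the Henyey-Greenstein phase function by inverse CDF; the mean
#' of the samples converges to g, and g = 0 reduces to a uniform cosine.
#'
#' @param n Number of draws.
#' @param g Anisotropy factor, -1 < g < 1.
#' @param seed Integer seed.
#' @return Numeric vector of deflection cosines.
#' @export
sample_hg <- function(n, g, seed) {
  stopifnot(g > -1, g < 1)
  sample_hg_cpp(as.integer(n), g, as.double(seed))
}

#' Sample launch radii of the Gaussian beam
#'
#' Radii drawn from the Gaussian intensity profile with 1/e^2 radius
#' `waist`; the fraction of samples with r < waist is 1 - exp(-2).
#'
#' @param n Number of draws.
#' @param waist 1/e^2 intensity radius, cm.
#' @param seed Integer seed.
#' @return Numeric vector of radii, cm.
#' @export
sample_beam_radius <- function(n, waist, seed) {
  sample_beam_cpp(as.integer(n), waist, as.double(seed))
}

#' Russian roulette weight termination (reference implementation)
#'
#' If the weight is below the threshold, the photon survives with
#' probability `survival_prob` and weight `weight / survival_prob`, else it
#' is terminated (weight 0). Expectation of the weight is preserved. This
#' mirrors the rule applied inside the compiled transport kernel.
#'
#' @param weight Current photon weight (> 0).
#' @param threshold Roulette threshold.
#' @param survival_prob Survival probability in (0, 1].
#' @param u Uniform random draw in \[0, 1); defaults to `runif(1)`.
#' @return The post-roulette weight (0 if terminated).
#' @export
roulette <- function(weight, threshold = 1e-4, survival_prob = 0.1,
                     u = stats::runif(1)) {
  stopifnot(weight > 0)
  if (survival_prob <= 0 || survival_prob > 1) {
    stop("survival_prob must lie in (0, 1]")
  }
  if (weight >= threshold) return(weight)
  if (u < survival_prob) weight / survival_prob else 0
}

#' Aperture detection rule (reference implementation)
#'
#' A photon exiting the domain is accepted iff its exit face matches the
#' detector face and its exit point lies within the aperture disc. With
#' numerical aperture 1 there is no angular cut. Mirrors the rule applied
#' inside the compiled kernel.
#'
#' @param exit_x,exit_y Exit coordinates, cm.
#' @param exit_face `"top"`, `"bottom"` or `"lateral"`.
#' @param detector A [detector_spec()].
#' @return Logical: accepted?
#' @export
detect_hit <- function(exit_x, exit_y, exit_face, detector) {
  if (exit_face != detector$face) return(FALSE)
  dx <- exit_x - detector$center[1]
  dy <- exit_y - detector$center[2]
  sqrt(dx^2 + dy^2) <= detector$diameter / 2
}

#' Write simulation outputs to disk
#'
#' Stores the fluence volume (if present) as a raw double array with a
#' text sidecar header, the per-detected-photon records as a
#' tab-separated table, and a run summary (seed, photon count, detected
#' DC, energy tallies) as a key-value text file.
#'
#' @param result An `mc_result` from [simulate_photons()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_mc_result <- function(result, prefix) {
  stopifnot(inherits(result, "mc_result"))
  paths <- character(0)
  if (!is.null(result$fluence)) {
    bin <- paste0(prefix, ".fluence.bin")
    writeBin(as.double(result$fluence), bin, size = 8)
    hdr <- paste0(prefix, ".fluence.header.txt")
    writeLines(c(
      "oxisim fluence v1",
      paste("dim:", paste(dim(result$fluence), collapse = " ")),
      "units: W/cm^2 per W incident",
      "storage: float64, x fastest, then y, then z"
    ), hdr)
    paths <- c(paths, bin, hdr)
  }
  rec <- paste0(prefix, ".records.tsv")
  utils::write.table(result$records, rec, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summ <- paste0(prefix, ".summary.txt")
  writeLines(c(
    paste("seed:", result$seed),
    paste("n_photons:", format(result$n_photons, scientific = FALSE)),
    paste("detected_dc:", format(result$detected_dc, digits = 12)),
    paste("n_detected:", result$n_detected),
    paste("absorbed:", format(result$absorbed, digits = 12)),
    paste("exit_top:", format(result$exit_top, digits = 12)),
    paste("exit_bottom:", format(result$exit_bottom, digits = 12)),
    paste("exit_lateral:", format(result$exit_lateral, digits = 12))
  ), summ)
  invisible(c(paths, rec, summ))
}
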