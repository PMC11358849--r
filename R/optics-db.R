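# Tissue optical-property database: chromophore-driven absorption and
# Rayleigh+Mie reduced scattering for the four finger-model media.

.oxisim_env <- new.env(parent = emptyenv())

#' Load the tissue optical-parameter configuration
#'
#' Reads the built-in parameter tables (chromophore absorption coefficients,
#' per-layer volume fractions, reduced-scattering model parameters, tabulated
#' epidermis/bone properties, geometry defaults) from a human-readable YAML
#' file. A user-supplied file with the same layout overrides the built-in one.
#'
#' @param path Path to a YAML configuration; `NULL` (default) uses the
#'   configuration shipped with the package.
#' @return A named list mirroring the configuration file.
#' @export
tissue_config <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.oxisim_env$config)) return(.oxisim_env$config)
    path <- system.file("extdata", "tissue_optics.yaml", package = "oxisim")
    cfg <- yaml::read_yaml(path)
    cfg$baseline_absorption$scale <- as.numeric(cfg$baseline_absorption$scale)
    .oxisim_env$config <- cfg
    return(cfg)
  }
  cfg <- yaml::read_yaml(path)
  cfg$baseline_absorption$scale <- as.numeric(cfg$baseline_absorption$scale)
  cfg
}

#' Chromophore absorption-coefficient table
#'
#' Wavelength-indexed absorption coefficients (cm^-1) of melanin, water,
#' oxyhemoglobin (HbO2) and deoxyhemoglobin (Hbb) at the two pulse-oximetry
#' wavelengths, 660 nm (red) and 940 nm (infrared).
#'
#' @param config Configuration list from [tissue_config()].
#' @return A data frame with columns `wavelength`, `melanin`, `water`,
#'   `hbo2`, `hbb`.
#' @export
chromophore_table <- function(config = tissue_config()) {
  ch <- config$chromophores
  tab <- data.frame(
    wavelength = as.numeric(ch$wavelength),
    melanin    = as.numeric(ch$melanin),
    water      = as.numeric(ch$water),
    hbo2       = as.numeric(ch$hbo2),
    hbb        = as.numeric(ch$hbb)
  )
  stopifnot(all(tab$melanin > 0), all(tab$water > 0),
            all(tab$hbo2 > 0), all(tab$hbb > 0))
  tab
}

.chromophore_row <- function(wavelength, table) {
  i <- match(wavelength, table$wavelength)
  if (is.na(i)) {
    stop("wavelength ", wavelength,
         " nm not present in the chromophore table (have: ",
         paste(table$wavelength, collapse = ", "),
         "); supply spectra via a user configuration to extend it")
  }
  table[i, ]
}

#' Baseline tissue absorption
#'
#' Background absorption attributed to chromophores other than melanin,
#' water and blood, modeled as a power law of wavelength:
#' `mu_a,baseline = 7.84e8 * lambda^-3.255` (cm^-1, lambda in nm).
#'
#' @param wavelength Wavelength in nm (vectorized).
#' @param config Configuration list from [tissue_config()].
#' @return Baseline absorption coefficient(s), cm^-1.
#' @export
baseline_absorption <- function(wavelength, config = tissue_config()) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    stop("wavelength must be positive")
  }
  b <- config$baseline_absorption
  b$scale * wavelength^b$exponent
}

#' Whole-blood absorption at a given oxygen saturation
#'
#' Linear mix of the oxy- and deoxyhemoglobin absorption coefficients:
#' `SO2 * mu_a,HbO2 + (1 - SO2) * mu_a,Hbb`.
#'
#' @param so2 Hemoglobin oxygen saturation, fraction in \[0, 1\].
#' @param wavelength Wavelength in nm; must be present in `table`.
#' @param table Chromophore table from [chromophore_table()].
#' @return Blood absorption coefficient, cm^-1.
#' @export
blood_absorption <- function(so2, wavelength, table = chromophore_table()) {
  if (any(so2 < 0 | so2 > 1)) stop("so2 must lie in [0, 1]")
  row <- .chromophore_row(wavelength, table)
  so2 * row$hbo2 + (1 - so2) * row$hbb
}

#' Construct a physiological state
#'
#' Bundles arterial saturation, the derived venous saturation (held 10
#' percentage points below arterial), cardiac phase and skin tone.
#'
#' @param sao2 Arterial oxygen saturation, fraction in \[0, 1\].
#' @param phase `"diastole"` or `"systole"`.
#' @param skin_tone `"light"` (Fitzpatrick ~2) or `"dark"` (Fitzpatrick ~5).
#' @return An object of class `physio_state`.
#' @export
physio_state <- function(sao2, phase = c("diastole", "systole"),
                         skin_tone = c("light", "dark")) {
  phase <- match.arg(phase)
  skin_tone <- match.arg(skin_tone)
  if (!is.numeric(sao2) || length(sao2) != 1L || sao2 < 0 || sao2 > 1) {
    stop("sao2 must be a single fraction in [0, 1]")
  }
  svo2 <- sao2 - 0.10
  if (svo2 < 0) {
    stop("sao2 = ", sao2, " implies a negative venous saturation ",
         "(SvO2 = SaO2 - 0.10)")
  }
  structure(
    list(sao2 = sao2, svo2 = svo2, phase = phase, skin_tone = skin_tone),
    class = "physio_state"
  )
}

#' @export
print.physio_state <- function(x, ...) {
  cat(sprintf("physio_state: SaO2 %.0f%%, SvO2 %.0f%%, %s, %s skin\n",
              100 * x$sao2, 100 * x$svo2, x$phase, x$skin_tone))
  invisible(x)
}

#' Layer absorption coefficient from chromophore composition
#'
#' Volume-fraction-weighted mixture of arterial blood, venous blood, water
#' and melanin absorption, with the residual volume assigned the baseline
#' absorption. The residual term is applied literally even when the
#' fractions sum above 1 (which makes it negative): the artery-layer
#' composition sums to 1.2 in diastole and 1.5 in systole, and no
#' renormalization is defined for it, so a warning is emitted once per
#' session when this occurs.
#'
#' @param comp Named list or one-row data frame of volume fractions
#'   `V_w`, `V_m`, `V_a`, `V_v` (each >= 0; missing treated as 0).
#' @param state A [physio_state()] providing SaO2/SvO2.
#' @param wavelength Wavelength in nm; must be in `table`.
#' @param table Chromophore table.
#' @param config Configuration list.
#' @return Layer absorption coefficient, cm^-1.
#' @export
layer_absorption <- function(comp, state, wavelength,
                             table = chromophore_table(),
                             config = tissue_config()) {
  get0f <- function(nm) {
    v <- comp[[nm]]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }
  vw <- get0f("V_w"); vm <- get0f("V_m")
  va <- get0f("V_a"); vv <- get0f("V_v")
  if (any(c(vw, vm, va, vv) < 0)) stop("volume fractions must be >= 0")
  row <- .chromophore_row(wavelength, table)
  mu_aa <- blood_absorption(state$sao2, wavelength, table)
  mu_av <- blood_absorption(state$svo2, wavelength, table)
  residual <- 1 - (va + vv + vw + vm)
  if (residual < 0 && !isTRUE(.oxisim_env$warned_residual)) {
    .oxisim_env$warned_residual <- TRUE
    warning("volume fractions sum to ", format(va + vv + vw + vm),
            " > 1; the baseline-absorption residual term is negative and ",
            "is applied literally (warned once per session)", call. = FALSE)
  }
  va * mu_aa + vv * mu_av + vw * row$water + vm * row$melanin +
    residual * baseline_absorption(wavelength, config)
}

#' Reduced scattering coefficient (Rayleigh + Mie power law)
#'
#' `mu_s'(lambda) = a' * (f_ray*(lambda/500)^-4 +
#'   (1 - f_ray)*(lambda/500)^-b_mie)` with lambda in nm. An unlisted
#' Rayleigh fraction is treated as 0 (pure Mie).
#'
#' @param model Named list with `a_prime` (cm^-1), `f_ray` (fraction,
#'   may be `NULL`/`NA` for 0) and `b_mie` (dimensionless).
#' @param wavelength Wavelength in nm (vectorized).
#' @return Reduced scattering coefficient, cm^-1.
#' @export
reduced_scattering <- function(model, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  a <- as.numeric(model$a_prime)
  f <- model$f_ray
  f <- if (is.null(f) || is.na(f)) 0 else as.numeric(f)
  b <- as.numeric(model$b_mie)
  if (f < 0 || f > 1) stop("f_ray must lie in [0, 1]")
  if (a <= 0) stop("a_prime must be positive")
  x <- wavelength / 500
  a * (f * x^-4 + (1 - f) * x^-b)
}

#' Scattering coefficient from reduced scattering
#'
#' `mu_s = mu_s' / (1 - g)` for anisotropy factor g < 1.
#'
#' @param mu_s_prime Reduced scattering coefficient, cm^-1.
#' @param g Scattering anisotropy (mean cosine of deflection), g < 1.
#' @return Scattering coefficient, cm^-1.
#' @export
scattering_coefficient <- function(mu_s_prime, g) {
  if (any(g >= 1)) stop("g must be < 1")
  mu_s_prime / (1 - g)
}

.composition_for <- function(layer, state, config) {
  comp <- config$compositions[[layer]]
  pick <- function(v, key) if (is.list(v)) as.numeric(v[[key]]) else as.numeric(v)
  list(
    V_w = pick(comp$V_w, NULL),
    V_m = if (is.list(comp$V_m)) as.numeric(comp$V_m[[state$skin_tone]])
          else as.numeric(comp$V_m),
    V_a = if (is.list(comp$V_a)) as.numeric(comp$V_a[[state$phase]])
          else as.numeric(comp$V_a),
    V_v = pick(comp$V_v, NULL)
  )
}

.tabulated_at <- function(tab, wavelength, field) {
  i <- match(wavelength, tab$wavelength)
  if (is.na(i)) stop("wavelength ", wavelength, " nm not tabulated")
  as.numeric(tab[[field]][[i]])
}

#' Assemble per-medium optical properties for one simulation state
#'
#' Produces the four media of the finger model, in phantom label order
#' (epidermis, dermis, artery, bone), for a given physiological state and
#' wavelength. Epidermis absorption comes from the chromophore mixture with
#' tone-dependent melanin volume and its scattering from the tone-dependent
#' tabulated values; dermis and artery absorption come from the chromophore
#' mixture (artery blood volume doubles in systole) and their scattering
#' from the Rayleigh+Mie model scaled by 1/(1-g); bone uses tabulated
#' constants. All media share g = 0.9 and n = 1.43.
#'
#' @param state A [physio_state()].
#' @param wavelength Wavelength in nm (660 or 940 with the built-in tables).
#' @param config Configuration list from [tissue_config()].
#' @return A data frame with one row per medium and columns `medium`,
#'   `mu_a`, `mu_s`, `g`, `n`.
#' @export
assemble_media <- function(state, wavelength, config = tissue_config()) {
  stopifnot(inherits(state, "physio_state"))
  tab <- chromophore_table(config)
  g <- as.numeric(config$global$anisotropy_g)
  n <- as.numeric(config$global$refractive_n)

  mu_a_epi <- layer_absorption(.composition_for("epidermis", state, config),
                               state, wavelength, tab, config)
  mu_s_epi <- .tabulated_at(config$tabulated$epidermis_mu_s, wavelength,
                            state$skin_tone)
  mu_a_der <- layer_absorption(.composition_for("dermis", state, config),
                               state, wavelength, tab, config)
  mu_s_der <- scattering_coefficient(
    reduced_scattering(config$scattering_models$dermis, wavelength), g)
  mu_a_art <- layer_absorption(.composition_for("artery", state, config),
                               state, wavelength, tab, config)
  mu_s_art <- scattering_coefficient(
    reduced_scattering(config$scattering_models$artery, wavelength), g)
  mu_a_bone <- .tabulated_at(config$tabulated$bone, wavelength, "mu_a")
  mu_s_bone <- .tabulated_at(config$tabulated$bone, wavelength, "mu_s")

  out <- data.frame(
    medium = c("epidermis", "dermis", "artery", "bone"),
    mu_a = c(mu_a_epi, mu_a_der, mu_a_art, mu_a_bone),
    mu_s = c(mu_s_epi, mu_s_der, mu_s_art, mu_s_bone),
    g = g, n = n
  )
  stopifnot(all(out$mu_a >= 0), all(out$mu_s >= 0))
  out
}
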