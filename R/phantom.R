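# Voxelized four-layer finger geometry and physiological state enumeration.

#' Geometry specification for the finger phantom
#'
#' Defaults reproduce the study geometry: a 1 x 1 x 0.41 cm cuboid divided
#' into 101 x 101 x 201 voxels, a 0.015 cm epidermis at both the
#' illuminated (top) and detection (bottom) faces — a finger has skin on
#' both sides of the light path, and the transmitted-light attenuation the
#' model produces requires both crossings — dermis in between, two artery
#' cylinders (radius 0.025 cm, axis depths 0.07 and 0.31 cm) and one bone
#' cylinder (radius 0.05 cm, axis depth 0.18 cm). Cylinder axes run along
#' y, centered at x = 0; "depth" is the depth of the cylinder axis.
#' Coordinates: x, y in \[-0.5, 0.5\] cm with the origin at the center of
#' the illuminated (top) surface, z in \[0, 0.41\] increasing into tissue.
#'
#' @param extent Numeric length-3, domain size (x, y, z) in cm.
#' @param bins Integer length-3, voxel counts per axis.
#' @param epidermis_thickness,dermis_thickness Layer thicknesses, cm.
#' @param bottom_epidermis_thickness Thickness of the epidermal layer at
#'   the bottom (detection) face, cm; 0 removes it.
#' @param artery_radius Artery cylinder radius, cm (0 removes arteries).
#' @param artery_center_depths Depths of the two artery axes, cm.
#' @param bone_radius Bone cylinder radius, cm (0 removes the bone).
#' @param bone_center_depth Depth of the bone axis, cm.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(extent = c(1, 1, 0.41),
                          bins = c(101L, 101L, 201L),
                          epidermis_thickness = 0.015,
                          dermis_thickness = 0.36,
                          bottom_epidermis_thickness = 0.015,
                          artery_radius = 0.025,
                          artery_center_depths = c(0.07, 0.31),
                          bone_radius = 0.05,
                          bone_center_depth = 0.18) {
  stopifnot(length(extent) == 3, all(extent > 0),
            length(bins) == 3, all(bins >= 1))
  spec <- list(
    extent = as.numeric(extent),
    bins = as.integer(bins),
    epidermis_thickness = epidermis_thickness,
    dermis_thickness = dermis_thickness,
    bottom_epidermis_thickness = bottom_epidermis_thickness,
    artery_radius = artery_radius,
    artery_center_depths = as.numeric(artery_center_depths),
    bone_radius = bone_radius,
    bone_center_depth = bone_center_depth
  )
  zmax <- spec$extent[3]
  cyl_ok <- function(depth, r) depth - r >= 0 && depth + r <= zmax
  for (d in spec$artery_center_depths) {
    if (spec$artery_radius > 0 && !cyl_ok(d, spec$artery_radius)) {
      stop("artery cylinder at depth ", d, " cm extends outside the domain")
    }
  }
  if (spec$bone_radius > 0 && !cyl_ok(spec$bone_center_depth, spec$bone_radius)) {
    stop("bone cylinder extends outside the domain")
  }
  structure(spec, class = "geometry_spec")
}

#' Build the labeled voxel phantom
#'
#' Assigns every voxel one of four medium labels by its center coordinate:
#' epidermis for depths within the epidermis thickness of the top face and
#' within the bottom epidermis thickness of the bottom face, dermis
#' elsewhere, with artery and bone cylinders overwriting dermis. An error
#' is raised if artery and bone cylinders overlap (they do not with the
#' default geometry).
#'
#' @param spec A [geometry_spec()].
#' @param media Data frame of per-medium optical properties in label order
#'   (epidermis, dermis, artery, bone), as from [assemble_media()], or
#'   `NULL` to build labels only.
#' @param provenance Optional list recording the (state, wavelength) the
#'   media were assembled for.
#' @return An object of class `tissue_phantom` with elements `labels`
#'   (3-d integer array: 1 epidermis, 2 dermis, 3 artery, 4 bone),
#'   `voxel_size`, `extent`, `media`, `spec`, `provenance`.
#' @export
build_phantom <- function(spec = geometry_spec(), media = NULL,
                          provenance = NULL) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (!is.null(media)) {
    stopifnot(is.data.frame(media), nrow(media) == 4)
  }
  nb <- spec$bins
  ext <- spec$extent
  vox <- ext / nb
  # voxel-center coordinates
  zc <- (seq_len(nb[3]) - 0.5) * vox[3]
  xc <- (seq_len(nb[1]) - 0.5) * vox[1] - ext[1] / 2

  # z-profile label for one x-column (labels depend only on x and z)
  in_cyl <- function(x, z, depth, r) (x^2 + (z - depth)^2) <= r^2
  bot <- spec$bottom_epidermis_thickness
  if (is.null(bot)) bot <- 0
  col_label <- function(x) {
    lab <- ifelse(zc < spec$epidermis_thickness |
                    zc > ext[3] - bot, 1L, 2L)
    art <- rep(FALSE, nb[3]); bon <- rep(FALSE, nb[3])
    if (spec$artery_radius > 0) {
      for (d in spec$artery_center_depths) {
        art <- art | in_cyl(x, zc, d, spec$artery_radius)
      }
    }
    if (spec$bone_radius > 0) {
      bon <- in_cyl(x, zc, spec$bone_center_depth, spec$bone_radius)
    }
    if (any(art & bon)) stop("artery and bone cylinders overlap")
    lab[art] <- 3L
    lab[bon] <- 4L
    lab
  }
  xz <- vapply(xc, col_label, integer(nb[3]))   # nz x nx
  labels <- array(0L, dim = nb)
  for (iy in seq_len(nb[2])) labels[, iy, ] <- t(xz)

  structure(
    list(labels = labels, voxel_size = vox, extent = ext,
         media = media, spec = spec, provenance = provenance),
    class = "tissue_phantom"
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("tissue_phantom: %d x %d x %d voxels (%.3g x %.3g x %.3g cm)\n",
              dim(x$labels)[1], dim(x$labels)[2], dim(x$labels)[3],
              x$extent[1], x$extent[2], x$extent[3]))
  tab <- table(factor(x$labels, levels = 1:4,
                      labels = c("epidermis", "dermis", "artery", "bone")))
  print(tab)
  invisible(x)
}

#' Convenience: phantom with media for one physiological state
#'
#' @param state A [physio_state()].
#' @param wavelength Wavelength, nm.
#' @param spec A [geometry_spec()].
#' @param config Configuration list.
#' @return A `tissue_phantom` carrying media and provenance.
#' @export
phantom_for_state <- function(state, wavelength, spec = geometry_spec(),
                              config = tissue_config()) {
  media <- assemble_media(state, wavelength, config)
  build_phantom(spec, media,
                provenance = list(state = state, wavelength = wavelength))
}

#' Enumerate the study's physiological/optical configurations
#'
#' Full cross-product of arterial saturations, skin tones, cardiac phases
#' and wavelengths; each configuration carries SvO2 = SaO2 - 0.10. The
#' defaults give the study sweep: 5 x 2 x 2 x 2 = 40 configurations.
#'
#' @param sao2_values Arterial saturations (fractions).
#' @param tones Skin tones.
#' @param phases Cardiac phases.
#' @param wavelengths Wavelengths, nm.
#' @return A data frame with columns `sao2`, `svo2`, `skin_tone`, `phase`,
#'   `wavelength`, one row per configuration.
#' @export
enumerate_states <- function(sao2_values = seq(0.6, 1.0, by = 0.1),
                             tones = c("light", "dark"),
                             phases = c("diastole", "systole"),
                             wavelengths = c(660, 940)) {
  if (any(sao2_values < 0.10)) {
    stop("sao2 below 0.10 implies negative venous saturation")
  }
  grid <- expand.grid(sao2 = sao2_values, skin_tone = tones, phase = phases,
                      wavelength = wavelengths, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$svo2 <- grid$sao2 - 0.10
  grid[, c("sao2", "svo2", "skin_tone", "phase", "wavelength")]
}

#' Write a phantom to disk (binary array + text header)
#'
#' Stores the label grid as raw bytes alongside a human-readable sidecar
#' header describing dimensions, voxel size and the label legend.
#'
#' @param phantom A `tissue_phantom`.
#' @param prefix Output path prefix; writes `<prefix>.labels.bin` and
#'   `<prefix>.header.txt`.
#' @return Invisibly, the two file paths.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  bin <- paste0(prefix, ".labels.bin")
  hdr <- paste0(prefix, ".header.txt")
  writeBin(as.raw(phantom$labels), bin)
  writeLines(c(
    "oxisim tissue_phantom v1",
    paste("bins:", paste(dim(phantom$labels), collapse = " ")),
    paste("voxel_size_cm:", paste(format(phantom$voxel_size, digits = 10),
                                  collapse = " ")),
    paste("extent_cm:", paste(format(phantom$extent, digits = 10),
                              collapse = " ")),
    "labels: 1=epidermis 2=dermis 3=artery 4=bone",
    "storage: uint8, x fastest, then y, then z"
  ), hdr)
  invisible(c(bin, hdr))
}

#' Read a phantom written by [write_phantom()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `tissue_phantom` (without media).
#' @export
read_phantom <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".header.txt"))
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    as.numeric(strsplit(sub(paste0(key, ": *"), "", ln), " +")[[1]])
  }
  bins <- as.integer(get_field("bins"))
  vox <- get_field("voxel_size_cm")
  ext <- get_field("extent_cm")
  raw <- readBin(paste0(prefix, ".labels.bin"), what = "raw",
                 n = prod(bins))
  labels <- array(as.integer(raw), dim = bins)
  structure(
    list(labels = labels, voxel_size = vox, extent = ext,
         media = NULL, spec = NULL, provenance = NULL),
    class = "tissue_phantom"
  )
}
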