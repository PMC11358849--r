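# Shared fixtures: small phantoms and media built in code.

# Homogeneous slab phantom (no cylinders, single medium repeated over the
# four label slots) for transport oracles.
homogeneous_phantom <- function(mu_a, mu_s, g = 0.9,
                                extent = c(1, 1, 0.41),
                                bins = c(21L, 21L, 41L)) {
  spec <- geometry_spec(extent = extent, bins = bins,
                        epidermis_thickness = 0,
                        bottom_epidermis_thickness = 0,
                        dermis_thickness = extent[3],
                        artery_radius = 0, bone_radius = 0)
  media <- data.frame(medium = c("epidermis", "dermis", "artery", "bone"),
                      mu_a = mu_a, mu_s = mu_s, g = g, n = 1.43)
  build_phantom(spec, media)
}

full_face_detector <- function(face = "bottom") {
  detector_spec(face, center = c(0, 0), diameter = 3)
}

# Study-grade phantom for a state, memoised per (tone, sao2, phase, wl)
# within one test file run.
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(sao2, phase, tone, wl) {
  key <- paste(sao2, phase, tone, wl, sep = "|")
  if (is.null(.phantom_cache[[key]])) {
    st <- physio_state(sao2, phase, tone)
    .phantom_cache[[key]] <- suppressWarnings(phantom_for_state(st, wl))
  }
  .phantom_cache[[key]]
}
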