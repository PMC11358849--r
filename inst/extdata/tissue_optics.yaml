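# Built-in tissue optical parameters for the four-layer finger model.
# All absorption/scattering coefficients in cm^-1, lengths in cm,
# wavelengths in nm. Users may supply a file with the same layout to
# tissue_config(path=).

chromophores:
  # wavelength-indexed absorption coefficients (cm^-1)
  wavelength: [660, 940]
  melanin:    [269.43, 82.99]
  water:      [0.0036, 0.2674]
  hbo2:       [1.71, 6.50]
  hbb:        [17.27, 3.71]

baseline_absorption:
  # mu_a,baseline(lambda) = scale * lambda^exponent  (lambda in nm)
  scale: 7.84e8
  exponent: -3.255

compositions:
  # volume fractions per layer; epidermis melanin depends on skin tone,
  # artery arterial blood volume depends on cardiac phase
  epidermis:
    V_w: 0.2
    V_m: {light: 0.05, dark: 0.25}
    V_a: 0.0
    V_v: 0.0
  dermis:
    V_w: 0.3
    V_m: 0.0
    V_a: 0.02
    V_v: 0.02
  artery:
    V_w: 0.6
    V_m: 0.0
    V_a: {diastole: 0.3, systole: 0.6}
    V_v: 0.3

scattering_models:
  # reduced-scattering model mu_s'(lambda) =
  #   a_prime * (f_ray*(lambda/500)^-4 + (1-f_ray)*(lambda/500)^-b_mie)
  dermis: {a_prime: 43.6, f_ray: 0.41, b_mie: 0.562}
  artery: {a_prime: 10.0, f_ray: 0.0,  b_mie: 1.0}

tabulated:
  # values taken directly from the optical-property table rather than the
  # composition/scattering models
  epidermis_mu_s:
    wavelength: [660, 940]
    light: [250, 150]
    dark:  [300, 170]
  bone:
    wavelength: [660, 940]
    mu_a: [0.351, 0.457]
    mu_s: [344.5, 247]

global:
  # "n" alone is a YAML boolean literal, hence the explicit names
  anisotropy_g: 0.9      # scattering anisotropy, all media
  refractive_n: 1.43     # refractive index, all media (uniform: no Fresnel)

geometry:
  extent: [1.0, 1.0, 0.41]       # (x, y, z) cm
  bins: [101, 101, 201]
  epidermis_thickness: 0.015
  dermis_thickness: 0.36
  bottom_epidermis_thickness: 0.015   # skin on the detection face too
  artery_radius: 0.025
  artery_center_depths: [0.07, 0.31]
  bone_radius: 0.05
  bone_center_depth: 0.18
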