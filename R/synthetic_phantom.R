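# Synthetic phantom scenarios: an epoxy/intralipid-like slab with a single
# blood-filled channel, plus "measured" spectra generated by the forward
# Monte Carlo model under an independent measurement seed. Everything here
# is a labelled synthetic stand-in for the physical phantom; no literature
# chromophore data are claimed.

#' Hemoglobin-like absorption template (synthetic)
#'
#' Smooth positive curve with a dominant Soret-like band near 420 nm and
#' secondary Q-band structure near 542/577 nm on a decaying baseline:
#' three Gaussians plus an exponential. Shape only - a fixture template,
#' not literature blood data.
#'
#' @param wavelength_nm Wavelengths in \[300, 1200\] nm.
#' @param scale Multiplier applied to the whole curve (mm^-1 scale; the
#'   default amplitudes put the 420 nm peak at roughly 120 mm^-1 for
#'   `scale = 1`, a whole-blood-like magnitude).
#' @return Absorption coefficient, mm^-1, one value per wavelength.
#' @export
#' @examples
#' hemoglobin_like_mu_a(c(420, 550, 700))
hemoglobin_like_mu_a <- function(wavelength_nm, scale = 1) {
  wl <- as.numeric(wavelength_nm)
  if (any(wl < 300 | wl > 1200))
    stop("wavelength outside [300, 1200] nm", call. = FALSE)
  gauss <- function(c0, s0, A) A * exp(-(wl - c0)^2 / (2 * s0^2))
  base <- 2 * exp(-(wl - 300) / 150) + 0.05
  scale * (gauss(420, 22, 120) + gauss(542, 14, 28) + gauss(577, 12, 30) +
             base)
}

#' Background scattering power law (synthetic)
#'
#' `mu_s(lambda) = mu_s0 (lambda / 500)^(-b)`; stands in for the
#' unpublished phantom scattering curve.
#'
#' @param wavelength_nm Wavelengths, nm.
#' @param mu_s0 Scattering coefficient at 500 nm, mm^-1.
#' @param b Scattering power.
#' @return mm^-1 per wavelength.
#' @export
background_mu_s <- function(wavelength_nm, mu_s0 = 2, b = 1) {
  mu_s0 * (wavelength_nm / 500)^(-b)
}

#' Scenario specification for the synthetic phantom
#'
#' Defaults reproduce the study conditions: a 2 mm epoxy-like slab
#' (n = 1.50) of 15 mm lateral extent with flat background absorption
#' 0.01 mm^-1 and power-law scattering (2 mm^-1 at 500 nm, power 1,
#' g = 0), a blood-filled channel with the hemoglobin-like template
#' (n = 1.37), a 0.5 mm flat-top spot, 10 wavelengths across the
#' 400-600 nm analysis band, and 1% multiplicative measurement noise.
#'
#' @param diameter_um Vessel diameter, micrometres.
#' @param axis_depth_mm Vessel axis depth, mm.
#' @param thickness_mm,lateral_mm Slab geometry, mm.
#' @param mu_a_bg Flat background absorption, mm^-1.
#' @param mu_s0,b Background scattering power law parameters.
#' @param n_bg,n_blood Refractive indices.
#' @param blood_scale Multiplier on the blood absorption template.
#' @param blood_mu_s Blood scattering coefficient, mm^-1.
#' @param spot_mm Beam spot diameter, mm.
#' @param wavelengths_nm Wavelength grid, nm.
#' @param noise Multiplicative Gaussian noise sd (0 disables noise).
#' @param photons Photons per wavelength for the synthetic measurement.
#' @param seed Measurement seed.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(diameter_um = 300, axis_depth_mm = 0.65,
                          thickness_mm = 2, lateral_mm = 15,
                          mu_a_bg = 0.01, mu_s0 = 2, b = 1,
                          n_bg = 1.50, n_blood = 1.37,
                          blood_scale = 1, blood_mu_s = 1,
                          spot_mm = 0.5,
                          wavelengths_nm = seq(400, 600, length.out = 10),
                          noise = 0.01, photons = 1e5, seed = 42) {
  if (noise < 0) stop("noise level must be >= 0", call. = FALSE)
  spec <- list(diameter_um = diameter_um, axis_depth_mm = axis_depth_mm,
               thickness_mm = thickness_mm, lateral_mm = lateral_mm,
               mu_a_bg = mu_a_bg, mu_s0 = mu_s0, b = b, n_bg = n_bg,
               n_blood = n_blood, blood_scale = blood_scale,
               blood_mu_s = blood_mu_s, spot_mm = spot_mm,
               wavelengths_nm = as.numeric(wavelengths_nm), noise = noise,
               photons = photons, seed = seed)
  structure(spec, class = "scenario_spec")
}

# Build the phantom model and beam implied by a scenario spec.
scenario_model <- function(spec, with_vessel = TRUE) {
  wl <- spec$wavelengths_nm
  bg <- optical_properties(mu_a = rep(spec$mu_a_bg, length(wl)),
                           mu_s = background_mu_s(wl, spec$mu_s0, spec$b),
                           g = 0, n = spec$n_bg)
  vessel <- NULL
  if (with_vessel && !is.null(spec$diameter_um)) {
    blood <- optical_properties(
      mu_a = hemoglobin_like_mu_a(wl, spec$blood_scale),
      mu_s = spec$blood_mu_s, g = 0, n = spec$n_blood)
    vessel <- cylindrical_vessel(spec$diameter_um, spec$axis_depth_mm,
                                 blood = blood)
  }
  model <- phantom_model(thickness_mm = spec$thickness_mm,
                         lateral_mm = spec$lateral_mm, background = bg,
                         vessel = vessel)
  beam <- beam_spec(spot_mm = spec$spot_mm, wavelengths_nm = wl)
  list(model = model, beam = beam)
}

#' Generate a synthetic "measured" scenario
#'
#' Builds the phantom model from a [scenario_spec()], runs the forward
#' Monte Carlo sweep under the measurement seed, applies multiplicative
#' Gaussian noise (clipped to \[0, 1\]), and returns - or writes - the
#' scenario with its ground truth embedded for audit.
#'
#' @param spec A [scenario_spec()].
#' @param dir Optional directory; when given, writes `model.json`,
#'   `measured.csv` and `truth.json` there.
#' @return List with `model` ([phantom_model()]), `beam`, `measured`
#'   (list of reflectance/transmittance `spectrum` objects), `truth`
#'   (diameter, depth, property curves, seed), and `dir` when written.
#' @export
#' @examples
#' sc <- generate_scenario(scenario_spec(photons = 2000, noise = 0))
#' sc$truth$axis_depth_mm
generate_scenario <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  mb <- scenario_model(spec)
  mc <- mc_config(photons = spec$photons, seed = spec$seed)
  sw <- sweep_spectrum(mb$model, mb$beam, mc)
  R <- sw$reflectance$value
  T <- sw$transmittance$value
  if (spec$noise > 0) {
    # noise RNG isolated from the transport kernel and from the caller
    noise_seed <- derive_seed(spec$seed, 999983)
    eps <- local({
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(noise_seed)
      stats::rnorm(2 * length(R), 0, spec$noise)
    })
    nR <- length(R)
    R <- pmin(pmax(R * (1 + eps[seq_len(nR)]), 0), 1)
    T <- pmin(pmax(T * (1 + eps[nR + seq_len(nR)]), 0), 1)
  }
  wl <- mb$beam$wavelengths_nm
  truth <- list(diameter_um = spec$diameter_um,
                axis_depth_mm = spec$axis_depth_mm,
                mu_a_bg = spec$mu_a_bg,
                mu_s_bg = background_mu_s(wl, spec$mu_s0, spec$b),
                blood_mu_a = hemoglobin_like_mu_a(wl, spec$blood_scale),
                noise = spec$noise, seed = spec$seed,
                photons = spec$photons, synthetic = TRUE)
  out <- list(model = mb$model, beam = mb$beam,
              measured = list(
                reflectance = as_spectrum(wl, R, "reflectance"),
                transmittance = as_spectrum(wl, T, "transmittance")),
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_config_json(mb$model, mb$beam, mc, file.path(dir, "model.json"))
    tab <- data.frame(wavelength_nm = wl, M_R = R, M_T = T)
    write_spectrum_csv(tab, file.path(dir, "measured.csv"),
                       seed = spec$seed)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$dir <- dir
  }
  out
}
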