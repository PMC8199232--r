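#' Unpolarized Fresnel reflectance
#'
#' Reflectance of an unpolarized ray at a planar interface, averaged over
#' the two polarizations. Returns 1 beyond the critical angle when going
#' from dense to rare medium.
#'
#' @param n_i Refractive index on the incidence side (>= 1).
#' @param n_t Refractive index on the transmission side (>= 1).
#' @param cos_theta_i Cosine of the incidence angle, in \[0, 1\].
#' @return Reflection probability in \[0, 1\]. Vectorized over
#'   `cos_theta_i`.
#' @export
#' @examples
#' fresnel_reflectance(1, 1.5, 1)     # 0.04 at normal incidence
#' fresnel_reflectance(1.5, 1, cos(60 * pi / 180))  # 1: total internal refl.
fresnel_reflectance <- function(n_i, n_t, cos_theta_i) {
  if (n_i < 1 || n_t < 1) stop("refractive indices must be >= 1",
                               call. = FALSE)
  if (any(cos_theta_i < 0 | cos_theta_i > 1))
    stop("cos_theta_i must lie in [0, 1]", call. = FALSE)
  vapply(cos_theta_i, function(ci) .fresnel_cpp(n_i, n_t, ci), numeric(1))
}

#' Sample the Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF sample of the deflection cosine for the one-parameter
#' Henyey-Greenstein phase function. For `g = 0` this reduces to the
#' isotropic `2u - 1`.
#'
#' @param g Anisotropy, in (-1, 1).
#' @param u Uniform variates in \[0, 1).
#' @return Cosines in \[-1, 1\], one per element of `u`.
#' @export
sample_henyey_greenstein <- function(g, u) {
  if (abs(g) >= 1) stop("g must lie strictly inside (-1, 1)", call. = FALSE)
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  .hg_sample_cpp(g, as.numeric(u))
}

#' Forward Monte Carlo transport at one wavelength
#'
#' Hop-drop-spin photon transport through the slab phantom, tallying the
#' full energy budget: specular reflection, diffuse reflectance,
#' transmittance, absorption in the background and in the vessel, and
#' lateral escape. The six budget terms sum to exactly 1 (tallies are
#' normalized by total terminal weight so that Russian roulette noise
#' cannot open the balance).
#'
#' @param model A [phantom_model()].
#' @param beam A [beam_spec()]; `wavelength_index` selects the grid point
#'   simulated.
#' @param mc An [mc_config()].
#' @param wavelength_index Index into the beam wavelength grid (and into
#'   any per-wavelength optical property vectors).
#' @return An object of class `energy_budget`: list with fractions
#'   `R_specular`, `R_diffuse`, `T`, `Abs_background`, `Abs_vessel`,
#'   `E_side`, Monte Carlo standard errors `se_R`, `se_T`,
#'   `photon_count`, `seed`, `wavelength_nm`, and (with
#'   `tally_fluence = TRUE`) an absorption grid `fluence` whose entries
#'   sum to `Abs_background + Abs_vessel`.
#' @export
#' @examples
#' m <- phantom_model(background = optical_properties(0.01, 2, 0, 1.5))
#' b <- beam_spec(wavelengths_nm = 550)
#' simulate_transport(m, b, mc_config(photons = 2000, seed = 1))
simulate_transport <- function(model, beam, mc, wavelength_index = 1L) {
  stopifnot(inherits(model, "phantom_model"), inherits(beam, "beam_spec"),
            inherits(mc, "mc_config"))
  i <- as.integer(wavelength_index)
  if (i < 1L || i > length(beam$wavelengths_nm))
    stop("wavelength_index outside the beam grid", call. = FALSE)
  nbg <- length(model$background$mu_a)
  if (nbg != 1L && i > nbg)
    stop("background properties missing at wavelength ",
         beam$wavelengths_nm[i], " nm", call. = FALSE)
  bg <- props_at(model$background, i)
  has_vessel <- !is.null(model$vessel)
  if (has_vessel) {
    nb <- length(model$vessel$blood$mu_a)
    if (nb != 1L && i > nb)
      stop("vessel present but blood properties missing at wavelength ",
           beam$wavelengths_nm[i], " nm", call. = FALSE)
    bl <- props_at(model$vessel$blood, i)
  } else {
    bl <- optical_properties(0, 0, 0, 1.37)
  }
  res <- .mc_transport_cpp(
    thickness = model$thickness_mm, half_extent = model$lateral_mm / 2,
    n_above = model$n_above, n_slab = bg$n, n_below = model$n_below,
    has_vessel = has_vessel,
    vessel_radius = if (has_vessel) model$vessel$radius_mm else 0,
    vessel_depth = if (has_vessel) model$vessel$axis_depth_mm else 0,
    n_vessel = bl$n, vessel_fresnel = mc$vessel_fresnel,
    mua_bg = bg$mu_a, mus_bg = bg$mu_s, g_bg = bg$g,
    mua_v = bl$mu_a, mus_v = bl$mu_s, g_v = bl$g,
    spot_radius = beam$spot_mm / 2,
    n_photons = mc$photons, seed = mc$seed,
    roulette_threshold = mc$roulette_threshold,
    roulette_survival = mc$roulette_survival,
    tally_fluence = mc$tally_fluence, voxel_mm = mc$voxel_mm)
  res$seed <- mc$seed
  res$wavelength_nm <- beam$wavelengths_nm[i]
  structure(res, class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf(
    "<energy_budget> %g nm, %d photons, seed %g\n", x$wavelength_nm,
    x$photon_count, x$seed))
  cat(sprintf(
    "  R_spec %.5f  R_diff %.5f (se %.1e)  T %.5f (se %.1e)\n",
    x$R_specular, x$R_diffuse, x$se_R, x$T, x$se_T))
  cat(sprintf("  Abs_bg %.5f  Abs_vessel %.5f  E_side %.5f  sum %.12f\n",
              x$Abs_background, x$Abs_vessel, x$E_side, budget_sum(x)))
  invisible(x)
}

#' Sum of the six energy-budget terms
#'
#' @param budget An `energy_budget`.
#' @return Numeric scalar; equals 1 up to floating-point roundoff.
#' @export
budget_sum <- function(budget) {
  budget$R_specular + budget$R_diffuse + budget$T +
    budget$Abs_background + budget$Abs_vessel + budget$E_side
}

# Deterministic per-wavelength seed derivation from a master seed.
derive_seed <- function(master, k) {
  (master * 69069 + 104729 * k) %% 2147483647
}

#' Sweep the forward model across the beam wavelength grid
#'
#' Runs [simulate_transport()] at every wavelength with per-wavelength
#' seeds derived deterministically from the master seed, so two sweeps
#' differing only in geometry share common random numbers wavelength by
#' wavelength.
#'
#' @inheritParams simulate_transport
#' @return List with `reflectance` and `transmittance` spectra (each a
#'   `spectrum` object, see [as_spectrum()]) and `budgets`, the list of
#'   per-wavelength energy budgets. The reflectance spectrum reports the
#'   diffuse component only; specular reflection is tallied separately in
#'   the budgets.
#' @export
sweep_spectrum <- function(model, beam, mc) {
  n <- length(beam$wavelengths_nm)
  budgets <- vector("list", n)
  for (i in seq_len(n)) {
    mci <- mc
    mci$seed <- derive_seed(mc$seed, i)
    budgets[[i]] <- tryCatch(
      simulate_transport(model, beam, mci, wavelength_index = i),
      error = function(e) stop("at wavelength ", beam$wavelengths_nm[i],
                               " nm: ", conditionMessage(e), call. = FALSE))
  }
  R <- vapply(budgets, `[[`, numeric(1), "R_diffuse")
  T <- vapply(budgets, `[[`, numeric(1), "T")
  list(reflectance = as_spectrum(beam$wavelengths_nm, R, "reflectance"),
       transmittance = as_spectrum(beam$wavelengths_nm, T, "transmittance"),
       budgets = budgets)
}

#' Construct a spectrum object
#'
#' @param wavelengths_nm Strictly increasing wavelengths, nm.
#' @param values Fractions in \[0, 1\], same length.
#' @param kind `"reflectance"` or `"transmittance"`.
#' @return A `spectrum` object (data.frame with columns `wavelength_nm`,
#'   `value`, attribute `kind`).
#' @export
as_spectrum <- function(wavelengths_nm, values,
                        kind = c("reflectance", "transmittance")) {
  kind <- match.arg(kind)
  wl <- as.numeric(wavelengths_nm)
  v <- as.numeric(values)
  if (length(wl) != length(v))
    stop("wavelengths and values must have equal length", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stop("spectrum values must be finite fractions in [0, 1]",
         call. = FALSE)
  structure(data.frame(wavelength_nm = wl, value = v),
            kind = kind, class = c("spectrum", "data.frame"))
}
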