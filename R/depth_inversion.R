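# Vessel-depth inversion: with known vessel diameter and known optical
# properties, diffuse reflectance in the 400-600 nm hemoglobin band rises
# monotonically with vessel axis depth; bisection on the Monte Carlo
# forward model locates the depth whose band-mean reflectance matches the
# measurement.

# Band-mean aggregate of a reflectance spectrum over [band_nm[1], band_nm[2]].
band_aggregate <- function(spectrum, band_nm = c(400, 600)) {
  sel <- spectrum$wavelength_nm >= band_nm[1] &
    spectrum$wavelength_nm <= band_nm[2]
  if (!any(sel)) stop("no wavelengths inside the analysis band",
                      call. = FALSE)
  mean(spectrum$value[sel])
}

# Forward band-mean reflectance for a vessel at depth d (CRN: the master
# seed is fixed, so each wavelength reuses its derived seed at any depth).
depth_forward <- function(model_template, diameter_um, d, beam, mc,
                          band_nm = c(400, 600), blood = NULL) {
  v0 <- model_template$vessel
  blood <- blood %||% (if (!is.null(v0)) v0$blood else
    blood_default(beam$wavelengths_nm))
  mod <- model_template
  mod$vessel <- NULL
  mod <- phantom_model(thickness_mm = mod$thickness_mm,
                       lateral_mm = mod$lateral_mm,
                       background = mod$background,
                       vessel = cylindrical_vessel(diameter_um, d, blood),
                       n_above = mod$n_above, n_below = mod$n_below)
  sw <- sweep_spectrum(mod, beam, mc)
  list(aggregate = band_aggregate(sw$reflectance, band_nm),
       sweep = sw)
}

#' Band-mean reflectance versus vessel depth
#'
#' Evaluates the forward model at a list of vessel axis depths under
#' common random numbers and returns the band-mean diffuse reflectance
#' at each depth. Strictly increasing in depth in the hemoglobin band:
#' a deeper vessel intercepts fewer photons.
#'
#' @param model_template [phantom_model()] supplying geometry, background
#'   properties and (optionally) the blood properties via its vessel.
#' @param diameter_um Vessel diameter, micrometres.
#' @param depths_mm Vessel axis depths to evaluate, mm.
#' @param beam A [beam_spec()].
#' @param mc An [mc_config()] (one master seed; shared across depths).
#' @param band_nm Analysis band, nm (default 400-600).
#' @return Data frame with columns `depth_mm`, `reflectance`.
#' @export
reflectance_depth_curve <- function(model_template, diameter_um, depths_mm,
                                    beam, mc, band_nm = c(400, 600)) {
  rv <- diameter_um / 2000
  L <- model_template$thickness_mm
  bad <- depths_mm - rv <= 0 | depths_mm + rv >= L
  if (any(bad))
    stop("depth(s) violate containment: ",
         paste(depths_mm[bad], collapse = ", "), " mm", call. = FALSE)
  agg <- vapply(depths_mm, function(d)
    depth_forward(model_template, diameter_um, d, beam, mc,
                  band_nm)$aggregate, numeric(1))
  data.frame(depth_mm = as.numeric(depths_mm), reflectance = agg)
}

#' Extract vessel axis depth from a measured reflectance spectrum
#'
#' Brackets the depth whose calculated band-mean diffuse reflectance
#' equals the measured one and bisects until the bracket is narrower
#' than `depth_tol` (or the mismatch falls below `mismatch_tol`). The
#' monotone direction is detected from the bracket endpoints rather than
#' assumed. Common random numbers across all solver evaluations make the
#' calculated curve a deterministic monotone function of depth.
#'
#' @param measured A reflectance `spectrum` (see [as_spectrum()]) or a
#'   data frame with `wavelength_nm` and a reflectance column.
#' @param diameter_um Known vessel diameter, micrometres (e.g. from
#'   speckle imaging).
#' @param model_template [phantom_model()] with background (and blood,
#'   via an optional vessel entry) properties at the beam wavelengths.
#' @param beam A [beam_spec()]; its grid must match `measured`.
#' @param mc An [mc_config()] for the solver (use a seed independent of
#'   the measurement's).
#' @param bracket Length-2 depth bracket (d1, d2), mm; defaults to the
#'   containment-feasible range inset by 0.05 mm.
#' @param band_nm Analysis band, nm.
#' @param depth_tol Bisection stopping width, mm (default 0.01).
#' @param mismatch_tol Optional early stop on relative reflectance
#'   mismatch (default 0: run to `depth_tol`).
#' @return Object of class `depth_estimate`: list with `d_hat` (mm),
#'   `iterations`, `mismatch` (final relative), `trace` (data frame of
#'   per-iteration depth/reflectance), `bracket`, `direction`.
#' @export
extract_depth <- function(measured, diameter_um, model_template, beam, mc,
                          bracket = NULL, band_nm = c(400, 600),
                          depth_tol = 0.01, mismatch_tol = 0) {
  if (inherits(measured, "spectrum") || is.data.frame(measured)) {
    nm <- tolower(names(measured))
    vcol <- intersect(c("value", "r_diffuse", "m_r", "reflectance"), nm)
    if (!length(vcol) || !"wavelength_nm" %in% nm)
      stop("measured must have wavelength_nm and a reflectance column",
           call. = FALSE)
    m_spec <- data.frame(wavelength_nm = measured[[
      which(nm == "wavelength_nm")]],
      value = measured[[which(nm == vcol[1])[1]]])
  } else stop("measured must be a spectrum or data frame", call. = FALSE)
  m_agg <- band_aggregate(m_spec, band_nm)

  rv <- diameter_um / 2000
  L <- model_template$thickness_mm
  if (is.null(bracket))
    bracket <- c(rv + 0.05, L - rv - 0.05)
  d1 <- min(bracket); d2 <- max(bracket)
  if (d1 >= d2 || d1 - rv <= 0 || d2 + rv >= L)
    stop("invalid depth bracket", call. = FALSE)

  fwd <- function(d) depth_forward(model_template, diameter_um, d, beam,
                                   mc, band_nm)
  f1 <- fwd(d1); f2 <- fwd(d2)
  C1 <- f1$aggregate; C2 <- f2$aggregate
  lo <- min(C1, C2); hi <- max(C1, C2)
  # endpoint grace: a measurement beyond an endpoint by no more than 3
  # MC standard errors is indistinguishable from the endpoint itself;
  # clamp it just inside instead of failing
  se_end <- function(fw) {
    sel <- fw$sweep$reflectance$wavelength_nm >= band_nm[1] &
      fw$sweep$reflectance$wavelength_nm <= band_nm[2]
    ses <- vapply(fw$sweep$budgets[sel], `[[`, numeric(1), "se_R")
    sqrt(sum(ses^2)) / sum(sel)
  }
  grace <- 3 * sqrt(2) * max(se_end(f1), se_end(f2))
  if (m_agg < lo - grace || m_agg > hi + grace)
    stop(sprintf(paste0("measured band reflectance %.5f outside the ",
                        "calculated range [%.5f, %.5f] for depths ",
                        "[%.3g, %.3g] mm; widen the bracket or check ",
                        "properties"), m_agg, lo, hi, d1, d2),
         call. = FALSE)
  m_agg <- min(max(m_agg, lo), hi)
  increasing <- C2 > C1
  # 3-sigma band for the monotonicity guard at the midpoints
  guard <- 3 * max(se_end(f1), se_end(f2))

  trace <- data.frame(iteration = c(0L, 0L), depth_mm = c(d1, d2),
                      reflectance = c(C1, C2))
  it <- 0L
  mismatch <- min(abs(c(C1, C2) - m_agg)) / max(m_agg, 1e-3)
  while (d2 - d1 > depth_tol) {
    it <- it + 1L
    dm <- (d1 + d2) / 2
    Cm <- fwd(dm)$aggregate
    if (Cm < min(C1, C2) - guard || Cm > max(C1, C2) + guard)
      stop(sprintf(paste0("non-monotone response at depth %.4g mm ",
                          "(reflectance %.5f outside [%.5f, %.5f] by ",
                          "more than 3 MC standard errors)"),
                   dm, Cm, min(C1, C2), max(C1, C2)), call. = FALSE)
    trace <- rbind(trace, data.frame(iteration = it, depth_mm = dm,
                                     reflectance = Cm))
    mismatch <- abs(Cm - m_agg) / max(m_agg, 1e-3)
    if ((Cm < m_agg) == increasing) { d1 <- dm; C1 <- Cm }
    else { d2 <- dm; C2 <- Cm }
    if (mismatch_tol > 0 && mismatch <= mismatch_tol) break
  }
  structure(list(d_hat = (d1 + d2) / 2, iterations = it,
                 mismatch = mismatch, trace = trace,
                 bracket = c(d1, d2),
                 direction = if (increasing) "increasing" else
                   "decreasing"),
            class = "depth_estimate")
}

#' @export
print.depth_estimate <- function(x, ...) {
  cat(sprintf(
    "<depth_estimate> d_hat = %.4f mm after %d bisections (mismatch %.3g)\n",
    x$d_hat, x$iterations, x$mismatch))
  invisible(x)
}
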