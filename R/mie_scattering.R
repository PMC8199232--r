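# Mie series for a homogeneous sphere: efficiencies and anisotropy.
# Series truncated at the Wiscombe criterion; the logarithmic derivative
# is computed by downward recurrence, Riccati-Bessel functions upward.

#' Single-sphere Mie efficiencies and anisotropy
#'
#' Computes the extinction and scattering efficiencies and the asymmetry
#' parameter g (mean scattering cosine) for a sphere of size parameter
#' `x = pi d / lambda` and relative refractive index `m = n_p / n_med`
#' (complex allowed).
#'
#' @param x Size parameter (> 0).
#' @param m Relative refractive index, possibly complex.
#' @param nmax Optional series truncation order; defaults to the
#'   Wiscombe criterion `x + 4 x^(1/3) + 2`.
#' @return List with `Q_ext`, `Q_sca`, `g`, `nmax`.
#' @export
#' @examples
#' mie_single(1, 1.1)           # near-Rayleigh sphere
#' mie_single(10, 1.33 + 0i)    # water droplet regime
mie_single <- function(x, m, nmax = NULL) {
  if (x <= 0) stop("size parameter x must be > 0", call. = FALSE)
  m <- as.complex(m)
  if (is.null(nmax)) nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmax <- max(3L, as.integer(nmax))
  mx <- m * x

  # logarithmic derivative D_n(mx) by downward recurrence
  nstart <- max(nmax + 16L, ceiling(Mod(mx)) + 16L)
  D <- complex(nstart + 1)
  for (k in nstart:1) {        # D_{k} from D_{k+1}: D_k = (k+1)/z - 1/(D_{k+1} + (k+1)/z)
    kk <- (k + 1) + 0i
    D[k] <- kk / mx - 1 / (D[k + 1] + kk / mx)
  }

  # Riccati-Bessel psi, chi at real argument x, upward recurrence
  psi0 <- sin(x); psi1 <- sin(x) / x - cos(x)
  chi0 <- cos(x); chi1 <- cos(x) / x + sin(x)
  a <- complex(nmax); b <- complex(nmax)
  psim1 <- psi0; psi <- psi1
  chim1 <- chi0; chi <- chi1
  for (k in seq_len(nmax)) {
    if (k > 1) {
      psinew <- (2 * k - 1) / x * psi - psim1
      chinew <- (2 * k - 1) / x * chi - chim1
      psim1 <- psi; psi <- psinew
      chim1 <- chi; chi <- chinew
    }
    zeta <- psi - 1i * chi
    zetam1 <- psim1 - 1i * chim1
    da <- D[k] / m + k / x
    db <- D[k] * m + k / x
    a[k] <- (da * psi - psim1) / (da * zeta - zetam1)
    b[k] <- (db * psi - psim1) / (db * zeta - zetam1)
  }
  k <- seq_len(nmax)
  Qext <- 2 / x^2 * sum((2 * k + 1) * Re(a + b))
  Qsca <- 2 / x^2 * sum((2 * k + 1) * (Mod(a)^2 + Mod(b)^2))
  if (!is.finite(Qext) || !is.finite(Qsca))
    stop("Mie series failed to stabilize at order ", nmax, call. = FALSE)
  k1 <- seq_len(nmax - 1)
  gsum <- sum(k1 * (k1 + 2) / (k1 + 1) *
                Re(a[k1] * Conj(a[k1 + 1]) + b[k1] * Conj(b[k1 + 1]))) +
    sum((2 * k + 1) / (k * (k + 1)) * Re(a * Conj(b)))
  g <- if (Qsca > 0) 4 / x^2 * gsum / Qsca else 0
  list(Q_ext = Qext, Q_sca = Qsca, g = g, nmax = nmax)
}

# Scattering amplitudes S1, S2 at cosines ct (for the phase-function
# cross-check oracle used in tests).
mie_amplitudes <- function(x, m, ct) {
  ms <- mie_single(x, m)
  nmax <- ms$nmax
  # recover a, b by re-running the coefficient loop
  m <- as.complex(m); mx <- m * x
  nstart <- max(nmax + 16L, ceiling(Mod(mx)) + 16L)
  D <- complex(nstart + 1)
  for (k in nstart:1)
    D[k] <- ((k + 1) + 0i) / mx - 1 / (D[k + 1] + ((k + 1) + 0i) / mx)
  psim1 <- sin(x); psi <- sin(x) / x - cos(x)
  chim1 <- cos(x); chi <- cos(x) / x + sin(x)
  a <- complex(nmax); b <- complex(nmax)
  for (k in seq_len(nmax)) {
    if (k > 1) {
      psinew <- (2 * k - 1) / x * psi - psim1
      chinew <- (2 * k - 1) / x * chi - chim1
      psim1 <- psi; psi <- psinew; chim1 <- chi; chi <- chinew
    }
    zeta <- psi - 1i * chi; zetam1 <- psim1 - 1i * chim1
    da <- D[k] / m + k / x; db <- D[k] * m + k / x
    a[k] <- (da * psi - psim1) / (da * zeta - zetam1)
    b[k] <- (db * psi - psim1) / (db * zeta - zetam1)
  }
  S1 <- complex(length(ct)); S2 <- complex(length(ct))
  for (j in seq_along(ct)) {
    mu <- ct[j]
    pim1 <- 0; pik <- 1
    s1 <- 0 + 0i; s2 <- 0 + 0i
    for (k in seq_len(nmax)) {
      tauk <- k * mu * pik - (k + 1) * pim1
      fac <- (2 * k + 1) / (k * (k + 1))
      s1 <- s1 + fac * (a[k] * pik + b[k] * tauk)
      s2 <- s2 + fac * (a[k] * tauk + b[k] * pik)
      pinew <- ((2 * k + 1) * mu * pik - (k + 1) * pim1) / k
      pim1 <- pik; pik <- pinew
    }
    S1[j] <- s1; S2[j] <- s2
  }
  list(S1 = S1, S2 = S2)
}

#' Particle suspension description
#'
#' @param d_p_um Particle diameter, micrometres (> 0).
#' @param n_p Particle refractive index.
#' @param n_med Medium refractive index.
#' @param number_density_mm3 Particle number density, mm^-3. Give either
#'   this or `mass_fraction`.
#' @param mass_fraction Particle mass fraction of the suspension.
#' @param particle_density_g_cm3 Particle material density used to
#'   convert a mass fraction to a number density (default 0.93, a
#'   soybean-oil-like lipid).
#' @param suspension_density_g_cm3 Bulk suspension density for the same
#'   conversion.
#' @return Object of class `particle_suspension`.
#' @export
#' @examples
#' particle_suspension(0.5, 1.47, 1.54, mass_fraction = 0.04)
particle_suspension <- function(d_p_um, n_p, n_med,
                                number_density_mm3 = NULL,
                                mass_fraction = NULL,
                                particle_density_g_cm3 = 0.93,
                                suspension_density_g_cm3 = 1.1) {
  if (d_p_um <= 0) stop("particle diameter must be > 0", call. = FALSE)
  if (n_p < 1 || n_med < 1)
    stop("refractive indices must be >= 1", call. = FALSE)
  if (is.null(number_density_mm3)) {
    if (is.null(mass_fraction))
      stop("give number_density_mm3 or mass_fraction", call. = FALSE)
    if (mass_fraction < 0) stop("mass fraction must be >= 0", call. = FALSE)
    # particle mass in g: rho [g/cm^3] * volume [cm^3]
    v_cm3 <- pi / 6 * (d_p_um * 1e-4)^3
    m_p <- particle_density_g_cm3 * v_cm3
    # particles per cm^3 -> per mm^3
    number_density_mm3 <- mass_fraction * suspension_density_g_cm3 /
      m_p / 1000
  }
  if (number_density_mm3 < 0)
    stop("number density must be >= 0", call. = FALSE)
  structure(list(d_p_um = d_p_um, n_p = n_p, n_med = n_med,
                 number_density_mm3 = number_density_mm3),
            class = "particle_suspension")
}

#' Scattering coefficient and anisotropy of a dilute suspension
#'
#' Independent-scatterer estimate: `mu_s = C sigma_g Q_sca` with the
#' geometric cross-section `sigma_g = pi (d_p/2)^2`, and g taken from the
#' single-particle Mie solution. The size parameter uses the wavelength
#' in the medium, `x = pi d_p n_med / lambda`.
#'
#' @param susp A [particle_suspension()].
#' @param wavelength_nm Vacuum wavelength(s), nm.
#' @return Data frame with columns `wavelength_nm`, `mu_s` (mm^-1), `g`,
#'   `Q_sca`, `Q_ext`; attribute `assumption = "dilute"` flags the
#'   independent-scatterer approximation.
#' @export
suspension_properties <- function(susp, wavelength_nm) {
  stopifnot(inherits(susp, "particle_suspension"))
  d_mm <- susp$d_p_um / 1000
  sigma_g <- pi * (d_mm / 2)^2          # mm^2
  m <- susp$n_p / susp$n_med
  rows <- lapply(wavelength_nm, function(wl) {
    x <- pi * d_mm * susp$n_med / (wl * 1e-6)  # wl nm -> mm
    ms <- mie_single(x, m)
    data.frame(wavelength_nm = wl,
               mu_s = susp$number_density_mm3 * sigma_g * ms$Q_sca,
               g = ms$g, Q_sca = ms$Q_sca, Q_ext = ms$Q_ext)
  })
  out <- do.call(rbind, rows)
  attr(out, "assumption") <- "dilute"
  out
}
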