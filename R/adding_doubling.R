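# Adding-doubling radiative transfer for a homogeneous slab, and its
# inverse (IAD): recover (mu_a, mu_s) from a measured (R, T) pair.
#
# Discretization: azimuthally averaged Henyey-Greenstein redistribution on
# a quadrature over cosine [0, 1] that contains a node exactly at mu = 1
# (Gauss-Radau), so the collimated normal beam is a grid direction. With a
# refractive-index mismatch the interval is split at the critical cosine:
# Gauss-Legendre below it, Gauss-Radau (endpoint 1) above it. Matrices are
# kept in "weighted" form X^ = C^{1/2} X C^{1/2} with C = diag(2 mu w), in
# which layer composition is plain matrix multiplication.

# Gauss-Legendre nodes/weights on [a, b] for weight function 1.
gauss_legendre01 <- function(n, a = 0, b = 1) {
  j <- seq_len(n - 1)
  beta <- j / sqrt(4 * j^2 - 1)
  J <- diag(0, n)
  J[cbind(j, j + 1)] <- beta
  J[cbind(j + 1, j)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = a + (b - a) * (x[ord] + 1) / 2, w = (b - a) / 2 * w[ord])
}

# Gauss-Radau on [a, b] with a node fixed at b (Legendre weight).
gauss_radau_right <- function(n, a = 0, b = 1) {
  # Radau on [-1, 1] with fixed node at -1 (Gautschi's modified Jacobi
  # matrix), then map -1 -> b.
  stopifnot(n >= 2)
  ak <- rep(0, n)
  bk <- c(2, sapply(seq_len(n - 1), function(k) k^2 / (4 * k^2 - 1)))
  x0 <- -1
  # monic polynomial values p_{n-1}(x0), p_{n-2}(x0)
  pm1 <- 0; p <- 1
  for (k in seq_len(n - 1)) {
    pnew <- (x0 - ak[k]) * p - (if (k >= 2) bk[k] else 0) * pm1
    pm1 <- p; p <- pnew
  }
  ak[n] <- x0 - bk[n] * pm1 / p
  J <- diag(ak)
  off <- sqrt(bk[2:n])
  idx <- seq_len(n - 1)
  J[cbind(idx, idx + 1)] <- off
  J[cbind(idx + 1, idx)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- bk[1] * e$vectors[1, ]^2
  # map t in [-1,1] -> mu in [a,b] with -1 -> b, +1 -> a
  mu <- b - (b - a) * (x + 1) / 2
  wt <- (b - a) / 2 * w
  ord <- order(mu)
  list(x = mu[ord], w = wt[ord])
}

# Quadrature for the slab: node at mu = 1 always present; split at the
# critical cosine when the slab index exceeds the ambient index.
ad_quadrature <- function(n, n_slab, n_out) {
  if (n_slab > max(n_out) + 1e-12) {
    mu_c <- sqrt(1 - (max(n_out) / n_slab)^2)
    n1 <- max(2, floor(n / 2)); n2 <- max(2, n - n1)
    q1 <- gauss_legendre01(n1, 0, mu_c)
    q2 <- gauss_radau_right(n2, mu_c, 1)
    list(mu = c(q1$x, q2$x), w = c(q1$w, q2$w))
  } else {
    q <- gauss_radau_right(n, 0, 1)
    list(mu = q$x, w = q$w)
  }
}

# Azimuthally averaged HG redistribution via the Legendre expansion
# p(cos) = sum (2k+1) g^k P_k; sign = +1 same hemisphere, -1 reflection.
hg_redistribution <- function(mu, g, sign) {
  n <- length(mu)
  if (abs(g) < 1e-12) return(matrix(1, n, n))
  K <- min(256, max(8, ceiling(log(1e-13) / log(abs(g)))))
  # Legendre values P_k(mu) by recurrence, rows k = 0..K
  P <- matrix(0, K + 1, n)
  P[1, ] <- 1; P[2, ] <- mu
  if (K >= 2) for (k in 2:K)
    P[k + 1, ] <- ((2 * k - 1) * mu * P[k, ] - (k - 1) * P[k - 1, ]) / k
  coef <- (2 * (0:K) + 1) * (g^(0:K)) * (sign^(0:K))
  t(P) %*% (coef * P)
}

# Core doubling: weighted R^, T^ for a bare homogeneous slab.
ad_bare_slab <- function(albedo, tau, g, quad) {
  mu <- quad$mu; w <- quad$w
  n <- length(mu)
  sc <- sqrt(2 * mu * w)
  if (tau <= 0) return(list(R = matrix(0, n, n), T = diag(n), quad = quad))
  k <- max(0, ceiling(log2(tau / 1e-8)))
  dtau <- tau / 2^k
  hplus <- hg_redistribution(mu, g, +1)
  hminus <- hg_redistribution(mu, g, -1)
  denom <- 4 * outer(mu, mu)
  Rh <- (albedo * dtau * hminus / denom) * outer(sc, sc)
  Th <- (albedo * dtau * hplus / denom) * outer(sc, sc)
  diag(Th) <- diag(Th) + (1 - dtau / mu)
  I <- diag(n)
  for (j in seq_len(k)) {
    A <- solve(I - Rh %*% Rh)
    TA <- Th %*% A
    Rh <- Rh + TA %*% Rh %*% Th
    Th <- TA %*% Th
  }
  list(R = Rh, T = Th, quad = quad)
}

#' Reflectance and transmittance of a homogeneous slab
#'
#' Adding-doubling solution for collimated normal incidence on a
#' homogeneous slab, with Fresnel boundary layers when the slab index
#' differs from the ambient indices. The returned reflectance excludes
#' the specular reflection of the incident beam (it is what an
#' integrating sphere reports as diffuse reflectance); the transmittance
#' includes the ballistic component.
#'
#' @param props [optical_properties()] at one wavelength (scalar fields).
#' @param thickness_mm Slab thickness, mm.
#' @param n_above,n_below Ambient refractive indices (default matched to
#'   the slab for the fast path).
#' @param n_quad Number of quadrature streams (doubled internally until
#'   the reflectance changes by less than `tol_quad` when
#'   `check_quadrature` is TRUE).
#' @param check_quadrature Verify quadrature convergence by comparing
#'   with a doubled order.
#' @param tol_quad Convergence tolerance between quadrature orders.
#' @return List with `R`, `T` (fractions), `R_specular`, and `n_quad`
#'   (order used).
#' @export
#' @examples
#' rt_slab(optical_properties(0.01, 1, 0, 1.5), 2, n_above = 1, n_below = 1)
rt_slab <- function(props, thickness_mm, n_above = props$n,
                    n_below = props$n, n_quad = 16,
                    check_quadrature = FALSE, tol_quad = 1e-6) {
  stopifnot(inherits(props, "optical_properties"), thickness_mm > 0)
  if (length(props$mu_a) != 1L)
    stop("rt_slab expects scalar (single-wavelength) properties",
         call. = FALSE)
  val <- rt_slab_order(props, thickness_mm, n_above, n_below, n_quad)
  if (check_quadrature) {
    val2 <- rt_slab_order(props, thickness_mm, n_above, n_below, 2 * n_quad)
    if (abs(val2$R - val$R) > tol_quad || abs(val2$T - val$T) > tol_quad) {
      val4 <- rt_slab_order(props, thickness_mm, n_above, n_below,
                            4 * n_quad)
      if (abs(val4$R - val2$R) > tol_quad || abs(val4$T - val2$T) > tol_quad)
        stop("adding-doubling quadrature did not converge at order ",
             4 * n_quad, call. = FALSE)
      val <- val4
    } else val <- val2
  }
  val
}

rt_slab_order <- function(props, thickness_mm, n_above, n_below, n_quad) {
  mu_t <- props$mu_a + props$mu_s
  tau <- mu_t * thickness_mm
  albedo <- if (mu_t > 0) props$mu_s / mu_t else 0
  quad <- ad_quadrature(n_quad, props$n, c(n_above, n_below))
  mu <- quad$mu; w <- quad$w
  n <- length(mu)
  sc <- sqrt(2 * mu * w)
  slab <- ad_bare_slab(albedo, tau, props$g, quad)
  Rh <- slab$R; Th <- slab$T
  # clamp just below 1: keeps the TIR bounce series summable when the
  # slab neither scatters nor absorbs (zero-injection trapped modes)
  rho_t <- pmin(vapply(mu, function(m) .fresnel_cpp(props$n, n_above, m),
                       numeric(1)), 1 - 1e-9)
  rho_b <- pmin(vapply(mu, function(m) .fresnel_cpp(props$n, n_below, m),
                       numeric(1)), 1 - 1e-9)
  i1 <- which.max(mu)                   # node at mu = 1
  rs <- .fresnel_cpp(n_above, props$n, 1)
  v <- numeric(n); v[i1] <- (1 - rs) / sc[i1]
  I <- diag(n)
  Pb <- diag(rho_b, n)
  Rsb <- Rh + Th %*% Pb %*% solve(I - Rh %*% Pb) %*% Th
  Pt <- diag(rho_t, n)
  D <- solve(I - Pt %*% Rsb, v)
  U <- Rsb %*% D
  G <- solve(I - Rh %*% Pb, Th %*% D)
  list(R = sum(sc * (1 - rho_t) * U), T = sum(sc * (1 - rho_b) * G),
       R_specular = rs, n_quad = n_quad)
}

#' Invert a measured (R, T) pair for absorption and scattering
#'
#' Inverse adding-doubling: finds the (mu_a, mu_s) whose [rt_slab()]
#' prediction reproduces a measured diffuse reflectance / transmittance
#' pair at a known anisotropy and refractive index. The search runs in
#' (log optical thickness, log(1 - albedo)) coordinates: a coarse grid
#' scan seeds a damped Newton iteration with a finite-difference
#' Jacobian.
#'
#' @param M_R Measured diffuse reflectance fraction.
#' @param M_T Measured transmittance fraction.
#' @param thickness_mm Slab thickness, mm.
#' @param g Anisotropy assumed during inversion (0 by default, the
#'   standard IAD convention; supply a Mie estimate to refine).
#' @param n Slab refractive index.
#' @param n_above,n_below Ambient indices.
#' @param tol Absolute tolerance on the reproduced (R, T).
#' @param n_quad Quadrature streams for the forward solver.
#' @return List with `mu_a`, `mu_s` (mm^-1), `residual_R`, `residual_T`,
#'   `iterations`.
#' @export
#' @examples
#' p <- optical_properties(0.05, 2, 0, 1.4)
#' f <- rt_slab(p, 2)
#' iad_invert(f$R, f$T, 2, g = 0, n = 1.4)
iad_invert <- function(M_R, M_T, thickness_mm, g = 0, n = 1.4,
                       n_above = n, n_below = n, tol = 1e-4, n_quad = 16) {
  if (M_R < 0 || M_T < 0 || M_R + M_T > 1)
    stop("need 0 <= M_R, 0 <= M_T, M_R + M_T <= 1", call. = FALSE)
  fwd <- function(mu_a, mu_s)
    rt_slab(optical_properties(mu_a, mu_s, g, n), thickness_mm,
            n_above, n_below, n_quad = n_quad)
  # transparent fast path
  f0 <- fwd(0, 0)
  if (abs(f0$R - M_R) < tol && abs(f0$T - M_T) < tol)
    return(list(mu_a = 0, mu_s = 0, residual_R = f0$R - M_R,
                residual_T = f0$T - M_T, iterations = 0L))
  # parameters: p = (log tau, log(1 - a)); a = albedo, tau = optical depth
  p2props <- function(p) {
    tau <- exp(p[1]); a <- 1 - exp(p[2])
    mu_t <- tau / thickness_mm
    c(mu_a = (1 - a) * mu_t, mu_s = a * mu_t)
  }
  resid <- function(p) {
    ms <- p2props(p)
    f <- fwd(ms[1], ms[2])
    c(f$R - M_R, f$T - M_T)
  }
  # coarse scan
  taus <- exp(seq(log(1e-3), log(64), length.out = 15))
  omas <- exp(seq(log(1e-5), log(1), length.out = 11))  # 1 - albedo
  best <- NULL
  for (tau in taus) for (om in omas) {
    p <- c(log(tau), log(om))
    r <- resid(p)
    s <- sum(r^2)
    if (is.null(best) || s < best$s ||
        (abs(s - best$s) < 1e-14 && p[1] < best$p[1]))
      best <- list(p = p, s = s, r = r)
  }
  p <- best$p; r <- best$r
  iter <- 0L
  for (it in seq_len(60)) {
    if (max(abs(r)) < tol * 1e-2) break
    h <- 1e-5
    J <- cbind((resid(p + c(h, 0)) - r) / h, (resid(p + c(0, h)) - r) / h)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    # clamp and damp
    step <- pmax(pmin(step, 4), -4)
    ok <- FALSE
    for (half in 0:8) {
      pn <- p + step / 2^half
      pn[2] <- min(pn[2], 0)            # albedo >= 0
      pn[1] <- min(max(pn[1], log(1e-8)), log(512))
      rn <- resid(pn)
      if (sum(rn^2) < sum(r^2)) { p <- pn; r <- rn; ok <- TRUE; break }
    }
    iter <- it
    if (!ok) break
  }
  if (max(abs(r)) > tol)
    stop(sprintf(paste0("no (mu_a, mu_s) reproduces (M_R = %.5g, ",
                        "M_T = %.5g) within %.1g at g = %.3g, n = %.3g ",
                        "(best residual %.3g); check inputs or g/n"),
                 M_R, M_T, tol, g, n, max(abs(r))), call. = FALSE)
  ms <- p2props(p)
  list(mu_a = unname(ms[1]), mu_s = unname(ms[2]),
       residual_R = r[1], residual_T = r[2], iterations = iter)
}

#' Batch IAD over a spectrum table
#'
#' Reads a CSV with columns `wavelength_nm`, `M_R`, `M_T`, inverts each
#' row with [iad_invert()], and optionally writes the result table.
#'
#' @param path Input CSV path (see [read_spectrum_csv()]).
#' @param thickness_mm Slab thickness, mm.
#' @param g,n,n_above,n_below Passed to [iad_invert()].
#' @param out Optional output CSV path.
#' @return Data frame with columns `wavelength_nm`, `mu_a_mm`, `mu_s_mm`,
#'   `g`, `residual_R`, `residual_T`.
#' @export
iad_batch <- function(path, thickness_mm, g = 0, n = 1.4, n_above = n,
                      n_below = n, out = NULL) {
  tab <- read_spectrum_csv(path)
  if (!all(c("m_r", "m_t") %in% names(tab)))
    stop("input must have columns wavelength_nm, M_R, M_T", call. = FALSE)
  res <- lapply(seq_len(nrow(tab)), function(i) {
    fit <- iad_invert(tab$m_r[i], tab$m_t[i], thickness_mm, g = g, n = n,
                      n_above = n_above, n_below = n_below)
    data.frame(wavelength_nm = tab$wavelength_nm[i], mu_a_mm = fit$mu_a,
               mu_s_mm = fit$mu_s, g = g, residual_R = fit$residual_R,
               residual_T = fit$residual_T)
  })
  res <- do.call(rbind, res)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
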