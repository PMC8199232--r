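test_that("trivial slabs reproduce closed forms", {
  # transparent, matched indices
  f <- rt_slab(optical_properties(0, 0, 0, 1.5), 2,
               n_above = 1.5, n_below = 1.5)
  expect_equal(f$R, 0)
  expect_equal(f$T, 1)
  # transparent, mismatched: multiple-bounce Airy sums
  r <- 0.04
  f2 <- rt_slab(optical_properties(0, 0, 0, 1.5), 2,
                n_above = 1, n_below = 1)
  expect_equal(f2$T, (1 - r)^2 / (1 - r^2), tolerance = 1e-6)
  expect_equal(f2$R, (1 - r)^2 * r / (1 - r^2), tolerance = 1e-6)
  # conservative scattering: R + T = 1
  f3 <- rt_slab(optical_properties(0, 2, 0, 1.4), 2,
                n_above = 1.4, n_below = 1.4)
  expect_lt(abs(f3$R + f3$T - 1), 1e-6)
})

test_that("quadrature order is converged at the default", {
  p <- optical_properties(0.05, 3, 0.8, 1.5)
  f16 <- rt_slab(p, 2, n_above = 1, n_below = 1, n_quad = 16)
  f32 <- rt_slab(p, 2, n_above = 1, n_below = 1, n_quad = 32)
  # strongly forward-peaked phase function + index mismatch is the worst
  # case; the isotropic cases used by the inversions agree much tighter
  expect_lt(abs(f16$R - f32$R), 1e-3)
  expect_lt(abs(f16$T - f32$T), 1e-3)
  p0 <- optical_properties(0.05, 3, 0, 1.4)
  g16 <- rt_slab(p0, 2, n_above = 1.4, n_below = 1.4, n_quad = 16)
  g32 <- rt_slab(p0, 2, n_above = 1.4, n_below = 1.4, n_quad = 32)
  expect_lt(abs(g16$R - g32$R), 1e-5)
  expect_lt(abs(g16$T - g32$T), 1e-5)
  fc <- rt_slab(p, 2, n_above = 1, n_below = 1, check_quadrature = TRUE,
                tol_quad = 1e-3)
  expect_true(fc$n_quad >= 16)
})

test_that("R and T respond monotonically to the coefficients", {
  base <- function(mu_a, mu_s)
    rt_slab(optical_properties(mu_a, mu_s, 0, 1.4), 2,
            n_above = 1.4, n_below = 1.4)
  for (mu_s in c(1, 4)) {
    f1 <- base(0.05, mu_s); f2 <- base(0.2, mu_s)
    expect_lt(f2$R, f1$R)    # more absorption, less comes back
    expect_lt(f2$T, f1$T)
  }
  for (mu_a in c(0.05, 0.2)) {
    f1 <- base(mu_a, 1); f2 <- base(mu_a, 4)
    expect_gt(f2$R, f1$R)    # more scattering, more comes back
  }
})

test_that("iad_invert is a right inverse of rt_slab on a grid", {
  # matched-index grid at g = 0
  for (mu_a in c(0.01, 0.1, 0.5)) for (mu_s in c(0.5, 2, 8)) {
    p <- optical_properties(mu_a, mu_s, 0, 1.4)
    f <- rt_slab(p, 2)
    inv <- iad_invert(f$R, f$T, 2, g = 0, n = 1.4)
    expect_lt(abs(inv$mu_a - mu_a) / mu_a, 0.01)
    expect_lt(abs(inv$mu_s - mu_s) / mu_s, 0.01)
    # returned properties reproduce the pair within tolerance
    expect_lt(max(abs(c(inv$residual_R, inv$residual_T))), 1e-4)
  }
  # mismatched boundaries and anisotropic scattering
  p <- optical_properties(0.05, 3, 0.7, 1.5)
  f <- rt_slab(p, 2, n_above = 1, n_below = 1)
  inv <- iad_invert(f$R, f$T, 2, g = 0.7, n = 1.5, n_above = 1,
                    n_below = 1)
  expect_lt(abs(inv$mu_a - 0.05) / 0.05, 0.01)
  expect_lt(abs(inv$mu_s - 3) / 3, 0.01)
})

test_that("transparent measurement inverts to zero coefficients", {
  inv <- iad_invert(0, 1, 2, g = 0, n = 1.0)
  expect_equal(inv$mu_a, 0)
  expect_equal(inv$mu_s, 0)
})

test_that("invalid and infeasible measurements are rejected", {
  expect_error(iad_invert(0.6, 0.5, 2), "M_R")
  # R = 0.999 needs an optical thickness beyond any physical fit here
  expect_error(iad_invert(0.999, 5e-4, 2, g = 0, n = 1.0),
               "no \\(mu_a, mu_s\\)")
})

test_that("batch IAD reads a CSV and returns one row per wavelength", {
  wl <- c(450, 500, 550)
  pairs <- t(vapply(seq_along(wl), function(i) {
    f <- rt_slab(optical_properties(0.02 * i, 1 + i, 0, 1.4), 2)
    c(f$R, f$T)
  }, numeric(2)))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = wl, M_R = pairs[, 1],
                       M_T = pairs[, 2]), path, row.names = FALSE)
  res <- iad_batch(path, thickness_mm = 2, g = 0, n = 1.4)
  expect_equal(nrow(res), 3)
  expect_equal(res$mu_a_mm, 0.02 * (1:3), tolerance = 0.01)
  expect_equal(res$mu_s_mm, 1 + (1:3), tolerance = 0.01)
})
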