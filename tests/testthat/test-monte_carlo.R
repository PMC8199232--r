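test_that("fresnel reflectance matches closed forms", {
  expect_equal(fresnel_reflectance(1, 1, 0.3), 0)
  # normal incidence: ((n-1)/(n+1))^2
  expect_equal(fresnel_reflectance(1, 1.5, 1), 0.04, tolerance = 1e-12)
  # beyond the critical angle (41.8 deg for n = 1.5) everything reflects
  expect_equal(fresnel_reflectance(1.5, 1, cos(60 * pi / 180)), 1)
  expect_error(fresnel_reflectance(1, 1.5, 1.2), "cos_theta_i")
})

test_that("Henyey-Greenstein sampling is isotropic at g = 0 and has mean g", {
  u <- seq(0, 0.999, length.out = 50)
  expect_equal(sample_henyey_greenstein(0, u), 2 * u - 1,
               tolerance = 1e-12)
  expect_equal(sample_henyey_greenstein(0, 0.5), 0)
  # E[cos theta] = g, checked at 3 standard errors
  set.seed(2)
  for (g in c(0.5, 0.9)) {
    draws <- sample_henyey_greenstein(g, runif(2e5))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - g), 3 * se)
  }
})

test_that("ballistic slab transmits everything with matched indices", {
  m <- slab_model(mu_a = 0, mu_s = 0, n = 1)
  s <- simulate_transport(m, one_wl_beam(), quick_mc())
  expect_equal(s$T, 1)
  expect_equal(s$R_diffuse + s$R_specular + s$Abs_background +
                 s$Abs_vessel + s$E_side, 0)
})

test_that("energy budget closes to machine precision for random configs", {
  set.seed(11)
  for (i in 1:10) {
    with_vessel <- i %% 2 == 0
    vessel <- if (with_vessel)
      cylindrical_vessel(runif(1, 50, 400), runif(1, 0.3, 1.6),
                         optical_properties(runif(1, 1, 50),
                                            runif(1, 0, 3), 0, 1.37))
    m <- phantom_model(
      thickness_mm = 2, lateral_mm = runif(1, 5, 20),
      background = optical_properties(runif(1, 0, 0.3), runif(1, 0.2, 5),
                                      runif(1, -0.5, 0.9),
                                      runif(1, 1.3, 1.6)),
      vessel = vessel, n_above = 1, n_below = 1)
    s <- simulate_transport(m, one_wl_beam(spot = runif(1, 0.2, 3)),
                            quick_mc(photons = 3000, seed = 100 + i))
    expect_budget_closed(s)
  }
})

test_that("fixed seed reproduces bit-identical budgets", {
  m <- vessel_model(0.65)
  b <- beam_spec(spot_mm = 0.5, wavelengths_nm = seq(420, 580, by = 40))
  s1 <- sweep_spectrum(m, b, quick_mc(photons = 4000, seed = 7))
  s2 <- sweep_spectrum(m, b, quick_mc(photons = 4000, seed = 7))
  expect_identical(s1$reflectance$value, s2$reflectance$value)
  expect_identical(s1$transmittance$value, s2$transmittance$value)
  s3 <- sweep_spectrum(m, b, quick_mc(photons = 4000, seed = 8))
  expect_false(identical(s1$reflectance$value, s3$reflectance$value))
})

test_that("MC matches adding-doubling on a homogeneous wide-beam slab", {
  # one representative cell of the equivalence grid (full grid runs in
  # the acceptance suite)
  p <- optical_properties(0.1, 0.9, 0, 1)
  ad <- rt_slab(p, 2, n_above = 1, n_below = 1)
  m <- slab_model(0.1, 0.9)
  s <- simulate_transport(m, one_wl_beam(), quick_mc(photons = 4e4,
                                                     seed = 5))
  expect_lt(abs(s$R_diffuse - ad$R), 3 * s$se_R)
  expect_lt(abs(s$T - ad$T), 3 * s$se_T)
})

test_that("absorption grid totals equal the absorbed budget terms", {
  m <- vessel_model(0.65)
  s <- simulate_transport(m, one_wl_beam(420, spot = 0.5),
                          quick_mc(photons = 5000, seed = 3,
                                   tally_fluence = TRUE, voxel_mm = 0.5))
  expect_lt(abs(sum(s$fluence) - (s$Abs_background + s$Abs_vessel)),
            1e-9)
})

test_that("missing blood properties at a wavelength raise a config error", {
  m <- phantom_model(
    background = optical_properties(c(0.01, 0.01, 0.01), c(2, 2, 2),
                                    0, 1.5),
    vessel = cylindrical_vessel(300, 0.65,
                                optical_properties(c(20, 25), 1, 0, 1.37)))
  b <- beam_spec(wavelengths_nm = c(450, 550, 650))
  expect_error(simulate_transport(m, b, quick_mc(), wavelength_index = 3),
               "blood properties missing")
})

test_that("a flipped vessel sits in weaker fluence and absorbs less", {
  # flipping moves the vessel from 0.65 mm to 1.35 mm below the
  # illuminated face; photon fluence decays with depth, so the flipped
  # vessel must intercept less energy (and reflectance must rise)
  m <- vessel_model(0.65, wl = 500)
  f <- flip_phantom(m)
  b <- one_wl_beam(500, spot = 0.5)
  s1 <- simulate_transport(m, b, quick_mc(photons = 4e4, seed = 21))
  s2 <- simulate_transport(f, b, quick_mc(photons = 4e4, seed = 21))
  expect_lt(s2$Abs_vessel, s1$Abs_vessel)
  expect_gt(s2$R_diffuse, s1$R_diffuse)
  expect_budget_closed(s1)
  expect_budget_closed(s2)
})
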