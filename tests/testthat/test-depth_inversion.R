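test_that("band reflectance rises with vessel depth and falls with diameter", {
  wl <- seq(420, 580, by = 40)
  m <- vessel_model(0.65, wl = wl)
  beam <- beam_spec(spot_mm = 0.5, wavelengths_nm = wl)
  mc <- quick_mc(photons = 2e4, seed = 77)
  # common random numbers -> strictly ordered curve even at modest N
  curve <- reflectance_depth_curve(m, 300, c(0.4, 0.9, 1.6), beam, mc)
  expect_true(all(diff(curve$reflectance) > 0))
  # larger vessel at fixed depth reflects less
  c100 <- reflectance_depth_curve(m, 100, 0.9, beam, mc)
  c300 <- reflectance_depth_curve(m, 300, 0.9, beam, mc)
  expect_lt(c300$reflectance, c100$reflectance)
  # no vessel bounds the deepest-vessel reflectance from above
  m0 <- m; m0$vessel <- NULL
  sw0 <- sweep_spectrum(m0, beam, mc)
  expect_gte(mean(sw0$reflectance$value),
             max(curve$reflectance))
})

test_that("depth curve is deterministic and guards containment", {
  wl <- seq(420, 580, by = 80)
  m <- vessel_model(0.65, wl = wl)
  beam <- beam_spec(spot_mm = 0.5, wavelengths_nm = wl)
  mc <- quick_mc(photons = 5000, seed = 3)
  c1 <- reflectance_depth_curve(m, 300, c(0.5, 1.2), beam, mc)
  c2 <- reflectance_depth_curve(m, 300, c(0.5, 1.2), beam, mc)
  expect_identical(c1, c2)
  expect_error(reflectance_depth_curve(m, 300, c(0.1, 0.5), beam, mc),
               "containment")
})

test_that("a measurement generated at the bracket edge returns that edge", {
  wl <- seq(420, 580, by = 40)
  m <- vessel_model(0.65, wl = wl)
  beam <- beam_spec(spot_mm = 0.5, wavelengths_nm = wl)
  mc <- quick_mc(photons = 2e4, seed = 13)
  d1 <- 0.4
  meas <- drsdepth:::depth_forward(m, 300, d1, beam, mc)$sweep$reflectance
  est <- extract_depth(meas, 300, m, beam, mc, bracket = c(d1, 1.7))
  expect_lt(abs(est$d_hat - d1), 0.02)
  expect_lte(est$iterations,
             ceiling(log2((1.7 - d1) / 0.01)))
})

test_that("noiseless same-seed inversion round-trips the true depth", {
  wl <- seq(420, 580, by = 40)
  m <- vessel_model(1.0, wl = wl)
  beam <- beam_spec(spot_mm = 0.5, wavelengths_nm = wl)
  mc <- quick_mc(photons = 2e4, seed = 55)
  meas <- drsdepth:::depth_forward(m, 300, 1.0, beam, mc)$sweep$reflectance
  est <- extract_depth(meas, 300, m, beam, mc, bracket = c(0.3, 1.7),
                       depth_tol = 0.005)
  expect_lt(abs(est$d_hat - 1.0), 0.01)
  expect_identical(est$direction, "increasing")
})

test_that("median depth error over noisy scenarios stays within 5%", {
  # scaled-down recovery property: 1% multiplicative noise, modest
  # photon budgets, depths across the informative range
  depths <- rep(c(0.5, 0.8, 1.1, 1.4, 1.7), 2)
  errs <- vapply(seq_along(depths), function(i) {
    d <- depths[i]
    sc <- generate_scenario(scenario_spec(
      diameter_um = 300, axis_depth_mm = d,
      wavelengths_nm = seq(420, 580, by = 40),
      photons = 2e4, noise = 0.01, seed = 7000 + 13 * i))
    est <- extract_depth(sc$measured$reflectance, 300, sc$model,
                         sc$beam, mc_config(photons = 2e4, seed = 17 + i))
    abs(est$d_hat - d) / d
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("out-of-range measurements trigger a bracket error", {
  wl <- seq(420, 580, by = 80)
  m <- vessel_model(0.65, wl = wl)
  beam <- beam_spec(spot_mm = 0.5, wavelengths_nm = wl)
  mc <- quick_mc(photons = 5000, seed = 2)
  fake <- as_spectrum(wl, rep(0.99, length(wl)), "reflectance")
  expect_error(extract_depth(fake, 300, m, beam, mc,
                             bracket = c(0.4, 1.6)),
               "outside the calculated range")
})
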