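test_that("hemoglobin-like template has the Soret hump and is linear", {
  expect_gt(hemoglobin_like_mu_a(420), hemoglobin_like_mu_a(700))
  expect_equal(hemoglobin_like_mu_a(c(400, 500, 600), scale = 0),
               c(0, 0, 0))
  expect_equal(hemoglobin_like_mu_a(520, scale = 2),
               2 * hemoglobin_like_mu_a(520))
  expect_error(hemoglobin_like_mu_a(250), "300")
  # local Q-band maximum inside 500-600 nm
  wl <- seq(500, 600, by = 2)
  mu <- hemoglobin_like_mu_a(wl)
  peak <- wl[which.max(mu)]
  expect_gt(peak, 520)
  expect_lt(peak, 590)
})

test_that("the vessel imprints a dip inside the 400-600 nm band", {
  # brute-force scan: reflectance loss (no-vessel minus vessel) must
  # peak strictly inside the band, where the template absorbs most
  wl <- seq(410, 640, by = 23)
  m1 <- vessel_model(0.5, D_um = 300, wl = wl)
  m0 <- m1; m0$vessel <- NULL
  beam <- beam_spec(spot_mm = 0.5, wavelengths_nm = wl)
  mc <- quick_mc(photons = 2e4, seed = 17)
  s1 <- sweep_spectrum(m1, beam, mc)
  s0 <- sweep_spectrum(m0, beam, mc)
  dip <- s0$reflectance$value - s1$reflectance$value
  k <- which.max(dip)
  expect_gte(wl[k], 400)
  expect_lte(wl[k], 600)
  expect_gt(dip[k], 0)
})

test_that("generated scenarios embed recoverable truth and valid spectra", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec(diameter_um = 100, axis_depth_mm = 1.35,
                        photons = 4000, noise = 0.02, seed = 31)
  sc <- generate_scenario(spec, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("model.json",
                                               "measured.csv",
                                               "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$axis_depth_mm, 1.35)
  expect_equal(truth$diameter_um, 100)
  expect_true(truth$synthetic)
  tab <- read_spectrum_csv(file.path(dir, "measured.csv"))
  expect_true(all(tab$m_r >= 0 & tab$m_r <= 1))
  expect_true(all(tab$m_r + tab$m_t <= 1 + 1e-12))
  cfg <- read_config_json(file.path(dir, "model.json"))
  expect_equal(cfg$model$vessel$diameter_um, 100)
})

test_that("noiseless scenarios reproduce the forward sweep exactly", {
  spec <- scenario_spec(photons = 4000, noise = 0, seed = 77)
  sc <- generate_scenario(spec)
  sw <- sweep_spectrum(sc$model, sc$beam,
                       mc_config(photons = 4000, seed = 77))
  expect_identical(sc$measured$reflectance$value, sw$reflectance$value)
})

test_that("flip-paired scenarios order their reflectance by depth", {
  # depths d and thickness - d describe the same phantom seen from the
  # two faces; seen from this face, the deeper (flipped) vessel leaves
  # more light to return
  s1 <- generate_scenario(scenario_spec(diameter_um = 300,
                                        axis_depth_mm = 0.65,
                                        wavelengths_nm = c(500, 540, 580),
                                        photons = 3e4, noise = 0,
                                        seed = 41))
  s2 <- generate_scenario(scenario_spec(diameter_um = 300,
                                        axis_depth_mm = 1.35,
                                        wavelengths_nm = c(500, 540, 580),
                                        photons = 3e4, noise = 0,
                                        seed = 41))
  expect_equal(s2$model$vessel$axis_depth_mm,
               s1$model$thickness_mm - s1$model$vessel$axis_depth_mm)
  expect_gt(mean(s2$measured$reflectance$value),
            mean(s1$measured$reflectance$value))
})
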