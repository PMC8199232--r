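test_that("constructors enforce physical invariants", {
  expect_error(optical_properties(-0.1, 1), "mu_a")
  expect_error(optical_properties(0.1, -1), "mu_s")
  expect_error(optical_properties(0.1, 1, g = 1), "g must")
  expect_error(optical_properties(0.1, 1, n = 0.9), "n must")
  expect_error(cylindrical_vessel(0, 0.5), "diameter")
  # containment: 300 um vessel cannot sit 0.1 mm deep in a 2 mm slab
  expect_error(phantom_model(vessel = cylindrical_vessel(300, 0.1)),
               "illuminated surface")
  expect_error(phantom_model(vessel = cylindrical_vessel(300, 1.95)),
               "bottom surface")
  expect_error(beam_spec(wavelengths_nm = c(500, 500)), "increasing")
  expect_error(beam_spec(wavelengths_nm = 1500), "1200")
  expect_error(mc_config(roulette_threshold = 2), "roulette_threshold")
})

test_that("region_at labels the example points and partitions space", {
  m <- phantom_model(vessel = cylindrical_vessel(300, 0.65))
  expect_identical(region_at(c(0, 0, 0.65), m), "vessel")
  expect_identical(region_at(c(0, 0, 0.65 + 0.15 + 1e-6), m),
                   "background")
  expect_identical(region_at(c(0, 0, -0.01), m), "ambient_above")
  expect_identical(region_at(c(0, 0, 2.5), m), "ambient_below")
  expect_identical(region_at(c(8, 0, 1), m), "lateral_exit")
  # every random point receives exactly one of the five labels
  set.seed(4)
  labels <- c("ambient_above", "background", "vessel", "ambient_below",
              "lateral_exit")
  for (i in 1:200) {
    pos <- c(runif(1, -10, 10), runif(1, -10, 10), runif(1, -1, 3))
    lab <- region_at(pos, m)
    expect_length(lab, 1L)
    expect_true(lab %in% labels)
  }
})

test_that("region_at commutes with flipping the phantom", {
  m <- phantom_model(vessel = cylindrical_vessel(300, 0.65))
  f <- flip_phantom(m)
  expect_equal(f$vessel$axis_depth_mm, 2 - 0.65)
  swap <- c(ambient_above = "ambient_below",
            ambient_below = "ambient_above",
            background = "background", vessel = "vessel",
            lateral_exit = "lateral_exit")
  set.seed(9)
  for (i in 1:200) {
    pos <- c(runif(1, -9, 9), runif(1, -9, 9), runif(1, -0.5, 2.5))
    flipped_pos <- c(pos[1], pos[2], m$thickness_mm - pos[3])
    expect_identical(region_at(flipped_pos, f),
                     unname(swap[region_at(pos, m)]))
  }
})

test_that("config JSON round-trips model, beam and MC settings", {
  m <- vessel_model(0.65)
  b <- beam_spec(spot_mm = 0.5, wavelengths_nm = seq(420, 580, by = 40))
  mc <- mc_config(photons = 1234, seed = 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_config_json(m, b, mc, path)
  cfg <- read_config_json(path)
  expect_equal(cfg$model$thickness_mm, m$thickness_mm)
  expect_equal(cfg$model$vessel$axis_depth_mm, 0.65)
  expect_equal(cfg$model$vessel$blood$mu_a, m$vessel$blood$mu_a)
  expect_equal(cfg$beam$wavelengths_nm, b$wavelengths_nm)
  expect_equal(cfg$mc$photons, 1234L)
  expect_equal(cfg$mc$seed, 99)
})

test_that("missing config keys are reported by name", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(geometry = list(thickness_mm = 2),
                            mc = list(seed = 1)),
                       path, auto_unbox = TRUE)
  expect_error(read_config_json(path), "beam")
})
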