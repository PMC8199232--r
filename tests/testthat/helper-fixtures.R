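# Shared fixtures: small, fast configurations used across the suite.
# Photon counts here are sized for test speed; statistically demanding
# checks carry their own counts.

quick_mc <- function(photons = 5000, seed = 1, ...) {
  mc_config(photons = photons, seed = seed, ...)
}

# homogeneous epoxy-like slab, matched or mismatched indices
slab_model <- function(mu_a = 0.01, mu_s = 2, g = 0, n = 1.0,
                       thickness = 2, lateral = 40) {
  phantom_model(thickness_mm = thickness, lateral_mm = lateral,
                background = optical_properties(mu_a, mu_s, g, n),
                n_above = 1, n_below = 1)
}

one_wl_beam <- function(wl = 550, spot = 1)
  beam_spec(spot_mm = spot, wavelengths_nm = wl)

# vessel scenario used by the depth tests (coarse but fast)
vessel_model <- function(d_mm, D_um = 300, wl = seq(420, 580, by = 40),
                         blood_scale = 1) {
  blood <- optical_properties(hemoglobin_like_mu_a(wl, blood_scale),
                              1, 0, 1.37)
  phantom_model(
    thickness_mm = 2, lateral_mm = 15,
    background = optical_properties(rep(0.01, length(wl)),
                                    background_mu_s(wl), 0, 1.5),
    vessel = cylindrical_vessel(D_um, d_mm, blood))
}

expect_budget_closed <- function(budget, tol = 1e-9) {
  expect_lt(abs(budget_sum(budget) - 1), tol)
}
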