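# drsdepth

Tools for extracting the depth of a subsurface blood vessel from diffuse
reflectance spectroscopy (DRS) of a tissue phantom — the measurement
problem behind personalized laser treatment of vascular skin lesions such
as port wine stains, whose target capillaries (diameter 30–300 µm, depth
a few hundred µm to ~2 mm) are too fine for ultrasound or MRI. Vessel
*diameter* is observable with speckle imaging; this package supplies the
missing half: given the diameter and the medium's optical properties,
invert the reflectance spectrum for the vessel's axis depth *d*.

The package is aimed at tissue-optics researchers working with layered or
channel phantoms (epoxy or resin matrix, lipid scatterers, blood-filled
microchannel) and provides the full chain as composable pieces:

* **Forward Monte Carlo** (`simulate_transport()`, `sweep_spectrum()`):
  weighted hop–drop–spin photon transport in a slab containing one
  cylindrical vessel, Henyey–Greenstein scattering, Fresnel boundaries,
  Russian roulette, compiled kernel with a self-contained deterministic
  RNG. Every run reports a closed energy budget
  `R_specular + R_diffuse + T + Abs_background + Abs_vessel + E_side = 1`.
* **Adding–doubling and IAD** (`rt_slab()`, `iad_invert()`): 1D radiative
  transfer by doubling on a Radau quadrature (collimated beam is a grid
  direction), and the inverse map from a measured (R, T) pair to
  (µ_a, µ_s) at fixed g and n.
* **IAD–FMC extraction** (`extract_optical_properties()`): the IAD seed
  refined by damped Newton steps whose residuals are evaluated with the
  3D Monte Carlo model under common random numbers, driving the spectral
  mismatch below 1%.
* **Mie anisotropy** (`mie_single()`, `suspension_properties()`): series
  solution for the lipid-droplet suspension's g and µ_s.
* **Depth inversion** (`extract_depth()`, `reflectance_depth_curve()`):
  the 400–600 nm band-mean diffuse reflectance rises monotonically with
  vessel depth (a deeper vessel intercepts fewer photons) and falls with
  diameter; with diameter known, bisection on the forward model pins the
  depth to a 0.01 mm bracket.
* **Synthetic phantom** (`scenario_spec()`, `generate_scenario()`):
  manufactures "measured" spectra with embedded ground truth —
  hemoglobin-like three-Gaussian blood template, power-law background
  scattering, multiplicative measurement noise — so the entire inverse
  chain is testable without laboratory data.

A command-line front end (`inst/cli/drsdepth`, subcommands `forward`,
`sweep`, `iad`, `iadfmc`, `depth`, `mie`, `synth`) wraps the same
functions for shell pipelines.

## Worked example

Synthesize a measurement for a 300 µm vessel buried 1.35 mm deep in a
2 mm slab, then recover the depth with an independent solver seed:

```r
library(drsdepth)

sc <- generate_scenario(scenario_spec(
  diameter_um = 300, axis_depth_mm = 1.35,
  photons = 1e5, noise = 0.01, seed = 20240901))

est <- extract_depth(sc$measured$reflectance, diameter_um = 300,
                     sc$model, sc$beam,
                     mc_config(photons = 1e5, seed = 555),
                     bracket = c(0.3, 1.8))
est
#> <depth_estimate> d_hat = 1.3635 mm after 8 bisections (mismatch 0.000197)
100 * abs(est$d_hat - 1.35) / 1.35
#> [1] 0.9982639
```

The solver evaluated the band-mean (400–600 nm) diffuse reflectance at
the bracket ends (0.2118 at 0.3 mm, 0.5024 at 1.8 mm — reflectance rises
with depth), verified the measured aggregate lay between them, and
bisected eight times to a 0.006 mm bracket: the estimate lands within 1%
of the true depth even with 1% multiplicative measurement noise.
`est$trace` holds the audited per-iteration depths and reflectances.

The forward model alone:

```r
m <- phantom_model(background = optical_properties(0.05, 2, 0, 1.5),
                   vessel = cylindrical_vessel(300, 0.65))
simulate_transport(m, beam_spec(wavelengths_nm = 550),
                   mc_config(photons = 1e5, seed = 7))
#> <energy_budget> 550 nm, 100000 photons, seed 7
#>   R_spec 0.04000  R_diff 0.26566 (se 1.1e-03)  T 0.09727 (se 7.2e-04)
#>   Abs_bg 0.16834  Abs_vessel 0.42744  E_side 0.00129  sum 1.000000000000
```

Four percent of the beam reflects specularly at the epoxy surface; the
blood-filled channel, though only 300 µm across and sitting under a
0.5 mm spot, intercepts 43% of all the light at this Q-band wavelength;
and the budget closes exactly.

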