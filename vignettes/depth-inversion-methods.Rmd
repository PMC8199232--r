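---
title: "Models and methods: from diffuse reflectance to vessel depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from diffuse reflectance to vessel depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Laser treatment of cutaneous vascular lesions (port wine stains being the
canonical case) needs two geometric facts about the target capillary: its
diameter and its depth below the surface. Diameter is observable by speckle
imaging; depth is not directly observable by any affordable modality at the
30–300 µm calibre relevant here. Diffuse reflectance spectroscopy (DRS)
offers a way in: a blood vessel selectively absorbs in the hemoglobin bands,
and how strongly that absorption imprints on the surface reflectance depends
on how deep the vessel sits. With the medium's optical properties and the
vessel diameter known, the spectrum-to-depth map is single-valued and can be
inverted.

`drsdepth` implements that whole chain for a laboratory tissue phantom: a
slab of epoxy-like matrix (refractive index ≈ 1.5) scattering through
suspended lipid droplets, with a single blood-filled cylindrical channel.
The package covers the forward physics (Monte Carlo photon transport), the
property-recovery stage (adding–doubling and its inverse, refined by forward
Monte Carlo), the anisotropy estimate (Mie theory for the droplet
suspension), and the final depth inversion (bisection on the forward model).

## Forward model

Photon transport uses the standard hop–drop–spin weighted random walk:
exponential path sampling on the local interaction coefficient
µ\_t = µ\_a + µ\_s, weight deposition µ\_a/µ\_t per collision,
Henyey–Greenstein deflection with anisotropy g, unpolarized Fresnel
reflection/refraction at the top and bottom faces (with partial-weight
splitting, which keeps the escape tallies smooth), termination at the
lateral boundary, and Russian roulette (threshold 1e-4, survival 0.1)
for low-weight paths. The vessel wall is, by default, not a refractive
interface — the blood/matrix index step is small and the vessel acts as a
selective absorber — though a Fresnel wall can be switched on.

Every simulation reports a complete energy budget

R\_specular + R\_diffuse + T + Abs\_background + Abs\_vessel + E\_side = 1,

and the package treats this identity as exact: tallies are normalized by
the total terminal weight, so Russian roulette variance (which conserves
energy only in expectation) cannot open the balance. The normalization
factor differs from unity by well under 1e-4 at default settings; the
budget's standard errors come from per-photon contribution moments.

The kernel carries its own xoshiro256++ generator. A given seed produces
bit-identical tallies on any platform and never touches R's RNG stream.
Spectral sweeps derive one seed per wavelength from the master seed, so two
sweeps that differ only in geometry share common random numbers — the
device that makes finite-photon comparisons across depths or diameters
noise-free to first order.

The measured quantity of an integrating-sphere experiment corresponds to
the diffuse tally: reported reflectance spectra are `R_diffuse`, with the
specular term kept separate.

## Adding–doubling and its inverse

The 1D solver discretizes direction cosine on a quadrature that always
contains a node exactly at µ = 1, so collimated normal incidence is a grid
direction (Gauss–Radau; split at the critical cosine into a Gauss–Legendre
panel below and a Radau panel above when the slab index exceeds the
ambient's, which keeps total internal reflection sharp). The
Henyey–Greenstein redistribution matrix comes from the Legendre expansion
truncated where gᵏ < 1e-13. A layer of optical thickness ~1e-8 is
initialized with single-scattering formulas and doubled to the target
thickness; boundary mismatch is added as diagonal Fresnel operators at the
internal angles. Sixteen streams reproduce a 32-stream solution to well
under 1e-4 in R and T for the property ranges used here, and an optional
`check_quadrature` pass verifies that at run time.

The inverse (IAD) searches in (log optical thickness, log(1 − albedo))
coordinates: a coarse 15 × 11 grid scan seeds a damped Newton iteration
with a finite-difference Jacobian, with ties between equivalent minima
broken toward smaller optical thickness. Following the usual convention, g
is held at zero during inversion unless the caller supplies a Mie estimate;
absorption and scattering are then effective coefficients at that g. A pair
that no (µ\_a, µ\_s) can reproduce within tolerance (default 1e-4 absolute)
raises an infeasible-measurement error rather than returning the nearest
fit, since that situation usually signals a wrong g or n.

## IAD–FMC property extraction

IAD alone is a 1D approximation; the phantom measurement is a 3D experiment
with a finite spot. The extractor therefore uses IAD only as a seed and
iterates: the residual between calculated and measured (R, T) is evaluated
with the full Monte Carlo model under a fixed per-wavelength seed (common
random numbers make the residual a deterministic function of the
properties), while the Newton step's Jacobian comes from the cheap
adding–doubling surrogate. Step halving accepts only residual reductions,
so the residual sequence is monotone non-increasing by construction. The
relative residual uses a 1e-3 floor in the denominator to stay finite at
near-zero signals. Defaults: 1% tolerance, 20 iterations. With two
observables and two unknowns per wavelength the refinement typically
converges in 0–3 steps, most of which are spent absorbing the ~0.5%
statistical offset between the measurement's seed and the solver's.

## Mie anisotropy

The droplet suspension's g comes from the Mie series (logarithmic
derivative by downward recurrence, truncation at the Wiscombe order
x + 4x^{1/3} + 2), with µ\_s = C σ\_g Q\_sca under the dilute
independent-scatterer assumption; the mass-fraction-to-number-density
conversion takes a configurable particle density (default 0.93 g/cm³,
soybean-oil-like, with a 1.1 g/cm³ bulk). For 0.5 µm droplets at
lipid-in-epoxy index contrast the computed g is large in the visible and
falls toward the infrared; reports of near-zero anisotropy for such
granules are not reproducible from any conventional index pair, so the
package asserts only the decreasing trend and lets the caller choose the
g actually fed to the solvers (the extraction and depth stages default to
g = 0, consistent with the IAD convention and with the fact that the
inverted µ\_s is then the matching effective coefficient).

## Depth inversion

With background and blood properties known and the diameter D given, the
band-mean diffuse reflectance over 400–600 nm — the hemoglobin absorption
hump, where the signal is most depth-sensitive — is strictly monotone in
the axis depth d: a deeper vessel intercepts fewer photons, so R rises
with d and falls with D. The solver evaluates the forward model at the
bracket ends, checks that the measured aggregate lies between them,
detects the monotone direction empirically rather than assuming it, and
bisects until the bracket is narrower than 0.01 mm (so the iteration count
is bounded by log₂(bracket/0.01)). All solver evaluations share one master
seed; a midpoint that falls outside the endpoint range by more than three
Monte Carlo standard errors aborts with a non-monotonicity error. A
measured aggregate that lies outside the calculated endpoint range by no
more than three combined standard errors is clamped to the range — near
the containment limits the reflectance–depth curve flattens into its
no-vessel asymptote, and an independent-seed measurement can straddle the
endpoint value by pure Monte Carlo noise; beyond that grace band the
solver refuses with a bracket error rather than extrapolate. The
default bracket is the containment-feasible depth range inset by 0.05 mm;
the default spot is 0.5 mm — large enough for signal, small enough that the
vessel's spectral signature is not diluted (without a vessel the spectra
are spot-independent; with one, a ≥ 2.5 mm spot visibly washes out the
hemoglobin dip, and the acceptance suite checks exactly this contrast
dilution).

Band-mean matching is the default aggregate; per-wavelength matching is a
straightforward variant but is not needed for unique inversion once D is
known, and the band mean is the more noise-robust statistic.

## Synthetic phantom

No measured phantom spectra or blood coefficients are published at usable
precision, so the generator manufactures the study conditions itself and
is explicit about being synthetic:

* geometry: 2.0 mm slab, 15 mm lateral extent. (The source experiment's
  printed thickness/diameter pair is internally inconsistent with its own
  depth range; the flip-pair arithmetic — vessels at 0.65/1.35 mm and
  0.2/1.8 mm being the same phantom seen from either face — fixes the slab
  at 2.0 mm, and depths are measured from the illuminated surface to the
  vessel axis.)
* background: flat µ\_a = 0.01 mm⁻¹; µ\_s(λ) = 2 mm⁻¹ · (λ/500)⁻¹, g = 0,
  n = 1.50 (epoxy-like; ambient n = 1.00; indices configurable since the
  originals were measured but not printed).
* blood: three Gaussians at 420/542/577 nm on a decaying baseline, peak
  ≈ 120 mm⁻¹ — a whole-blood-magnitude, hemoglobin-shaped template, not
  literature data — with µ\_s = 1 mm⁻¹, n = 1.37.
* measurement: forward MC sweep under a dedicated measurement seed,
  optional multiplicative Gaussian noise (default 1%) clipped to [0, 1];
  the truth (D, d, property curves, seed) is embedded in `truth.json`.

A remark on the experimental flip trick (measuring the phantom from its
other face to reach depth L − d): in this package flipping is a model
relabelling (`flip_phantom()`), so depths d and L − d are literally the
same phantom. One symmetry that might be expected — equal total
transmittance from the two faces — does **not** hold for a collimated
beam: light entering on the vessel side crosses the covering layer
ballistically, light arriving from the far side crosses it diffusely at
oblique angles, and the path lengths (hence absorption) differ. The
symmetries the suite does assert are the ones the experiment relies on:
the flipped vessel absorbs less and reflects more (fluence decays with
depth), and depth estimates recovered independently for a flip pair sum
to the slab thickness.

What passing tests on these fixtures demonstrate is the correctness and
conditioning of the inverse machinery — that the depth estimate converges
to the truth of a known forward model under realistic noise, photon budgets
and spectral sampling. What they cannot demonstrate is transferability to
in vivo skin: melanin, a layered epidermis, vessel plexuses and
physiological variation are all outside the model, and real use would also
inherit whatever error the property-extraction stage makes on real
measurements.

## Numerical choices and problem sizes

* Monte Carlo: 10⁵ photons per wavelength for quantitative runs; unit
  tests use 3–40 × 10³ where only ordering or closure is asserted. The
  budget closes to < 1e-9 by construction; MC-vs-adding-doubling agreement
  is asserted at 3σ.
* Degenerate inputs: µ\_t = 0 regions propagate ballistically; a purely
  absorbing collision (µ\_s = 0) deposits the remaining weight; boundary
  reflectances are clamped at 1 − 1e-9 so the zero-scattering
  total-internal-reflection geometric series stays summable.
* IAD: convergence when both residuals < 1e-6 (acceptance at 1e-4);
  parameters clamped to optical thickness ∈ [1e-8, 512].
* Depth: tolerance 0.01 mm, i.e. 0.5–5% of the depths of interest, chosen
  to sit below the 5% accuracy target at every benchmark depth.
* The acceptance script runs the full four-depth 100 µm suite at 10⁵
  photons and 10 wavelengths; the test suite runs the two central depths
  of that suite, the study's own scaled-down variant.

## Known limitations

* Single straight vessel parallel to the surface; no multi-layer skin, no
  melanin, no polarization, no fluorescence.
* The adding–doubling boundary treatment is flux-consistent but drops the
  n² radiance rescaling, which is irrelevant for hemispherical totals but
  means angular radiances at the boundary are not individually physical.
* Simultaneous (µ\_a, µ\_s, g) inversion is deliberately unsupported —
  with an R/T pair it is ill-posed — as is joint (d, D) inversion, which
  is resolved in practice by taking D from imaging.
* The depth solver assumes the background/blood properties fed to it; in a
  real workflow those come from the extraction stage and their errors
  propagate into d.
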