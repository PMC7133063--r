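---
title: "Simulating isotropic SAXS detector images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating isotropic SAXS detector images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(saxsim)
```

## The model

A dilute solution of randomly oriented macromolecules scatters X-rays
isotropically: the 2D pattern on an area detector depends on the pixel
position only through its distance `r` to the beam centre. saxsim simulates
such patterns photon by photon. The chain of ideas is short:

1. **Geometry.** A pixel at radius `r` on a flat detector normal to the beam,
   at distance `D` from the sample, sees scattering angle `2θ = atan(r/D)`,
   hence momentum transfer `s = (4π/λ) sin(atan(r/D)/2)` (reported in
   nm⁻¹). The virtual beamline is ideal: no ray-tracing, no polarization or
   solid-angle corrections, no detector tilt.

2. **Event distribution.** Because the pattern is isotropic, the azimuth of
   a photon event is uniform on [−π, π). The radius is distributed with
   density proportional to `I_eff(s(r)) · r`: the effective intensity at
   that angle times the circle-circumference (area) Jacobian. `I_eff(s) =
   c·I_sample(s) + I_bg(s)`, where `I_sample` is a calculated curve on
   absolute scale per unit concentration and `I_bg` a background, by default
   the double-exponential `a1·exp(−b1 s) + a2·exp(−b2 s)`.

3. **Inverse-transform sampling.** The density is tabulated on a dense
   radius grid, integrated (trapezoid) into a piecewise-linear CDF, and each
   event draws `u ~ U[0,1]`, `r = Q(u)` with `Q` the quantile function, plus
   an independent uniform azimuth.

4. **Counting statistics.** The number of events of a frame is Poisson with
   mean `flux · exposure · κ`, where `κ` is the ratio of the
   annulus-weighted integrated intensity of `I_eff` to that of the pure
   background. Thus `flux` has a concrete meaning — the expected event rate
   of the pure background — `κ = 1` at concentration 0, and sample
   scattering adds events linearly in concentration. Per-pixel counts are
   then automatically Poisson.

5. **Quantization.** Each polar event maps to Cartesian coordinates
   `beam + (r/pixel)·(cos φ, sin φ)` and increments the single containing
   pixel (a photon-counting detector has a one-pixel point-spread function;
   the containing pixel of a continuous coordinate is its nearest integer
   index, i.e. `floor(x + 0.5)`). Events falling off the grid or into an
   insensitive module gap are discarded but tallied, so
   `sum(counts) + discarded = generated` always holds.

Radial averaging inverts step 5: every live pixel joins the bin given by its
rounded centre distance to the beam (bin `i` is the annulus `[i−0.5, i+0.5)`
in pixel units), bin intensities are mean counts per pixel per second, and
the Poisson error of the summed counts propagates to
`σ_i = sqrt(Σc) / (npix · T)`. Background subtraction operates on rates, so a
10 s background frame and a 1 s sample frame combine correctly, and division
by concentration returns to the per-unit-concentration scale of the input.

## Absolute scale and the rate bridge

The simulated counts relate to the absolute-intensity input through a single
factor derived from the sampling construction:

```
rate(s) = scale · I_eff(s),   scale = flux · pixel² / (2π · W_bg),
W_bg    = ∫ I_bg(s(r)) · r dr
```

Every simulated image stores `scale`, and it survives into reduced curves and
`.dat` headers. Validation against the input model therefore needs no
fitting: `standardized_residuals()` compares the subtracted curve with
`scale · I_input(s)` directly.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `wavelength` | 1.24e-10 | m | 10 keV; reproduces the package's reference angular calibration (0.0145–3.8497 nm⁻¹ at 6 m on a Pilatus 6M, etc.) to 4 decimals under the bin convention below |
| `distance` | — | m | beamline choice; 1.5–6 m covers the usual range |
| `beam` | fast axis centred; slow 173 px (Pilatus 6M) | px | continuous coordinates, may be off-detector; the 6M default yields outermost bin 2656 |
| `flux` | 1e7 | events/s | realistic photon-counting rate; gives ≥10⁷ events in a 1 s frame |
| `exposure` | 1 | s | per frame; backgrounds are typically exposed longer (10 s) |
| `concentration` | 0 | mg/ml | 0 simulates pure background |
| background `a1,b1,a2,b2` | 0.9, 0.05, 0.1, 2.0 | —, nm | nearly flat with a mild low-angle rise; package choice, always overridable and recorded in output headers |
| `beamstop_diameter` | 3e-3 | m | 3 mm disc at the beam position |
| `n_nodes` | 8192 | — | radius-grid density of the event distribution |

Detector models (Pilatus 1M/2M/6M, Eiger 4M/9M/16M) live in a CSV catalogue
(`inst/extdata/detectors.csv`) holding pixel counts, pixel size and the
module/gap tiling; new detectors need no code change.

## Conventions and numerical choices

* Pixel `(i, j)` (0-based) has its centre at continuous coordinate `(i, j)`
  and covers `[i−0.5, i+0.5) × [j−0.5, j+0.5)`.
* Radial bin `i` is assigned the momentum transfer `s(i · pixel)`; an axis
  file tabulates this mapping. The outermost bin is the rounded largest
  pixel-centre distance to the beam.
* A bin is dropped from reduced curves when its annulus intersects the
  beamstop disc (a 3 mm stop on 172 µm pixels has radius 8.7209 px, so bins
  0–9 go and curves start at bin 10), or when it contains no live pixel.
  With the annulus rule the Pilatus 6M reference geometry yields exactly
  2647 reported bins (10…2656).
* The radial distribution is tabulated on 8192 uniform nodes from 0 to the
  farthest pixel corner — the infinite detector plane is truncated there
  because farther events cannot land on the detector. Node masses are exact
  trapezoid weights, so a flat intensity reproduces the closed forms
  `cdf(r) = (r/R)²` and `Q(u) = R√u` to grid accuracy, and the pdf sums to 1
  to well below 1e-9.
* The quantile is the inverse of the piecewise-linear CDF: smallest node
  with `cdf ≥ u`, linearly interpolated. The compiled sampler and the pure-R
  engine implement the identical arithmetic and consume the identical RNG
  stream (two uniforms per event, radius before azimuth), so both engines
  produce bit-identical images under a seed; the R engine doubles as a
  readable oracle for the compiled one.
* Empty bins would have zero Poisson error; `σ` uses `sqrt(max(Σc, 1))`
  (standard counting-statistics floor) so χ² comparisons stay defined. The
  floor is noted in `.dat` headers.
* Sample curves are interpolated linearly, held constant below their first
  grid point (hidden by the beamstop anyway) and set to zero above their
  last (no invented high-angle intensity). An input `σ` column is carried
  through but ignored: simulation noise is purely Poisson.

## Statistical validation

Two case-0 tests certify that a simulated, reduced, subtracted curve is the
input model plus noise:

* **Reduced χ²** — `Σ((obs−model)/σ)²/(n−1)` with the upper-tail probability
  of the χ² distribution with `n−1` degrees of freedom. Values near 1 with
  non-extreme p mean the differences are explained by counting noise.
* **Anderson–Darling (case 0)** — the standardized residuals are tested
  against the fully specified N(0, 1); no parameters are estimated, because
  model and errors are known. `A²` uses log-CDF asymptotics for extreme
  residuals; p-values come from the Marsaglia & Marsaglia (2004) series
  approximation of the limiting distribution plus their finite-n
  correction (the correction moves p in the 4th decimal at the sample sizes
  used here).

The significance convention is α = 0.01 throughout, and p-values are upper
tails. `pairwise_compare()` applies the reduced χ² test with combined
variances to every unordered pair of frames; for `m` frames that is
`m(m−1)/2` results. Note the pairs share frames, so while each statistic
follows χ²_{n−1}/(n−1) marginally, the 1225 statistics of a 50-frame
ensemble are correlated — goodness-of-fit tests that assume independence
are approximate on such ensembles.

## What the synthetic input emulates — and what it does not

The built-in `sphere_curve()` (homogeneous sphere, default radius 3 nm,
`I(0) = I0` on absolute scale) stands in for a calculated macromolecular
curve so that no external curve-calculation tool is needed. It exercises the
identical code path as any real input: a monotone low-angle Guinier region
(`Rg² = 3R²/5`), oscillations, and several orders of magnitude of dynamic
range. It differs from real macromolecular curves in having mathematically
exact zeros at its form-factor minima (real particles are polydisperse and
hydrated, which fills minima in), and the simulator deliberately omits
structure factors, inter-particle interference, instrumental smearing,
beam-profile and wavelength spread, and detector artefacts (dead time,
charge sharing). Passing tests therefore certify the counting statistics,
geometry and reduction chain — not those sample- or instrument-level
effects.

Comparing binned counts against the *pointwise* input curve is itself an
approximation: the counts in a bin average the intensity over the bin's
pixels, which differs from the intensity at the bin centre wherever the
curve is curved, and the convention of estimating `σ` from the observed
rather than the expected counts adds a further `O(1/√counts)` distortion to
each standardized residual. Both effects are part of the standard reduction
chain, not of the simulator. In background-subtracted comparisons the
background's share cancels, so the reduced χ² sits at 1 within noise; the
tail-sensitive Anderson–Darling test can feel the residue at the full 2647
bins, which is why its p-values skew somewhat low rather than uniform —
occasionally dipping below a few percent — while remaining compatible with
the α = 0.01 convention in the large majority of datasets. The effect is
independent of the radius-grid density and grows with per-bin counts, as
expected for a fixed small relative misfit under shrinking noise.

## Problem sizes used by the test suite

The statistical-fidelity checks run the full Pilatus 6M reference setup
(background 10 s, sample 1 s at 0.5 mg/ml, flux 10⁷ events/s, 2647 bins)
over 20 independent seeds; the pairwise-comparison check uses 50 background
frames on a 128×128 virtual detector (1225 comparisons, ~90 bins); size
calibration of the tests uses 1200 replicates at n = 600. These sizes were
chosen to give each check clear statistical resolution while keeping the
whole suite comfortably interactive.

## Known limitations

* Non-photon-counting detectors (point-spread functions wider than one
  pixel) are not modelled.
* No structure factor or concentration effects beyond linear scaling; no
  smearing. High-concentration or interacting systems are out of scope.
* CBF output is not written; TIFF and EDF cover the downstream tools.
* Bit-identical reproduction across platforms is a goal, not a guarantee:
  results are deterministic for a given build via R's RNG, but libm
  differences can in principle flip a pixel at quantization boundaries.
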