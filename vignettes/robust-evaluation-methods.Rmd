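---
title: "Robust evaluation of HDR prostate brachytherapy plans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust evaluation of HDR prostate brachytherapy plans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(brachyrobust)
```

## The problem

A high-dose-rate (HDR) prostate brachytherapy plan is evaluated clinically
on its *nominal* dose distribution: the dose computed from the approved
dwell positions, dwell times and contours. Between imaging and the end of
irradiation, however, needles move, contours carry delineation uncertainty,
the afterloader positions and times the source imperfectly, and the dose
engine itself has a calibration uncertainty. The delivered distribution is
therefore one draw from a family of possible distributions around the
nominal plan. `brachyrobust` quantifies how robust a plan's dose-volume
histogram (DVH) metrics are to the *combined* effect of these uncertainties,
using two complementary strategies:

* **probabilistic scenarios** — each uncertainty parameter is drawn from a
  zero-mean normal distribution with a literature-derived standard
  deviation, truncated at the 90% confidence interval (±1.65 SD), giving
  the likely spread of each DVH metric; and
* **worst-case scenarios** — an enumerated set of combinations of the
  ±1.65 SD limits, giving the extreme envelope, however improbable.

## The six uncertainty operators

A scenario is produced by applying six operators to the nominal case, in a
fixed order (1–6). All geometry is in the DICOM patient coordinate system
(x left, y posterior, z superior; mm).

1. **Dwells move along the needle.** Each needle is represented by a dense
   interpolated curve (a clamped interpolating cubic spline through the tip
   control point and the dwell positions, chord-length parameterised,
   6000 points) with a cumulative arc-length map. A dwell is relocated to
   the path point whose arc length is nearest to its original arc length
   minus the shift `x`; positive `x` is superior (towards the tip). Shifts
   beyond a path end clamp at the end point with a warning. Interpolating
   (rather than approximating) the dwells means a zero shift reproduces the
   nominal dwells to the path sampling resolution (< 0.01 mm).
2. **Prostate boundary expansion/contraction.** Every contour vertex moves
   by exactly `x` mm along the ray from the whole-gland geometric centre
   (the mean of all vertices). Because this de-planarises slices, the
   structure is resampled: vertices sharing a within-slice index form
   superior–inferior boundary curves; each curve is refit with an
   interpolating cubic spline against z and re-evaluated on the uniform
   grid of original slice width centred on the original mean z. Evaluating
   the spline at the target z directly (rather than densely sampling and
   re-selecting nearest points) keeps the identity case exact and the
   resampled slices exactly planar; it is the continuous limit of the
   dense-resample-and-select procedure. This requires corresponding vertex
   counts across slices, which holds for template-generated or resampled
   contours.
3. **Urethra/rectum slice-wise scaling.** Per transverse slice, every
   vertex moves by exactly `x` mm along the ray from that slice's centroid;
   z is unchanged and no resampling is needed because these tubes extend
   beyond their contoured superior–inferior range. The urethra budget is
   quoted as a diameter in the source literature; by default the value is
   applied as a radial change, with `urethra_diameter_mode = TRUE`
   available to halve it.
4. **Transverse needle displacement.** All dwells of needle *i* translate
   by `[X_i, Y_i, 0]`. Probabilistic draws are independent per needle and
   axis; worst-case modes move all needles coherently (radially out from or
   in towards the prostate transverse centre line, or posteriorly towards
   the rectum). Source orientation is deliberately not updated.
5. **Dwell-time scale and offset.** `t <- t × scale + offset`, with
   `scale = 1 + pct/100`; negative results are clipped to zero (physical
   non-negativity) with a logged count.
6. **Rigid prostate motion.** Prostate, urethra and all dwells translate by
   `[X, Y, Z]`; the rectum stays fixed, so the operator models
   prostate–rectum relative motion.

Operators 1, 4 and 6 act on overlapping geometry, so the order matters and
is frozen at 1→6 for reproducibility.

## The uncertainty budget

Default standard deviations are quadrature combinations of published
uncertainty components for TRUS-based single-fraction planning:

| parameter | components | total SD |
|---|---|---|
| dwell shift along needle | tip reconstruction 1.1, rigid SI 0.34, source positioning 1.0 mm | 1.5 mm |
| prostate contour | — | 2.0 mm |
| urethra contour | — | 0.5 mm |
| rectum contour | — | 1.0 mm |
| transverse needle movement | reconstruction 1.2, rigid 0.86 mm | 1.5 mm (per axis) |
| dwell-time percentage | medium 1, planning 3, activity 3 % | 4.4 % |
| dwell-time offset | — | 0.06 s |
| rigid motion | — | AP 0.5, LR 0.1, SI 0 mm |

Every value is user-configurable through `uncertainty_budget()`. Note that
the published worst-case magnitudes for the demonstration patient imply a
smaller urethra SD (0.41/1.65 ≈ 0.25 mm) than the tabulated program input
(0.5 mm); the package follows the tabulated budget and leaves the
discrepancy to the user's configuration rather than resolving it.

Probabilistic sampling truncates hard at ±1.65 SD by rejection; the
worst-case set is the full factorial of the five scalar parameters at
{−1.65 SD, 0, +1.65 SD} — the dwell-time percentage and offset vary
jointly with the same sign, since they stem from a common delivery
mechanism and enumerating them independently would only multiply the
scenario count without changing the extrema materially — crossed with four
transverse direction modes (none/out/in/posterior) and the two signs of
the rigid-motion vector: 3^5 × 4 × 2 = 1944 scenarios under the default
budget. The composition rule is a package choice (the enumeration is
configurable via `modes` and the budget); the count is reported, never
asserted.

## Dose model

Dose is computed with the TG-43 formalism: dose rate
`S_K Λ (G_L(r,θ)/G_L(1 cm, 90°)) g(r) F(r,θ)`, dose to water in water, no
shielding, scatter or transit-dose corrections. The line-source geometry
function uses the subtended-angle form `β/(L r sinθ)` with the on-axis
limit `1/(r² − L²/4)`; it diverges on the source segment itself, so within
the physically invalid near-axis core (radii comparable to L/2) it is
regularised by capping at the value obtained with sinθ floored at 0.1.
Radial dose is interpolated log-linearly in r (held at the table minimum
below it, with the affected pair count reported; extrapolated log-linearly
above the maximum); anisotropy is interpolated log-linearly in r and
linearly in θ, clamped at the grid edges.

For throughput the tables are combined at source construction into a fine
uniform product grid `T(r, cosθ) = g G_ratio F r²` (radial step 0.02 cm,
cosθ step 0.04, both grids placed so the reference point r = 1 cm, θ = 90°
is a knot), making a line-mode dose rate a single bilinear lookup
`k T / r²`. The pure-R single-pair path (`dose_rate_at()`) and the C++ bulk
kernel evaluate the same grid with identical arithmetic, so they agree to
floating-point precision; the product-grid approximation agrees with the
direct composition of the analytic geometry factor and table
interpolations to about 0.3% beyond 4 mm from a source, with larger local
deviations only inside the regularised near-axis core.

The bundled source model is a *generic* Ir-192 stepping source: smooth
synthetic g(r) and F(r,θ) tables of realistic shape, dose-rate constant
1.109 cGy h⁻¹ U⁻¹, active length 3.5 mm, air-kerma strength 40700 U. It is
not a consensus dataset for any commercial source; all framework
properties (identities, linearity, envelopes, statistics) are
source-model-agnostic, and clinical use requires substituting measured
tables via `source_model()`.

## DVH machinery

Dose points are a deterministic regular grid (default 1 mm) inside the
stacked-polygon volume; each point carries a `spacing³` volume weight, so
the summed weight estimates the structure volume. A grid, rather than
Monte Carlo sampling, makes every scenario exactly reproducible and lets
volume estimates be checked against analytic phantoms. `D_x` (minimum dose
to the hottest x% or cc) is computed by descending-dose accumulation over
weighted samples without interpolation — exact and directly checkable
against a sort-based oracle; `V_y` is the weighted fraction at or above
the threshold. V100/V150/V200 and V75 are defined relative to the 16 Gy
prescription. DVH curves use 0.01 Gy bins by default. The eight clinical
constraints (D90 ≥ 16 Gy, V100 ≥ 90%, V150 ≤ 40%, V200 ≤ 10%,
urethra D10 ≤ 18.4 Gy and D0.01cc ≤ 18.4 Gy, rectum V75 ≤ 1.0 cc and
D0.1cc ≤ 13 Gy) treat boundary equality as a pass.

## Statistics

Scenario ensembles are summarised per metric by mean, SD, quartiles, an
SEM-based 95% CI (normal quantile z = 1.96, appropriate at ensemble sizes
of hundreds to thousands and matching published interval arithmetic),
Fisher–Pearson skewness (unadjusted g1 by default; the adjusted G1 is
available — the published analysis does not state which variant it used),
and constraint pass rates (each constraint, all constraints, and all
excluding V200, which clinics sometimes waive). For skewed metrics a
bootstrap percentile CI of the median is provided: resample medians, take
order statistics at the (B+1)α Efron positions; the whole-curve
sensitivity of a structure is the SD-per-dose area — the across-scenario
SD of relative volume per dose bin, summed times the bin width (Gy).

## The synthetic phantom

Because no clinical plan ships with the package, `phantom_spec()` /
`generate_phantom()` build a deterministic case emulating a typical
ultrasound-planned patient: a 38.1 cc ellipsoidal prostate (semi-axes
22.5 × 19 × 21.3 mm, 2.5 mm slices, 48 vertices per slice), a 3 mm-radius
central urethra contoured 9 mm further inferior and 6 mm further superior
than the prostate, a 10 mm-radius rectum tube 2 mm behind the posterior
surface contoured 15 mm further inferior and 6 mm further superior, and 16
needles — twelve on a peripheral ellipse ring about 4.5 mm inside the
capsule plus four interior — with 5 mm dwell spacing inside the gland.
A uniform-time plan on a rectangular needle grid, once normalised to
D90 = prescription, produces grossly unclinical hotspots (V150 ≈ 60%,
urethra D10 ≈ 24 Gy); the peripheral ring plus a deterministic radial
weighting of the initial dwell times (t ∝ (r/15 mm)⁴) stands in for the
clinical optimiser while keeping the generator fully deterministic.
Normalisation itself exploits exact dose linearity in a global time scale:
the single factor prescription/D90 pins the nominal D90 at the
prescription in one step (a bisection loop would converge to the same
factor; linearity makes it closed-form).

The phantom is deliberately idealised: convex analytic organ shapes,
straight parallel needles, a surrogate (not inverse-optimised) dwell-time
pattern that remains hotter than a clinical plan (V150 ≈ 42%,
urethra D10 ≈ 18.9 Gy at nominal), and no anatomy-dependent restriction of
movements. Tests passing on the phantom therefore demonstrate the
correctness of the *machinery* — operators, dose engine, DVH metrics,
sampling, enumeration, statistics — not the clinical robustness values of
any real plan; the phantom's own robustness numbers (e.g. a D90 SD of
roughly 13% of the prescription) are larger than those published for a
clinically optimised plan, as expected for its steeper peripheral dose
gradients.

## Numerical choices and degenerate inputs

* Nearest-point and nearest-arc-length queries break ties towards the
  lowest index (determinism).
* Slice-spacing uniformity is enforced to 0.01 mm (float round-trip
  noise); fixture round-trips preserve coordinates to 1e-6 mm.
* Contractions that would push a vertex through its centre are errors, as
  are single-slice or sub-three-vertex structures where an operator needs
  more.
* Scenario evaluation is pure: the nominal case is never mutated; each
  evaluation draws all scenario parameters up-front from one stream seeded
  by the run seed, making the run reproducible bit-for-bit and the
  aggregation order-independent.
* Evaluation problem sizes used in the shipped checks: 1 mm dose grid on
  the phantom (about 59k points over the three structures), 200
  probabilistic scenarios against the full 1944-scenario worst-case set
  for the envelope property, 10,000 draws for sampling recovery, and 500
  replications for bootstrap coverage — sizes at which the checked
  statistics are stable at their stated tolerances.

## Known limitations

* TG-43 water-phantom dose only; no heterogeneity, inter-needle
  attenuation, or transit dose.
* The DICOM-RT adapter is limited to an informative error in this build;
  the plain-text fixture dialect is the supported interchange format, and
  the schema is documented in the README.
* Oedema, anatomy-limited movement beyond the 90% CI truncation, and
  robust *optimisation* are out of scope.
* Worst-case extremity is only explored at the ±1.65 SD corners (plus
  zero); interior combinations could in principle be more extreme for
  non-monotone metrics, though none were observed on the phantom.
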