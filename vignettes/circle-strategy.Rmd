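---
title: "The circle strategy: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The circle strategy: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`circlemap`, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real electroanatomic maps.

## 1. Data model and file contract

A map is a triangulated chamber surface (`map_surface`) with per-vertex
scalar fields: local activation time `lat_ms` (ms), unipolar amplitude
`amplitude_mv` (mV), a `cutout` flag for transitions to vessels and
neighbouring chambers, and a `wall` label (anterior, posterior, lateral,
septal, superior for the atrial roof, or unassigned). Units are fixed by
contract: coordinates in mm, time in ms, amplitude in mV — with the
convenient consequence that mm/ms is numerically m/s. Vertex indices are
0-based both in memory and on disk. Missing scalars are written as `nan`
and are legal only on cutout vertices; `validate_map()` reports any
violation without raising.

Files are ASCII legacy VTK polydata with the arrays named exactly
`lat_ms`, `amplitude_mv`, `cutout`, `wall_id` (integer codes 0–5), plus a
YAML sidecar `<file>.meta.yaml` carrying animal, chamber, rhythm, pacing
site/access and mean heart rate. Metadata is deliberately kept out of the
mesh file so any standard mesh viewer still opens the geometry. The writer
formats numbers with a fixed `%.9g`, so writing the same map twice is
byte-identical — which is what makes the pipeline's manifest hashes
meaningful.

## 2. Circle covering

Centers are sampled by greedy farthest-point sampling (FPS) over the
non-cutout vertices: repeatedly accept the vertex farthest from all
accepted centers until no vertex is at least `spacing_mm` from every
center. The seed only breaks the initial-vertex tie, so center sets are
deterministic. Members of a circle are the non-cutout vertices within a
**Euclidean** ball of radius 5 mm, boundary inclusive (a fixed, arbitrary
convention, tested explicitly). Euclidean membership matches the spherical
filters of standard mesh tooling; on strongly folded surfaces it can merge
opposing walls — a documented limitation, as geodesic discs are not
implemented. Covered area sums triangles whose centroid lies in the ball
(triangles touching a cutout vertex excluded); the centroid rule converges
to the exact disc area with mesh density and is within 1% of
$\pi r^2 = 78.54\,\mathrm{mm^2}$ on a 0.5-mm flat grid. Circles with fewer
than 10 members are dropped — a guard against meaningless activation-time
differences on near-empty circles.

**Default spacing = 4.4 mm.** The study regime this package emulates
reports ~134 circles per chamber of ~77.8 mm² each, with ~104 points per
circle and ~5600 points per map. Those numbers jointly imply heavily
overlapping circles: 134 × 77.8 mm² of circle area on a ~4000 mm² open
surface is a 2.6-fold covering, i.e. one center per ~30 mm². FPS produces
about one center per 1.66 s² at spacing s, so s ≈ 4.4 mm reproduces
132 ± 6 circles per chamber and, as a side effect, places every non-cutout
vertex within 5 mm of a center (the ≥ 99% coverage property holds with
margin). Larger spacings (6–7 mm) yield only 50–70 circles and leave
vertices uncovered, so they are inconsistent with the reported regime;
spacing remains a config knob for other designs.

## 3. Local metrics

Per circle, CV is the theoretical diameter (10 mm) divided by the time
difference between first and last activation among the member points —
deliberately the *theoretical* diameter even though the covered area of a
curved patch is slightly smaller. VA is the arithmetic mean amplitude.
Exclusion rules, applied in order: fewer than 10 finite LATs
(`too_few_points`), coincident first/last activation (`zero_dt` — excluded
rather than assigned infinite CV; the outlier rule would drop them
anyway), and CV strictly above 6 m/s (`outlier_cv`). "Exceeding 6 m/s" is
read as a strict inequality: 6.0 m/s is kept, 6 + ε is dropped. Excluded
rows stay in the metrics table with their reason for audit and are removed
before modelling.

Estimator properties worth knowing:

- For a planar wavefront crossing a flat circle the estimate is exact
  (Δt = diameter/speed); the test suite verifies float-level exactness on
  constructed LATs and on grid meshes whose discretisation spans the full
  diameter.
- Finite sampling biases the estimate upward: with ~1.3 points/mm² the
  sampled extent of a 10-mm disc falls ~0.6 mm short of the diameter,
  giving ≈ +7% CV at study resolution; the bias shrinks as density grows
  (one-sided convergence is asserted in the tests).
- For focal (radial) waves the first-to-last difference is taken over a
  chord ≤ diameter, so the estimate never falls below the true speed on
  flat fixtures (asserted).
- Under multiplicative conduction heterogeneity, shortest-path propagation
  selects fast corridors, adding a further upward shift. Together these
  effects make absolute circle CVs run ~10% above the generating point
  speeds at study resolution. The shift is common to all maps and groups,
  so it cancels in rate-law exponents and paced/sinus ratios — the
  quantities the analysis reports — but absolute chamber intercepts should
  be read with this in mind (on real maps the same caveat applies to the
  circle estimator itself).

## 4. The mixed-effects layer

Both responses are modelled as
`response ~ heart_rate_bpm + group + (1 | animal_id)` fitted by REML, with
`group` the chamber × rhythm/pacing-site interaction (or
chamber × wall × site for the regional analysis) and *no* rate-by-group
interaction — the rate effect is assumed common to all chambers. CV is
log-transformed with the natural log; the base only rescales the
coefficient, and the per-bpm multiplier `exp(b)` is base-free. Marginal
means are population-level predictions (random intercept at its mean, 0)
at a reference heart rate of 90 or 145 bpm; requesting a rate more than
20% outside the observed range warns. Degrees of freedom use the
Satterthwaite approximation — a documented knob, chosen to match the
default of the mixed-model testing toolchain this layer wraps.

Multiplicity: paced-vs-sinus contrasts within one chamber (or one wall)
form the family. `adjustment = "sidak"` adjusts only the targeted
paced-vs-NSR comparisons; `"tukey"` draws p-values from the all-pairwise
Tukey HSD family and returns the vs-NSR rows. CV contrasts are
back-transformed to ratios with delta-method SEs.

With only four animals the random-intercept variance frequently estimates
at the boundary (zero), especially in reduced test studies; such fits are
accepted with a warning rather than rejected, since the fixed-effect
estimates remain valid. Groups with fewer than two observations, designs
with fewer than two animals, and rank-deficient groupings (e.g. heart rate
perfectly confounded with group) are rejected with errors naming the
problem.

## 5. Paired-map differences

Circles of a paced map are matched to the sinus map of the same chamber
and animal by mutual nearest centers within 2.5 mm (half the radius);
since the generator reuses one mesh per animal-chamber, centers coincide
and matching is exact by construction — with independently reconstructed
real maps the tolerance does the work, and unmatchable map pairs are
simply reported as such. Pairs where either member was excluded are
dropped. Four statistics follow, implemented exactly as defined: the mean
of absolute differences; its IQR; the absolute difference ratio
(mean |Δ| over the mean intrinsic value — an algebraic identity that the
tests assert on every input); and the IQR of relative change, where each
difference is divided by *its own* intrinsic value, while the per-circle
relative-change distribution divides by the *map mean* intrinsic value.
The distinction matters and is locked in by oracle tests. IQRs use the
type-7 (linear interpolation) quantile convention; with ~130 circles the
convention shifts IQRs by under 2%, and it is overridable. Intrinsic
values of exactly zero make the relative-change IQR undefined and raise an
error listing the offending circles.

## 6. The synthetic generator

The generator exists so that every stage — file I/O, covering, metrics,
models, paired differences — is testable end-to-end with known truth. Its
defaults *are* the study conditions it emulates:

- **Protocol**: 44 maps over RA/LA/RV/LV under sinus rhythm and pacing
  from RA/LA/RV/LV at 86–171 bpm, four animals assigned round-robin within
  each chamber × site cell (the emulated study does not publish a map-to-
  animal assignment).
- **Geometry**: ellipsoid chambers with ~4200–4500 mm² surface (semi-axes
  17–24 mm), 1.3 points/mm² (≈ 5600 vertices per map, matching the
  reported 5593 ± 214), 8% contiguous cutouts, angular-sector walls with a
  superior cap on the atria. Meshes are latitude-ring triangulations with
  parameter-space jitter; one mesh per animal-chamber, shared by that
  animal's maps so paced/sinus circles can be matched.
- **Rate laws**: CV speed fields scale as intercept × 1.004^(HR − 145) —
  the multiplicative law re-parameterised so chamber intercepts are
  interpretable at the 145 bpm normalisation point; the fitted per-bpm
  base is unchanged by the shift. VA shifts by −0.012 mV/bpm.
- **Pacing effects**: per-chamber CV multipliers (e.g. RA←RA ×0.75,
  RA←LA ×1.44, LA←RA ×0.62, RV←RA ×0.75, LV←RA ×0.49, LV←RV ×1.4) and VA
  offsets (RV +1.21/+1.236/+2.55 mV under RA/LA/LV pacing; LV −1.83 mV
  under RA pacing), with an optional per-wall override table to emulate
  regionally concentrated effects.
- **Chamber intercepts** at 145 bpm (CV 0.85/1.05/0.75/0.90 m/s, VA
  3.0/4.3/8.4/13.3 mV for RA/LA/RV/LV) are backed out from the emulated
  study's paired-difference tables (mean intrinsic = mean absolute
  difference / absolute difference ratio), since the study reports its
  estimates only graphically.
- **Wavefronts**: sinus maps activate from a fixed chamber-specific sinus
  entry, paced maps from a pacing-site entry — fixed, anatomy-flavoured
  but arbitrary locations. Focal activation uses Dijkstra shortest paths
  over mesh edges (edge time = length / mean endpoint speed), not a true
  eikonal solver: graph distances overestimate geodesics by ~4% on average
  (direction-dependent, up to ~10%), which is adequate at study resolution
  and bounded by a sphere-versus-great-circle test.
- **Noise architecture**: per-animal intercepts (SD 0.1 on log CV, 0.5 mV
  on VA) are drawn once per animal and shared across its maps. Circle-
  scale variability comes from smooth regional heterogeneity fields
  (lognormal SD 0.3 for CV at ~6 mm correlation length; 0.8 mV for VA at
  ~8 mm), plus white per-point noise (lognormal SD 0.05 on speed; 1.5 mV
  on VA). The regional fields are centred to zero mean per map: they model
  within-map heterogeneity, while map-level variation is carried by the
  heart-rate, group and animal terms. This keeps the mixed model's
  independence assumptions honest — un-centred long-range fields would
  induce map-level clustering that the model (which has no per-map random
  effect, by design) would mistake for precision, and the generator's job
  is to produce data with the statistical structure the analysis assumes.
  Amplitudes are truncated at 0 mV; with the default intercepts the
  truncation probability is small and its effect on the fitted slope is an
  order of magnitude below its standard error.

**What the generator does not emulate**: anatomically realistic chamber
geometry, fibre-orientation anisotropy, AV-nodal conduction, colliding
wavefronts, beat-to-beat annotation error, and epicardial-vs-endocardial
access differences (access is recorded as metadata only, as no effect size
is available for it). Passing tests therefore demonstrate that the
estimators and models recover known effects under realistic point
densities, noise scales and design imbalance — not that they are robust to
anatomy- or annotation-driven artefacts of clinical recordings.

## 7. Problem sizes and determinism

The acceptance-level checks run the full 44-map protocol at study scale
(~5700 circles, ~25 s end to end); replicate-based calibration tests
(parameter recovery across 20 studies, CI coverage ≥ 90%) use chambers
scaled to half the linear size to keep the suite fast, and mesh-free
circle-table simulations serve as the independent oracle for the
statistical layer. All stochastic stages are keyed by a single integer
seed through a deterministic splitter, so identical configurations
reproduce byte-identical files and equal manifest hashes; tests assert
this at map, study and pipeline level.

## 8. Known limitations

- Euclidean (not geodesic) circle membership; see §2.
- Graph-geodesic wavefronts carry a ~4% mean metric stretch; see §6.
- Absolute CV levels at study resolution sit ~10% above generating point
  speeds (sampling + path selection, §3); ratios and exponents are
  unaffected.
- The mixed model contains no per-map random effect, mirroring the
  emulated analysis; with strongly clustered real data its standard errors
  would be optimistic.
- Mutual-nearest matching is a stand-in for whatever registration a
  clinical system would provide across separately acquired maps.
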