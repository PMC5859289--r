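---
title: "Modelling growth trajectories of dense landmark configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth trajectories of dense landmark configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotraj)
```

This vignette is the package's account of its method: the model and its
assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the known limitations.

## The data model

The unit of analysis is a *configuration*: an ordered set of 3D vertex
coordinates in fixed correspondence across individuals, typically produced
by warping a common template onto each surface scan. A
`template_topology` fixes that correspondence scheme — vertex count,
triangulation (needed only for surface normals), the left–right vertex
pairing and midline set, and the mirror axis. A `cohort` adds per-case
metadata: decimal age in years, one of exactly two group labels, and the
physical centroid size recorded *before* any scaling.

Two pre-processing steps mirror standard geometric-morphometrics practice:

* **Symmetrization.** Each configuration is averaged with its
  reflected-and-relabelled copy, restricting the analysis to the symmetric
  component of shape variation. The reflection plane passes through the
  centroid, normal to the template's declared mirror axis; as a
  consequence the symmetrized output is centered. Centering first and
  reflecting through the centroid plane is the only canonical choice once
  translation is treated as nuisance.
* **Generalized Procrustes alignment** (`gpa()`). Configurations are
  centered, optionally divided by centroid size, and iteratively rotated
  onto an evolving consensus. Size is measured throughout as the *mean*
  vertex–centroid distance, both for reporting (mm) and for scaling; it
  differs from the classical root-sum-of-squares centroid size only by a
  per-template constant, and using one measure for both purposes keeps
  sizes and scalings mutually consistent. With `scale = FALSE` the
  analysis proceeds in size-and-shape space, which is the right frame
  whenever physically calibrated growth (mm/year) is of interest.

### Robust alignment

`robust_align()` fits each superimposition by iteratively reweighted least
squares so that grossly displaced vertices (scan artefacts, hair, open
mouths) do not drag the fit. Weights are flat at 1 for residuals within 3
robust standard deviations (1.4826 × median residual norm) and decay with
a Gaussian tail beyond; ten IRLS iterations are run. The flat bulk is a
deliberate choice: on outlier-free data every weight is exactly 1, so the
robust fit coincides with the ordinary Procrustes solution — a property
the test suite asserts at 1e-6 — while points beyond the cutoff are
suppressed essentially to zero.

Two numerical details of `gpa()` matter in practice:

* **Frame anchoring.** With per-configuration robust weights, the mean of
  the robustly aligned configurations is very slightly rotated relative to
  the consensus it was built from; iterating naively makes the whole frame
  rotate indefinitely at a constant rate while shapes stay put. Each new
  consensus is therefore rigidly re-anchored onto the previous one, after
  which the iteration converges (typically in 3–6 sweeps at tolerance
  1e-8 on the consensus change; non-convergence after 100 sweeps returns
  the current state with a warning).
* **Canonical orientation.** GPA determines the common frame only up to a
  global rotation inherited from the first configuration. After
  convergence the consensus is rotated into its principal-axes frame with
  a deterministic sign convention (the sign of a fixed linear functional
  of each axis, with paired column flips so the determinant stays +1 — the
  shape is never reflected). Because superimposing a configuration on a
  fixed consensus is exactly invariant to that configuration's own initial
  similarity transform, the final coordinates are invariant (to numerical
  precision) to arbitrary similarity transforms applied to the inputs.

## Growth trajectories

For one group, the expected configuration (or size) at target age $a$ is
the prediction of a locally weighted linear regression: observations
receive Gaussian kernel weights $w_i = \exp(-(a_i - a)^2 / 2h^2)$ and a
weighted linear partial least-squares regression of the responses on age
is evaluated at $a$. Predictor and responses are weighted-mean centered
before fitting and the intercept restored at prediction, which gives
correct local-linear behaviour at the edges of the kernel. With the single
predictor age the PLS score direction is age itself, so the fit equals the
weighted least-squares slope for every component count; the
`n_components` argument is validated but cannot change the fit, and the
equivalence is unit-tested against `lm(..., weights = )`.

The slope vector of the same local fit is the **growth field**: one 3D
vector per vertex, in coordinate units per year. Its mean vector length is
the overall **growth rate** at that age. A kernel width of $h$ means cases
within one width of $a$ dominate and cases beyond two widths are
essentially ignored ($e^{-2} \approx 0.135$ at exactly two widths).

**Defaults.** Shape regressions default to $h = 2.75$ y and size
regressions to $h = 0.75$ y. `tune_kernel_width()` re-tunes $h$ for any
dataset by a repeated cross-validated grid search (default 10 folds × 10
repeats, held-out Euclidean prediction error, fixed seed); for data from a
straight-line trajectory the cross-validation error decreases with width,
while curvature pushes the optimum down — both behaviours are asserted in
the tests.

**Evaluation range.** Near the edges of the sampled ages almost all kernel
weight sits on one side of the target and the local fit degrades into
extrapolation. The supported range is the maximal contiguous interval
(scanned at 0.01-y steps, a resolution finer than any reported age) on
which the kernel-weight sum of strictly older vs strictly younger cases,
or its inverse, stays at or above the support threshold (default 0.4).
The ratio is discontinuous at each observed age, so small samples can show
interior dips; the longest contiguous run is returned. Predictions outside
the range are allowed but warn.

## Comparing two groups

The dimorphism-magnitude curve is the Procrustes distance between the two
groups' expected heads on an age grid. Since all configurations share one
aligned frame, distance is the plain Frobenius norm of the coordinate
difference — the standard tangent-space approximation, which also keeps
the classifier's projection geometry exactly linear.

* **Permutation test.** Group labels are permuted (sizes preserved), both
  regressions refitted with the same kernel width, and the distance
  recomputed; the add-one estimator $p = (1 + \#\{D^* \ge D\})/(1 +
  n_{perm})$ avoids zero p-values. Alignment is label-blind, so permuted
  refits reuse the original superimposition. No multiple-testing
  correction is applied across ages by default (per-age significance is
  reported); Benjamini–Hochberg is available as an option.
* **Bootstrap.** Percentile intervals from resampling cases with
  replacement *within* each group: the comparison is conditional on group
  membership, so group sizes are part of the design.
* **Maps.** Shape difference along the reference group's outward surface
  normals (area-weighted vertex normals), per-axis differences, the
  growth-rate difference (by default the difference of the fields' normal
  components, matching the inward/outward convention of the shape maps; a
  vector-magnitude mode is also provided since the overall rate curve uses
  vector lengths), and the angle between growth vectors (0° = same
  direction, 180° = opposite). Exaggeration morphs
  `ref + factor (other − ref)` make subtle contrasts visible.

## Age-adaptive classification

A case of age $a$ is scored by projecting it onto the axis joining the two
groups' expected heads *at that age*, normalized by half the distance
between them, so the group means anchor −1 and +1 and 0 is the midpoint.
Performance is assessed by repeated stratified k-fold cross-validation:
folds are balanced within group × integer-year age strata (integer years
match how such cohorts are recruited and reported); for each held-out case
the expected heads are refitted from the remaining folds. Cases whose age
falls outside a training set's supported range are scored at the nearest
in-range age and flagged — every case is scored, including infants below
the range floor. Fold-level AUC (rank-based, ties counting one half) and
per-group correct rates at threshold zero are aggregated into age brackets
(default <5, 5–10, 10–15, 15–20 y) as means with 2.5/97.5 percentile
intervals over all repetitions × folds.

Alignment is performed once on the full cohort before cross-validation,
mirroring the pipeline order of studies this supports; the leakage through
the shared Procrustes frame is negligible (alignment is label-blind) but
worth stating.

## The synthetic-data generator

Real cohorts of identifiable children's scans cannot be shared, so the
package generates study-shaped surrogates with known truth. The template
is a watertight triangulated ellipsoid with exact left–right symmetry;
the default semi-axes (75, 95, 85) mm give a head-sized object with
centroid size ≈ 85 mm. The baseline growth field points radially outward
with magnitude graded smoothly from 0.6 to 1.4 mm/year over the surface
(mean ≈ 1 mm/year, a realistic head-surface displacement rate); scenarios
derive from it:

* `null` — both groups identical;
* `rate` — group B's field scaled by 1.5: a pure rate contrast;
* `direction` — group B's vectors tilted 45° about local tangent axes:
  equal magnitudes, different directions;
* `pubertal` — an extra component appearing after age 12;
* `separated` — a constant shape offset of 10 noise-sd, orthogonalized
  against the growth field so the group contrast is not confounded with
  age.

Ages are uniform on [0.5, 18.5] y; vertex noise is i.i.d. isotropic
Gaussian with sd defaulting to 2% of template size; nuisance similarity
transforms (rotations up to 20°, translations up to ±20 mm, optional
scaling) emulate arbitrary scanner frames. Mean trajectories are centered
per age; the analytic fields are exact per-vertex constructions, and
`true_growth_field(frame = "centered")` returns their centered projection,
which is what models fitted to centered data estimate.

What the generator does *not* emulate: anatomical detail, non-Gaussian or
spatially correlated measurement error, correspondence (registration)
error, asymmetry, maturation-rate heterogeneity, and non-uniform age
distributions (a per-year-count option would be a small extension).
Passing tests on these surrogates therefore demonstrates correctness of
the estimators under the stated model, not robustness to registration
artefacts in real scans.

## Problem sizes and numerical choices

The shipped checks run at sizes chosen to exercise the statistics while
staying desk-sized: recovery uses a 26-vertex template with 400 cases per
group (the estimated rate ratio lands within a few percent of the true
1.5 and mean direction errors under 5°); permutation calibration uses 200
null cohorts of 60 per group with 200 permutations; classifier checks use
250 per group with 5 × 10-fold cross-validation. Degenerate inputs are
handled explicitly: coincident configurations refuse to align, identical
ages make the regression singular, zero-length growth vectors yield
missing angles, empty fold-brackets are dropped from aggregation, and an
exact-fit robust alignment short-circuits to uniform weights.

## Limitations

Cross-sectional trajectories describe population-level change, not
individual growth; age only approximates maturation. Allometry (the
size–shape association) is deliberately not adjusted for: size is strongly
correlated with age, so regressing it out would remove the growth signal
itself — analyse size-and-shape (`scale = FALSE`) when calibrated growth
matters. The tangent-space distance is accurate for small shape variation
around the consensus, which holds for within-species craniofacial data but
not for arbitrary shape collections.
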