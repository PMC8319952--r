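---
title: "Predicting OAR D2cm3 from sub-OAR ring volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting OAR D2cm3 from sub-OAR ring volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In tandem-and-ovoid brachytherapy for cervical cancer, each fraction is
planned on fresh anatomy: the applicator, the high-risk clinical target
volume (HR-CTV) and the organs at risk (OARs -- bladder, rectum, sigmoid
colon, small intestine) all move between fractions.  The planner must push
the prescription dose (here 7 Gy per fraction, four fractions) into the
HR-CTV while keeping the OAR hot spots -- summarized by D2cm3, the minimum
dose to the hottest 2 cm^3 of an organ -- below per-fraction aims
(bladder < 5.2 Gy; rectum, sigmoid colon, small intestine < 4.7 Gy).
Whether a given plan's D2cm3 is "as good as achievable" for that anatomy is
hard to judge plan by plan.  `suboar` implements a knowledge-based
quality-assurance approach: predict the achievable
D2cm3/Dprescription ratio per organ from purely geometric features, and
flag plans whose realized ratio deviates from the prediction by more than a
chosen threshold delta.

## Sub-OAR ring-volume features

The geometric features are *sub-OAR volumes*.  The HR-CTV is expanded
outward into concentric shells ("rings") of width 0.5 cm, at most 10 of
them; the intersection of ring *k* with an organ is sub-OAR *k*, and its
volume in cm^3 is a feature.  Organs that push close to the target have
large near-ring volumes and unavoidably receive more dose, so these volumes
carry the dose-geometry signal that drives the achievable D2cm3.

Per organ, the model input is a six-vector: a global volume followed by
sub-OAR volumes 1-5 (the five rings nearest the target carry essentially
all of the signal; more distant rings add noise).  For bladder, rectum and
sigmoid colon the global feature is the HR-CTV volume; for the small
intestine it is the *bladder* volume, whose filling state displaces bowel
loops relative to the target.

### Distance transform and ring conventions

Rings are derived from an exact anisotropic Euclidean distance transform
(the separable lower-envelope algorithm), measured voxel-center to
voxel-center.  A voxel belongs to ring *k* iff its distance *d* satisfies
`(k-1)*w < d <= k*w` -- half-open shells, so every voxel lands in exactly
one ring and the rings partition the expansion zone.  Organ masks that
overlap the HR-CTV are rejected as input errors rather than clipped: the
rings are strictly external by construction, and an overlap indicates a
contouring problem upstream.

Binary masks limit how precisely any convention can localize a structure
surface.  The center-to-center distance slightly over-measures the distance
to a digitized surface (the nearest voxel *center* sits up to half a voxel
inside it), which biases the innermost ring volume low by a few percent at
typical CT resolution; the bias shrinks proportionally with voxel size.  On
the analytic sphere-and-shell phantom used in the test suite, ring volumes
agree with closed-form shell volumes to 1.95% (mean relative difference) at
1 mm voxels and 0.74% at 0.5 mm.  An alternative `"surface"` metric --
distance to the midsurface of the interpolated voxel indicator -- is
available in `distance_map()` and `derive_rings()`; it trades the outward
offset for a comparable inward one and is not the default.  We assume the
expansion is 3-D isotropic (not slice-wise): it is the convention a margin
tool approximates as resolution improves, and the only one with a
resolution-independent definition.

## Dosimetry

All DVH quantities are computed from the exact voxel dose multiset: sort
the organ's voxel doses descending, accumulate voxel volumes, and
interpolate linearly at the requested volume crossing.  This is bin-free,
so D2cm3 and D90 are reproducible to machine precision and agree with a
brute-force oracle by construction of the algorithm rather than by choice
of histogram bin width.  D90 (minimum dose to the hottest 90% of the
HR-CTV) defines prescription coverage: every phantom plan is renormalized
so that D90 equals the 7 Gy prescription exactly, and the model target is
the dimensionless per-fraction ratio D2cm3/Dprescription.  EQD2 conversion
(`n d (d + a/b) / (2 + a/b)`, alpha/beta 10 for targets, 3 for OARs) is
provided for relating per-fraction aims to cumulative biological-dose
limits; all modelling stays on the per-fraction scale, matching the
per-fraction planning constraints.

## The synthetic phantom cohort

No public cohort of paired structure sets and dose grids exists for this
setting, so the package ships a seeded generator that emulates one at desk
scale: 200 plans on a 2.5 mm isotropic lattice (76 x 96 x 96 voxels).
Each plan draws:

* an ellipsoidal HR-CTV, semi-axes `base * exp(U(-0.08, 0.08))` with
  `base ~ U(16, 28)` mm -- target volumes span roughly 17-100 cm^3 while
  staying near-spherical, so the target volume is informative of every
  axis;
* a spherical bladder (radius 20-32 mm) anterior, a rectal tube (radius
  9-14 mm) posterior, a tilted sigmoid tube posterior-superior, and a broad
  flat-bottomed "bowel bag" slab superior, each placed with a
  surface-to-target gap drawn from U(2, 14) mm.  The bowel gap is coupled
  negatively to the drawn bladder radius (fuller bladder, closer bowel), so
  bladder volume carries a positive association with small-intestine dose;
* a dwell layout: tandem dwells stepping 5 mm over a fixed 30 mm active
  length starting 4 mm below the superior target surface, plus two ovoid
  dwells at the inferior-lateral surface.  Base weights are optimized
  deterministically toward uniform target-surface dose (a multiplicative
  update against surface probe points), emulating the manual/graphical
  optimization with which clinical plans are made conformal; the optimizer
  sees only the target surface, never the OARs.  Lognormal jitter
  (sd 0.05) then models residual plan-to-plan optimizer variability;
* dose from a clipped inverse-square point-source kernel
  (`sum_i w_i / max(r_i, 1 mm)^2`), rescaled so D90(HR-CTV) = 7 Gy.

Design choices worth making explicit: the kernel omits the radial dose
function and anisotropy of a real Ir-192 source model -- it preserves the
geometric falloff the features exploit, which is what the model needs, not
absolute dosimetric realism.  Constraint violations are recorded per plan
but never "repaired" by re-optimization against the OARs, so the cohort's
volume-dose relationship stays purely geometric.  The bowel bag is modelled
as one contiguous planning volume (as bowel is commonly contoured) rather
than separate loops: its flat lower envelope makes the ring intersections
smooth functions of both the gap and the target's dome curvature, which is
also what makes the small-intestine model learnable from its stated
features.  What the phantom does *not* emulate: inter-fraction deformation,
applicator shielding, heterogeneity corrections, contouring variability,
and the correlation structure of repeated plans from the same patient.
Passing the synthetic quality bar therefore demonstrates that the pipeline
recovers a geometry-driven dose signal end to end -- not that the same
accuracy would be achieved on clinical data.

## The regression model

Per organ, an epsilon-support-vector regression with the radial basis
function kernel `K(x, y) = exp(-gamma ||x - y||^2)` maps the six features
to the D2cm3/Dprescription ratio.  Features are z-scored before kernel
evaluation (the RBF mixes feature scales; volumes range from fractions of
a cm^3 to over 100).  The tube width epsilon defaults to 0.01 on the ratio
scale -- about 0.07 Gy at a 7 Gy prescription, comfortably below clinical
relevance.  `C` and `gamma` are chosen by grid search
(`C` in 0.1...1000, `gamma` in 0.001...10, decade steps) minimizing 5-fold
cross-validated MSE within the 160-plan training group only; ties break
toward smaller `C`, then smaller `gamma` (the simpler model).  The 40-plan
verification group is never touched during selection.  The quadratic
program is solved by libsvm (via `e1071`); the test suite independently
checks its solutions against a direct dual QP on small problems.
Degenerate inputs are handled explicitly: constant feature columns are
dropped with a warning (a ring an organ never reaches carries no
information), and a constant target yields a model that predicts the
constant.

Evaluation reports mean squared error, `R^2 = 1 - SS_res/SS_tot`, the
per-plan absolute error `delta = |actual - predicted|` with mean and sample
sd, Pearson correlations (two-sided p from the t-transform on n-2 df)
between each feature and the actual ratio, and a two-sided paired t-test
between predicted and actual ratios.  Two p-value conventions are fixed
deliberately: all tests are two-sided, and no multiple-testing correction
is applied across the feature-correlation tables.

## Quality assurance

`cmd_qa()` compares a new plan's planned ratio against the model
prediction per organ and flags organs with `delta` above a threshold
(default 0.1 on the ratio scale, configurable per organ).  A flagged organ
suggests the plan leaves dose on the table for that anatomy -- further
optimization or applicator adjustment is worth attempting before treating.

## Problem sizes, determinism, and what the tests compute

The packaged experiment sizes are chosen for a desk-scale run: the
200-plan cohort generates in about two minutes and the four grid searches
in well under one.  All randomness flows from explicit integer seeds (one
root seed derives per-plan seeds, the cohort split, and the
cross-validation folds), so cohort CSVs are byte-identical across reruns.
The test suite asserts, among others: exactness of the distance transform
against an O(n^2) brute force; ring partition and volume-conservation
invariants; convergence of ring volumes to closed-form shell volumes at
2, 1 and 0.5 mm; DVH metrics against a sort-and-accumulate oracle to 1e-9;
SVR predictions against a direct dual QP to 1e-4; recovery of a known
volume-to-ratio law with Gaussian noise (sd 0.02) to a validation delta
mean within three noise standard deviations and no significant
predicted-vs-actual bias; and, on the default cohort, training MSE below
0.05 and training R^2 above 0.9 for all four organ models.

## Known limitations

* Ring-volume accuracy is voxel-limited; at coarse spacing the innermost
  populated ring is biased low by a few percent (see above).
* The phantom's organ shapes are parametric idealizations; absolute ratio
  levels and correlation magnitudes are not calibrated to a clinical
  distribution.
* Plan-level (not patient-level) splitting is the default; with repeated
  plans per patient this can leak anatomy between training and
  verification.  `split_cohort()` operates on arbitrary identifiers, so a
  patient-level split is available to callers that track patient ids.
* Models are point predictors; no uncertainty intervals accompany the
  predicted ratios.
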