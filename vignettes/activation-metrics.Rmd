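---
title: "Chamber-specific electrical activation metrics for CRT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber-specific electrical activation metrics for CRT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crt80)
```

## The problem and the quantities computed

Cardiac resynchronization therapy (CRT) paces one or both ventricles to
restore electrical synchrony in heart failure with conduction disease. The
surface-ECG QRS duration (QRSd) summarizes *biventricular* depolarization
in a single number and cannot separate left-ventricular from
right-ventricular delay. Epicardial activation maps — per-vertex activation
times on a labelled LV/RV surface mesh — can.

`crt80` computes, for each chamber scope (LV, RV, or both = BIV), the
*activation-versus-time function*: the cumulative fraction of the scope's
epicardial surface area activated by time $t$ from QRS onset. The core
statistics are time-to-fraction readings of that curve:

* $\mathrm{LV80}$, $\mathrm{RV80}$, $\mathrm{BIV80}$ — the time at which
  80% of the LV, RV or biventricular surface is activated (ms); 70%, 90%
  and 100% variants are computed alongside;
* the ratios $\mathrm{LV80}/\mathrm{QRSd}$ etc., compared against the
  **constant-rate reference 0.8**: if a chamber activates at a constant
  rate throughout the QRS, 80% of its surface is activated in 80% of the
  QRS duration, so ratios far from 0.8 diagnose temporally variable
  (front-loaded or long-tailed) activation;
* $|\mathrm{LVRVDIFF}| = |\mathrm{LV80}-\mathrm{RV80}|$, an
  interventricular electrical synchrony score used to compare pacing
  settings;
* fractional changes $(\mathrm{post}-\mathrm{pre})/\mathrm{pre}$, both for
  the LV end-systolic volume index (remodelling response; negative =
  improvement) and for RV80 under biventricular pacing.

The 80% reading is deliberately insensitive to the long temporal "tails"
that bundle-branch-block activation curves exhibit: the time to activate
*most* of a chamber matters more than the time to activate its last
element.

## Discretization: curves on triangle meshes

Activation times are stored per vertex (that is how mapping systems and
the simulator emit them). A triangle's element time is the arithmetic mean
of its three vertex times; the curve is the right-continuous step function
obtained by sorting element times and accumulating element areas,
normalized by the scope's total area. Exactly tied element times are merged
into a single event so the step function is well defined.
`time_to_fraction(curve, f)` returns the smallest event time whose
cumulative fraction reaches `f` — a step-function infimum, with no
interpolation between surface elements, matching the discrete nature of the
data. Area weighting is the default; `weighting = "count"` weights every
element equally instead (the two coincide exactly on uniform-area meshes).
Both are offered because mapping systems do not document which of the two
their percentages use.

The QRS duration entering the ratios is, by default, the map-derived
biventricular completion time (`qrs_source = "map_derived"`); a measured
12-lead QRSd can be supplied instead and may legitimately differ from the
map's completion time.

## Synthetic data: what is emulated and what is not

No mapping data ship with the package; every downstream stage is exercised
on synthetic maps with controlled structure.

**Geometry.** `biv_shell_mesh()` joins two ellipsoidal half-shells sharing
the short (35 mm) and long (60 mm) semi-axes along the $x=0$ seam, with LV
half-width 45 mm and RV half-width 30 mm — a dilated-heart scale. The
surface is a subdivided octahedron ($8\cdot 4^k$ triangles).

**Wavefront propagation.** `simulate_activation()` computes each vertex's
time as the minimum over breakthrough sites of onset delay plus
shortest-path travel time on the mesh edge graph, with edge traversal time
(length / local velocity). Local velocity is a base velocity (default
0.8 mm/ms, within the 0.3–1 mm/ms epicardial range) scaled per chamber,
reduced on seam-straddling edges, and reduced inside scar patches (scar
membership by Euclidean distance from the patch seed, for determinism).
Shortest-path propagation was chosen over fast marching deliberately: it is
exactly reproducible by an independent shortest-path oracle, so the
simulator is testable to machine precision, and geometric fidelity of the
front is immaterial for the statistics under test.

**Bundle branch block and pacing presets.** LBBB is emulated
phenomenologically: a single RV free-wall breakthrough, a faster
(Purkinje-backed) RV, and strongly slowed trans-seam conduction (scale
0.18–0.32), which delays the LV and produces LV80 > RV80 with a long LV
tail; RBBB is the mirror image. Paced presets stimulate the LV lateral
free wall and/or the RV apical free wall with no Purkinje support (base
velocity × 0.85, milder seam slowing 0.5–0.7); `BIVP_LV30` stimulates the
LV 30 ms before the RV. With a seed, velocities and site placement are
jittered; the chamber ordering guarantees hold for every seed. The RV
pacing landmark sits on the apical free wall rather than the polar tip —
both more anatomically faithful for an RV lead and necessary for
simultaneous biventricular pacing to balance the chambers, as it should.

**Cohorts.** `simulate_cohort()` draws bundle-branch type (P(LBBB) = 2/3,
as in a typical CRT referral population of 30 patients), simulates the
five settings per patient with jitter, and generates outcomes as
`intercept + slope × predictor + Normal(0, noise_sd)` with predictors
exactly the ones the response models use: |LVRVDIFF| under LVP and RVP for
the LVESVI fractional change, LV80 under BIVP for post-CRT log BNP, the
RV80 fractional change under BIVP for the change in peak VO₂, and the
intrinsic RV80 for the pre-CRT RV ejection fraction. Default couplings
(see `cohort_outcome_model()`) are scaled to clinical magnitudes, e.g.
−0.35 + 0.006/ms for the LVESVI fractional change (a 40 ms
interventricular difference erases ~0.24 of remodelling response) with
residual sd 0.10. Each setting's map is a fresh jittered draw; the
generator does not model within-patient persistence of conduction
properties across settings or visits. All randomness flows from one
integer seed through a single RNG stream, so a fixed seed reproduces a
cohort bitwise.

**What passing tests do not show.** The synthetic maps have smooth,
single-front activation on an idealized closed shell without a septal
surface, valve orifices, His–Purkinje trees, or measurement noise;
outcomes are linear in single predictors with Gaussian residuals. Passing
the suite therefore validates the *computations* (curves, statistics,
model fitting), not the clinical fidelity of any simulated patient.

## The constant-rate (linear) limit

`linear_activation_map()` constructs the analytic reference: a map whose
cumulative area fraction rises linearly from 0 to the requested duration
in every scope, so every 80% ratio equals 0.8. Because the element time is
the *mean* of three vertex times, naively placing vertices at their
area-cumulative positions biases the completion time (the latest element
mean undershoots the duration by half a local mesh spacing), which
violates the one-triangle granularity bound at any refinement. The
construction therefore targets *element* times directly — each in-scope
triangle is assigned the time at its area-cumulative position along an
apex-to-base sweep, both chambers swept in the same direction so targets
agree near the seam — and solves for vertex times in sparse least squares,
with a weak prior (each vertex anchored at its incident-triangle mean
target, relative weight $10^{-4}$) that suppresses the oscillatory modes
the data term leaves undetermined. At subdivision 5 (8192 triangles) all
three 80% ratios equal 0.8 within the area fraction of a single triangle
(~4×10⁻⁴), the package's operational definition of granularity.

## Statistical layer

* **Linearity tests**: two-sided one-sample t-tests of per-patient ratio
  samples against 0.8 (`one_sample_t_vs()`). A zero-variance sample at the
  reference returns t = 0, p = 1 rather than an error. Applying the test to
  per-patient ratios (not to regression slopes) follows the definition of
  the hypothesis; slope-based testing would be an alternative reading.
* **Group structure**: per-group OLS slopes of a metric on QRSd with the
  group difference tested by the group×QRS interaction
  (`slope_by_group()`); ratio-on-group models with one group×moderator
  interaction at a time (`ratio_model()`); Kruskal–Wallis / Fisher exact
  group comparisons with Shapiro–Wilk normality diagnostics
  (`group_compare()`). These delegate to the standard R implementations.
* **Robust response models**: `huber_lm()` implements Huber M-estimation
  by IRLS — tuning constant 1.345 (≈95% Gaussian efficiency), scale =
  median absolute deviation about zero re-estimated each iteration,
  convergence when the largest coefficient change is below 10⁻⁸, at most
  200 iterations (non-convergence is an error carrying the last iterate).
  The Huber variant (rather than a redescending bisquare) is the
  ecosystem-default reading of "robust linear regression" and is fixed for
  reproducibility. Standard errors use the M-estimation sandwich with an
  HC3-type leverage adjustment (each squared influence divided by
  $(1-h_i)^2$): in small clinical cohorts the electrical predictors —
  fractional changes especially — have influential tails, and the
  leverage adjustment keeps ±2 SE intervals at nominal coverage where the
  plain X'X formula is slightly anticonservative. R² is reported from the
  final weighted least-squares step, and the model p-value from the
  corresponding weighted F statistic; both are conventions, since no
  canonical robust R² exists. Missing outcomes are dropped listwise per
  model with `n_used` reported. Raw p-values are reported throughout;
  `stats::p.adjust` can be applied by the caller, but no multiplicity
  correction is built in.

The parameter-recovery experiment in the test suite (500 cohorts of
n = 200) checks that every generating slope is recovered within 2 reported
SEs in ≈95% of replicates. Note the design point: a perfectly calibrated
±2 SE interval covers 95.45% in the Gaussian limit, so this check sits by
construction within Monte-Carlo noise of its own threshold; it validates
calibration, not a safety margin.

## Pacing comparison and recommendation

`pacing_session()` collects one patient's per-setting metrics (the
intrinsic rhythm is the mandatory reference), `config_table()` derives the
deltas of LV80/RV80/BIV80/|LVRVDIFF| against the intrinsic rhythm (the
pacing-configuration-plot data), and `recommend_setting()` returns the
paced setting minimizing |LVRVDIFF|, the synchrony score most strongly
tied to LV functional response. Exact ties are broken by the smaller BIV80
and then by the fixed order BIVP, BIVP_LV30, LVP, RVP — a deterministic
rule chosen because a recommendation must be unique; BIVP_LV30 is kept as
a candidate distinct from BIVP. Response thresholds are inclusive: LVESV
fractional change ≤ −0.05 and peak-VO₂ improvement ≥ 1 mL/kg/min;
missing outcomes yield absent (NA) flags, never FALSE.

## Problem sizes and numerical choices

* Cohort simulations run on the subdivision-2 shell (66 vertices, 128
  triangles): chamber statistics on it are within a few ms of finer
  meshes, and a 200-patient, five-setting cohort simulates in well under a
  second, which makes 500-replicate recovery experiments routine.
* The linear-limit reference uses subdivision 5 (8192 triangles), where
  one-triangle granularity is ~4×10⁻⁴ of scope area.
* Simulator–oracle equivalence is asserted *exactly* (tolerance zero):
  Dijkstra and Bellman–Ford both solve the same fixpoint equations with
  identical floating-point sums.
* Mesh and map files are plain text; coordinates and times are written
  with 17 significant digits so ASCII round-trips are bit-exact.
* Maps whose minimum time is positive are re-referenced to 0 with a
  logged shift by default (`strict = TRUE` turns this into an error).

## Limitations

The septal surface is not represented at all — metrics are epicardial
free-wall statistics. The simulator is a graph-geodesic caricature: no
transmural conduction, no anisotropy, no electrogram morphology, no
torso. The recommendation rule operationalizes a single synchrony score
and ignores hemodynamics, lead constraints and atrio-ventricular timing,
which a device clinic would not. Cohort outcome couplings are univariate
and linear by construction; they exist to make estimator behaviour
testable, not to imitate clinical effect sizes beyond their scale.
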