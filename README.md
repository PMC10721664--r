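# crt80 — chamber-specific electrical activation analysis for CRT

Cardiac resynchronization therapy (CRT) paces the ventricles of failing
hearts with conduction disease, but patient selection and device
programming still lean on the surface-ECG QRS duration — a single number
that cannot say *which* ventricle is late, or whether activation is
front-loaded with a long tail. Epicardial activation maps (per-vertex
activation times on a labelled LV/RV surface mesh) can.

`crt80` is an R package for analysts working with such maps. It computes
the chamber-specific **time-to-80%-activation** statistics and everything
the analysis around them needs:

* **Activation curves** — for a scope S ∈ {LV, RV, BIV}, the cumulative
  area fraction of S activated by time *t* from QRS onset (a step function
  over area-weighted mesh triangles).
* **LV80 / RV80 / BIV80** — the time at which 80% of the LV, RV or
  combined epicardial surface is activated (70/90/100% variants
  alongside), and their ratios to the QRS duration. Under constant-rate
  activation, time-to-80% equals 0.8·QRSd, so **ratios ≠ 0.8** diagnose
  temporally variable activation; one-sample t-tests against 0.8 formalize
  this.
* **|LVRVDIFF| = |LV80 − RV80|** — an interventricular electrical
  synchrony score, compared across the five pacing settings (intrinsic,
  RVP, LVP, simultaneous BIVP, BIVP with a 30 ms LV-first offset) to
  recommend a configuration per patient.
* **Robust (Huber) regression** of multidimensional CRT response —
  LV remodelling (LVESVI fractional change), post-CRT log BNP, change in
  peak VO₂ — on the electrical predictors, via the classic modelling
  interface `huber_lm(formula, data)` with `print`/`summary`/`coef`/
  `predict`/`residuals`/`vcov` methods.
* **A fully synthetic data layer** — an ellipsoidal biventricular shell
  mesh, a wavefront simulator (shortest paths on the mesh edge graph) with
  LBBB/RBBB/pacing presets, analytic constant-rate maps, and a seeded
  cohort generator whose outcomes are linearly coupled to the electrical
  predictors — so the entire pipeline is testable without any patient
  data.

Mesh, map and cohort I/O use plain text (CSV pair or ASCII PLY with face
labels; activation maps as `vertex_id,time_ms` CSV), written at full
precision so round-trips are bit-exact.

## Worked example

Simulate an LBBB patient on the synthetic shell, read off the chamber
metrics, then compare pacing settings:

```r
library(crt80)
mesh <- biv_shell_mesh(2)                            # 128-triangle biventricular shell
map  <- preset_activation_map(mesh, "LBBB", seed = 42)
chamber_metrics(map)
#> <chamber_metrics> setting INTRINSIC, QRS 117.0 ms (map_derived)
#> times (ms):
#>      0.7  0.8   0.9     1
#> LV  91.7 99.8 110.8 117.0
#> RV  38.6 42.0  48.1  52.5
#> BIV 77.9 89.5 104.0 117.0
#> ratios to QRS:
#>      0.7  0.8  0.9    1
#> LV  0.78 0.85 0.95 1.00
#> RV  0.33 0.36 0.41 0.45
#> BIV 0.67 0.76 0.89 1.00
#> |LV80 - RV80| = 57.7 ms
```

The signature left bundle branch block pattern: the RV is 80% activated
within 42 ms (RV80/QRS = 0.36, far below the constant-rate 0.8 — RV
activation is front-loaded), while the LV needs 99.8 ms of a 117 ms QRS,
leaving a 57.7 ms interventricular difference. Now pace:

```r
maps <- list(INTRINSIC = map,
             RVP  = preset_activation_map(mesh, "RVP",  seed = 42),
             LVP  = preset_activation_map(mesh, "LVP",  seed = 42),
             BIVP = preset_activation_map(mesh, "BIVP", seed = 42),
             BIVP_LV30 = preset_activation_map(mesh, "BIVP_LV30", seed = 42))
recommend_setting(pacing_session("P001", lapply(maps, chamber_metrics)))
#> <pacing_recommendation> patient P001: BIVP
#>    setting   lv80  rv80  biv80 lvrvdiff
#>       BIVP  76.47 105.0  90.45    28.53
#>        RVP 154.72 121.1 137.10    33.62
#>  BIVP_LV30  80.07 115.5 104.75    35.40
#>        LVP  94.69 139.3 126.86    44.62
```

Simultaneous biventricular pacing halves |LVRVDIFF| relative to the
intrinsic rhythm (28.5 vs 57.7 ms) and is the recommended setting for this
patient. For cohort-level analysis, `simulate_cohort()` →
`analyze_cohort()` runs the full battery (ratio t-tests vs 0.8 by
bundle-branch group, per-group slopes on QRSd with interaction tests,
robust response models, RV80–RVEF correlation), and `run_pipeline()`
orchestrates everything from a YAML config into a reproducible output
directory with a manifest.

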