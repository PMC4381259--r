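---
title: "Methods: semi-quantitative PET response prediction on phantom cohorts"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were open, and what its validation does and does not show.

## The procedure

For each patient the pipeline consumes a staging scan (PET1), an interim
scan after two chemotherapy cycles (PET2), injection metadata, lesion
masks drawn on PET1, and a binary outcome (relapse during follow-up vs
ongoing complete remission). It then:

1. converts activity (kBq/mL) to SUV images under three normalizations —
   body weight, body surface area (DuBois–DuBois), lean body mass (James,
   sex-specific);
2. segments isocontour VOIs inside each mask: voxels strictly above the
   scheme threshold, outside exclusion regions. Thresholds: fixed 2.5 for
   the body-weight and body-surface-area schemes; for the SUL scheme the
   individualized value mean + 2·SD of a 5.15 cm liver reference sphere,
   measured per scan;
3. extracts SUVmax, SUVmean, MTV and TLG = SUVmean × MTV per lesion,
   aggregates per patient, re-measures the identically placed masks on
   PET2, and forms percentage decreases Δ = (v1 − v2)/v1 × 100;
4. evaluates every parameter as a relapse predictor: DeLong AUC, 95% CI
   and a two-sided test against 0.5; cutoff chosen among midpoints of
   adjacent distinct scores to maximize accuracy subject to zero false
   negatives (NPV = 100%); Benjamini–Hochberg FDR over the family of AUC
   p-values of the run; optional paired DeLong comparisons and a logistic
   regression of outcome on PET2 uptake/volume.

## Assumptions

* Activity volumes are decay-corrected and calibrated; uptake time is
  carried as metadata but not corrected for, and the staging and interim
  scans share one voxel grid (phantom pairs are co-registered by
  construction).
* Relapse is the positive class everywhere; a visual (Deauville-type)
  score is consumed as supplied data, dichotomised at score ≥ 3, never
  computed from images.
* The liver is lesion-free, so the individualized SUL threshold is always
  measurable.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| segmentation threshold (bw, bsa) | 2.5 | fixed SUV isocontour; strict `>` |
| liver sphere diameter | 5.15 cm | SUL reference region |
| SUL threshold | liver mean + 2 SD | individualized background exclusion |
| Δ | (v1 − v2)/v1 × 100 | percent decrease, positive baseline required |
| cutoff constraint | NPV = 100% | zero false negatives among candidates |
| FDR level | 0.05 | BH across the run's AUC p-value family |

A deliberate unit subtlety: on the conventional body-surface-area scale
(activity × BSA in cm² / dose in kBq) typical tissue values are several
times smaller than SUV_bw, so the fixed threshold of 2.5 is far more
stringent there. The scheme is implemented exactly as specified and is
excluded from the default report set for the same reason that
body-surface-area parameters are uninformative at that threshold; pass
`schemes = c(..., "suv_bsa_2.5")` to include it.

## The synthetic cohort

`cohort_design()` fixes the study conditions the pipeline is exercised
under: 54 patients with 6 relapses (~11% prevalence); pediatric metadata
(sex-dependent height from age, BMI around 18.5, ~4.5 MBq/kg dosing,
uptake time near 72 ± 20 min); one to four ellipsoidal lesions per patient
(semi-axes 6–18 mm, peak SUV lognormal around 8, uniform or
gaussian-falloff profile); a heterogeneous liver sphere with per-voxel SUL
drawn from N(1.8, 0.15); one high-uptake physiological hotspot with a
matching exclusion region; additive gaussian image noise of 0.1 SUV; and a
true percentage SUVmax decrease per patient drawn from N(92, 13) for
responders and N(55, 15) for non-responders, both truncated at 100%.

The responder SD of 13 was chosen (once) so that roughly 15% of
responders fall below a ~78% decrease — the overlap regime in which an
NPV-constrained cutoff accumulates false positives, which is the
phenomenon of interest; the non-responder (55, 15) spec is the natural
counterpart with essentially all mass below that boundary. Interim
lesions are the staging lesions with peak intensity scaled by
1 − Δ/100, so the designed decrease is exact in the noise-free image.
Synthetic visual scores are drawn so that score ≥ 3 occurs in about two
thirds of relapsing and ~29% of remitting patients, reproducing a visual
read's characteristic false-negative/false-positive behaviour.

Default grids: 128 × 128 × 160 voxels at 4 mm for single phantoms;
64 × 64 × 80 at 4 mm (a 25.6 × 25.6 × 32 cm child-torso field of view)
for cohorts, which keeps a 54-patient run in tens of megabytes because
scans are realised lazily per patient from per-scan seeds fixed at cohort
creation (`realize_scan()`; bit-identical on every call).

What the phantom does **not** emulate: scanner physics (point-spread
function, scatter, attenuation, reconstruction artefacts), partial-volume
effects, Poisson counting noise, patient motion, anatomic background
variation, or inter-scanner calibration differences. Passing tests
therefore demonstrate correctness of the measurement and statistics
chain under known ground truth — not clinical performance on real
scans, where partial-volume and calibration effects dominate small-lesion
quantification.

## Numerical choices

* Voxel membership everywhere is the voxel-centre-inside test (boundary
  `<=`), making segmentation reproducible and translation-invariant under
  whole-voxel shifts.
* Threshold comparisons are strict (`>`), and classification at a cutoff
  is strict in both directions; ties are negative.
* Lesions replace background via voxelwise maximum, so a designed peak is
  the value actually observed at the lesion centre; ground truth (true
  SUVmax; true volume of voxels above SUV 2.5) is measured on the
  noise-free image, which is what makes exact round-trip tests possible.
* Empty VOIs (nothing above threshold) report MTV = TLG = 0 with
  SUVmax/SUVmean taken over the whole mask and a `below_threshold` flag;
  patients below threshold already at PET1 are excluded from that
  scheme's Δ analysis with a logged warning.
* Per-patient aggregation over lesions (the multi-lesion convention is
  otherwise unspecified): SUVmax by maximum, MTV and TLG by sum, SUVmean
  as the MTV-weighted mean — chosen so the patient-level identity
  TLG = SUVmean × MTV holds to machine precision.
* Cutoff candidates are midpoints of adjacent distinct observed scores
  plus one point beyond each extreme; ties in accuracy break toward
  higher specificity, then toward fewer positive calls. If only the
  all-positive cutoff preserves NPV = 100%, it is returned flagged with a
  warning rather than silently.
* DeLong CIs are normal-approximation, truncated to [0, 1]; the test
  against AUC = 0.5 is two-sided. With perfect separation the variance
  estimate is 0 and the p-value is reported as 0/1 by the sign of the
  difference rather than as 0/0.
* The power computation is the one-sided one-sample proportion test under
  the normal approximation without continuity correction; only the
  "at least 90% at n = 44" design property is asserted, since the exact
  software convention behind finer printed figures is unknowable.
* Complete separation in the logistic model is detected (fitted
  probabilities numerically 0/1, or non-convergence) and flagged instead
  of reporting spurious finite estimates.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
brute-force voxel-centre membership on small random volumes; an O(n²)
pairwise-concordance AUC; an exhaustive cutoff scan; a stratified
bootstrap of the paired AUC difference (10⁴ resamples); the step-up FDR
definition; and a published DeLong implementation (pROC) as an external
cross-check. Cohort-level checks use 54-patient runs at the default grid
and a 200-patient run at 48 × 48 × 64, for which the pipeline AUC is
required to land within three standard errors of the design AUC computed
by numerical integration of the two truncated normal Δ distributions —
that run uses a low background (0.3 SUV) and low noise so measured Δ is
an essentially unbiased estimate of true Δ; with the default background
of 1.0, a complete responder's measured SUVmax2 floors at background
level, which compresses extreme Δ values (a real phenomenon, but one that
would conflate measurement bias with statistical recovery in that test).

## Known limitations

* No partial-volume correction; SUVmax of small lesions on real scans is
  underestimated in ways the phantom does not model.
* No connected-component pruning by default (every supra-threshold voxel
  in a mask counts); a 6-connectivity option exists (`connected = TRUE`)
  but is off, matching the isocontour-within-mask definition.
* The bsa scheme's threshold/unit mismatch is reproduced by design, not
  resolved.
* TLG is defined with SUVmean (TLG = SUVmean × MTV); a SUVmax-based
  product can be formed from the records but is not a report column,
  since only the SUVmean-based definition is well specified.
* AUC p-values under near-perfect separation are astronomically small and
  should be read as "separation on this phantom", not as calibrated
  evidence; the FDR family is whatever set of parameters one run
  evaluates.
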