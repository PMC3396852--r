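---
title: "Fiducial co-registration and stereotactic targeting accuracy with stereofid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial co-registration and stereotactic targeting accuracy with stereofid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereofid)
```

## The problem

MRI-guided stereotactic implantation plans a target on a pre-operative
scan, implants a fine cannula, and verifies placement on a post-operative
scan. The two scans live in different coordinate frames, so the planned
target cannot be compared with the measured cannula tip until the frames
are co-registered. An arc carrying nine spherical fiducial markers, fixed
rigidly to the head holder and visible in both scans, provides the
landmarks for that co-registration. `stereofid` implements the full
quantitative chain: marker localization, correspondence, closed-form
registration, target mapping, and cohort error statistics, together with
a synthetic-data generator that makes every stage testable against known
ground truth.

All coordinates are world millimetres; the axis convention is
x = sagittal, y = coronal, z = axial.

## The registration model

Let $F_1 = \{p_i\}$ and $F_2 = \{q_i\}$ be the fiducial centres measured
in the pre- and post-operative scans, in corresponding order. The scans
are related by a similarity transform — rotation $R$ (3 d.o.f.),
translation $t$ (3 d.o.f.) and optionally an isotropic scale $s$ (1
d.o.f.) — and `horn_register()` finds the global minimizer of

$$ E(R, t, s) = \sum_i \lVert q_i - (s\,R\,p_i + t) \rVert^2 $$

in closed form via unit quaternions: after centering both sets, the
optimal rotation is the principal eigenvector of the symmetric
$4 \times 4$ matrix built from the cross-covariance of the centered
sets; translation and scale then follow analytically. No iteration or
initialization is involved, so there are no convergence or local-minimum
failure modes. Three non-collinear fiducials (nine scalar constraints)
are the identifiability minimum; using nine markers averages localization
noise down by roughly $\sqrt{3}$ relative to three.

Two details are worth making explicit:

* **Scale estimator.** With `with_scale = TRUE` the default
  (`scale_method = "least_squares"`) uses
  $s = \sum_i \langle q_i', R p_i' \rangle / \sum_i \lVert p_i'
  \rVert^2$ on the centered sets, which is the exact minimizer of
  $E$ and therefore the estimate consistent with treating $F_1$ as the
  space being mapped. The symmetric alternative
  $s = \sqrt{\sum \lVert q_i' \rVert^2 / \sum \lVert p_i' \rVert^2}$
  (`scale_method = "symmetric"`) treats the two scans interchangeably
  and is independent of the rotation; it gives a marginally larger
  residual on noisy data. The two coincide exactly on noiseless scaled
  data, and for same-scanner pre/post pairs both sit within noise of
  $s = 1$. `with_scale = FALSE` forces $s = 1$ exactly.
* **Residual statistic.** The fiducial re-positioning error is the
  residual misfit after optimal registration. The quadratic form is
  $e^2 = \sum_i (\Delta x_i^2 + \Delta y_i^2 + \Delta z_i^2)$, a *sum*
  over fiducials, but as an "average re-positioning error" it is most
  naturally read per fiducial; `residual_e` is therefore the
  root-mean-square per-fiducial distance (fiducial-count invariant),
  with the raw sum of squares exposed as `residual_ss` so both readings
  are available. The same duality applies to repositioning-trial
  ensembles, where `simulate_repositioning_trials()` reports both the
  arithmetic mean and the RMS of per-trial residuals.

Euler angles are reporting plumbing only: the fixed convention is
intrinsic $R = R_x(\alpha) R_y(\beta) R_z(\gamma)$, chosen once and
stamped into every transform JSON (`convention` key). At gimbal lock
($|\beta| = \pi/2$), where only $\alpha \pm \gamma$ is determined,
`decompose_rotation()` returns the canonical representative with
$\alpha = 0$.

Degenerate geometry is detected on the centered pre-operative set: if
the second-smallest singular value falls below $10^{-6}$ times the
largest, the fiducials are treated as collinear and registration is
refused — the rotation about the common line would be unidentifiable.
The quaternion eigenvector's sign ambiguity is fixed by requiring a
non-negative scalar component (ties broken toward the first non-zero
component positive), making results deterministic.

## Marker localization and correspondence

`detect_fiducials()` thresholds the volume, labels supra-threshold
voxels into 26-connected components (compact spheres do not split under
the looser connectivity, even as thin partial-volume shells), discards
components below 3 voxels (single-voxel noise), and returns
intensity-weighted centroids. Weights are intensities minus the
background level, estimated as the median of sub-threshold voxels; this
makes centroids invariant to a constant background offset (with the
threshold shifted accordingly). Partial voluming is the reason for
weighting: a 2.5 mm sphere on a 0.575 × 0.575 × 0.8 mm grid appears
slightly oval, but the mixed voxel intensities are proportional to the
in-sphere volume fraction, so the weighted centroid recovers the true
centre to a few hundredths of a millimetre.

The cannula tip appears as a small *hypointense* volume; `locate_tip()`
splits a spherical region of interest with Otsu's threshold, takes the
darker class's largest 26-connected component, and returns its
*unweighted* geometric centroid — the centre of the dark volume is the
defined tip location, with no intensity model attached to it. A uniform
ROI has no Otsu split and raises a tip-not-found error.

`match_fiducials()` restores reference ordering: after aligning the
centroids of the detected and reference sets (removing any gross
translation), it solves the exact minimum-total-squared-distance
one-to-one assignment. No installed package exposes a linear-sum
assignment solver, so a small $O(n^3)$ Hungarian implementation is kept
internal; it is tested against exhaustive enumeration. Any matched pair
farther than a 10 mm gate (configurable) raises an ambiguous-match
error rather than silently mis-corresponding; with tens of millimetres
between arc markers and sub-millimetre localization noise, mismatches
are effectively impossible.

## Targeting accuracy and cohort statistics

`map_planned_target()` carries a planned target through the fitted
transform; `target_error()` takes the difference
`delta = tip - planned_postop` (signed, positive = overshoot along the
positive axis) and its Euclidean norm. Published tables print per-axis
magnitudes, so rendered reports use absolute values; the Euclidean error
is unaffected by that convention.

`cohort_summary()` rounds each record's Euclidean error to the 2-decimal
reporting precision *before* averaging, and uses the sample ($n-1$)
standard deviation of the same rounded values. This matches the
arithmetic of a report whose per-record cells are printed at 2 d.p.: for
the shipped twelve-implantation porcine cohort the rounded-column mean
is 0.623 mm whereas the unrounded mean is 0.625 mm, and only the sample
(not population) SD reproduces 0.33 at 2 d.p. Unrounded summaries are
exposed alongside (`mean_unrounded_mm`, `sd_unrounded_mm`). A cohort of
one reports its SD as `NA`, never 0. `build_accuracy_table()` renders
the deterministic report: coordinates at 1 d.p., errors at 2 d.p., and
a caption line with the cohort mean and SD.

The shipped cohort (`porcine_cohort()`) carries planned target
coordinates and per-axis error magnitudes only — tips are reconstructed
as `planned + error`, which is exact for every derived statistic because
the Euclidean error depends only on the magnitudes.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* `fiducial_arc()` — the fixed nine-marker arc geometry (sagittal
  coordinates relative to marker 5, coronal to the arc back, axial to
  the arc base). Its asymmetric layout makes correspondence unambiguous.
* `simulate_scan_pair()` — both scans' fiducial coordinates under a
  known ground-truth motion, each perturbed by independent i.i.d.
  per-axis Gaussian localization noise. No noise model is implied by the
  physics alone; i.i.d. Gaussian is the standard reduced model for the
  combined scanner/partial-volume/search-routine error, and an
  anisotropic per-axis sd (e.g. larger along the coarser 0.8 mm axis)
  is available via a length-3 `noise_sd`. The default
  `noise_sd = 0.1` mm is a plausible sub-voxel localization error on a
  half-millimetre grid and puts 30-trial repositioning means near the
  0.2 mm scale — a plausibility anchor, not a fitted value.
* `rasterize_spheres()` — partial-volume rendering: each voxel's
  intensity interpolates background→foreground by the fraction of the
  voxel inside any sphere, estimated with a fixed 3 × 3 × 3 sub-voxel
  sampling (deterministic, cheap, and accurate to ~1% in total sphere
  volume at the default grid; the residual discretization is exactly
  the partial-volume effect the detector must cope with).
* `simulate_tip()` — per-axis Gaussian tip displacement; the Euclidean
  error then follows a chi distribution with 3 d.o.f. (mean
  $\sigma\sqrt{8/\pi}$), which supplies a closed-form check on the
  accuracy statistics.
* `ced_ramp_regime()` / `total_infusion_volume()` — the ramped
  convection-enhanced delivery schedule (0.5, 1, 2.5 µl/min for 5 min
  each, then 5 µl/min for 20 min; 120 µl total).

Every stochastic operation is a pure function of its inputs and an
integer seed (the caller's RNG stream is left untouched); trial $k$ of
an ensemble uses `seed + k - 1`.

What the generator does *not* emulate: MR contrast physics, intensity
inhomogeneity, motion artefact, infusate transport, or any systematic
(non-zero-mean) localization bias. Passing tests therefore demonstrate
the correctness of the geometry, statistics and detection algorithms
under the stated noise model — not robustness to artefact-laden clinical
data.

## Numerical choices and problem sizes

* Rotation validity is enforced at $10^{-9}$ (orthonormality and
  determinant); noiseless synthetic pairs must be recovered to
  $10^{-8}$ in every parameter.
* The closed form is cross-checked against two independent oracles: a
  multi-start (≥ 20 random starts) iterative least-squares fit over
  $(\alpha, \beta, \gamma, t, s)$, which it must never lose to, and an
  SVD-based (Kabsch) registration, with which it must agree pairwise to
  $10^{-8}$ on noisy ensembles.
* Monte-Carlo checks use 500-trial ensembles for the noise-scaling law
  (mean residual at $2\sigma$ vs $\sigma$ within $[1.8, 2.2]$),
  120-trial ensembles for rotation-recovery monotonicity, 1000 trials
  for correspondence robustness, and $10^4$ draws for the chi-mean
  check at 2% tolerance. These sizes keep each statistic's sampling
  error an order of magnitude below the tolerance it is tested at while
  keeping the full suite fast.
* Volumes in tests are a few million voxels at most; detection on the
  full rasterized arc runs in well under a second.

## Command-line interface

The installed script `exec/stereofid` wraps the pipeline for shell use:

```
stereofid simulate --output-dir sim --seed 42 --noise-sd 0.1 --volume
stereofid localize --volume sim/f2_volume.nii.gz --threshold 50 --count 9 --out sim/detections.csv
stereofid register --pre sim/f1_fiducials.csv --post sim/f2_fiducials.csv --out sim/transform.json
stereofid evaluate --plans plans.csv --tips tips.csv --transform sim/transform.json --out report.csv
```

Machine outputs (CSV, JSON, NIfTI) go to files at full double precision;
human-readable logs go to standard error; display rounding (1 d.p.
coordinates, 2 d.p. errors) is applied only in rendered reports.

## Known limitations

* Registration is point-based, similarity-only: no weighted points, no
  deformable or intensity-based registration, no ICP for unknown
  correspondence beyond the assignment gate.
* NIfTI axis orientation is taken as stored; volumes from other sources
  should be reoriented before use.
* The detector assumes bright, well-separated, roughly spherical
  markers; it is not a general blob detector and has no bias-field
  correction.
* Repositioning-error ensembles characterize the *statistical* behaviour
  of the residual under the assumed noise model; they cannot attribute
  error between scanner, hardware repositioning and localization
  components.
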