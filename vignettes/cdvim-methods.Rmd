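---
title: "Connectivity-defined Vim localisation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-defined Vim localisation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The ventral intermediate nucleus (Vim) of the thalamus is targeted in tremor
surgery but cannot be seen on conventional MRI. Because it occupies a fixed
station on the dentato-thalamo-cortical pathway (DTCp), the region can instead
be defined by connectivity: reconstruct the DTCp with probabilistic
tractography, intersect it with a thalamic mask, threshold, and take the
centroid. This vignette documents how `cdvim` implements each stage, which
parameters matter, and where genuine design freedom was resolved by a choice
of ours rather than by an external constraint.

## 1. The synthetic phantom

Every quantitative claim in the package is exercised on synthetic subjects
with *known* anatomy, so correctness can be checked against ground truth
rather than against another tractography implementation.

**Geometry.** The world frame is RAS (x right/ML, y anterior/AP, z
superior/SI) with the origin at the mid-commissural point; the default grid is
64³ voxels at 1.25 mm isotropic — the resolution class of modern
high-angular-resolution diffusion protocols. Each hemisphere's DTCp is a tube
around a smooth skeleton interpolated (natural cubic spline over chord
length) through fixed control points: an M1 patch at (∓20, −8, 30), a
straight transit through the thalamic box centred on the canonical Vim at
(∓13.75, −6.25, 2.5), a descent to the decussation (the skeleton crosses the
midline exactly once, at z ≈ −18), a narrow superior-cerebellar-peduncle
(SCP) waist on the contralateral side (z ∈ [−23, −19]), and a cerebellar
blob at (±17, −18, −28). The transit segment through the thalamus is built
from three collinear control points centred on the Vim, so the voxelised
tube-thalamus intersection is point-symmetric about the true centroid; this
is what makes "centroid of the intersection" a sharp ground truth (recovered
within half a voxel in the tests).

**Tube and SCP waist.** The tube is rasterised as a union of balls along the
dense skeleton (sample spacing 0.4 mm). The main radius is 2.5 mm; inside
the SCP band the radius is `scp_width_vox`·1.25/2 mm (default diameter two
voxels, matching a structure "a few voxels wide"), with a linear taper over
2 mm on either side. The SCP mask is the tube restricted to the band, so its
voxel volume scales with the square of the configured width — the property
the bottleneck analysis relies on.

**Fibre field.** Each tube voxel carries one fibre population whose mean
direction is the tangent of the nearest skeleton sample, with volume fraction
0.45 and angular dispersion 8° by default. Where the two pathways cross at
the decussation a voxel carries both populations; 0.45 was chosen so that
crossing voxels respect the "fractions sum to ≤ 1" constraint of
ball-and-sticks-style models. Dispersion is modelled as a Gaussian
perturbation of the polar angle about the mean with uniform azimuth — the
simplest sampler with one interpretable parameter. 8° gives realistic
behaviour (most streamlines survive, a visible minority is lost at the SCP
waist); 0° makes the tracker fully deterministic, which the recovery tests
exploit. The phantom emits orientations directly: **no diffusion signal, no
b-vectors, no model fitting** — the field stands in for the output of a
multi-fibre fit, and nothing downstream can tell the difference.

**Masks.** Besides seed/waypoint masks (M1, thalamus box of ±5 mm,
cerebellum), each pathway gets the two canonical exclusion regions of
decussating-tract protocols — contralateral cerebrum (|x| ≥ 5 mm on the wrong
side, z ≥ 5) and ipsilateral cerebellum (wrong side, z ≤ −20) — plus a CSF
termination box placed anterior-superior of the tract, explicitly made
disjoint from tract voxels. These exclusions are not decorative: with two
crossing tubes, a small fraction of streamlines genuinely switches tract at
the decussation (the kissing/crossing error of real tractography) and climbs
the contralateral pathway; the contralateral-cerebrum mask is what rejects
them.

**Subjects.** Between-subject variability is a per-hemisphere rigid jitter of
the whole pathway (control points, thalamus box, M1 and cerebellar ends
together — the phantom's anatomy stays self-consistent), drawn per axis from
N(offset, `jitter_sd`²). The default SDs (1.2, 1.3, 1.5) mm per axis are in
the range reported for tractography-defined Vim centroids in adult cohorts;
the hemispheric mean offsets default to zero (symmetric anatomy), and
systematic asymmetry can be injected through them. Because the magnitude of
true anatomical jitter versus measurement noise is not separable from
published group tables, both are exposed as free parameters rather than
asserted. Test-retest pairs share the subject-level jitter and add
independent within-scan noise (default SD 0.5 mm per axis), which must not
exceed the between-subject SD — the regime in which test-retest reliability
is a meaningful question. Five confounds are drawn per subject (movement
surrogates log-normal; M1, cerebellar and total intracranial volumes normal,
the latter centred on 1.42 L ± 0.14); they are independent of the jitter
unless `confound_coupling` explicitly correlates M1 volume with the ML
jitter, which the null-calibration tests use. The Jacobian-determinant field
is 1 everywhere with a configurable multiplicative bump (default 1.2) inside
the SCP masks, isolating the volumetric integration step.

`sample_cohort()` and `sample_test_retest_pair()` accept `truth_only = TRUE`
to return ground truth without building volumes; statistical studies that
never run the tracker use this to stay fast and small in memory.

## 2. Probabilistic tracking

The tracker (Rcpp) propagates bidirectional streamlines from the centre of
every seed voxel:

* **Orientation sampling.** At each step the voxel containing the current
  point is looked up (nearest-voxel, no interpolation — a documented
  simplification; with ≥ 2-voxel-radius tubes the bias is far below the
  half-voxel acceptance scale). On the first step a population is drawn
  proportionally to volume fractions; afterwards the population above the
  fraction floor (default 0.05) maximising |⟨mean, previous⟩| is used —
  mirroring how multi-fibre trackers follow the compatible compartment
  without re-implementing posterior sampling. The mean is perturbed by the
  population's dispersion and sign-aligned with the previous direction.
* **Gating.** A step is kept only if cos(previous, new) ≥
  `curvature_threshold` (default 0.2 ≈ 78.5° permitted bend, the convention
  of the reference tool); violating it rejects the whole streamline.
  Entering any exclusion mask rejects; entering the termination (CSF) mask
  ends that half-track; leaving the grid, exhausting `max_steps` (2000) or
  finding no population ends it silently. A streamline is **accepted** iff
  the full track visited every waypoint mask.
* **PICo maps.** The raw map value of a voxel is the fraction of all
  launched streamlines that were accepted and visited it (counted once per
  streamline). The reference protocol reports streamline counts; a fraction
  is the same quantity up to the global scale, which cancels in the combined
  normalisation. The two seeded runs per pathway (M1-seeded with
  contralateral cerebellum + ipsilateral thalamus waypoints; cerebellum-
  seeded with the mirror-image waypoints) are summed and divided by the
  maximum of the sum, so the combined DTCp map has maximum exactly 1; the
  divisor is kept as `raw_max`, the quantity correlated against SCP volume.

Defaults: step 0.5 mm, 250 samples per seed voxel. The protocol value of
5000 is available by configuration; the suite verifies that 250- and
5000-sample maps agree voxelwise within binomial bounds, which is why the
smaller default is the working scale. All randomness flows through R's RNG:
`set.seed()` makes every map, and hence the whole pipeline, bit-reproducible.

## 3. cd-Vim localisation

The normalised DTCp map is restricted to the thalamic mask (elementwise
product). An all-zero intersection — no accepted streamline reached the
thalamus — raises a classed condition (`cdvim_no_connectivity`); the cohort
driver catches it, excludes that subject-hemisphere, logs it and continues.

The **adaptive threshold** keeps voxels ≥ 20 % of the intersection maximum
(`≥`, so the maximal voxel always survives and the ROI is never empty).
Being relative, it is invariant to any positive rescaling of the map — a
property tested bit-for-bit — and avoids the bias of absolute PICo cut-offs
toward high-anisotropy regions.

The **centroid** is taken over the largest 26-connected component
(26-connectivity because probabilistic maps connect diagonally), as the
unweighted mean of 0-based voxel centres mapped through the voxel-to-world
affine. Unweighted was chosen because it is insensitive to map
normalisation; a PICo-weighted variant sits behind `weighted = TRUE`. Size
ties are broken by the higher mean intersection value. The ROI volume is
reported post-threshold (foreground count × voxel volume), with the
pre-threshold positive-intersection volume emitted alongside, since either
reading of "intersection ROI volume" is defensible.

One numerical convention runs through everything: the affine maps integer
voxel indices to voxel *centres*, so the voxel containing a continuous point
is the nearest integer under the inverse affine. The phantom, the tracker
and the centroid all share it; mixing centre and corner conventions would
shift results by half a voxel, which is exactly the acceptance scale.

## 4. The atlas target

From AC and PC the surgical coordinate is AP = PC + (L/3 − 2) mm along
PC→AC (L the AC-PC length), ML = ±12.5 mm off the midline (the conventional
12–14 mm range is warned about when overridden), SI = 0 in the AC-PC axial
plane. For landmarks that are not axis-aligned the target is built in a
local frame — AP axis along PC→AC, SI axis the component of world +z
orthogonal to it, ML completing the right-handed frame — and mapped back.
How SI = 0 should be defined for a tilted AC-PC plane is not standardised;
this local-frame convention is our choice, and the tests pin it down via
rotation equivariance. L ≤ 6 mm would place the target behind PC and is
flagged.

## 5. The statistics suite

All tests return a uniform row (statistic, df, p, tail, significance at the
applied α = 0.05 unless stated).

* **Displacements.** Per-axis absolute distances and the Euclidean distance
  (ED) of each centroid from a reference (cohort mean or atlas target);
  cohort summaries are RMS ED, maximum ED, and per-axis maximum absolute
  displacement — all translation invariant.
* **Hemispheric position.** Paired t-tests per axis, on |ML| (laterality,
  not sign) and signed AP/SI. Zero-variance differences are reported as
  exact offsets (p = 0 if nonzero, 1 if all zero) instead of dividing by
  zero.
* **Hemispheric variance (Pitman-Morgan).** For paired samples the ordinary
  variance-ratio F-test is invalid; with F = s₁²/s₂² and r the pair
  correlation, t = (F − 1)√(n − 2) / (2√(F(1 − r²))) on n − 2 df. This is
  algebraically the t-test of cor(x + y, x − y) = 0, which supplies an
  independent validation route: the suite checks the formula's p-values
  against a 10,000-draw permutation of the within-pair differences against
  the sums (agreement within 0.01 over 30 cases), and its type-I error is
  calibrated by simulation.
* **Atlas offsets.** One-sample t-tests of the signed per-axis differences
  (centroid − atlas) against zero; degenerate inputs reported exactly.
* **Confound screen.** Each of the four displacement metrics is regressed on
  each of the five confounds (simple linear regression, F-test): 20 cells
  per hemisphere. Significance is flagged at the conventional corrected
  level 0.007 *and* at the nominal 0.05/20 = 0.0025, because the two do not
  coincide and a reader should see both. A constant confound invalidates
  only its own cells.
* **Principal directions.** Eigendecomposition of the 3 × 3 centroid
  covariance, eigenvalues descending, eigenvector signs fixed (first
  non-negligible component positive) so runs are comparable.
* **SCP volumetrics.** Regional volume is the Jacobian determinant summed
  over the mask times the voxel volume; non-positive determinants inside the
  mask are an error, not a warning. The correlation with DTCp maximum raw
  PICo enforces the contralateral pairing (left DTCp ↔ right SCP), because
  the pathway decussates.
* **Test-retest.** Left-tailed Wilcoxon signed-rank on within-subject minus
  between-subject displacements per metric (AP, ML, SI, ED), reflecting the
  a-priori expectation that scan-rescan displacements are smaller. Zero
  differences are dropped (Wilcoxon's original treatment); the exact
  distribution is used for ≤ 25 nonzero differences and the normal
  approximation with continuity correction above. RMS ED of both arms is
  reported alongside.
* **Volume asymmetry.** Two-sided Wilcoxon signed-rank on paired left/right
  ROI volumes with medians reported — chosen over a t-test because volumes
  are skewed and medians are the natural summary; this choice is an
  assumption, not a convention.

A calibration helper, `type1_calibration()`, re-simulates matching nulls
(bivariate normal pairs with correlation 0.5 for the paired tests,
independent normals for the regression) and reports empirical rejection
rates; at 10,000 replicates and n = 100 all four implementations sit within
three binomial standard errors of 0.05.

## 6. Problem sizes and runtime envelope

The scales used by the shipped tests and the acceptance script are package
choices balancing statistical resolution against desk-scale runtime: 250
tracking samples per seed voxel (with one 5000-sample comparison run),
cohorts of 5 (noiseless recovery) and 100 (variance recovery) subjects,
10,000 replicates for type-I calibration, 20 repetitions per SCP width, and
100 simulated 44-pair cohorts for the test-retest direction. A 100-subject
tracked cohort completes in roughly 1.5 minutes on one CPU; the full
acceptance script in about 2.5.

## 7. What the phantom does and does not show

Passing on phantoms demonstrates that the *pipeline logic* is correct:
masks, gating, normalisation, thresholding, coordinate mapping and the
statistics do what they claim, and ground truth is recovered at sub-voxel
accuracy under controlled noise. It does **not** demonstrate performance on
real diffusion data: the phantom has a single smooth tube per hemisphere
(plus its mirror twin), no fanning, no partial-volume gradients, no
susceptibility distortion, no registration error beyond a rigid jitter, and
its fibre uncertainty is a one-parameter dispersion rather than a fitted
posterior. Absolute volumes and PICo levels are therefore not comparable to
in-vivo values (the phantom's median cd-Vim volume of ~50 mm³ reflects the
chosen tube and thalamus-box geometry, not thalamic anatomy). Claims that
transfer are the relative/structural ones: scale invariance, recovery,
monotonicity in the SCP width, calibration of the tests, and the
within-smaller-than-between test-retest direction.
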