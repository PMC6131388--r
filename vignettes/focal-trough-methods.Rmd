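---
title: "Deriving an average dental arch and panoramic focal trough: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving an average dental arch and panoramic focal trough}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `archtrough`, the parameters that
matter, the numerical choices made where the procedure left room, and what
the synthetic phantom does and does not establish about real data.

## The procedure and its assumptions

The pipeline estimates a cohort-average mandibular arch shape and, from it,
the geometry of a panoramic focal trough. Its core assumptions are:

* **Bimodality after confinement.** Otsu thresholding assumes a bimodal
  histogram of bone against everything else. Cone-beam CT violates this
  globally (soft tissue, shading, and bones other than the mandible), so
  the pipeline first removes the midface, anterior face, cervical
  vertebrae and temporal bone, and then thresholds each axial slice only
  within a mask propagated from the previous slices. Anatomy continues
  smoothly from slice to slice, so the propagated mask is a valid prior.
* **Operator landmarks are trustworthy up to a few millimetres.** Ten
  points drive the removals and the cohort alignment; their reliability is
  what the ICC statistics quantify. The pipeline never detects landmarks
  itself.
* **Bilateral symmetry of the trough.** A panoramic focal trough is built
  symmetric, so right and left measurements are pooled: every fitted curve
  is mirror-symmetrized about the midsagittal axis through the canine
  midpoint before smoothing.
* **Translation-only cohort alignment.** Subjects are superimposed by
  whole-pixel translation onto the canine midpoint, with no rotation or
  scaling: volumes are already orientation-standardized by the Frankfort
  reorientation, and avoiding scaling keeps the average arch metric (areas
  and thicknesses in mm) interpretable.

## Parameters, units, defaults

| parameter | default | unit | role |
|---|---|---|---|
| `vertebraMagnification` | 1.5 | — | scaling of detected vertebral regions before removal; generous so the removal covers halo voxels |
| `maskMagnification` | 1.2 | — | scaling of the propagated binarization mask; allows ~20% slice-to-slice drift |
| `condyleEllipse` | 15 × 21 | mm | anteroposterior × superoinferior axes of the condylar removal ellipse |
| `toothLength` | 20 | mm | average tooth length; depth of the occlusal band used for vertebra detection and the dental projection band |
| `kPrevSlices` | 3 | slices | how many previous binary slices feed the propagated mask |
| `thresholdGridStep` | 0.01 | — | candidate grid for the area-matched average-arch threshold |
| `splineSmooth` | 0.02 | — | smoothing parameter *p* in *p·Σr² + (1−p)·∫f″²* |
| `thicknessStep` | 1 | mm | arc-length sampling of the thickness profile |

All are overridable per run (`pipelineConfig()`, or the YAML config of the
command-line wrapper).

**Why `splineSmooth = 0.02`.** In the csaps-style objective the equivalent
smoothing kernel bandwidth is $((1-p)/p)^{1/4}$ in units of the sample
spacing. The centerline is sampled at ~1 mm, and its dominant error is the
half-pixel staircase of a skeleton extracted from a ~1 mm grid. A *p* near
1 (bandwidth well under a pixel) passes that jitter straight into the
first and second derivatives that the transition step consumes; *p* = 0.02
gives a ~2.6 mm bandwidth — several pixels, but an order of magnitude
below the ~10 mm scale of the arch-to-ramus bend it must preserve. The
sensitivity is mild between roughly 0.005 and 0.1; the value is exposed
precisely because the original procedure does not state one.

## Numerical choices and degenerate inputs

* **Intensity normalization** is the affine map $(x-\min)/(\max-\min)$,
  exactly spanning $[0,1]$; a constant volume is an error. The map is
  idempotent, so re-running the pipeline on an already-normalized volume
  is harmless.
* **Otsu threshold**: 256 equal bins on $[0,1]$, threshold = the bin edge
  maximizing between-class variance, ties toward the lower edge. A
  single-occupied-bin histogram errors at the API level; inside the slice
  loop it degrades to an all-background slice instead, because empty
  slices are normal at the stack ends.
* **Propagated mask**: the union of the support of the summed previous
  slices and its 1.2×-magnified copy. Pure similarity scaling about the
  centroid was considered and rejected: a U-shaped band is not star-shaped
  about its centroid, so its scaled copy shifts outward by ~0.2× its
  centroid distance and fails to cover the band's inner half — in pipeline
  runs the propagated mask then erodes the segmentation to near-zero
  within a few slices. The union restores the invariant a propagated mask
  must satisfy (it contains what generated it) while keeping the
  magnification semantics. If every previous slice is empty, the slice
  falls back to unmasked Otsu.
* **Vertebra rule**: components of the occlusal-band MIP other than the
  largest, with centroid posterior to the largest's centroid. Anterior
  blobs are deliberately not removed — the rule is logged, and anything
  anterior is assumed to be mandible-adjacent anatomy.
* **Condylar stop plane**: the most inferior Z of the removed ellipses
  (center minus half the 21 mm axis). The alternative — the clicked point
  itself — would leave 10.5 mm of temporal bone in the stack; the
  inferior-edge rule guarantees the binarization never enters the removed
  region.
* **Centerline**: Zhang–Suen thinning, then iterative pruning of spur
  branches shorter than 5% of total skeleton length, then the skeleton's
  weighted diameter path. Thinning leaves one-pixel staircase duplicates;
  the "single dominant path" check therefore measures how far residual
  branches *stray* from the main path rather than counting off-path
  pixels. The trough center is subsequently **refined to the boundary
  mid-curve**: the skeleton is accurate only to about half a pixel, while
  the bilinear mask-edge crossings along the center normals are sub-pixel,
  so the midpoint of the buccal and lingual crossings replaces the
  skeleton estimate before the final fit.
* **Boundary correspondence** is by center-normal intersection, matching
  the straightened-center construction of the thickness profile; samples
  closer to the path ends than half the local thickness are dropped (the
  skeleton is biased by the square-cut ends there), and a normal failing
  to hit both contours at more than 5% of samples is an error.
* **Area-matched threshold**: candidates step, 2·step, …, 1; ties broken
  toward the candidate nearest 0.5 — the value the threshold approaches as
  the cohort grows — then toward the lower candidate.
* **Transition detector.** With the center of one side written as lateral
  offset $x(u)$ against the posterior coordinate $u$, the procedure's
  defining property is that $d^2x/du^2$ is nonzero along the dental arch
  and vanishes on the straight ramus. The *argmax* of $|d^2x/du^2|$ is not
  a usable estimator of the joint: for any convex arch (including the
  parabola-plus-line geometry of the phantom) that magnitude decreases
  monotonically toward the ramus, so its maximum sits at the anterior end
  of the domain, not at the bend. The transition is therefore located as
  the *onset of the vanishing-second-derivative segment*, by segmented
  least squares: $x(u)$ is fit by a line plus a one-sided quadratic hinge
  $c_2\,(u_T-u)_+^2$ (the leading term of any smooth curve departing from
  a straight segment), the hinge's quadratic growth clipped beyond a
  window of 25% of the posterior extent (with a slope-matched linear
  continuation) so the local expansion is not stretched over the whole
  arch, and the changepoint $u_T$ minimizing the full-range residual is
  the transition. All tolerances are relative to the posterior extent, so
  the slope is scale-free and the location scales linearly under uniform
  scaling. A center that a single line explains to within 0.3% of the
  posterior extent has no transition and errors. The slope is
  $\arctan|dx/du|$ of the straight segment, in degrees against the
  midsagittal axis.
* **ICC form**: two-way random effects, absolute agreement, single
  measures — ICC(2,1). Absolute agreement is the right form for
  coordinate reproducibility because a systematic offset between raters
  is a real disagreement about where a landmark is; the choice is fixed
  and documented in the function.

## The synthetic phantom

`generatePhantom()` renders, at spacing 1.2 mm on a 128³ grid (a 154 mm
field of view), a parabolic arch band $x = \pm b\sqrt{y'/a}$ with anterior
half-depth $a$ = 25 mm and half-width $b$ = 30 mm, joined with continuous
tangent to straight rami at $\theta$ = 40° from the midsagittal axis
(giving a closed-form joint at $x_t = b^2/(2a\tan\theta)$), a 12 mm band
width, a 20 mm body below the occlusal plane, rami rising 35 mm to 7 mm
condylar knobs, soft tissue (0.15) inside an elliptic cylinder, a
posterior vertebral cylinder and a cranial slab at bone intensity (0.85)
over background 0.05, a smooth multiplicative polynomial bias field of
amplitude 0.1, and Gaussian noise of s.d. 0.02. These are one realistic
adult-scale operating point, chosen once: arch dimensions and the gonial
flare angle sit in the adult range, and the 2:1-plus bone/soft contrast
with 10% shading mimics uncalibrated CBCT gray values. Cohorts perturb the
five shape parameters (arch depth and half-width, ramus angle, band width,
ramus length) by independent Gaussians (default 5% relative s.d.),
truncated to geometric validity.

The phantom's true landmarks are placed so the landmark-driven removal
lines actually separate its structures: the coronal cut runs just above
the condylar knobs (below the cranial slab), and the sagittal occlusal
line is tilted upward posteriorly so that it removes the anterior face
region while sparing the ascending ramus — in a real head the operator
achieves the same separation by eye. The occlusal plane height used for
band placement is taken from the anterior occlusal landmark.

What passing on phantoms does **not** show: the phantom has no individual
teeth (the dental band is a uniform envelope — the algorithm operates on
the arch envelope, so per-tooth structure is irrelevant to its geometry
but does sharpen real histograms), no metal artifacts or scatter, an
analytic (not anatomical) arch, and operator-free, error-free landmarks.
Recovery on phantoms validates the geometry and the segmentation
machinery, not clinical accuracy on patient CBCT; the published
cohort-level reference values (a 0.91 dice against manual segmentation,
the 0.49 threshold against a 2413.30 mm² mean area, the 37.25/37.03 mm
and 41.24° transition, the 13.09/19.25 mm minima) derive from a
30-patient dataset that is not redistributable and are carried as
documentation, not as test surfaces.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
128³ × 1.2 mm volumes, cohorts of 10 subjects at 5% variability, a
half-annulus boundary-recovery case at 0.5 mm pixels, and 1000-histogram
threshold comparisons; these sizes resolve the 12 mm band with ten pixels
across it and keep a complete cohort run in tens of seconds. Finer grids
sharpen the skeleton and the transition estimate but change no defaults.

## Known limitations

* Readers support axis-aligned orientations (permutations and flips);
  oblique acquisitions must be resampled upstream.
* The vertebra rule keys on "posterior to the largest component"; a
  pathology that splits the mandibular arch into two comparable components
  in the occlusal band would confuse it (the run log records every removed
  component).
* The transition estimator assumes a genuinely straight ramus segment over
  the posterior quarter of the center; an arch that curves continuously to
  its posterior end reports either no transition or an
  anterior-biased one.
* Cohort averaging assumes comparable pixel spacing across subjects;
  mixed-resolution cohorts must be resampled first (the superimposition
  refuses mixed spacing rather than resampling silently).
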