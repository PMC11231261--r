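---
title: "Quantifying paternal mitochondrial elimination: models, parameters and design choices"
author: "pmequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paternal mitochondrial elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

After a *Drosophila* egg is fertilized, the sperm contributes a single
giant mitochondrion — the mitochondrial derivative (MD) — that runs the
length of the ~1.8 mm flagellum alongside a microtubule axoneme, both
wrapped in the sperm plasma membrane. The egg eliminates the MD within
hours (paternal mitochondrial elimination, PME) while sparing the
axoneme, by wrapping flagellar segments in vesicular sheaths derived
from egg multivesicular bodies (MVBs). Studying this process rests on a
handful of image-derived quantities:

* **MD-elimination kinetics** — how fast the fluorescent MD signal
  decays over 0–3 h after egg laying (AEL) in 2D time-lapse images;
* **distance-shell (envelope) profiles** — how much punctate signal
  (e.g. Atg8a) sits at each distance from the segmented axoneme in 3D;
* **membrane/axoneme volume ratio** — how much sperm plasma membrane
  still touches the axoneme;
* **vesicle colocalization** — what fraction of primary-marker vesicles
  also carry a secondary marker, with envelope-based background
  correction, plus pooled Pearson and Manders coefficients;
* **MVB-fraction proteomics enrichment** — abundance filtering and
  fold-change listing of the vesicle proteome.

pmequant implements each of these as pure functions over a validated
`image_stack` container, and pairs them with a synthetic-scene generator
whose ground truth makes every stage testable at desk scale.

## The kinetics statistic

For each frame, the egg is segmented on the brightfield channel by a
trainable random-forest pixel classifier, eroded by 15 px (Euclidean
distance, so a 40 px-wide feature survives as its 10 px core) to avoid
edge artifacts, and cleaned of small non-egg components (default floor:
5% of the largest component, a scale-free choice since no absolute
number is published). The MD channel is background-subtracted by a
rolling ball and thresholded at a fixed raw-scale value. The normalized
MD intensity is

$$\mathrm{NMI} \;=\; (\bar I_{\mathrm{pos}} - \bar I_{\mathrm{neg}})
\cdot \frac{A_{\mathrm{pos}}}{A_{\mathrm{egg}}},$$

the mean intensity difference between MD-positive and MD-negative egg
pixels, weighted by the positive area fraction. Two degenerate cases
are defined explicitly (the source assay is silent on them): no pixel
above threshold gives NMI = 0, and an all-positive egg takes the
negative mean as 0. Both choices keep NMI continuous and non-negative.

Key parameters (`analysis_config()`), all on the raw 16-bit camera
scale where applicable:

| parameter | default | meaning |
|---|---|---|
| `threshold_md` | 1200 a.u. | fixed MD cutoff (alternate-microscope dialect: 250) |
| `erosion_px` | 15 px | Euclidean egg-mask erosion |
| `rolling_ball_radius_px` | 35 px | disc radius of the background opening |
| `shell_count`, `shell_width_um` | 10, 1 µm | envelope geometry |
| `object_filter_fraction` | 0.40 | smallest-objects pre-filter |
| `vesicle_min_volume_um3` | 15 µm³ | vesicle volume floor |
| `guard_um`, `background_um` | 0.2, 0.3 µm | vesicle envelopes |
| `md_guard_um`, `md_background_um` | 0.5, 1.0 µm | MD-proximal envelopes |

The original assays describe the background step as a rolling ball
with a *sigma* of 35 pixels, conflating a Gaussian parameter with a
ball radius. We implement a grayscale morphological opening with a
flat disc of radius 35 px (the parameter Fiji's *Subtract Background*
takes), and expose an optional Gaussian pre-smooth
(`rolling_ball_presmooth_sigma`) covering the other reading. Opening is computed on intensities
normalized by the image maximum — grayscale morphology commutes with
positive scaling, and the underlying library clips values above 1.

The unknown image bit depth is handled as a configuration decision, not
a fact: the 1200/250 cutoffs are interpreted on the raw 16-bit-class
camera scale, and all pipelines work in floating point internally.

Decay rates are estimated per egg by least squares on
$I_0 e^{-kt}$ (Levenberg–Marquardt, log-linear start). A constant
series returns $k = 0$ exactly; an all-zero series is an error rather
than a silently arbitrary rate.

## Distance shells and envelopes

All physical distances are voxel-center Euclidean distances computed by
an exact separable distance transform that takes per-axis spacing, so
anisotropic confocal stacks (e.g. 0.25 × 0.25 × 0.5 µm) are handled
without resampling. Shell *k* around a reference mask holds the voxels
at distance in $((k-1)w,\; kw]$; the reference itself is excluded.
Binning decisions are made on squared distances, so voxels landing
exactly on a shell boundary are classified exactly, and the whole
partition equals a brute-force all-pairs enumeration on every grid we
test. Shells truncated by the image border use their truncated volumes
in normalization — the alternative (idealized volumes) would bias
profiles downward at egg margins.

The smallest-40% object pre-filter is described in two ways that are
inconsistent in general — as removing the smallest 40% of *objects*,
and as leaving 60% of the total *volume*; the two coincide only for
particular volume distributions. We take the count rule as primary — remove the
$\lfloor 0.4\,n\rfloor$ smallest objects, ties broken by label order —
and report the realized retained-volume fraction alongside.

Object-to-shell assignment is voxel-wise, not centroid-based: an object
spanning two shells contributes its voxels to each, which matches a
"total volume within an envelope" definition and conserves total volume
exactly (a property the tests assert).

"Touching the axoneme" (membrane assay) has no published distance; we
use one-voxel 26-connectivity adjacency as the minimal reading, with a
physical `touch_um` override available.

The vesicle assay's background envelope is stated with a thickness of
300 µm, which cannot fit inside a ~200 µm egg; we read it as 300 nm,
consistent with its 200 nm guard envelope, and keep it configurable.

## Vesicle positivity and pooled colocalization

Each segmented vesicle (≥ 15 µm³) is measured against two envelopes: a
guard shell that separates it from its surroundings and a background
shell whose mean is its local background. The egg-level background is
the unweighted mean of the per-vesicle envelope means. A vesicle whose
secondary mean falls below its own envelope is omitted; among the rest,
a vesicle is positive when its secondary mean exceeds the egg
background. Pearson and Manders (M1) coefficients are pooled at the
voxel level over all non-omitted vesicle masks across eggs (one
coefficient pair for the whole egg set); M1 defines
secondary-positive voxels by the sign of the background-subtracted
secondary intensity, not by a Costes threshold, because the envelope
construction is the assay's own background model.

## The synthetic scenes: what they emulate, and what they do not

The generator renders three scene families, deterministic in
`(params, seed)`, each with a manifest sufficient to re-render the
scene bit-identically:

* **2D kinetics** (`make_timelapse_2d`): an elliptical egg (textured
  interior over darker exterior on the brightfield channel) and a
  cubic-spline flagellar tube whose MD amplitude is
  $I_0 e^{-kt}$ over frames at 0–3 h AEL. Study conditions: $I_0 =
  30000$ a.u. so the fixed 1200 threshold stays below the signal
  through 3 h at the control rate $k = 1\ \mathrm{h^{-1}}$ (at 3 h the
  amplitude is ~1494 a.u.); knockdown condition $k = 0.1$; background
  100 a.u.; additive Gaussian noise, sd 20.
* **3D axoneme** (`make_axoneme_volume_3d`): a curved axoneme tube,
  spherical puncta placed with a configurable radial density
  `radial_weight(d)` over distance to the axoneme *object* (the same
  field the shell assay measures), and a coaxial membrane tube filled
  to `membrane_fill_fraction` (0.15 in cleared/control scenes, 0.70 in
  blocked/knockdown scenes). Spacing 0.5 × 0.25 × 0.25 µm.
* **3D vesicles** (`make_vesicle_volume_3d`): non-overlapping spheres
  (envelopes included in the overlap test), per-vesicle brightness
  jitter with the positives' secondary load coupled to it (so pooled
  voxel correlation is positive by construction), a weak nonspecific
  secondary level on negatives, and a 0.3 µm Gaussian PSF applied to
  both channels. The PSF matters scientifically here: optical
  spill-over elevates positive vesicles' envelopes, which lifts the
  egg-level background above any single envelope — precisely the
  configuration in which the omit-then-compare rule classifies true
  negatives correctly instead of coin-flipping on symmetric noise. For
  the axoneme scenes the PSF defaults to off, since the downstream
  measurements never deconvolve.

The noise model is additive Gaussian on an ideal signal; photon
statistics, depth-dependent attenuation, chromatic offsets, autofocus
drift and real egg texture are *not* emulated. Passing tests therefore
demonstrate that the measurement code computes its definitions
correctly and recovers known truth under realistic geometry, noise and
optics-lite conditions — not that segmentation would be this easy on
real eggs, where the published workflow relied on interactive classifier
training and manual ROI correction (a hook we keep: `roi_mask`).

## Numerical and design choices

* **Distance transform**: exact lower-envelope algorithm per axis
  (quadratic-time worst cases do not exist; it is linear per line), in
  C++; distances derive from voxel centers, axis order fixed (z, y, x).
* **Erosion** is defined through the distance transform (strictly
  farther than *r* from background, image border counted as
  background), making it exactly the Euclidean operation the tests
  enumerate, rather than an iterated structuring-element erosion.
* **Connected components**: 8-connectivity in 2D, 26 in 3D, labels in
  raster order of first voxel — determinism that the tie-break rules of
  the object filter rely on.
* **Pixel classifier**: a random forest over a fixed multiscale bank
  (raw, Gaussian, gradient magnitude, Laplacian at σ = 1, 2, 4 px),
  single pass; an AutoContext-style second stage adds complexity with
  no measurable benefit on these scenes. 3D stacks get 2D features per
  slice — tube cross-sections carry the discriminative signal at these
  scales. Training subsamples at most 4000 px per class, seeded;
  forests are single-threaded so that training and prediction are
  bit-reproducible.
* **Split-plot RM-ANOVA** is computed from the closed-form balanced
  decomposition (group tested against subjects-within-groups; time and
  interaction against the within-subject error), which makes 10,000
  calibration fits cheap; `aov()` with an `Error(subject)` stratum is
  the independent oracle in the tests, including unequal group sizes.
  No sphericity correction is applied by default (none is mentioned in
  the source assays); synthetic cohorts are generated compound-symmetric.
* **Dunnett's many-to-one comparison** needs multivariate-t quantiles
  out of proportion to its role here; a seeded Monte-Carlo
  approximation (`dunnett_mc`) is provided, with Šídák as the
  documented default adjustment.
* **Fisher's exact test** is the full hypergeometric enumeration with
  the conventional 1e-7 relative tie tolerance; the tests sweep every
  table with margins ≤ 12 against the reference implementation.
* **Proteomics pseudocount** defaults to half the smallest nonzero
  intensity (the sources quantify without normalization and are silent
  on zeros); it avoids infinities while preserving rank, and rows that
  are zero in both columns are flagged rather than scored.

## Problem sizes

The shipped analyses and tests use desk-scale scenes chosen to exercise
the geometry class, not the physical scale, of the original data:
2D frames of 160 × 220 px; 3D volumes of 32–64 z-planes at 96–192 px
laterally; cohorts of 20 eggs per condition; 200 vesicles per egg with
10 seeds for recovery; 10⁴ puncta for the uniform-density flatness
check; 10⁴ simulations for type-I calibration. The full acceptance
recomputation runs in a few minutes on one core.

## Known limitations

* The classifier is not Ilastik: feature banks and hyper-parameters
  differ, so masks on real data will differ in detail from the
  published ones even at identical thresholds.
* Envelope volumes at image borders are truncated, not extrapolated;
  profiles from eggs clipped by the field of view are biased only
  through the reduced sampling volume.
* The PCC/Manders pooling domain (vesicle voxels) is one reading of the
  published analysis; pooling over whole images would give different
  coefficients on the same data.
* 2D-per-slice classifier features ignore axial context; a strongly
  z-elongated PSF would degrade 3D segmentation more than our scenes
  suggest.
* `fit_decay` assumes a single-exponential with no floor term; a
  nonzero asymptote (incomplete elimination) inflates neither $k$ nor
  $I_0$ gracefully and should be modeled explicitly if observed.
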