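# pmequant

Quantification pipelines for studying **paternal mitochondrial
elimination (PME)** in fertilized *Drosophila* eggs. After
fertilization, the egg degrades the sperm's giant mitochondrion (the
mitochondrial derivative, MD, running the length of the flagellum)
while sparing the axoneme, by coating flagellar segments with
vesicular sheaths derived from egg multivesicular bodies (MVBs).
pmequant reimplements the image-derived measurements this biology is
studied with, as tested, scriptable R functions:

* **2D MD-elimination kinetics** — per-frame *normalized MD intensity*
  on brightfield + fluorescence time-lapses,
  `NMI = (mean_pos − mean_neg) × (positive area / egg area)`,
  computed inside a classifier-segmented, 15 px-eroded egg mask after
  rolling-ball background subtraction and a fixed raw-scale threshold
  (1200 a.u.; alternate-microscope dialect 250), plus per-egg
  exponential decay fits `I0·exp(−k·t)`;
* **3D distance-shell (envelope) analysis** — normalized signal volume
  in ten 1 µm shells around the segmented axoneme, after discarding
  the smallest 40% of objects, using an exact anisotropic Euclidean
  distance transform;
* **membrane/axoneme ratio** — sperm plasma membrane volume touching
  the axoneme, over axoneme volume;
* **vesicle colocalization** — per-vesicle (≥ 15 µm³) secondary-marker
  positivity against a 200 nm guard + 300 nm background envelope, with
  egg-level background averaging, plus pooled Pearson and Manders (M1)
  coefficients over vesicle voxels;
* **MVB-fraction proteomics enrichment** — PSM < 10 abundance filter
  and strict log2FC > 1 enrichment listing;
* **the statistics attached to these assays** — balanced split-plot
  (two-way repeated-measures) ANOVA, Šídák and Holm–Šídák adjustment,
  two-sided Fisher's exact test by enumeration, pooled-variance
  Student's t, and a Monte-Carlo many-to-one (Dunnett-style) option.

A synthetic-scene generator (`make_timelapse_2d`,
`make_axoneme_volume_3d`, `make_vesicle_volume_3d`) renders all three
assay geometries with additive noise and a ground-truth manifest, so
every pipeline stage is testable at desk scale; real acquisitions enter
through TIFF/OME-TIFF with physical spacing metadata.

## Worked example

Generate a control egg, train the egg classifier on brightfield, and
recover the decay rate:

```r
library(pmequant)
cfg <- analysis_config()                 # published defaults
p   <- scene2d_params(seed = 3)          # k = 1.0 per hour
sc  <- make_timelapse_2d(p)

bf  <- get_channel(sc$frames[[1]], "brightfield")
clf <- train_pixel_classifier(
  bf, sparse_labels_from_mask(pmequant:::egg_mask_2d(p), 800, seed = 7),
  seed = 7)

ms <- quantify_timelapse(sc$frames, clf, cfg)
sapply(ms, function(m) m$nmi)
#> [1] 2895.7520 1065.0788  391.7270  144.1735
tc <- build_timecourse(ms)
fit_decay(tc$nmi[1, ], tc$times)$k
#> [1] 1.000182
```

The NMI falls by a factor of e each hour (the generator's decay rate is
1.0 per hour) and the fit recovers it to four digits; on noisy cohorts
of 20 eggs the median recovered rate stays within a few percent.

The numbered drivers under `analysis/` run the full study on synthetic
scenes and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # scenes + truth manifests
Rscript analysis/02_kinetics.R        # NMI time courses, decay fits, RM-ANOVA
Rscript analysis/03_shell_profiles.R  # envelope profiles, Holm-Šídák contrasts
Rscript analysis/04_membrane_ratio.R  # touching-volume ratios, t test
Rscript analysis/05_vesicle_coloc.R   # positivity fraction, pooled PCC/M1
Rscript analysis/06_proteomics.R      # PSM filter + log2FC enrichment
Rscript analysis/07_calibration.R     # type-I rates of the tests
```

For example, `analysis/04_membrane_ratio.R` prints

```
membrane/axoneme ratio: control 0.411 vs knockdown 1.970, t = -101.94, p = 6e-48
```

— control scenes emulate near-complete membrane clearance (15% of the
membrane tube retained) versus blocked clearance (70%) in the
knockdown-like condition, and the touching-volume measurement separates
them decisively.

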