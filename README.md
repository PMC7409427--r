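# octacvd

Visualization of deep choroidal vasculature and measurement of choroidal
vascular density (CVD) from swept-source OCT angiography (SS-OCTA),
validated end to end on synthetic choroid phantoms.

## The problem

On SS-OCTA, medium and large choroidal vessels beneath the
choriocapillaris appear as **dark** stripes — fringe washout, RPE
attenuation and threshold masking suppress the flow signal inside fast
lumens — mirroring the dark vessels of en-face structural OCT. That makes
deep choroidal vascularity measurable from OCTA, provided the slab depth
is chosen well and the dark-pixel (not bright-pixel) fraction is
quantified. This package implements that workflow for researchers in
retinal imaging:

* **Slabs**: OCTA / en-face OCT single-pixel slab pairs referenced to
  Bruch membrane (BM), quantized to the device's 2.6 µm axial grid
  (nominal 50, 100, …, 550 µm → actual 49.4, 98.8, …, 551.2 µm), plus a
  percentile series at 12.5–87.5% of the subfoveal choroidal thickness
  (SCT).
* **Binarization**: Otsu's histogram threshold (minimal intra-class
  variance), black = vessel lumen; conventions (inclusive black,
  smallest tie) pinned and oracle-tested.
* **Comparison**: pixel-agreement similarity
  `100 · #matched / #pixels`, four-colour comparison maps
  (white/black/green/red), an explicit automated criterion for
  "displays choroidal vessels", per-depth profiles, and lexicographic
  optimal-depth selection.
* **CVD**: percentage of black pixels in the binarized OCTA slab at the
  optimal depth (98.8 µm beneath BM by default).
* **QC**: artefact and image-score exclusion rules with a per-eye reason
  log.
* **Statistics**: Pearson correlation, OLS regression of CVD on age,
  axial length and SCT (slope per 100 µm SCT with 95% CI), one-way ANOVA
  from raw data or from published summary statistics, SCT-adjusted
  ANCOVA, Lilliefors normality, and matched-control selection.
* **Phantoms**: a synthetic eye generator (dark-lumen tubes, granular
  choriocapillaris band, exponential depth attenuation, Gaussian noise,
  cohort-level SCT/CVD structure) with voxel-level ground truth, so every
  stage is testable without patient scans.

## Worked example

Generate one phantom eye, measure its CVD at the quantized 100 µm slab,
and compare the binarized modalities:

```r
library(octacvd)

cfg <- phantom_config(sct = 300, lumen_fraction_by_depth = c("98.8" = 0.6),
                      seed = 7)
eye <- generate_phantom_eye(cfg, eye_id = "demo")

lumen_fraction(eye$truth, 98.8)       # ground truth at the slab
#> [1] 0.6016

measure_cvd_eye(eye$volume, nominal_depth = 100)
#> CVD demo at 98.8 um beneath BM: 59.9% (threshold 48, 53950/90000 black)

pair <- extract_slab(eye$volume, 98.8)
comparison_map(binarize(pair$octa_image), binarize(pair$oct_image))
#> Comparison map 300 x 300: similarity 99.0%
#>           both_white           both_black octa_white_oct_black
#>                35498                53567                  552
#> octa_black_oct_white
#>                  383
```

The measured CVD (59.9%) recovers the configured lumen fraction (60%)
to within a fraction of a percentage point, and the OCTA slab agrees
with its en-face OCT counterpart on 99% of pixels.

The whole pipeline — cohort generation, QC, depth profiles, optimal
depth, CVD, statistics — runs from one YAML config:

```r
cfgfile <- system.file("extdata", "small_phantom_config.yml",
                       package = "octacvd")
res <- run_pipeline(cfgfile, out_dir = "demo_run")
res$profile_fixed
#> Depth profile (fixed series)
#>      49.4 um  n=  6  displaying   6 (100.0%)  similarity 93.0 +/- 0.3
#>      98.8 um  n=  6  displaying   6 (100.0%)  similarity 98.7 +/- 0.2
#>     150.8 um  n=  6  displaying   6 (100.0%)  similarity 90.5 +/- 0.2
#>     200.2 um  n=  6  displaying   6 (100.0%)  similarity 73.0 +/- 1.7
#>     249.6 um  n=  4  displaying   0 (  0.0%)  similarity 60.9 +/- 1.6
#>     299.0 um  n=  4  displaying   0 (  0.0%)  similarity 54.4 +/- 0.6
#>     351.0 um  n=  2  displaying   0 (  0.0%)  similarity 51.7 +/- 1.3
#>     400.4 um  n=  2  displaying   0 (  0.0%)  similarity 50.5 +/- 0.8
#>     449.8 um  n=  1  displaying   0 (  0.0%)  similarity 51.3
#>     499.2 um  n=  0  displaying   0 (   NA%)  similarity --
#>     551.2 um  n=  0  displaying   0 (   NA%)  similarity --
```

Eyes drop out of deeper rows as the slab passes their chorioscleral
interface (`n` shrinks), similarity peaks at 98.8 µm and collapses
toward 50% (coin-flip agreement between noise masks) at depth, and the
report selects 98.8 µm / 25% SCT as the optimal depths:

```
octacvd pipeline report
eyes generated: 6; included after QC: 6; excluded: 0
optimal fixed depth: 98.8 um
optimal percentile depth: 25 %SCT
CVD at 98.8 um: mean 57.4%, SD 7.3% (n = 6)
```

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --config cfg.yml --out-dir out --seed 7`).

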