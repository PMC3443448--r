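# spinedisk

Unsupervised segmentation and 3D reconstruction of intervertebral disks
from short-TE MR volumes of scoliotic spines, with the full quantitative
evaluation toolkit needed to validate such a reconstruction against a
manual gold standard.

## Who this is for

Researchers in spine image analysis and computer-assisted surgery who need
closed, reproducible 3D disk models from sagittal MR acquisitions —
for example as the preoperative anatomy behind thoracoscopic disk-resection
guidance — together with the statistics (overlap, volume bias, boundary
distance, rater variability, factorial robustness) used to report how good
those models are. Because clinical MR data cannot ship with a package,
`spinedisk` also includes a synthetic scoliotic-spine phantom generator so
every stage is testable end to end.

## The method

The reconstruction has three stages, run per patient volume:

1. **Marker-controlled watershed segmentation**, slice by slice. Each
   sagittal (and later coronal) slice is reduced to a morphological
   gradient `g = δ_B(f) − ε_B(f)` (dilation minus erosion by a disc `B`).
   Internal markers `F_int` — connected pixel sets inside bright,
   homogeneous structures — are found by opening/closing-by-reconstruction
   smoothing followed by h-maxima and an area filter; external markers
   `F_ext` are the valley lines surrounding every internal marker (the
   ridge lines of the watershed of the distance-from-marker map, plus the
   image border). The combined markers `F = F_int ∪ F_ext` are imposed as
   the only regional minima of `g`, and flooding `g` from those minima
   yields closed candidate regions. Over-segmentation is expected and left
   to the classifier.

2. **Texture-based k-NN labelling** of sagittal candidates. Each region is
   described by eight features: histogram mean, standard deviation,
   skewness and entropy, plus four descriptors of the polar energy Fourier
   spectrum `S(θ)` of the region patch — `θ_max`, `S(θ)_max`, `var S(θ)`
   and `S(θ)_max − S(θ)_mean`. A supervised k-nearest-neighbour vote in
   standardized feature space labels each region `disk` or `background`.

3. **Coronal reconstruction and fusion.** Coronal slices are reconstructed
   from the sagittal stack by trilinear resampling to an isotropic grid and
   segmented the same way (no classifier; area and border rules only).
   Per-disk volumes are stacked from the labelled sagittal masks
   (`D_ref`) and from the coronal masks (`D_cor`), matched by centroid
   proximity, and fused by union:

   `D = D_ref ∪ D_cor`

   which fills the lateral portions of each disk that sagittal slices
   see only as small, easily-missed structures.

Validation follows the companion evaluation suite: the Dice similarity
coefficient `DSC(X, Y) = 2|X ∩ Y| / (|X| + |Y|)` in 3D and per slice (with
the mid-sagittal 80% / lateral 10%-per-side split), signed volume
discrepancy `(|auto| − |manual|)/|manual|`, a posterior-band boundary
distance near the spinal canal, pairwise rater/automatic variability
tables, and a 3-level fractional-factorial robustness design
(`3^(4−2) × 3 blocks = 27` runs) analysed by ANOVA with a Pareto ranking
of standardized effects.

## Worked example

```r
library(spinedisk)

spec    <- phantom_spec()                         # 5 disks, 30 deg curve, medic preset
phantom <- make_spine_phantom(spec)
model   <- train_knn(make_training_regions(spec, n_per_class = 20, seed = 1), k = 5)
result  <- run_pipeline(phantom$volume, model)
report  <- evaluate_reconstruction(result$fused, phantom$truth_masks,
                                   result$grid$spacing_mm)
report$per_disk
```

which prints

```
# A tibble: 5 × 5
   disk dsc_3d n_auto n_truth discrepancy
  <int>  <dbl>  <int>   <int>       <dbl>
1     1  0.793   1418    2014      -0.296
2     2  0.812   1516    2014      -0.247
3     3  0.812   1513    2032      -0.255
4     4  0.801   1473    2014      -0.269
5     5  0.794   1406    2014      -0.302
```

Every disk is recovered with a 3D DSC around 0.8 — above the 0.70
threshold conventionally read as good segmentation agreement — and the
negative discrepancies show the deliberate ~25–30% volume under-estimation
of the watershed-line contour convention: the automatic model sits safely
inside the true disk, which surgeons treat as a margin of safety. Fusion
only ever helps: for each disk the fused DSC is at least the
sagittal-only DSC (compare `result$reference` with `result$fused`).

A command-line front end for shell pipelines ships in
`inst/cli/spinedisk.R` with subcommands `phantom`, `segment`, `classify`,
`fuse`, `evaluate`, `robustness` and `run`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "spinedisk.R", package = "spinedisk"))')" \
    phantom --n-disks 5 --cobb 30 --out phantom_out
```

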