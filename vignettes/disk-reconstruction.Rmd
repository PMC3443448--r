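---
title: "Reconstructing intervertebral disks from spine MR volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing intervertebral disks from spine MR volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedisk)
```

`spinedisk` reconstructs intervertebral disks from sagittal short-TE MR
acquisitions of scoliotic spines and quantifies how well the reconstruction
matches a reference segmentation. This vignette records the model, its
assumptions, and the design decisions behind every tunable — the material a
maintainer or reviewer needs that does not fit in function reference pages.

## The reconstruction model

The pipeline assumes short-echo-time contrast: intervertebral disks render
brighter than vertebral bodies and surrounding tissue, without separating
the annulus from the nucleus. It is strictly per-slice in its segmentation
stage (2D watershed), becoming 3D only when labelled per-slice masks are
stacked and fused.

**Stage 1 — marker-controlled watershed.** Each slice is mapped to a
morphological gradient (dilation minus erosion with a disc of radius
`se_radius_px`, default 1 px). Internal markers are extracted by smoothing
(opening then closing, both by greyscale reconstruction, disc radius
`smooth_radius_px` = 2 px), taking h-maxima at `h_fraction` (default 10%)
of the slice dynamic range, and removing components below `min_area_mm2`
(default 30 mm², converted through the pixel area). External markers are
the ridge lines of the watershed of the Euclidean distance-from-marker
map, plus the one-pixel image border; with fewer than two internal
components only the border frame is used. The combined markers are imposed
as the only regional minima of the gradient by reconstruction-by-erosion,
and Meyer-style flooding grows one basin per marker component.

Two conventions here deserve emphasis:

* *Determinism.* Flooding pops the lowest gradient value first and breaks
  gray-level ties by insertion order, which itself follows column-major
  pixel order. The same image and markers always produce the same basins,
  on any platform; the test suite checks basin-for-basin agreement with an
  independent ordered-queue oracle on random images.
* *Watershed lines.* Pixels whose 8-neighbourhood touches a different
  basin belong to the line, not to any region. Candidate regions therefore
  exclude their outermost transition shell. This makes contours slightly
  conservative — reconstructed disks systematically under-fill the true
  volume by roughly a quarter, which downstream users read as a margin of
  safety — and it guarantees that two structures never share a voxel face
  or corner once slices are stacked, so stacked components cannot bleed
  into each other. Marker components that fail the area filter are demoted
  to background seeds rather than discarded, so small real structures
  cannot be silently absorbed by a neighbouring basin.

Degenerate inputs are well defined: a constant slice has no h-significant
maxima and yields no regions; an empty marker mask makes minima imposition
refuse to run (the watershed would be unseeded); imposing minima on an
image whose minima already equal the marker set returns the image
unchanged, making imposition idempotent.

**Stage 2 — region classification.** Only sagittal regions are classified
(coronal regions are matched later by anatomical correspondence, which is
far cheaper than classifying every coronal candidate). Eight features per
region: histogram mean, standard deviation, skewness (third standardized
moment, defined as 0 for constant regions) and Shannon entropy over 32
equal-width bins spanning the slice dynamic range; and four descriptors of
the polar spectrum — the patch is cropped to the region bounding box,
pixels outside the region are set to the region mean (so the silhouette
does not dominate), the patch is mean-subtracted, zero-padded to at least
64×64, and the squared Fourier magnitude is summed over radius into S(θ)
on 5° bins covering [0°, 180°) (Hermitian symmetry; DC excluded). Regions
with a bounding box under 8×8 px get an all-zero spectrum. The energy
(|F|²) convention is used; `classification_params()` exposes a
`"magnitude"` switch, and bin counts, padding and angular width are all
configuration keys because no principled single value exists — the
defaults keep S(θ) well populated for regions of 10²–10³ pixels.

The classifier is a deterministic k-NN (default k = 5, odd so a two-class
vote cannot tie; distance ties resolve by training-row order) on
z-standardized features. Standardization makes the decision invariant to
affine rescaling of any feature. Training data are built the way clinical
training sets are: candidate regions from segmented phantom slices,
labelled by majority overlap with the ground-truth masks. Training on
idealized synthetic shapes instead was tried and rejected — a classifier
that has never seen a watershed-shaped vertebral basin mislabels them.

**Stage 3 — coronal reconstruction and fusion.** The volume is resampled
to an isotropic grid (default 1 mm) by trilinear interpolation on physical
slice-centre positions, which handles gapped acquisitions (2 mm slices at
2.4 mm centres) without special cases; binary masks move between grids by
nearest neighbour. Coronal slices of the resampled volume are segmented
with the same parameters, filtered only by area and border rules. Stacked
sagittal disk masks give reference volumes, coronal masks give candidate
volumes, and each coronal component joins the reference disk with the
nearest centroid if that distance is at most `max_dist_mm` (default 10 mm,
about half a vertebral-body height — far coronal components are
background). The fused disk is the voxel union of the reference with all
assigned coronal components, so `|D| ≥ |D_ref|` always, and fusion
recovers the lateral disk portions that sagittal slices render as small,
area-filtered structures.

Connected components are defined with face (6-) connectivity. With corner
(26-) connectivity, a disk basin and a vertebral basin on adjacent slices
that touch only at a voxel corner merge into one component — observed on
the reference phantom, where it collapsed the coronal disk components'
purity — while every face-connected component trivially satisfies the
26-connectivity invariant a disk volume promises. The connectivity is an
argument for users who want the looser definition.

## The synthetic phantom

`make_spine_phantom()` emulates what the pipeline assumes about the data,
not MR physics. Disks are ellipsoids (default semi-axes 10, 12, 4 mm in
ap, lr, si) oriented perpendicular to a single-arc centreline in the
coronal plane whose end-tangent angle difference is the `cobb_like_angle`;
vertebral bodies are larger, darker ellipsoids between them. Intensities
are piecewise constant (background 0.20, vertebra 0.45, disks near 0.80 —
each disk minutely distinct so that in the noise-free limit each truth
mask is the level set of its own intensity), followed by Gaussian point
spread (default σ 0.8 mm) and additive Gaussian noise (default σ 0.05 of
the disk/background contrast). Rician noise is deliberately not modelled:
the pipeline uses only magnitude-like contrast and makes no SNR claims.
Presets: `medic` and `fisp` are 1 mm isotropic; `spin_echo` uses 2 mm
slices with a 0.4 mm gap along lr and 0.67 mm in-plane pixels;
`fisp` additionally blurs disk boundaries (a wider kernel blended in near
mask edges), and `bright_nucleus` renders the nucleus brighter than the
annulus — the artefact that misleads boundary detection in some spin-echo
acquisitions. Ground-truth masks are the voxelized ellipsoids before blur
and noise.

The reference study conditions — the package defaults — are five disks, a
30° curve, the `medic` preset, noise 0.05 and seed 42 on a 44×48×120 mm
grid. The test suite uses a smaller three-disk phantom (28×36×80) where
the full-size one is not needed; these sizes are the package's choices for
a thorough-but-quick default suite.

What the phantom does *not* emulate — and hence what passing tests cannot
show about clinical data: vertebral rotation and wedging, double curves,
intensity inhomogeneity and coil shading, partial-volume anisotropy beyond
the slice gap, cerebrospinal fluid and other bright confounders, and real
inter-patient contrast variability. Results on the phantom bound the
method's behaviour under its own assumptions, nothing more.

## Evaluation conventions

* DSC is undefined for two empty sets (an error, not 0 or 1); per-slice
  DSC skips slices empty in both sets and scores 0 where exactly one is
  empty. Voxel-weighted pooling of per-slice values reproduces the 3D DSC
  exactly, which the tests assert numerically.
* The mid-sagittal/lateral split takes ⌈0.10 n⌉ slices per side. The
  ceiling form is the unique simple rule consistent with all 27 published
  per-disk (mid, lateral) count pairs the suite replays.
* The canal boundary distance is directional — manual boundary pixels in
  the posterior band (posterior 25% of the disk's ap extent; a
  configuration key) to the nearest automatic boundary pixel — because the
  quantity of interest is how far the automatic contour retreats from the
  canal edge. Distances are pooled over slices with a population standard
  deviation; across-disk variability tables use the sample convention.
* Volume discrepancy is signed, negative meaning under-estimation.

## The robustness design

`generate_design()` builds a 3-level fractional factorial: a full 3²
factorial in two base factors plus generator columns `F3 = F1 + F2 (mod 3)`
and `F4 = F1 + 2·F2 (mod 3)`, replicated over three blocks (27 runs, every
factor level appearing 9 times), run order randomized within block by a
seed. Because the 27 runs contain only 9 distinct treatment combinations,
every two-factor interaction is aliased with main effects;
`estimate_effects()` therefore fits block (categorical) plus orthogonal
linear and quadratic contrasts per factor — coded so the linear contrast
is the level itself and the quadratic is `3·level² − 2`, both summing to
zero — and adds interaction columns only when they survive a rank check,
reporting the dropped (aliased) ones. Externally supplied designs (e.g. a
transcribed published run table) can be analysed through the same path via
`read_design_csv()`, where richer treatment structures may make some
interactions estimable. Standardized effects are t statistics on the
residual degrees of freedom; `pareto_ranking()` sorts by their absolute
value, the tabular form of a Pareto chart (`plot_pareto()` draws it, with
quadratic terms carrying the conventional `*` suffix).

A constant response gives zero estimates with undefined p-values (reported
as `NA` rather than invented); a saturated model is refused with the
degrees-of-freedom deficit named.

## Numerical and implementation notes

* Greyscale reconstruction uses the raster/anti-raster sweep with a FIFO
  queue; minima imposition shifts the image by a relative offset (10⁻³ of
  the dynamic range) before reconstruction so plateau minima off the
  markers are destroyed regardless of scale.
* The flooding, reconstruction, regional-extrema and 3D labelling engines
  are compiled (Rcpp); the morphological gradient's dilate/erode are also
  package-compiled because they must be shift-invariant for arbitrary
  intensity ranges, with neighbourhoods clipped at the border so constants
  are fixed points. EBImage supplies the distance transform and oriented
  contours; RNifti supplies NIfTI-1 I/O (volumes are written with a
  scanner-anatomical qform so the axis order is trusted on read).
* All generator randomness flows through explicit seeds, and seeded code
  restores the caller's RNG state.

## Known limitations

* The marker recipe reconstructs the intent of "connected pixels inside
  the regions of interest" from first principles; its three constants are
  configuration keys, not fitted values, and other recipes could trade
  over- for under-segmentation differently.
* Classification quality depends on the training regions resembling the
  candidates at prediction time; the phantom trainer holds that by
  construction, clinical use would need a curated region table
  (`region_feature_table()` + `train_knn()`).
* The centroid-matching threshold is geometric and global; pathologically
  close structures (severe collapse, fused levels) could mis-assign
  coronal components.
* Per-slice 2D watershed cannot exploit 3D continuity; thin or highly
  tilted disks on gapped acquisitions rely entirely on the fusion stage.
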