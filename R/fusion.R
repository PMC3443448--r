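#' Default fusion parameters
#'
#' \describe{
#'   \item{iso_mm}{isotropic spacing of the common fusion grid.}
#'   \item{max_dist_mm}{maximum centroid distance for matching a coronal
#'     component to a sagittal reference disk (about half a vertebral-body
#'     height, so background components cannot attach).}
#'   \item{min_component_voxels}{3D components smaller than this are
#'     dropped when building disk volumes.}
#' }
#' @return Named list of defaults.
#' @export
fusion_params <- function() {
  list(iso_mm = 1, max_dist_mm = 10, min_component_voxels = 30L)
}

# linear-interpolation weight matrix mapping source samples at centres
# (j - 0.5) * sp onto target centres (i - 0.5) * iso, clamped at the ends
interp_weights <- function(n_src, sp, n_tgt, iso) {
  W <- matrix(0, n_tgt, n_src)
  src <- (seq_len(n_src) - 0.5) * sp
  tgt <- (seq_len(n_tgt) - 0.5) * iso
  for (i in seq_len(n_tgt)) {
    t <- tgt[i]
    if (t <= src[1]) { W[i, 1] <- 1; next }
    if (t >= src[n_src]) { W[i, n_src] <- 1; next }
    j <- findInterval(t, src)
    w <- (t - src[j]) / (src[j + 1] - src[j])
    W[i, j] <- 1 - w
    W[i, j + 1] <- w
  }
  W
}

#' Resample a volume to an isotropic grid (coronal reconstruction)
#'
#' Trilinear resampling of the sagittal slice stack onto an isotropic grid,
#' from which coronal slices are read as fixed-`ap` planes; gap-aware along
#' `lr` because interpolation operates on physical slice-centre positions.
#'
#' @param volume a [voxel_volume()].
#' @param iso_mm target isotropic spacing (> 0).
#' @return A [voxel_volume()] with spacing `iso_mm` on all axes.
#' @export
reconstruct_coronal <- function(volume, iso_mm = 1) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (iso_mm <= 0) stop("`iso_mm` must be > 0")
  d <- dim(volume$data)
  extent <- d * volume$spacing_mm
  if (iso_mm > min(extent))
    stop("`iso_mm` exceeds the smallest volume extent")
  n_tgt <- pmax(1L, floor(extent / iso_mm))
  if (all(n_tgt == d) && all(volume$spacing_mm == iso_mm))
    return(volume)
  arr <- volume$data
  W1 <- interp_weights(d[1], volume$spacing_mm[1], n_tgt[1], iso_mm)
  arr <- array(W1 %*% matrix(arr, d[1]), c(n_tgt[1], d[2], d[3]))
  W2 <- interp_weights(d[2], volume$spacing_mm[2], n_tgt[2], iso_mm)
  a2 <- aperm(arr, c(2, 1, 3))
  a2 <- array(W2 %*% matrix(a2, d[2]), c(n_tgt[2], n_tgt[1], d[3]))
  arr <- aperm(a2, c(2, 1, 3))
  W3 <- interp_weights(d[3], volume$spacing_mm[3], n_tgt[3], iso_mm)
  a3 <- aperm(arr, c(3, 1, 2))
  a3 <- array(W3 %*% matrix(a3, d[3]), c(n_tgt[3], n_tgt[1], n_tgt[2]))
  arr <- aperm(a3, c(2, 3, 1))
  voxel_volume(arr, rep(iso_mm, 3))
}

#' Resample a binary mask to an isotropic grid by nearest neighbour
#'
#' @param mask logical 3D array on the native grid.
#' @param spacing_mm native per-axis spacing.
#' @param iso_mm target isotropic spacing.
#' @return Logical 3D array on the isotropic grid.
#' @export
resample_mask <- function(mask, spacing_mm, iso_mm = 1) {
  d <- dim(mask)
  extent <- d * spacing_mm
  n_tgt <- pmax(1L, floor(extent / iso_mm))
  nn <- function(n_src, sp, n_t) {
    j <- round(((seq_len(n_t) - 0.5) * iso_mm) / sp + 0.5)
    pmin(n_src, pmax(1L, j))
  }
  mask[nn(d[1], spacing_mm[1], n_tgt[1]),
       nn(d[2], spacing_mm[2], n_tgt[2]),
       nn(d[3], spacing_mm[3], n_tgt[3]), drop = FALSE]
}

#' Stack per-slice masks into per-disk 3D volumes
#'
#' Joins the per-slice binary masks into a 3D grid and splits it into
#' connected components, each becoming one [disk_volume()]; components
#' below `min_voxels` are dropped. Components are defined with face
#' (6-)connectivity by default: neighbouring anatomical structures whose
#' per-slice basins meet only at a voxel corner must not merge into one
#' volume, and every face-connected set trivially satisfies the disk
#' volume's 26-connectivity invariant.
#'
#' @param masks logical 3D array `[lr, ap, si]` of stacked per-slice masks.
#' @param plane the plane the slices came from (`"sagittal"` gives source
#'   `"sagittal_reference"`, `"coronal"` gives `"coronal"`).
#' @param spacing_mm per-axis spacing of the grid.
#' @param min_voxels minimum component size.
#' @param connectivity 6 (face, default) or 26 (face + edge + corner).
#' @return List of [disk_volume()], ordered along the scan; empty when no
#'   component survives.
#' @export
build_disk_volumes <- function(masks, plane = c("sagittal", "coronal"),
                               spacing_mm = c(1, 1, 1),
                               min_voxels = fusion_params()$min_component_voxels,
                               connectivity = 6L) {
  plane <- match.arg(plane)
  if (!is.array(masks) || length(dim(masks)) != 3L)
    stop("`masks` must be a 3D array of stacked slice masks")
  src <- if (plane == "sagittal") "sagittal_reference" else "coronal"
  if (!any(masks != 0)) {
    msg("build_disk_volumes: all masks empty")
    return(list())
  }
  lab <- cpp_label3d(as.logical(masks), dim(masks), as.integer(connectivity))
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  out <- list()
  for (k in seq_len(n)) {
    if (sizes[k] < min_voxels) next
    out[[length(out) + 1L]] <-
      disk_volume(which(lab == k), dim(masks), spacing_mm, src)
  }
  out
}

#' Match coronal components to reference disks and fuse
#'
#' Every coronal component is assigned to the sagittal reference disk with
#' the nearest centroid, provided that distance is at most `max_dist_mm`
#' (otherwise it is discarded as background); ties go to the lower disk
#' index. Each reference disk then yields one fused volume, the union of
#' the reference voxels with all assigned coronal voxels.
#'
#' @param reference list of [disk_volume()] from classified sagittal masks.
#' @param coronal list of [disk_volume()] from coronal segmentation.
#' @param max_dist_mm centroid matching threshold.
#' @return List of fused [disk_volume()] (source `"fused"`), one per
#'   reference disk, each carrying attributes `n_reference`, `n_coronal`
#'   and `assigned` (indices of the coronal components it absorbed).
#' @export
match_and_fuse <- function(reference, coronal,
                           max_dist_mm = fusion_params()$max_dist_mm) {
  if (length(reference) == 0L)
    stop("empty reference list: nothing to anchor anatomical correspondence")
  dims <- reference[[1]]$dim
  for (v in c(reference, coronal))
    if (!all(v$dim == dims))
      stop("all volumes must live on the same resampled grid")
  ref_cent <- do.call(rbind, lapply(reference, function(v) v$centroid_mm))
  assigned <- vector("list", length(reference))
  if (length(coronal) > 0L) {
    for (j in seq_along(coronal)) {
      d <- sqrt(rowSums(sweep(ref_cent, 2, coronal[[j]]$centroid_mm)^2))
      i <- which.min(d)                      # strict min, ties: lower index
      if (d[i] <= max_dist_mm)
        assigned[[i]] <- c(assigned[[i]], j)
    }
  }
  out <- vector("list", length(reference))
  for (i in seq_along(reference)) {
    idx <- reference[[i]]$idx
    for (j in assigned[[i]]) idx <- union(idx, coronal[[j]]$idx)
    fused <- disk_volume(idx, dims, reference[[i]]$spacing_mm, "fused")
    attr(fused, "n_reference") <- length(reference[[i]]$idx)
    attr(fused, "n_coronal") <- sum(vapply(assigned[[i]], function(j)
      length(coronal[[j]]$idx), 0L))
    attr(fused, "assigned") <- assigned[[i]]
    out[[i]] <- fused
  }
  out
}
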