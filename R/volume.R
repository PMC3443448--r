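#' Voxel volume container
#'
#' A 3D scalar intensity grid with per-axis voxel spacing in millimetres.
#' Axes follow the fixed anatomical convention `[lr, ap, si]`:
#' left-right (the sagittal stacking axis), anterior-posterior (the coronal
#' stacking axis) and superior-inferior. A sagittal slice is a fixed `lr`
#' index, a coronal slice a fixed `ap` index.
#'
#' @param data 3D numeric array indexed `[lr, ap, si]`.
#' @param spacing_mm numeric length-3 vector of voxel spacings in mm
#'   (`lr`, `ap`, `si`), all strictly positive.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing_mm) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive values")
  names(spacing_mm) <- c("lr", "ap", "si")
  structure(list(data = data, spacing_mm = spacing_mm),
            class = "voxel_volume")
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels [lr, ap, si], spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 3), collapse = " x ")))
  invisible(x)
}

#' Single-slice image container
#'
#' One 2D slice extracted from a [voxel_volume()]. For a sagittal slice the
#' pixel grid is indexed `[ap, si]`; for a coronal slice `[lr, si]`.
#'
#' @param pixels 2D numeric matrix of intensities, at least 16 x 16.
#' @param spacing_mm (row, col) pixel spacing in mm.
#' @param plane `"sagittal"` or `"coronal"`.
#' @param index position of the slice along its stacking axis.
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, spacing_mm, plane = c("sagittal", "coronal"),
                        index = 1L) {
  plane <- match.arg(plane)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (any(dim(pixels) < 16L)) stop("slice must be at least 16 x 16 pixels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 2L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be two strictly positive values")
  structure(list(pixels = pixels, spacing_mm = spacing_mm, plane = plane,
                 index = as.integer(index)),
            class = "slice_image")
}

#' Extract a slice from a volume
#'
#' @param volume a [voxel_volume()].
#' @param index slice position along the stacking axis.
#' @param plane `"sagittal"` (fixed `lr`) or `"coronal"` (fixed `ap`).
#' @return A [slice_image()].
#' @export
get_slice <- function(volume, index, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$data)
  if (plane == "sagittal") {
    if (index < 1L || index > d[1]) stop("slice index out of range")
    slice_image(volume$data[index, , , drop = TRUE],
                volume$spacing_mm[c("ap", "si")], plane, index)
  } else {
    if (index < 1L || index > d[2]) stop("slice index out of range")
    slice_image(volume$data[, index, , drop = TRUE],
                volume$spacing_mm[c("lr", "si")], plane, index)
  }
}

# accept either a slice_image or a bare matrix (spacing defaults to 1 mm)
as_slice <- function(x) {
  if (inherits(x, "slice_image")) return(x)
  if (is.matrix(x)) return(slice_image(x, c(1, 1)))
  stop("expected a slice_image or a matrix")
}

#' Per-disk voxel volume
#'
#' A connected 3D voxel set for one intervertebral disk, stored as linear
#' voxel indices on a stated grid together with its provenance: the sagittal
#' reference volume, a coronal volume, or their fusion.
#'
#' @param idx integer vector of linear voxel indices (column-major).
#' @param dim grid dimensions `[lr, ap, si]`.
#' @param spacing_mm per-axis spacing in mm.
#' @param source one of `"sagittal_reference"`, `"coronal"`, `"fused"`.
#' @return An object of class `disk_volume` carrying `centroid_mm`, the
#'   spacing-weighted mean of voxel centres.
#' @export
disk_volume <- function(idx, dim, spacing_mm,
                        source = c("sagittal_reference", "coronal", "fused")) {
  source <- match.arg(source)
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) stop("a disk volume cannot be empty")
  if (any(idx < 1L) || any(idx > prod(dim))) stop("voxel index out of grid")
  spacing_mm <- as.numeric(spacing_mm)
  names(spacing_mm) <- c("lr", "ap", "si")
  co <- arrayInd(idx, dim)
  centroid_mm <- (colMeans(co) - 0.5) * spacing_mm
  structure(list(idx = idx, dim = as.integer(dim), spacing_mm = spacing_mm,
                 source = source, centroid_mm = centroid_mm),
            class = "disk_volume")
}

#' @export
print.disk_volume <- function(x, ...) {
  cat(sprintf("<disk_volume:%s> %d voxels, centroid (%.1f, %.1f, %.1f) mm\n",
              x$source, length(x$idx), x$centroid_mm[1], x$centroid_mm[2],
              x$centroid_mm[3]))
  invisible(x)
}

#' Render a disk volume as a binary mask array
#'
#' @param x a [disk_volume()].
#' @return A logical 3D array on the disk's grid.
#' @export
disk_volume_mask <- function(x) {
  stopifnot(inherits(x, "disk_volume"))
  m <- array(FALSE, x$dim)
  m[x$idx] <- TRUE
  m
}

# coerce logical array / disk_volume to linear indices + dims
as_voxel_set <- function(x) {
  if (inherits(x, "disk_volume"))
    return(list(idx = x$idx, dim = x$dim))
  if (is.array(x) && (is.logical(x) || is.numeric(x)))
    return(list(idx = which(x != 0), dim = dim(x)))
  stop("expected a disk_volume or a binary array")
}
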