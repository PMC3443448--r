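#' Morphological gradient of a slice
#'
#' Pointwise dilation minus erosion with a disc-shaped structuring element,
#' the edge-strength image on which the marker-controlled watershed operates.
#'
#' @param slice a [slice_image()] or a numeric matrix.
#' @param se_radius_px structuring-element radius in pixels (>= 1).
#' @return A numeric matrix of the same shape, nonnegative everywhere.
#' @export
morphological_gradient <- function(slice, se_radius_px = 1L) {
  s <- as_slice(slice)
  if (se_radius_px < 1L) stop("`se_radius_px` must be >= 1")
  se <- disc_se(se_radius_px)
  px <- s$pixels
  cpp_morpho(px, se, 0L) - cpp_morpho(px, se, 1L)
}

# disc-shaped flat structuring element of the given pixel radius
disc_se <- function(radius_px) {
  r <- as.integer(radius_px)
  g <- expand.grid(i = -r:r, j = -r:r)
  matrix(g$i^2 + g$j^2 <= r^2, 2L * r + 1L, 2L * r + 1L)
}

# greyscale reconstruction by dilation of `marker` under `mask` (marker <= mask)
reconstruct_dilate <- function(marker, mask, connectivity = 4L) {
  cpp_reconstruct_dilate(marker, mask, connectivity)
}

# dual: reconstruction by erosion of `marker` above `mask` (marker >= mask)
reconstruct_erode <- function(marker, mask, connectivity = 4L) {
  -cpp_reconstruct_dilate(-marker, -mask, connectivity)
}

# smoothing used before marker extraction: opening then closing, both by
# reconstruction, with a disc structuring element; preserves region shapes
# while flattening small bright/dark specks
smooth_by_reconstruction <- function(px, radius_px = 2L) {
  se <- disc_se(radius_px)
  er <- cpp_morpho(px, se, 1L)
  ob <- reconstruct_dilate(er, px)
  di <- cpp_morpho(ob, se, 0L)
  reconstruct_erode(di, ob)
}

#' Regional minima of an image
#'
#' Plateau-aware regional minima: a connected set of equal-valued pixels with
#' no strictly lower neighbour.
#'
#' @param px numeric matrix.
#' @param connectivity pixel connectivity, 4 or 8.
#' @return Logical matrix marking minima pixels.
#' @export
regional_minima <- function(px, connectivity = 4L) {
  cpp_regional_maxima(-px, connectivity)
}

#' Impose minima on a gradient image
#'
#' Morphological reconstruction forcing the regional minima of `gradient` to
#' coincide exactly with the connected components of `markers`, so that the
#' subsequent watershed floods one basin per marker. If the minima of
#' `gradient` already equal the marker set the image is returned unchanged.
#'
#' @param gradient numeric matrix (typically a morphological gradient).
#' @param markers logical matrix of combined internal and external markers.
#' @return A numeric matrix whose regional minima are exactly `markers`.
#' @export
impose_minima <- function(gradient, markers) {
  if (!all(dim(gradient) == dim(markers)))
    stop("`gradient` and `markers` must share dimensions")
  markers <- markers != 0
  if (!any(markers))
    stop("empty marker mask: the watershed would be unseeded")
  # idempotence short-cut: nothing to do if minima are already the markers
  cur <- regional_minima(gradient, 4L)
  if (identical(unname(cur == TRUE), unname(markers)))
    return(gradient)
  f0 <- gradient - min(gradient)
  rng <- max(f0)
  delta <- if (rng == 0) 1 else rng * 1e-3
  hi <- rng + 2 * delta
  fm <- ifelse(markers, 0, hi)
  g <- pmin(f0 + delta, fm)
  reconstruct_erode(fm, g, connectivity = 4L)
}

# label the connected components of a 2D logical mask
# (8-connectivity by default, matching the marker convention)
label_components <- function(mask, connectivity = 8L) {
  conn3d <- if (connectivity == 8L) 26L else 6L
  lab <- cpp_label3d(as.logical(mask), c(dim(mask), 1L), conn3d)
  matrix(lab, nrow(mask), ncol(mask))
}
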