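#' Default segmentation parameters
#'
#' Parameters of the per-slice marker-controlled watershed:
#' \describe{
#'   \item{se_radius_px}{disc radius (pixels) of the morphological-gradient
#'     structuring element.}
#'   \item{smooth_radius_px}{disc radius of the opening/closing-by-
#'     reconstruction smoothing applied before marker extraction.}
#'   \item{h_fraction}{h-maxima contrast threshold as a fraction of the
#'     slice dynamic range; maxima shallower than this are not markers.}
#'   \item{min_area_mm2}{minimum physical area of an internal-marker
#'     component; converted to pixels through the slice spacing.}
#' }
#' @return Named list of defaults.
#' @export
segmentation_params <- function() {
  list(se_radius_px = 1L, smooth_radius_px = 2L, h_fraction = 0.10,
       min_area_mm2 = 30)
}

#' 2D candidate region
#'
#' A closed, connected pixel set produced by the watershed on one slice.
#' Carries the member pixel coordinates and intensities, an ordered closed
#' contour, and (once computed) its texture feature vector and class label.
#'
#' @param px two-column integer matrix of (row, col) member pixels.
#' @param intensities numeric vector of member-pixel intensities (same order).
#' @param spacing_mm (row, col) pixel spacing of the owning slice.
#' @param plane,index identity of the owning slice.
#' @param slice_range intensity range of the owning slice (used for the
#'   histogram-entropy feature); defaults to the region's own range.
#' @param label `"unlabeled"`, `"disk"` or `"background"`.
#' @return Object of class `region2d`.
#' @export
region2d <- function(px, intensities, spacing_mm = c(1, 1),
                     plane = "sagittal", index = 1L, slice_range = NULL,
                     label = "unlabeled") {
  px <- matrix(as.integer(px), ncol = 2L,
               dimnames = list(NULL, c("row", "col")))
  if (nrow(px) == 0L) stop("a region cannot be empty")
  if (length(intensities) != nrow(px))
    stop("one intensity per member pixel is required")
  if (is.null(slice_range)) slice_range <- range(intensities)
  structure(list(px = px, intensities = as.numeric(intensities),
                 spacing_mm = as.numeric(spacing_mm), plane = plane,
                 index = as.integer(index),
                 slice_range = as.numeric(slice_range),
                 contour = NULL, features = NULL, label = label),
            class = "region2d")
}

#' @export
print.region2d <- function(x, ...) {
  cat(sprintf("<region2d:%s> %d px on %s slice %d\n", x$label, nrow(x$px),
              x$plane, x$index))
  invisible(x)
}

# render the region as a logical mask on its slice grid
region_mask <- function(region, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[region$px] <- TRUE
  m
}

# ordered closed boundary of a region mask (EBImage oriented contour),
# returned as 1-based (row, col) pixel coordinates
trace_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) return(matrix(integer(), ncol = 2L))
  ct <- oc[[which.max(vapply(oc, nrow, 0L))]] + 1L
  colnames(ct) <- c("row", "col")
  ct
}

#' Marker set for one slice
#'
#' Internal markers seed one watershed basin per candidate structure;
#' external markers trace the valley lines separating them, and always
#' include the image border so that the unbounded background basin is
#' labelled external.
#'
#' @param internal,external disjoint logical masks.
#' @return Object of class `marker_set` with `internal`, `external` and
#'   `combined` (their union).
#' @export
marker_set <- function(internal, external) {
  internal <- internal != 0
  external <- external != 0
  if (!all(dim(internal) == dim(external)))
    stop("marker masks must share dimensions")
  if (any(internal & external))
    stop("internal and external markers must be disjoint")
  structure(list(internal = internal, external = external,
                 combined = internal | external),
            class = "marker_set")
}

#' Extract internal watershed markers
#'
#' Finds connected pixel sets inside locally bright, homogeneous areas:
#' the slice is smoothed by opening-then-closing by reconstruction, its
#' h-maxima (contrast `h_fraction` of the dynamic range) are taken, and
#' components smaller than `min_area_mm2` are removed.
#'
#' @param slice a [slice_image()] or matrix.
#' @param params list as in [segmentation_params()].
#' @return Logical matrix of internal markers (possibly empty).
#' @export
extract_internal_markers <- function(slice, params = segmentation_params()) {
  s <- as_slice(slice)
  p <- modifyList(segmentation_params(), params)
  px <- s$pixels
  sm <- smooth_by_reconstruction(px, p$smooth_radius_px)
  rng <- max(sm) - min(sm)
  if (rng == 0) return(matrix(FALSE, nrow(px), ncol(px)))
  h <- p$h_fraction * rng
  hmax <- reconstruct_dilate(sm - h, sm)
  mk <- cpp_regional_maxima(hmax, 8L)
  min_area_px <- ceiling(p$min_area_mm2 / prod(s$spacing_mm))
  lab <- label_components(mk, 8L)
  rejected <- matrix(FALSE, nrow(px), ncol(px))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area_px)
    rejected <- matrix(lab > 0L & !(lab %in% keep), nrow(px), ncol(px))
    mk <- matrix(lab %in% keep, nrow(px), ncol(px))
  }
  # components below the area threshold are not candidate seeds, but they
  # still mark real local structure: callers may demote them to background
  # (external) seeds so neighbouring basins cannot flood across them
  attr(mk, "rejected_small") <- rejected
  mk
}

#' Extract external watershed markers
#'
#' Valley lines surrounding every internal marker: the ridge lines of the
#' watershed of the Euclidean distance-from-marker map, seeded by the
#' internal components, unioned with the one-pixel image border frame.
#' With fewer than two internal components the border frame alone is
#' returned.
#'
#' @param internal logical matrix of internal markers.
#' @param shape dimensions of the slice (defaults to `dim(internal)`).
#' @return Logical matrix, disjoint from `internal`.
#' @export
extract_external_markers <- function(internal, shape = dim(internal)) {
  internal <- internal != 0
  nr <- shape[1]; nc <- shape[2]
  frame <- matrix(FALSE, nr, nc)
  frame[1, ] <- frame[nr, ] <- TRUE
  frame[, 1] <- frame[, nc] <- TRUE
  lab <- label_components(internal, 8L)
  if (max(lab) < 2L) return(frame & !internal)
  dist <- unclass(as.matrix(EBImage::distmap(1 - internal)))
  basins <- cpp_marker_watershed(dist, lab, 4L)
  # one-pixel-thick ridge: pixel whose right or lower neighbour lies in a
  # different basin
  ridge <- matrix(FALSE, nr, nc)
  ridge[, -nc] <- basins[, -nc] != basins[, -1]
  ridge[-nr, ] <- ridge[-nr, ] | (basins[-nr, ] != basins[-1, ])
  (ridge | frame) & !internal
}

#' Marker-controlled flooding of an intensity image
#'
#' Floods the image from the labelled seed pixels in order of increasing
#' intensity (Meyer's algorithm without explicit lines): every pixel joins
#' the basin of the first seed wave that reaches it. Deterministic:
#' gray-level ties are resolved by insertion order, which follows
#' column-major pixel order.
#'
#' @param image numeric matrix (e.g. a gradient).
#' @param seeds integer matrix of the same shape; 0 = unlabelled, positive
#'   values label the seed basins.
#' @param connectivity 4 or 8.
#' @return Integer matrix of basin labels covering every pixel.
#' @export
marker_watershed <- function(image, seeds, connectivity = 4L) {
  if (!all(dim(image) == dim(seeds)))
    stop("`image` and `seeds` must share dimensions")
  cpp_marker_watershed(image, matrix(as.integer(seeds), nrow(image)),
                       as.integer(connectivity))
}

#' Marker-controlled watershed of one slice
#'
#' Floods the minima-imposed gradient from the combined markers; basins
#' grown from internal marker components become candidate regions, basins
#' grown from external markers and any basin touching the image border are
#' discarded as background.
#'
#' @param modified_gradient numeric matrix with minima imposed at the
#'   markers (see [impose_minima()]).
#' @param markers a [marker_set()].
#' @param slice optional owning [slice_image()] supplying the intensities
#'   stored on each region.
#' @return List of [region2d()] candidate regions (label `"unlabeled"`),
#'   pairwise disjoint, each with a closed contour.
#' @export
watershed_segment <- function(modified_gradient, markers, slice = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  if (!any(markers$combined))
    stop("empty marker mask: the watershed would be unseeded")
  lab_int <- label_components(markers$internal, 8L)
  n_int <- max(lab_int)
  seeds <- lab_int
  seeds[markers$external] <- n_int + 1L
  basins <- cpp_marker_watershed(modified_gradient, seeds, 4L)
  if (n_int == 0L) return(list())
  nr <- nrow(basins); nc <- ncol(basins)
  # watershed-line convention: pixels whose 8-neighbourhood meets a
  # different basin belong to the line, not to a region. Regions therefore
  # exclude their outermost transition shell (a slightly conservative,
  # under-estimating contour) and two structures never share a face or a
  # 3D diagonal once the per-slice masks are stacked into volumes.
  line <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    src_r <- max(1, 1 + dr):min(nr, nr + dr)
    src_c <- max(1, 1 + dc):min(nc, nc + dc)
    dst_r <- src_r - dr; dst_c <- src_c - dc
    hit <- basins[dst_r, dst_c] != basins[src_r, src_c]
    line[dst_r, dst_c] <- line[dst_r, dst_c] | hit
  }
  basins[line] <- 0L
  border <- matrix(FALSE, nr, nc)
  border[1, ] <- border[nr, ] <- TRUE
  border[, 1] <- border[, nc] <- TRUE
  s <- if (is.null(slice)) NULL else as_slice(slice)
  regions <- list()
  for (k in seq_len(n_int)) {
    in_basin <- basins == k
    if (!any(in_basin) || any(in_basin & border)) next
    # shaving can in principle split a basin; keep its largest 4-connected
    # piece so the region stays connected with a closed contour
    lab_k <- label_components(in_basin, 4L)
    if (max(lab_k) > 1L) {
      sizes <- tabulate(lab_k[lab_k > 0L])
      in_basin <- lab_k == which.max(sizes)
    }
    px <- which(in_basin, arr.ind = TRUE)
    ints <- if (is.null(s)) modified_gradient[in_basin] else s$pixels[in_basin]
    reg <- region2d(px, ints,
                    spacing_mm = if (is.null(s)) c(1, 1) else s$spacing_mm,
                    plane = if (is.null(s)) "sagittal" else s$plane,
                    index = if (is.null(s)) 1L else s$index,
                    slice_range = if (is.null(s)) NULL else range(s$pixels))
    reg$contour <- trace_contour(in_basin)
    regions[[length(regions) + 1L]] <- reg
  }
  regions
}

#' Segment one slice into candidate regions
#'
#' Chains the first stage of the reconstruction pipeline on a single
#' sagittal or coronal slice: morphological gradient, internal and external
#' marker extraction, minima imposition, and marker-controlled watershed.
#' Deterministic; an empty list (no internal markers found) is a valid
#' outcome on laterally extreme slices.
#'
#' @param slice a [slice_image()] or matrix.
#' @param params list as in [segmentation_params()].
#' @return List of candidate [region2d()] (possibly empty).
#' @export
segment_slice <- function(slice, params = segmentation_params()) {
  s <- as_slice(slice)
  p <- modifyList(segmentation_params(), params)
  internal <- extract_internal_markers(s, p)
  if (!any(internal)) {
    msg("segment_slice: no internal markers on ", s$plane, " slice ", s$index)
    return(list())
  }
  rejected <- attr(internal, "rejected_small")
  external <- extract_external_markers(internal)
  if (!is.null(rejected)) external <- external | rejected
  mk <- marker_set(internal, external)
  grad <- morphological_gradient(s, p$se_radius_px)
  modg <- impose_minima(grad, mk$combined)
  watershed_segment(modg, mk, slice = s)
}
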