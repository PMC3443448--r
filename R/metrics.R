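#' Dice similarity coefficient of two voxel sets
#'
#' `DSC(X, Y) = 2 |X ∩ Y| / (|X| + |Y|)`, the spatial-overlap statistic
#' in `[0, 1]`: 1 means perfect overlap, 0 means no overlap, and values
#' above 0.7 are conventionally read as good segmentation agreement.
#'
#' @param x,y binary 3D arrays or [disk_volume()] objects on the same grid;
#'   not both empty.
#' @return Object of class `dsc_result`: `value`, `n_x`, `n_y`,
#'   `n_intersection`.
#' @export
dsc <- function(x, y) {
  xs <- as_voxel_set(x)
  ys <- as_voxel_set(y)
  if (!all(xs$dim == ys$dim))
    stop("`x` and `y` must live on the same grid")
  n_x <- length(xs$idx); n_y <- length(ys$idx)
  if (n_x + n_y == 0L)
    stop("DSC is undefined when both sets are empty")
  n_int <- length(intersect(xs$idx, ys$idx))
  structure(list(value = 2 * n_int / (n_x + n_y), n_x = n_x, n_y = n_y,
                 n_intersection = n_int),
            class = "dsc_result")
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("DSC = %.4f  (|X| = %d, |Y| = %d, overlap = %d)\n",
              x$value, x$n_x, x$n_y, x$n_intersection))
  invisible(x)
}

#' Per-slice 2D Dice coefficients
#'
#' The 2D DSC of every slice along the given axis where the union of the
#' two sets is nonempty; slices where exactly one set is empty score 0,
#' slices where both are empty are skipped.
#'
#' @param x,y binary 3D arrays or [disk_volume()] on the same grid.
#' @param axis slicing axis (1 = `lr`, the sagittal stacking axis).
#' @return Tibble with `slice`, `value`, `n_x`, `n_y`, `n_intersection`.
#' @export
dsc_per_slice <- function(x, y, axis = 1L) {
  xs <- as_voxel_set(x)
  ys <- as_voxel_set(y)
  if (!all(xs$dim == ys$dim))
    stop("`x` and `y` must live on the same grid")
  sx <- arrayInd(xs$idx, xs$dim)[, axis]
  sy <- arrayInd(ys$idx, ys$dim)[, axis]
  slices <- sort(unique(c(sx, sy)))
  rows <- lapply(slices, function(s) {
    ix <- xs$idx[sx == s]; iy <- ys$idx[sy == s]
    ni <- length(intersect(ix, iy))
    data.frame(slice = s, value = 2 * ni / (length(ix) + length(iy)),
               n_x = length(ix), n_y = length(iy), n_intersection = ni)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Partition a disk's slice span into mid-sagittal and lateral groups
#'
#' Mid-sagittal slices are the central ~80% of the slices spanning a disk;
#' the lateral slices are the remainder, split symmetrically with
#' `ceiling(0.10 * n)` slices on each side.
#'
#' @param spanning_indices ordered slice indices covering the disk (>= 3).
#' @param lateral_fraction per-side lateral fraction (default 0.10).
#' @return Object of class `slice_partition`: `mid_indices`,
#'   `lateral_indices`, `n_mid`, `n_lateral`.
#' @export
partition_mid_lateral <- function(spanning_indices, lateral_fraction = 0.10) {
  idx <- sort(as.integer(spanning_indices))
  n <- length(idx)
  if (n < 3L) stop("at least 3 spanning slices are required")
  per_side <- ceiling(lateral_fraction * n)
  if (2L * per_side >= n)
    stop("lateral fraction leaves no mid-sagittal slices")
  lateral <- c(idx[seq_len(per_side)], idx[n - per_side + seq_len(per_side)])
  mid <- setdiff(idx, lateral)
  structure(list(mid_indices = mid, lateral_indices = lateral,
                 n_mid = length(mid), n_lateral = length(lateral)),
            class = "slice_partition")
}

#' @export
print.slice_partition <- function(x, ...) {
  cat(sprintf("<slice_partition> %d mid-sagittal + %d lateral slices\n",
              x$n_mid, x$n_lateral))
  invisible(x)
}

#' Volume discrepancy between automatic and manual segmentations
#'
#' Signed relative voxel-count difference `(|auto| - |manual|) / |manual|`;
#' negative values indicate under-estimation by the automatic method.
#'
#' @param auto,manual binary 3D arrays or [disk_volume()] on the same grid.
#' @param spacing_mm per-axis spacing used for the mm^3 report.
#' @return List: `relative`, `n_auto`, `n_manual`, `mm3_auto`, `mm3_manual`.
#' @export
volume_discrepancy <- function(auto, manual, spacing_mm = c(1, 1, 1)) {
  as_ <- as_voxel_set(auto)
  ms <- as_voxel_set(manual)
  if (!all(as_$dim == ms$dim))
    stop("`auto` and `manual` must live on the same grid")
  if (length(ms$idx) == 0L) stop("`manual` set must be nonempty")
  vv <- prod(spacing_mm)
  list(relative = (length(as_$idx) - length(ms$idx)) / length(ms$idx),
       n_auto = length(as_$idx), n_manual = length(ms$idx),
       mm3_auto = length(as_$idx) * vv, mm3_manual = length(ms$idx) * vv)
}

# one-pixel boundary of a 2D mask (pixels with a 4-neighbour outside)
mask_boundary2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  m & !inner
}

#' Boundary distance near the spinal canal
#'
#' On each listed sagittal slice, every manual boundary pixel inside the
#' posterior band (the posterior `posterior_fraction` of the disk's
#' anterior-posterior extent on that slice; higher row index = more
#' posterior) is mapped to its nearest automatic boundary pixel, and the
#' Euclidean distances in mm are pooled over slices.
#'
#' @param auto,manual binary 3D arrays `[lr, ap, si]` of the two
#'   segmentations.
#' @param canal_slices nonempty `lr` indices of the slices spanning the
#'   canal.
#' @param spacing_mm per-axis spacing.
#' @param posterior_fraction fraction of the ap extent forming the band.
#' @return List: `mean_mm`, `sd_mm` (population), `n_points`, and a
#'   per-slice tibble. Slices with an empty automatic mask are skipped.
#' @export
canal_boundary_distance <- function(auto, manual, canal_slices,
                                    spacing_mm = c(1, 1, 1),
                                    posterior_fraction = 0.25) {
  if (length(canal_slices) == 0L) stop("`canal_slices` must be nonempty")
  dists <- numeric(0)
  rows <- list()
  for (s in canal_slices) {
    m2 <- manual[s, , ] != 0
    a2 <- auto[s, , ] != 0
    if (!any(m2)) stop("manual mask empty on slice ", s)
    if (!any(a2)) {
      msg("canal_boundary_distance: automatic mask empty on slice ", s,
          "; skipped")
      next
    }
    mb <- which(mask_boundary2d(m2), arr.ind = TRUE)
    ab <- which(mask_boundary2d(a2), arr.ind = TRUE)
    ap_rng <- range(which(rowSums(m2) > 0))
    band_lo <- ap_rng[2] - posterior_fraction * (ap_rng[2] - ap_rng[1] + 1)
    mb <- mb[mb[, 1] >= band_lo, , drop = FALSE]
    if (nrow(mb) == 0L) next
    sp2 <- spacing_mm[2:3]
    d <- vapply(seq_len(nrow(mb)), function(i) {
      dd <- (ab[, 1] - mb[i, 1]) * sp2[1]
      ee <- (ab[, 2] - mb[i, 2]) * sp2[2]
      sqrt(min(dd^2 + ee^2))
    }, 0)
    dists <- c(dists, d)
    rows[[length(rows) + 1L]] <-
      data.frame(slice = s, n_points = length(d), mean_mm = mean(d))
  }
  if (length(dists) == 0L)
    stop("no usable boundary points in the posterior band")
  list(mean_mm = mean(dists), sd_mm = sd_pop(dists), n_points = length(dists),
       per_slice = tibble::as_tibble(do.call(rbind, rows)))
}

#' Pairwise variability table across raters and the automatic method
#'
#' For each unordered pair of segmentation sources (e.g. `user1`, `user2`,
#' `auto`) the per-disk 3D DSC is computed and summarised as mean and
#' sample (n - 1) standard deviation over disks. Disks missing a source are
#' excluded for the pairs involving it.
#'
#' @param segmentations list with one element per disk, each a named list
#'   of binary arrays / [disk_volume()] (the same names across disks).
#' @return Tibble: `a`, `b`, `mean_dsc`, `sd_dsc`, `n_disks`.
#' @export
variability_table <- function(segmentations) {
  if (length(segmentations) < 1L) stop("at least one disk is required")
  nms <- sort(unique(unlist(lapply(segmentations, names))))
  if (length(nms) < 2L)
    stop("at least two named segmentations per disk are required")
  pairs <- utils::combn(nms, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    vals <- numeric(0)
    for (d in seq_along(segmentations)) {
      sd_ <- segmentations[[d]]
      if (is.null(sd_[[a]]) || is.null(sd_[[b]])) {
        msg("variability_table: disk ", d, " lacks ", a, " or ", b,
            "; excluded")
        next
      }
      vals <- c(vals, dsc(sd_[[a]], sd_[[b]])$value)
    }
    data.frame(a = a, b = b,
               mean_dsc = if (length(vals)) mean(vals) else NA_real_,
               sd_dsc = if (length(vals) > 1L) sd(vals) else NA_real_,
               n_disks = length(vals))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Full evaluation report for one reconstruction
#'
#' Per-disk 3D DSC, voxel counts and volume discrepancy, plus per-slice 2D
#' DSC with the mid-sagittal/lateral partition group of each slice.
#'
#' @param fused list of [disk_volume()] (or binary arrays), one per disk.
#' @param truth list of binary arrays / [disk_volume()] ground truth, same
#'   order and grid.
#' @param spacing_mm per-axis spacing.
#' @param lateral_fraction per-side lateral fraction for the partition.
#' @return List of tibbles `per_disk` and `per_slice`.
#' @export
evaluate_reconstruction <- function(fused, truth, spacing_mm = c(1, 1, 1),
                                    lateral_fraction = 0.10) {
  if (length(fused) != length(truth))
    stop("`fused` and `truth` must have one entry per disk")
  per_disk <- list()
  per_slice <- list()
  for (i in seq_along(fused)) {
    d3 <- dsc(fused[[i]], truth[[i]])
    vd <- volume_discrepancy(fused[[i]], truth[[i]], spacing_mm)
    per_disk[[i]] <- data.frame(disk = i, dsc_3d = d3$value,
                                n_auto = d3$n_x, n_truth = d3$n_y,
                                discrepancy = vd$relative)
    ps <- dsc_per_slice(fused[[i]], truth[[i]], axis = 1L)
    span <- ps$slice
    grp <- rep("mid_sagittal", nrow(ps))
    if (length(span) >= 3L) {
      part <- partition_mid_lateral(span, lateral_fraction)
      grp[ps$slice %in% part$lateral_indices] <- "lateral"
    }
    ps$group <- grp
    ps$disk <- i
    per_slice[[i]] <- ps
  }
  list(per_disk = tibble::as_tibble(do.call(rbind, per_disk)),
       per_slice = tibble::as_tibble(do.call(rbind, per_slice)))
}
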