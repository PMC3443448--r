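#' Segment every slice of a volume along one plane
#'
#' Runs the per-slice marker-controlled watershed over the whole stack and
#' collects the candidate regions and their stacked binary mask.
#'
#' @param volume a [voxel_volume()].
#' @param plane `"sagittal"` or `"coronal"`.
#' @param params list as in [segmentation_params()].
#' @return List: `mask` (logical array on the volume grid, all candidate
#'   regions), `regions` (list of lists of [region2d()], one per slice) and
#'   `table` (tibble: slice, region, area_px, bounding box).
#' @export
segment_volume <- function(volume, plane = c("sagittal", "coronal"),
                           params = segmentation_params()) {
  plane <- match.arg(plane)
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$data)
  n_slices <- if (plane == "sagittal") d[1] else d[2]
  mask <- array(FALSE, d)
  regions <- vector("list", n_slices)
  rows <- list()
  for (s in seq_len(n_slices)) {
    regs <- segment_slice(get_slice(volume, s, plane), params)
    regions[[s]] <- regs
    for (r in seq_along(regs)) {
      px <- regs[[r]]$px
      if (plane == "sagittal") {
        m2 <- mask[s, , ]; m2[px] <- TRUE; mask[s, , ] <- m2
      } else {
        m2 <- mask[, s, ]; m2[px] <- TRUE; mask[, s, ] <- m2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        slice = s, region = r, area_px = nrow(px),
        row_min = min(px[, 1]), row_max = max(px[, 1]),
        col_min = min(px[, 2]), col_max = max(px[, 2]))
    }
  }
  tab <- if (length(rows)) tibble::as_tibble(do.call(rbind, rows))
         else tibble::tibble(slice = integer(), region = integer(),
                             area_px = integer(), row_min = integer(),
                             row_max = integer(), col_min = integer(),
                             col_max = integer())
  list(mask = mask, regions = regions, table = tab)
}

#' Run the full disk-reconstruction pipeline
#'
#' The three-stage reconstruction: (1) marker-controlled watershed
#' segmentation of every native sagittal slice, (2) k-NN labelling of the
#' sagittal candidate regions and stacking of the disk-labelled masks into
#' per-disk reference volumes, (3) isotropic coronal reconstruction,
#' segmentation of the coronal slices (area and border rules only, no
#' classifier), and centroid-matched fusion `D = Dref ∪ Dcor`.
#'
#' @param volume a [voxel_volume()] (sagittal acquisition).
#' @param model a [train_knn()] disk/background classifier.
#' @param config configuration list (see [default_config()]); partial
#'   configurations are completed.
#' @return Object of class `pipeline_result`: `fused`, `reference` and
#'   `coronal` lists of [disk_volume()] on the isotropic grid, plus the
#'   grid description and the completed `config`.
#' @export
run_pipeline <- function(volume, model, config = list()) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(model, "knn_model"))
  cfg <- validate_config(config)
  iso <- cfg$fusion$iso_mm

  sag <- segment_volume(volume, "sagittal", cfg$segmentation)
  n_cand <- sum(lengths(sag$regions))
  disk_mask <- array(FALSE, dim(volume$data))
  n_disk_regions <- 0L
  for (s in seq_along(sag$regions)) {
    regs <- classify_regions(model, sag$regions[[s]], cfg$classification)
    for (r in regs) {
      if (r$label != "disk") next
      m2 <- disk_mask[s, , ]; m2[r$px] <- TRUE; disk_mask[s, , ] <- m2
      n_disk_regions <- n_disk_regions + 1L
    }
  }
  msg(sprintf("sagittal: %d candidate regions, %d labelled disk",
              n_cand, n_disk_regions))

  if (all(volume$spacing_mm == iso)) {
    disk_mask_iso <- disk_mask
    iso_vol <- volume
  } else {
    disk_mask_iso <- resample_mask(disk_mask, volume$spacing_mm, iso)
    iso_vol <- reconstruct_coronal(volume, iso)
  }
  reference <- build_disk_volumes(disk_mask_iso, "sagittal",
                                  rep(iso, 3), cfg$fusion$min_component_voxels)
  if (length(reference) == 0L)
    stop("classification produced an empty reference set: ",
         "no disk-labelled sagittal regions survived")
  msg(sprintf("reference: %d disk volumes", length(reference)))

  if (isTRUE(cfg$fusion$enabled)) {
    cor <- segment_volume(iso_vol, "coronal", cfg$segmentation)
    coronal <- build_disk_volumes(cor$mask, "coronal", rep(iso, 3),
                                  cfg$fusion$min_component_voxels)
    msg(sprintf("coronal: %d components", length(coronal)))
    fused <- match_and_fuse(reference, coronal, cfg$fusion$max_dist_mm)
  } else {
    coronal <- list()
    fused <- lapply(reference, function(v) {
      f <- disk_volume(v$idx, v$dim, v$spacing_mm, "fused")
      attr(f, "n_reference") <- length(v$idx)
      attr(f, "n_coronal") <- 0L
      attr(f, "assigned") <- integer(0)
      f
    })
  }
  structure(list(fused = fused, reference = reference, coronal = coronal,
                 grid = list(dim = reference[[1]]$dim,
                             spacing_mm = rep(iso, 3)),
                 config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d fused disks (from %d reference, ",
                     "%d coronal components) on a %s grid\n"),
              length(x$fused), length(x$reference), length(x$coronal),
              paste(x$grid$dim, collapse = "x")))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(n_fused = length(x$fused),
                 n_reference = length(x$reference),
                 n_coronal = length(x$coronal),
                 voxels_fused = sum(vapply(x$fused, function(v)
                   length(v$idx), 0L)))
}
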