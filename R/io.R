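#' Read / write a volume as NIfTI-1
#'
#' Volumes are stored with the data array in the package's `[lr, ap, si]`
#' axis convention and the per-axis spacing in the NIfTI `pixdim` field.
#' Reading demands usable orientation/spacing metadata (a nonzero
#' qform/sform) unless `axes` asserts that the file is already in
#' `[lr, ap, si]` order.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param axes set to `"lr,ap,si"` to accept a file without orientation
#'   metadata as already being in the package convention.
#' @return `read_volume` returns a [voxel_volume()]; `write_volume`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, axes = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI volume: ",
                                           conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0 && hdr$sform_code == 0 &&
      !identical(axes, "lr,ap,si"))
    stop("volume has no orientation metadata; pass axes = \"lr,ap,si\" ",
         "to assert the axis order explicitly")
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  arr <- array(as.vector(arr), dim(arr))   # strip NIfTI attributes
  voxel_volume(arr, RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param volume a [voxel_volume()] (or a logical mask array plus
#'   `spacing_mm`).
#' @param spacing_mm spacing used when `volume` is a bare array.
#' @export
write_volume <- function(volume, path, spacing_mm = NULL) {
  if (inherits(volume, "voxel_volume")) {
    arr <- volume$data
    sp <- volume$spacing_mm
  } else {
    if (is.null(spacing_mm))
      stop("`spacing_mm` is required when writing a bare array")
    arr <- volume * 1
    sp <- spacing_mm
  }
  img <- RNifti::asNifti(arr)
  # scanner-anatomical qform so readers can trust the axis order
  RNifti::qform(img) <- structure(diag(c(sp, 1)), code = 2L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom to disk
#'
#' Writes the intensity volume and each ground-truth disk mask as NIfTI-1
#' files plus a JSON sidecar holding the generating parameters and the
#' per-disk centroids.
#'
#' @param phantom a [make_spine_phantom()] result.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return Invisibly, the sidecar path.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  stopifnot(inherits(phantom, "phantom_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, paste0(stem, ".nii.gz")))
  for (i in seq_along(phantom$truth_masks))
    write_volume(phantom$truth_masks[[i]],
                 file.path(dir, sprintf("%s_disk%02d.nii.gz", stem, i)),
                 spacing_mm = phantom$volume$spacing_mm)
  sidecar <- file.path(dir, paste0(stem, ".json"))
  spec <- phantom$spec
  jsonlite::write_json(
    list(spec = unclass(spec),
         disk_centroids_mm = as.data.frame(phantom$disk_centroids_mm)),
    sidecar, digits = NA, auto_unbox = TRUE)
  invisible(sidecar)
}

#' Default pipeline configuration
#'
#' Nested configuration blocks covering every tunable of the pipeline;
#' a fully-defaulted configuration is valid. Unknown keys are rejected by
#' [validate_config()].
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    phantom = list(n_disks = 5L, cobb_like_angle_deg = 30,
                   contrast_preset = "medic", blur_sigma_mm = 0.8,
                   noise_sigma = 0.05, bright_nucleus = FALSE),
    segmentation = segmentation_params(),
    classification = classification_params(),
    fusion = c(list(enabled = TRUE), fusion_params()),
    evaluation = list(posterior_fraction = 0.25, lateral_fraction = 0.10),
    robustness = list(M = 3L, k = 4L, p = 2L, blocks = 3L),
    seed = 42L,
    output_dir = ".",
    log_level = "info"
  )
}

#' Validate and complete a pipeline configuration
#'
#' @param config partial named nested list; missing keys take defaults,
#'   unknown keys raise an error.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  check <- function(given, ref, path) {
    bad <- setdiff(names(given), names(ref))
    if (length(bad) > 0L)
      stop("unknown configuration key", if (length(bad) > 1) "s", ": ",
           paste0(path, bad, collapse = ", "))
    for (nm in names(given))
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
        check(as.list(given[[nm]]), ref[[nm]], paste0(path, nm, "."))
  }
  check(as.list(config), def, "")
  modifyList(def, config)
}

#' Read a configuration file (YAML or JSON)
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return The validated, completed configuration.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' Read / write a design matrix with responses as CSV
#'
#' Columns: `run`, `block`, one per factor, and optionally `response`.
#'
#' @param path file path.
#' @return `read_design_csv` returns a tibble usable by
#'   [estimate_effects()].
#' @export
read_design_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  if (!all(c("run", "block") %in% names(df)))
    stop("design CSV needs `run` and `block` columns")
  structure(df, class = c("design_matrix", class(df)),
            factor_names = setdiff(names(df), c("run", "block", "response")))
}

#' @rdname read_design_csv
#' @param design a design tibble.
#' @export
write_design_csv <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}
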