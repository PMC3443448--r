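#' Specification of a synthetic scoliotic-spine phantom
#'
#' Describes a synthetic short-TE spine MR volume: bright elliptical
#' intervertebral disks between darker vertebral bodies along a laterally
#' curved spine, with Gaussian point spread, additive Gaussian noise, and
#' sequence-specific artefact modes. The defaults are the reference study
#' conditions used throughout the package's tests: a 5-disk spine with a
#' 30 degree lateral curvature, moderate noise, and the 1 mm isotropic
#' short-TE contrast preset.
#'
#' @param grid_shape voxel counts per axis `(lr, ap, si)`; preset-specific
#'   default when `NULL`.
#' @param spacing_mm per-axis spacing in mm; preset-specific default when
#'   `NULL` (`medic`/`fisp`: 1 mm isotropic; `spin_echo`: 2 mm slices with a
#'   0.4 mm gap along `lr`, i.e. 2.4 mm centre-to-centre, and 0.67 mm
#'   in-plane pixels).
#' @param n_disks number of intervertebral disks (>= 1).
#' @param cobb_like_angle_deg lateral curvature severity: the tangent-angle
#'   difference between the two end vertebrae of a single coronal-plane arc,
#'   in `[0, 90)`. 0 gives a straight spine.
#' @param disk_semi_axes_mm ellipsoid semi-axes `(ap, lr, si)` of each disk.
#' @param contrast_preset `"medic"`, `"spin_echo"` or `"fisp"`. All render
#'   disks brighter than vertebrae and background; `fisp` additionally blurs
#'   disk boundaries (larger effective point spread at mask edges).
#' @param blur_sigma_mm Gaussian point-spread width (>= 0).
#' @param noise_sigma additive Gaussian noise standard deviation, relative
#'   to the disk/background intensity contrast (>= 0).
#' @param bright_nucleus emulate the short-TE spin-echo artefact in which
#'   the nucleus renders brighter than the annulus.
#' @param seed integer; all phantom randomness flows from it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL, spacing_mm = NULL, n_disks = 5L,
                         cobb_like_angle_deg = 30,
                         disk_semi_axes_mm = c(ap = 10, lr = 12, si = 4),
                         contrast_preset = c("medic", "spin_echo", "fisp"),
                         blur_sigma_mm = 0.8, noise_sigma = 0.05,
                         bright_nucleus = FALSE, seed = 42L) {
  contrast_preset <- match.arg(contrast_preset)
  if (is.null(spacing_mm))
    spacing_mm <- if (contrast_preset == "spin_echo") c(2.4, 0.67, 0.67)
                  else c(1, 1, 1)
  if (is.null(grid_shape))
    grid_shape <- if (contrast_preset == "spin_echo") c(18L, 72L, 180L)
                  else c(44L, 48L, 120L)
  if (n_disks < 1L) stop("`n_disks` must be >= 1")
  if (any(spacing_mm <= 0)) stop("all spacings must be > 0")
  if (blur_sigma_mm < 0) stop("`blur_sigma_mm` must be >= 0")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (cobb_like_angle_deg < 0 || cobb_like_angle_deg >= 90)
    stop("`cobb_like_angle_deg` must lie in [0, 90)")
  if (length(disk_semi_axes_mm) != 3L || any(disk_semi_axes_mm <= 0))
    stop("`disk_semi_axes_mm` must be three positive semi-axes (ap, lr, si)")
  names(disk_semi_axes_mm) <- c("ap", "lr", "si")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 n_disks = as.integer(n_disks),
                 cobb_like_angle_deg = cobb_like_angle_deg,
                 disk_semi_axes_mm = disk_semi_axes_mm,
                 contrast_preset = contrast_preset,
                 blur_sigma_mm = blur_sigma_mm, noise_sigma = noise_sigma,
                 bright_nucleus = isTRUE(bright_nucleus),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# intensity levels shared by the presets; disks get slightly distinct
# intensities so each truth mask is the level set of its own disk value
# in the noise-free, blur-free limit
phantom_levels <- function(n_disks) {
  list(background = 0.20, vertebra = 0.45,
       disk = if (n_disks == 1L) 0.80 else seq(0.78, 0.82, length.out = n_disks))
}

# single-arc centreline in the coronal (lr-si) plane; s is arc length,
# phi the end-tangent angle difference (radians)
centreline_xz <- function(s, L, phi) {
  if (phi == 0) return(cbind(x = rep(0, length(s)), z = s))
  R <- L / phi
  a <- phi * (s / L - 0.5)
  cbind(x = R * (cos(phi / 2) - cos(a)),
        z = R * (sin(a) + sin(phi / 2)))
}

# separable Gaussian blur of a 3D array, sigma in mm per axis
gauss3d <- function(arr, sigma_mm, spacing_mm) {
  d <- dim(arr)
  sigma_vox <- sigma_mm / spacing_mm
  kern_mat <- function(n, s) {
    r <- max(1L, ceiling(3 * s))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- exp(-((j - i)^2) / (2 * s^2))
      K[i, j] <- w / sum(w)
    }
    K
  }
  if (sigma_vox[1] > 1e-8) {
    K <- kern_mat(d[1], sigma_vox[1])
    arr <- array(K %*% matrix(arr, d[1]), d)
  }
  if (sigma_vox[2] > 1e-8) {
    K <- kern_mat(d[2], sigma_vox[2])
    a2 <- aperm(arr, c(2, 1, 3))
    a2 <- array(K %*% matrix(a2, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(a2, c(2, 1, 3))
  }
  if (sigma_vox[3] > 1e-8) {
    K <- kern_mat(d[3], sigma_vox[3])
    a3 <- aperm(arr, c(3, 1, 2))
    a3 <- array(K %*% matrix(a3, d[3]), c(d[3], d[1], d[2]))
    arr <- aperm(a3, c(2, 3, 1))
  }
  arr
}

# voxelize a tilted ellipsoid (tilt alpha in the lr-si plane, thin axis
# along the local centreline tangent); returns linear voxel indices
voxelize_ellipsoid <- function(centre, semi, alpha, dims, sp) {
  rmax <- max(semi) + 2 * max(sp)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor((centre[a] - rmax) / sp[a] + 0.5))
    hi <- min(dims[a], ceiling((centre[a] + rmax) / sp[a] + 0.5))
    if (lo > hi) integer() else lo:hi
  })
  if (any(lengths(rng) == 0L)) return(integer())
  xs <- (rng[[1]] - 0.5) * sp[1] - centre[1]
  ys <- (rng[[2]] - 0.5) * sp[2] - centre[2]
  zs <- (rng[[3]] - 0.5) * sp[3] - centre[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  u1 <- cos(alpha) * g$x - sin(alpha) * g$z     # lr' (in-plane lateral)
  u3 <- sin(alpha) * g$x + cos(alpha) * g$z     # si' (along tangent)
  inside <- (u1 / semi["lr"])^2 + (g$y / semi["ap"])^2 +
            (u3 / semi["si"])^2 <= 1
  if (!any(inside)) return(integer())
  gi <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])[inside, ]
  gi$i + (gi$j - 1L) * dims[1] + (gi$k - 1L) * dims[1] * dims[2]
}

#' Generate a synthetic scoliotic-spine phantom
#'
#' Renders a [phantom_spec()] into an MR-like [voxel_volume()] together with
#' per-disk ground-truth masks (the noise-free voxelized ellipsoids, before
#' blurring). Disks are ellipsoids oriented perpendicular to the local
#' centreline tangent; vertebral bodies are larger, darker ellipsoids between
#' them. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom_volume`: a list with `volume`
#'   ([voxel_volume()]), `truth_masks` (list of logical arrays, one per
#'   disk, superior to inferior), `disk_ids`, `disk_centroids_mm` and the
#'   originating `spec`.
#' @export
make_spine_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$spacing_mm
  extent <- dims * sp
  semi <- spec$disk_semi_axes_mm
  pitch <- 4 * semi["si"] + 6                  # disk centre-to-centre (mm)
  vert_semi <- c(ap = unname(semi["ap"]) + 2, lr = unname(semi["lr"]) + 2,
                 si = unname((pitch - 2 * semi["si"] - 2) / 2))
  L <- spec$n_disks * pitch
  phi <- spec$cobb_like_angle_deg * pi / 180
  z_span <- if (phi == 0) L else 2 * (L / phi) * sin(phi / 2)
  if (extent[3] < z_span)
    stop(sprintf(paste0("grid too small along si for %d disks: needs a ",
                        "superior-inferior extent of at least %.0f mm ",
                        "(have %.0f mm)"),
                 spec$n_disks, ceiling(z_span), extent[3]))
  dev <- if (phi == 0) 0 else (L / phi) * (1 - cos(phi / 2))
  z0 <- (extent[3] - z_span) / 2
  x0 <- extent[1] / 2 + dev / 2
  y0 <- extent[2] / 2
  place <- function(s) {
    xz <- centreline_xz(s, L, phi)
    list(centre = c(x0 + xz[, "x"], y0, z0 + xz[, "z"]),
         alpha = if (phi == 0) 0 else phi * (s / L - 0.5))
  }
  lev <- phantom_levels(spec$n_disks)
  canvas <- array(lev$background, dims)
  # vertebral bodies at the midpoints between disks (ends included)
  vertebra <- vector("list", spec$n_disks + 1L)
  for (j in 0:spec$n_disks) {
    pj <- place(j * pitch)
    vidx <- voxelize_ellipsoid(pj$centre, vert_semi, pj$alpha, dims, sp)
    canvas[vidx] <- lev$vertebra
    vm <- array(FALSE, dims)
    vm[vidx] <- TRUE
    vertebra[[j + 1L]] <- vm
  }
  truth <- vector("list", spec$n_disks)
  centroids <- matrix(NA_real_, spec$n_disks, 3,
                      dimnames = list(NULL, c("lr", "ap", "si")))
  for (i in seq_len(spec$n_disks)) {
    pi_ <- place((i - 0.5) * pitch)
    didx <- voxelize_ellipsoid(pi_$centre, semi, pi_$alpha, dims, sp)
    if (length(didx) == 0L)
      stop("disk ", i, " fell outside the grid; enlarge `grid_shape`")
    dint <- lev$disk[min(i, length(lev$disk))]
    if (spec$bright_nucleus) {
      nidx <- voxelize_ellipsoid(pi_$centre, semi * 0.55, pi_$alpha, dims, sp)
      canvas[didx] <- dint - 0.12
      canvas[nidx] <- dint + 0.12
    } else {
      canvas[didx] <- dint
    }
    m <- array(FALSE, dims)
    m[didx] <- TRUE
    truth[[i]] <- m
    centroids[i, ] <- pi_$centre
  }
  vol <- canvas
  if (spec$contrast_preset == "fisp") {
    any_mask <- Reduce(`|`, truth)
    ms <- gauss3d(any_mask * 1, 1.0, sp)
    w <- pmin(1, 4 * ms * (1 - ms))             # peaks on disk boundaries
    vb <- gauss3d(vol, max(spec$blur_sigma_mm, 1) + 1.5, sp)
    vol <- vol * (1 - w) + vb * w
  }
  if (spec$blur_sigma_mm > 0) vol <- gauss3d(vol, spec$blur_sigma_mm, sp)
  if (spec$noise_sigma > 0) {
    contrast <- mean(lev$disk) - lev$background
    vol <- with_seed(spec$seed,
      vol + array(rnorm(prod(dims), 0, spec$noise_sigma * contrast), dims))
  }
  structure(list(volume = voxel_volume(vol, sp), truth_masks = truth,
                 disk_ids = seq_len(spec$n_disks),
                 disk_centroids_mm = centroids,
                 vertebra_masks = vertebra, spec = spec),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %d disks, preset %s, cobb-like %.0f deg\n",
              length(x$truth_masks), x$spec$contrast_preset,
              x$spec$cobb_like_angle_deg))
  print(x$volume)
  invisible(x)
}

#' Synthesize labelled training regions from a phantom
#'
#' Builds a supervised training set for the region classifier the way one
#' is built on clinical data: sagittal slices of a rendered phantom are
#' segmented by the marker-controlled watershed, and each candidate region
#' is labelled `disk` when the majority of its pixels fall inside a
#' ground-truth disk mask and `background` otherwise. Disk regions are
#' bright, elliptical and smooth; background regions (vertebral-body and
#' soft-tissue basins) are irregular with different intensity statistics.
#' `n_per_class` regions of each label are drawn; slices are visited in a
#' seed-controlled random order so the set is reproducible.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_class regions per label (>= 1).
#' @param seed integer controlling the sampling (independent of the
#'   phantom's own seed).
#' @param params segmentation parameters, see [segmentation_params()].
#' @return List of labelled [region2d()], disk regions first.
#' @export
make_training_regions <- function(spec, n_per_class = 20L, seed = 1L,
                                  params = segmentation_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1")
  ph <- make_spine_phantom(spec)
  dims <- dim(ph$volume$data)
  disk_any <- Reduce(`|`, ph$truth_masks)
  disk_regs <- list()
  bg_regs <- list()
  order_slices <- with_seed(seed, sample(dims[1]))
  for (i in order_slices) {
    if (length(disk_regs) >= n_per_class && length(bg_regs) >= n_per_class)
      break
    regs <- segment_slice(get_slice(ph$volume, i, "sagittal"), params)
    tm <- disk_any[i, , ]
    for (r in regs) {
      frac <- mean(tm[r$px])
      if (frac >= 0.5) {
        if (length(disk_regs) < n_per_class) {
          r$label <- "disk"
          disk_regs[[length(disk_regs) + 1L]] <- r
        }
      } else if (length(bg_regs) < n_per_class) {
        r$label <- "background"
        bg_regs[[length(bg_regs) + 1L]] <- r
      }
    }
  }
  if (length(disk_regs) < n_per_class || length(bg_regs) < n_per_class)
    stop(sprintf(paste0("phantom yielded only %d disk and %d background ",
                        "candidate regions; lower `n_per_class` or enlarge ",
                        "the phantom"),
                 length(disk_regs), length(bg_regs)))
  c(disk_regs, bg_regs)
}
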