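test_that("identity resample returns the input volume unchanged", {
  set.seed(41)
  v <- voxel_volume(array(runif(24 * 20 * 18), c(24, 20, 18)), c(1, 1, 1))
  out <- reconstruct_coronal(v, 1)
  expect_identical(out$data, v$data)
})

test_that("trilinear interpolation stays within local voxel bounds", {
  set.seed(42)
  v <- voxel_volume(array(runif(12 * 10 * 14), c(12, 10, 14)), c(2, 1, 1.5))
  out <- reconstruct_coronal(v, 1)
  expect_true(all(out$data >= min(v$data) - 1e-12))
  expect_true(all(out$data <= max(v$data) + 1e-12))
  expect_equal(unname(out$spacing_mm), c(1, 1, 1))
  expect_error(reconstruct_coronal(v, 100), "extent")
})

test_that("gap-aware resampling recovers the ellipsoid volume within 15%", {
  spec <- phantom_spec(contrast_preset = "spin_echo",
                       grid_shape = c(16L, 54L, 130L), n_disks = 2L,
                       cobb_like_angle_deg = 10, noise_sigma = 0)
  ph <- make_spine_phantom(spec)
  analytic <- 4 / 3 * pi * prod(spec$disk_semi_axes_mm)
  for (m in ph$truth_masks) {
    iso <- resample_mask(m, ph$volume$spacing_mm, 1)
    expect_lt(abs(sum(iso) - analytic) / analytic, 0.15)
  }
})

test_that("stacked truth masks yield one component per disk", {
  ph <- tiny_phantom()
  all_masks <- Reduce(`|`, ph$truth_masks)
  vols <- build_disk_volumes(all_masks, "sagittal", ph$volume$spacing_mm)
  expect_length(vols, length(ph$truth_masks))
  expect_true(all(vapply(vols, function(v) v$source, "") ==
                  "sagittal_reference"))
})

test_that("single-slice masks and grid round-trips behave", {
  m <- array(FALSE, c(10, 12, 14))
  m[5, 3:6, 4:8] <- TRUE
  vols <- build_disk_volumes(m, "coronal", c(1, 1, 1), min_voxels = 1)
  expect_length(vols, 1L)
  expect_identical(length(vols[[1]]$idx), sum(m))
  expect_identical(disk_volume_mask(vols[[1]]), m)
  expect_identical(build_disk_volumes(array(FALSE, c(8, 8, 8)), "coronal"),
                   list())
})

test_that("well-separated components split; centroid is spacing weighted", {
  m <- array(FALSE, c(12, 12, 30))
  m[4:6, 4:6, 2:6] <- TRUE
  m[4:6, 4:6, 15:19] <- TRUE
  vols <- build_disk_volumes(m, "sagittal", c(1, 1, 2), min_voxels = 1)
  expect_length(vols, 2L)
  expect_equal(unname(vols[[1]]$centroid_mm),
               c(mean(4:6) - 0.5, mean(4:6) - 0.5, (mean(2:6) - 0.5) * 2))
})

test_that("fusion honours the union, absorption and monotonicity rules", {
  dims <- c(20L, 20L, 40L)
  ref_mask <- array(FALSE, dims); ref_mask[6:14, 6:14, 5:10] <- TRUE
  ref <- build_disk_volumes(ref_mask, "sagittal", c(1, 1, 1))
  # empty coronal: unchanged voxel sets
  f0 <- match_and_fuse(ref, list())
  expect_identical(f0[[1]]$idx, ref[[1]]$idx)
  expect_identical(f0[[1]]$source, "fused")
  # coronal subset of reference: absorbed
  sub_mask <- array(FALSE, dims); sub_mask[8:12, 8:12, 6:9] <- TRUE
  cor_sub <- build_disk_volumes(sub_mask, "coronal", c(1, 1, 1))
  f1 <- match_and_fuse(ref, cor_sub)
  expect_identical(f1[[1]]$idx, ref[[1]]$idx)
  # overlapping coronal: union grows, monotone in both inputs
  add_mask <- array(FALSE, dims); add_mask[6:14, 6:14, 9:13] <- TRUE
  cor_add <- build_disk_volumes(add_mask, "coronal", c(1, 1, 1))
  f2 <- match_and_fuse(ref, cor_add)
  expect_gte(length(f2[[1]]$idx), length(ref[[1]]$idx))
  expect_gte(length(f2[[1]]$idx), length(cor_add[[1]]$idx))
  expect_identical(sort(f2[[1]]$idx),
                   sort(union(ref[[1]]$idx, cor_add[[1]]$idx)))
  # far coronal component is discarded as background
  far_mask <- array(FALSE, dims); far_mask[2:5, 2:5, 30:36] <- TRUE
  f3 <- match_and_fuse(ref, build_disk_volumes(far_mask, "coronal",
                                               c(1, 1, 1)))
  expect_identical(f3[[1]]$idx, ref[[1]]$idx)
  expect_error(match_and_fuse(list(), cor_sub), "reference")
})

test_that("fused volumes stay disjoint when references are well separated", {
  dims <- c(20L, 20L, 60L)
  m <- array(FALSE, dims)
  m[6:14, 6:14, 5:10] <- TRUE
  m[6:14, 6:14, 30:35] <- TRUE
  ref <- build_disk_volumes(m, "sagittal", c(1, 1, 1))
  cm <- array(FALSE, dims)
  cm[5:15, 6:14, 6:11] <- TRUE
  cm[5:15, 6:14, 29:34] <- TRUE
  cor <- build_disk_volumes(cm, "coronal", c(1, 1, 1))
  fused <- match_and_fuse(ref, cor)
  expect_length(fused, 2L)
  expect_length(intersect(fused[[1]]$idx, fused[[2]]$idx), 0L)
})

test_that("phantom fusion improves or preserves per-disk 3D Dice", {
  ph <- tiny_phantom()
  res <- run_pipeline(ph$volume, tiny_model())
  expect_length(res$fused, length(ph$truth_masks))
  for (i in seq_along(res$fused)) {
    fm <- disk_volume_mask(res$fused[[i]])
    rm_ <- disk_volume_mask(res$reference[[i]])
    ov <- vapply(ph$truth_masks, function(t) sum(fm & t), 0)
    t <- ph$truth_masks[[which.max(ov)]]
    expect_gte(dsc(fm, t)$value, dsc(rm_, t)$value)
  }
})
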