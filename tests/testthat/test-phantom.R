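test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(n_disks = 0), "n_disks")
  expect_error(phantom_spec(cobb_like_angle_deg = 90), "cobb")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(blur_sigma_mm = -0.1), "blur")
  expect_error(phantom_spec(spacing_mm = c(1, 0, 1)), "spacing")
})

test_that("a too-short grid reports the minimal si extent", {
  spec <- phantom_spec(grid_shape = c(28L, 36L, 40L), n_disks = 3L)
  expect_error(make_spine_phantom(spec), "superior-inferior extent")
})

test_that("straight spine puts all disk centroids on the same lr/ap line", {
  ph <- make_spine_phantom(tiny_spec(cobb_like_angle_deg = 0,
                                     noise_sigma = 0, blur_sigma_mm = 0))
  cent <- t(vapply(ph$truth_masks, function(m)
    colMeans(which(m, arr.ind = TRUE)), numeric(3)))
  expect_lt(max(cent[, 1]) - min(cent[, 1]), 1e-9)
  expect_lt(max(cent[, 2]) - min(cent[, 2]), 1e-9)
})

test_that("disk count, disjointness and 3D connectivity hold by construction", {
  ph <- tiny_phantom()
  expect_length(ph$truth_masks, 3L)
  overlap <- Reduce(`+`, lapply(ph$truth_masks, function(m) m * 1L))
  expect_true(all(overlap <= 1L))
  for (m in ph$truth_masks) {
    lab <- spinedisk:::cpp_label3d(as.logical(m), dim(m), 26L)
    expect_identical(max(lab), 1L)
  }
})

test_that("phantom generation is voxel-identical for a fixed seed", {
  a <- make_spine_phantom(tiny_spec())
  b <- make_spine_phantom(tiny_spec())
  expect_identical(a$volume$data, b$volume$data)
  c <- make_spine_phantom(tiny_spec(seed = 99L))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("voxelized disk volume approximates the analytic ellipsoid volume", {
  # semi-axes of at least 4 voxels on every axis
  spec <- phantom_spec(grid_shape = c(30L, 36L, 80L), n_disks = 2L,
                       cobb_like_angle_deg = 0,
                       disk_semi_axes_mm = c(ap = 8, lr = 9, si = 4.5))
  ph <- make_spine_phantom(spec)
  analytic <- 4 / 3 * pi * 8 * 9 * 4.5
  for (m in ph$truth_masks) {
    v <- sum(m) * prod(ph$volume$spacing_mm)
    expect_lt(abs(v - analytic) / analytic, 0.10)
  }
})

test_that("curvature severity strictly increases lateral centroid deviation", {
  dev_of <- function(angle) {
    ph <- make_spine_phantom(tiny_spec(cobb_like_angle_deg = angle,
                                       noise_sigma = 0, blur_sigma_mm = 0))
    mid <- dim(ph$volume$data)[1] / 2 + 0.5
    max(abs(vapply(ph$truth_masks, function(m)
      mean(which(m, arr.ind = TRUE)[, 1]) - mid, 0)))
  }
  devs <- vapply(c(0, 10, 20, 30), dev_of, 0)
  expect_true(all(diff(devs) > 0))
})

test_that("noise- and blur-free phantom is piecewise constant with truth masks as level sets", {
  ph <- make_spine_phantom(tiny_spec(noise_sigma = 0, blur_sigma_mm = 0))
  vals <- sort(unique(as.vector(ph$volume$data)))
  # background, vertebra, and one distinct intensity per disk
  expect_identical(length(vals), 2L + length(ph$truth_masks))
  for (m in ph$truth_masks) {
    lev <- unique(ph$volume$data[m])
    expect_length(lev, 1L)
    expect_identical(unname(which(ph$volume$data == lev)), which(m))
  }
})

test_that("fisp preset blurs disk boundaries more than medic", {
  base <- tiny_spec(noise_sigma = 0)
  medic <- make_spine_phantom(base)
  fisp_spec <- tiny_spec(noise_sigma = 0, contrast_preset = "fisp")
  fisp_spec$spacing_mm <- base$spacing_mm
  fisp_spec$grid_shape <- base$grid_shape
  fisp <- make_spine_phantom(fisp_spec)
  # gradient magnitude across the disk boundary drops under fisp
  edge_grad <- function(ph) {
    m <- ph$truth_masks[[2]]
    i <- round(mean(which(apply(m, 1, any))))
    g <- morphological_gradient(ph$volume$data[i, , ])
    max(g)
  }
  expect_lt(edge_grad(fisp), edge_grad(medic))
})

test_that("bright-nucleus mode renders the nucleus brighter than the annulus", {
  ph <- make_spine_phantom(tiny_spec(bright_nucleus = TRUE, noise_sigma = 0,
                                     blur_sigma_mm = 0))
  m <- ph$truth_masks[[1]]
  co <- which(m, arr.ind = TRUE)
  centre <- colMeans(co)
  d2 <- rowSums(sweep(co, 2, centre)^2)
  nucleus <- ph$volume$data[m][d2 < quantile(d2, 0.2)]
  annulus <- ph$volume$data[m][d2 > quantile(d2, 0.8)]
  expect_gt(mean(nucleus), mean(annulus))
})

test_that("spin-echo preset defaults to gapped lr sampling", {
  spec <- phantom_spec(contrast_preset = "spin_echo")
  expect_identical(spec$spacing_mm[1], 2.4)
  expect_identical(spec$spacing_mm[2], 0.67)
})

test_that("training regions have the required counts, labels and contrast", {
  regs <- make_training_regions(tiny_spec(), n_per_class = 8, seed = 5)
  labs <- vapply(regs, function(r) r$label, "")
  expect_identical(sum(labs == "disk"), 8L)
  expect_identical(sum(labs == "background"), 8L)
  mean_disk <- mean(vapply(regs[labs == "disk"], function(r)
    mean(r$intensities), 0))
  mean_bg <- mean(vapply(regs[labs == "background"], function(r)
    mean(r$intensities), 0))
  expect_gt(mean_disk, mean_bg)
  # determinism
  regs2 <- make_training_regions(tiny_spec(), n_per_class = 8, seed = 5)
  expect_identical(lapply(regs, function(r) r$px),
                   lapply(regs2, function(r) r$px))
})
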