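cube <- function(dims, r1, r2, r3) {
  m <- array(FALSE, dims)
  m[r1, r2, r3] <- TRUE
  m
}

test_that("DSC satisfies its defining identity, symmetry and range", {
  a <- cube(c(10, 10, 10), 2:5, 2:5, 2:5)
  b <- cube(c(10, 10, 10), 4:7, 2:5, 2:5)
  r <- dsc(a, b)
  expect_equal(r$value, 2 * r$n_intersection / (r$n_x + r$n_y))
  expect_equal(dsc(b, a)$value, r$value)
  expect_identical(dsc(a, a)$value, 1)
  disj <- cube(c(10, 10, 10), 7:9, 7:9, 7:9)
  expect_identical(dsc(a, disj)$value, 0)
  expect_error(dsc(a, cube(c(9, 9, 9), 1:2, 1:2, 1:2)), "grid")
  expect_error(dsc(array(FALSE, c(5, 5, 5)), array(FALSE, c(5, 5, 5))),
               "empty")
})

test_that("the worked 6/4/3 example gives 0.6", {
  x <- array(FALSE, c(4, 4, 1)); x[1:6] <- TRUE
  y <- array(FALSE, c(4, 4, 1)); y[4:7] <- TRUE
  expect_equal(dsc(x, y)$value, 2 * 3 / (6 + 4))
})

test_that("per-slice DSC handles identity, disjointness and the pooling identity", {
  a <- cube(c(12, 8, 8), 3:5, 2:6, 2:6)
  ps <- dsc_per_slice(a, a)
  expect_true(all(ps$value == 1))
  expect_identical(ps$slice, 3:5)
  b <- cube(c(12, 8, 8), 6:8, 2:6, 2:6)
  ps2 <- dsc_per_slice(a, b)
  expect_identical(ps2$slice, 3:8)
  expect_true(all(ps2$value == 0))
  # voxel-weighted pooling of per-slice values reproduces the 3D DSC
  set.seed(71)
  x <- array(runif(10 * 9 * 8) > 0.6, c(10, 9, 8))
  y <- array(runif(10 * 9 * 8) > 0.6, c(10, 9, 8))
  ps3 <- dsc_per_slice(x, y)
  pooled <- sum(ps3$value * (ps3$n_x + ps3$n_y)) / sum(ps3$n_x + ps3$n_y)
  expect_equal(pooled, dsc(x, y)$value, tolerance = 1e-12)
})

test_that("mid/lateral partition follows the ceiling ten-percent-per-side rule", {
  p13 <- partition_mid_lateral(1:13)
  expect_identical(c(p13$n_mid, p13$n_lateral), c(9L, 4L))
  p50 <- partition_mid_lateral(1:50)
  expect_identical(c(p50$n_mid, p50$n_lateral), c(40L, 10L))
  p10 <- partition_mid_lateral(1:10)
  expect_identical(c(p10$n_mid, p10$n_lateral), c(8L, 2L))
  # symmetric: equal count at each end, union covers the span
  expect_identical(sort(c(p13$mid_indices, p13$lateral_indices)), 1:13)
  expect_identical(sum(p13$lateral_indices <= 2), 2L)
  expect_error(partition_mid_lateral(1:2), "at least 3")
})

test_that("volume discrepancy reports signed relative differences", {
  man <- cube(c(10, 10, 10), 1:4, 1:5, 1:5)  # 100 voxels
  aut <- cube(c(10, 10, 10), 1:3, 1:5, 1:5)  # 75 voxels
  expect_equal(volume_discrepancy(aut, man)$relative, -0.25)
  aut2 <- array(FALSE, c(10, 10, 10)); aut2[1:130] <- TRUE
  expect_equal(volume_discrepancy(aut2, man)$relative, 0.30)
  expect_equal(volume_discrepancy(man, man)$relative, 0)
  vd <- volume_discrepancy(aut, man, spacing_mm = c(1, 1, 2))
  expect_equal(vd$mm3_manual, 200)
  expect_error(volume_discrepancy(man, array(FALSE, c(10, 10, 10))),
               "nonempty")
})

test_that("canal boundary distance is zero on identity and ~2 mm after a 2 px shift", {
  dims <- c(5L, 24L, 50L)
  man <- array(FALSE, dims)
  man[2:4, 5:16, 5:44] <- TRUE
  r0 <- canal_boundary_distance(man, man, canal_slices = 2:4)
  expect_equal(r0$mean_mm, 0)
  # automatic contour pulled 2 px forward from the posterior edge
  aut <- array(FALSE, dims)
  aut[2:4, 5:14, 5:44] <- TRUE
  r2 <- canal_boundary_distance(aut, man, canal_slices = 2:4)
  expect_lt(abs(r2$mean_mm - 2), 0.5)
  # doubling the in-plane spacing doubles the distance
  r4 <- canal_boundary_distance(aut, man, canal_slices = 2:4,
                                spacing_mm = c(1, 2, 2))
  expect_equal(r4$mean_mm, 2 * r2$mean_mm, tolerance = 1e-9)
})

test_that("variability tables aggregate pairwise DSC over disks", {
  base <- cube(c(10, 10, 10), 2:6, 2:6, 2:6)
  segs <- list(
    list(user1 = base, user2 = base, auto = base),
    list(user1 = base, user2 = base, auto = base))
  tab <- variability_table(segs)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$mean_dsc == 1))
  expect_true(all(tab$sd_dsc == 0))
  # two disks with pairwise DSC 0.8 and 0.6 -> mean 0.7
  a1 <- cube(c(1, 1, 10), 1, 1, 1:4)   # |X|=4
  b1 <- cube(c(1, 1, 10), 1, 1, 1:6)   # |Y|=6, overlap 4 -> 0.8
  a2 <- cube(c(1, 1, 10), 1, 1, 1:3)   # |X|=3
  b2 <- cube(c(1, 1, 10), 1, 1, 3:7)   # |Y|=5, overlap 1 -> 0.25
  segs2 <- list(list(u = a1, v = b1), list(u = a2, v = b2))
  tab2 <- variability_table(segs2)
  expect_equal(tab2$mean_dsc, mean(c(0.8, 0.25)))
  expect_equal(tab2$sd_dsc, sd(c(0.8, 0.25)))
  # order of names does not matter
  segs3 <- list(list(v = b1, u = a1), list(v = b2, u = a2))
  expect_equal(variability_table(segs3)$mean_dsc, tab2$mean_dsc)
})

test_that("evaluation report combines 3D, per-slice and partition views", {
  ph <- tiny_phantom()
  rep_ <- evaluate_reconstruction(ph$truth_masks, ph$truth_masks,
                                  ph$volume$spacing_mm)
  expect_identical(nrow(rep_$per_disk), 3L)
  expect_true(all(rep_$per_disk$dsc_3d == 1))
  expect_true(all(rep_$per_disk$discrepancy == 0))
  expect_true(all(rep_$per_slice$value == 1))
  expect_true(all(c("mid_sagittal", "lateral") %in% rep_$per_slice$group))
})
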