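test_that("internal markers land inside well-separated bright ellipses", {
  img <- matrix(0.1, 48, 48)
  e1 <- draw_ellipse(48, 48, c(14, 16), c(7, 9))
  e2 <- draw_ellipse(48, 48, c(36, 32), c(7, 9))
  img[e1] <- 0.9
  img[e2] <- 0.85
  mk <- extract_internal_markers(slice_image(img, c(1, 1)))
  lab <- spinedisk:::label_components(mk, 8L)
  expect_identical(max(lab), 2L)
  expect_true(all(mk[!e1 & !e2] == FALSE))
})

test_that("constant slices and sub-area components give empty marker masks", {
  expect_false(any(extract_internal_markers(matrix(1, 32, 32))))
  img <- matrix(0.1, 32, 32)
  img[draw_ellipse(32, 32, c(16, 16), c(2, 2))] <- 0.9  # ~13 px < 30 px min
  mk <- extract_internal_markers(slice_image(img, c(1, 1)))
  expect_false(any(mk))
  expect_true(any(attr(mk, "rejected_small")))
})

test_that("external markers trace the bisector between two point markers", {
  for (cols in list(c(10, 20), c(8, 23))) {
    internal <- matrix(FALSE, 30, 30)
    internal[15, cols[1]] <- TRUE
    internal[15, cols[2]] <- TRUE
    ext <- extract_external_markers(internal)
    expect_false(any(ext & internal))
    mid <- floor(mean(cols))
    ridge_cols <- unique(which(ext & !row(ext) %in% c(1, 30) &
                               !col(ext) %in% c(1, 30), arr.ind = TRUE)[, 2])
    expect_true(any(abs(ridge_cols - mid) <= 1))
    # oracle: ridge must separate the two nearest-marker cells
    vor <- oracle_voronoi(c(30, 30), rbind(c(15, cols[1]), c(15, cols[2])))
    expect_true(all(abs(ridge_cols - mean(cols)) <= 1 |
                    ridge_cols %in% c(1, 30)))
    expect_identical(sort(unique(as.vector(vor))), c(1L, 2L))
  }
})

test_that("fewer than two internal components fall back to the border frame", {
  internal <- matrix(FALSE, 20, 20)
  internal[10:12, 10:12] <- TRUE
  ext <- extract_external_markers(internal)
  frame <- matrix(FALSE, 20, 20)
  frame[c(1, 20), ] <- TRUE
  frame[, c(1, 20)] <- TRUE
  expect_identical(unname(ext), unname(frame))
  expect_false(any(ext & internal))
})

test_that("flooding matches the ordered-queue oracle on random images", {
  set.seed(101)
  for (rep in 1:8) {
    nr <- sample(10:20, 1); nc <- sample(10:20, 1)
    img <- matrix(sample(0:6, nr * nc, TRUE), nr, nc)
    seeds <- matrix(0L, nr, nc)
    for (k in 1:3) seeds[sample(nr, 1), sample(nc, 1)] <- k
    got <- marker_watershed(img, seeds, 4L)
    expect_identical(got, oracle_flood(img, seeds, 4))
  }
})

test_that("a single marked ellipse yields exactly one candidate region", {
  img <- matrix(0.1, 40, 40)
  ell <- draw_ellipse(40, 40, c(20, 20), c(8, 11))
  img[ell] <- 0.9
  internal <- draw_ellipse(40, 40, c(20, 20), c(3, 4))
  external <- extract_external_markers(internal)
  mk <- marker_set(internal, external)
  grad <- morphological_gradient(img, 1)
  regs <- watershed_segment(impose_minima(grad, mk$combined), mk, img)
  expect_length(regs, 1L)
  rmask <- matrix(FALSE, 40, 40)
  rmask[regs[[1]]$px] <- TRUE
  d <- 2 * sum(rmask & ell) / (sum(rmask) + sum(ell))
  expect_gt(d, 0.8)
})

test_that("candidate regions are pairwise disjoint with closed contours", {
  ph <- tiny_phantom()
  mid <- round(dim(ph$volume$data)[1] / 2)
  regs <- segment_slice(get_slice(ph$volume, mid, "sagittal"))
  expect_gt(length(regs), 0L)
  seen <- matrix(FALSE, dim(ph$volume$data)[2], dim(ph$volume$data)[3])
  for (r in regs) {
    expect_false(any(seen[r$px]))
    seen[r$px] <- TRUE
    # region pixels form one 4-connected component
    m <- matrix(FALSE, nrow(seen), ncol(seen))
    m[r$px] <- TRUE
    expect_identical(max(spinedisk:::label_components(m, 4L)), 1L)
    # closed contour: consecutive contour pixels (wrapping) are 8-adjacent
    ct <- r$contour
    expect_gt(nrow(ct), 2L)
    nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
    expect_true(all(pmax(abs(ct[, 1] - nxt[, 1]),
                         abs(ct[, 2] - nxt[, 2])) <= 1))
    # no region touches the slice border
    expect_true(all(r$px[, 1] > 1 & r$px[, 1] < nrow(seen) &
                    r$px[, 2] > 1 & r$px[, 2] < ncol(seen)))
  }
})

test_that("mid-sagittal phantom slices recover most disks at 2D Dice >= 0.7", {
  ph <- tiny_phantom()
  mid <- round(dim(ph$volume$data)[1] / 2)
  regs <- segment_slice(get_slice(ph$volume, mid, "sagittal"))
  k <- length(ph$truth_masks)
  hits <- 0L
  for (j in seq_len(k)) {
    tm <- ph$truth_masks[[j]][mid, , ]
    best <- 0
    for (r in regs) {
      rm <- matrix(FALSE, nrow(tm), ncol(tm)); rm[r$px] <- TRUE
      best <- max(best, 2 * sum(rm & tm) / (sum(rm) + sum(tm)))
    }
    if (best >= 0.7) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.8 * k))
})

test_that("segmentation of a slice is deterministic and empty on constants", {
  expect_identical(segment_slice(matrix(0.5, 24, 24)), list())
  ph <- tiny_phantom()
  s <- get_slice(ph$volume, 12, "sagittal")
  a <- segment_slice(s)
  b <- segment_slice(s)
  expect_identical(lapply(a, function(r) r$px), lapply(b, function(r) r$px))
})
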