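# Independent oracle implementations used to cross-check the package's
# compiled engines. Deliberately naive and written against the algorithm
# definitions, not against the implementation under test.

# ordered-queue flooding: pop the lowest (gray value, insertion sequence)
# frontier pixel, assign the label of the pixel that inserted it, push its
# unlabelled neighbours (up, down, left, right, then diagonals)
oracle_flood <- function(img, seeds, connectivity = 4) {
  nr <- nrow(img); nc <- ncol(img); np <- nr * nc
  lab <- as.integer(seeds)
  nbrs <- function(i) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    out <- integer()
    if (r > 1) out <- c(out, i - 1)
    if (r < nr) out <- c(out, i + 1)
    if (c > 1) out <- c(out, i - nr)
    if (c < nc) out <- c(out, i + nr)
    if (connectivity == 8) {
      if (r > 1 && c > 1) out <- c(out, i - 1 - nr)
      if (r > 1 && c < nc) out <- c(out, i - 1 + nr)
      if (r < nr && c > 1) out <- c(out, i + 1 - nr)
      if (r < nr && c < nc) out <- c(out, i + 1 + nr)
    }
    out
  }
  qv <- numeric(0); qs <- numeric(0); qi <- integer(0); ql <- integer(0)
  seq_ <- 0
  push <- function(j, l) {
    qv[length(qv) + 1] <<- img[j]; qs[length(qs) + 1] <<- seq_
    qi[length(qi) + 1] <<- j; ql[length(ql) + 1] <<- l
    seq_ <<- seq_ + 1
  }
  for (i in seq_len(np)) if (lab[i] > 0)
    for (j in nbrs(i)) if (lab[j] == 0) push(j, lab[i])
  while (length(qi) > 0) {
    k <- order(qv, qs)[1]
    j <- qi[k]; l <- ql[k]
    qv <- qv[-k]; qs <- qs[-k]; qi <- qi[-k]; ql <- ql[-k]
    if (lab[j] != 0) next
    lab[j] <- l
    for (m in nbrs(j)) if (lab[m] == 0) push(m, l)
  }
  matrix(lab, nr, nc)
}

# plateau-aware regional minima by flood fill
oracle_regional_minima <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  state <- matrix(0L, nr, nc)  # 0 unseen, 1 min plateau, 2 not min
  for (s in which(state == 0)) {
    if (state[s] != 0) next
    v <- px[s]
    plateau <- integer(0); queue <- s; state[s] <- 1L
    is_min <- TRUE
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      plateau <- c(plateau, i)
      r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1) * nr + rr
        if (px[j] < v) is_min <- FALSE
        else if (px[j] == v && state[j] == 0) { state[j] <- 1L; queue <- c(queue, j) }
      }
    }
    if (!is_min) state[plateau] <- 2L
  }
  state == 1L
}

# nearest-marker (Voronoi) partition of a grid by physical pixel distance
oracle_voronoi <- function(shape, marker_px) {
  nr <- shape[1]; nc <- shape[2]
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  d2 <- sapply(seq_len(nrow(marker_px)), function(k)
    (grid$row - marker_px[k, 1])^2 + (grid$col - marker_px[k, 2])^2)
  matrix(apply(d2, 1, which.min), nr, nc)
}

# quick exact skewness by the explicit third-moment sum
oracle_skewness <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / length(x))
  if (s == 0) return(0)
  sum((x - m)^3) / (length(x) * s^3)
}

# exhaustive angular energy spectrum of a patch via a direct DFT
# (independent of stats::fft): returns S(theta) on bins of `bin_deg`
oracle_angular_spectrum <- function(patch, pad = 64, bin_deg = 5) {
  nr <- nrow(patch); nc <- ncol(patch)
  P1 <- max(pad, nr); P2 <- max(pad, nc)
  padded <- matrix(0, P1, P2)
  padded[seq_len(nr), seq_len(nc)] <- patch - mean(patch)
  rows <- 0:(P1 - 1); cols <- 0:(P2 - 1)
  n_bins <- ceiling(180 / bin_deg)
  s_theta <- numeric(n_bins)
  for (u in 0:(P1 - 1)) for (v in 0:(P2 - 1)) {
    fr <- if (u <= P1 / 2) u else u - P1
    fc <- if (v <= P2 / 2) v else v - P2
    if (!(fc > 0 || (fc == 0 && fr > 0))) next
    ang <- outer(rows * u / P1, cols * v / P2, `+`)
    re <- sum(padded * cos(-2 * pi * ang))
    im <- sum(padded * sin(-2 * pi * ang))
    e <- re^2 + im^2
    th <- atan2(fr, fc) * 180 / pi
    if (th < 0) th <- th + 180
    b <- min(n_bins, floor((th %% 180) / bin_deg) + 1)
    s_theta[b] <- s_theta[b] + e
  }
  s_theta
}

# draw a filled ellipse mask on a pixel grid
draw_ellipse <- function(nr, nc, centre, semi) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - centre[1]) / semi[1])^2 + ((c - centre[2]) / semi[2])^2 <= 1
}
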