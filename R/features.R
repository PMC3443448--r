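#' Default classification parameters
#'
#' \describe{
#'   \item{k}{neighbour count of the k-NN classifier (odd).}
#'   \item{n_bins}{equal-width histogram bins for the entropy feature,
#'     spanning the owning slice's dynamic range.}
#'   \item{pad_to}{minimum zero-padded side of the Fourier patch.}
#'   \item{angle_bin_deg}{angular bin width of the polar spectrum over
#'     `[0, 180)` degrees.}
#'   \item{spectrum}{`"energy"` (squared magnitude) or `"magnitude"`.}
#' }
#' @return Named list of defaults.
#' @export
classification_params <- function() {
  list(k = 5L, n_bins = 32L, pad_to = 64L, angle_bin_deg = 5,
       spectrum = "energy")
}

#' Histogram-statistical texture features of a region
#'
#' Population mean and standard deviation of the member-pixel intensities,
#' the third standardized moment (0 for a constant region), and the Shannon
#' entropy (base 2) of the normalized intensity histogram over the owning
#' slice's dynamic range.
#'
#' @param region a [region2d()].
#' @param params list as in [classification_params()] (`n_bins` is used).
#' @return Named numeric: `hist_mean`, `hist_std`, `hist_skewness`,
#'   `hist_entropy`.
#' @export
statistical_features <- function(region, params = classification_params()) {
  stopifnot(inherits(region, "region2d"))
  p <- modifyList(classification_params(), params)
  x <- region$intensities
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  skew <- if (s == 0) 0 else mean((x - m)^3) / s^3
  rng <- region$slice_range
  if (diff(rng) == 0) {
    ent <- 0
  } else {
    br <- seq(rng[1], rng[2], length.out = p$n_bins + 1L)
    cnt <- tabulate(pmin(p$n_bins,
                         pmax(1L, findInterval(x, br, rightmost.closed = TRUE))),
                    nbins = p$n_bins)
    pr <- cnt[cnt > 0] / length(x)
    ent <- -sum(pr * log2(pr))
  }
  c(hist_mean = m, hist_std = s, hist_skewness = skew, hist_entropy = ent)
}

#' Polar-spectrum texture features of a region
#'
#' The region's bounding-box patch (pixels outside the region set to the
#' region mean, so the features describe internal texture rather than the
#' silhouette) is mean-subtracted, zero-padded to at least
#' `pad_to` x `pad_to`, and Fourier-transformed. The spectrum, expressed in
#' polar coordinates with the DC term excluded, is summed over radius into
#' S(theta) on angular bins covering `[0, 180)` degrees (Hermitian
#' symmetry). Regions with a bounding box smaller than 8 x 8 pixels get the
#' all-zero spectrum.
#'
#' @param region a [region2d()].
#' @param params list as in [classification_params()].
#' @return Named numeric: `theta_max_deg` (bin centre of the arg-max angle,
#'   smallest on ties), `s_max`, `s_var` (population variance of S(theta))
#'   and `s_max_minus_mean`.
#' @export
spectral_features <- function(region, params = classification_params()) {
  stopifnot(inherits(region, "region2d"))
  p <- modifyList(classification_params(), params)
  zero <- c(theta_max_deg = 0, s_max = 0, s_var = 0, s_max_minus_mean = 0)
  rr <- range(region$px[, "row"]); cr <- range(region$px[, "col"])
  nr <- rr[2] - rr[1] + 1L; nc <- cr[2] - cr[1] + 1L
  if (nr < 8L || nc < 8L) return(zero)
  m <- mean(region$intensities)
  patch <- matrix(m, nr, nc)
  patch[cbind(region$px[, "row"] - rr[1] + 1L,
              region$px[, "col"] - cr[1] + 1L)] <- region$intensities
  patch <- patch - mean(patch)
  P1 <- max(p$pad_to, nr); P2 <- max(p$pad_to, nc)
  padded <- matrix(0, P1, P2)
  padded[seq_len(nr), seq_len(nc)] <- patch
  F <- fft(padded)
  S <- Mod(F)
  if (identical(p$spectrum, "energy")) S <- S^2
  fr <- ifelse(seq_len(P1) - 1L <= P1 / 2, seq_len(P1) - 1L,
               seq_len(P1) - 1L - P1)
  fc <- ifelse(seq_len(P2) - 1L <= P2 / 2, seq_len(P2) - 1L,
               seq_len(P2) - 1L - P2)
  FR <- matrix(fr, P1, P2)
  FC <- matrix(fc, P1, P2, byrow = TRUE)
  half <- FC > 0 | (FC == 0 & FR > 0)          # Hermitian half-plane, no DC
  theta <- atan2(FR[half], FC[half]) * 180 / pi
  theta <- ifelse(theta < 0, theta + 180, theta) %% 180
  n_bins <- ceiling(180 / p$angle_bin_deg)
  bin <- pmin(n_bins, floor(theta / p$angle_bin_deg) + 1L)
  s_theta <- vapply(seq_len(n_bins),
                    function(b) sum(S[half][bin == b]), 0)
  if (all(s_theta == 0)) return(zero)
  imax <- which.max(s_theta)
  c(theta_max_deg = (imax - 0.5) * p$angle_bin_deg,
    s_max = s_theta[imax],
    s_var = mean((s_theta - mean(s_theta))^2),
    s_max_minus_mean = s_theta[imax] - mean(s_theta))
}

#' All eight texture features of a region
#'
#' @param region a [region2d()].
#' @param params list as in [classification_params()].
#' @return The region with its `features` field set to the named
#'   8-vector (four histogram-statistical, four polar-spectrum).
#' @export
region_features <- function(region, params = classification_params()) {
  region$features <- c(statistical_features(region, params),
                       spectral_features(region, params))
  region
}

#' Feature table of a region collection
#'
#' @param regions list of [region2d()] (features computed on the fly where
#'   missing).
#' @param params list as in [classification_params()].
#' @return A tibble with the eight feature columns plus `label`, `plane`,
#'   `slice`, `n_px`; one row per region.
#' @export
region_feature_table <- function(regions, params = classification_params()) {
  rows <- lapply(regions, function(r) {
    if (is.null(r$features)) r <- region_features(r, params)
    c(as.list(r$features),
      list(label = r$label, plane = r$plane, slice = r$index,
           n_px = nrow(r$px)))
  })
  tibble::as_tibble(do.call(rbind.data.frame, rows))
}
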