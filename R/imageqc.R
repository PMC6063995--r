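# Image quality control: SNR estimators and artifact classifiers -------------

#' Multi-scale blob detection (determinant of Hessian)
#'
#' Keypoints are local maxima of the scale-normalized determinant-of-Hessian
#' response over position and scale, thresholded relative to the strongest
#' response (so detection is invariant to affine gray maps). Deterministic.
#'
#' @param image numeric matrix, at least 32 x 32.
#' @param sigmas scale ladder, px.
#' @param threshold_rel keep responses above this fraction of the maximum
#'   (default 0.02; pixel-noise responses sit far below structure responses).
#' @param dark_only keep only dark-on-bright blobs (positive Laplacian, the
#'   SURF sign convention); in EM, stained structure is dark, so this puts
#'   keypoints on biology rather than on bright lumina (default TRUE).
#' @return data.frame with 0-based \code{x}, \code{y}, \code{sigma},
#'   \code{response}; zero rows when the image has no structure.
#' @export
detect_features <- function(image, sigmas = c(2, 2.8, 4, 5.7, 8),
                            threshold_rel = 0.02, dark_only = TRUE) {
  if (nrow(image) < 32 || ncol(image) < 32) stopf("image must be at least 32x32")
  nr <- nrow(image); nc <- ncol(image)
  resp <- array(0, c(nr, nc, length(sigmas)))
  for (k in seq_along(sigmas)) {
    s <- sigmas[k]
    L <- gauss_blur(image, s)
    Lx <- matrix(0, nr, nc); Ly <- matrix(0, nr, nc)
    Lx[, 2:(nc - 1)] <- (L[, 3:nc] - L[, 1:(nc - 2)]) / 2
    Ly[2:(nr - 1), ] <- (L[3:nr, ] - L[1:(nr - 2), ]) / 2
    Lxx <- matrix(0, nr, nc); Lyy <- matrix(0, nr, nc); Lxy <- matrix(0, nr, nc)
    Lxx[, 2:(nc - 1)] <- L[, 3:nc] - 2 * L[, 2:(nc - 1)] + L[, 1:(nc - 2)]
    Lyy[2:(nr - 1), ] <- L[3:nr, ] - 2 * L[2:(nr - 1), ] + L[1:(nr - 2), ]
    Lxy[2:(nr - 1), 2:(nc - 1)] <- Lx[3:nr, 2:(nc - 1)] - Lx[1:(nr - 2), 2:(nc - 1)]
    Lxy <- Lxy / 2
    r <- s^4 * (Lxx * Lyy - Lxy^2)
    if (dark_only) r[Lxx + Lyy <= 0] <- 0
    resp[, , k] <- r
  }
  mx <- max(resp)
  if (mx <= 1e-12) return(data.frame(x = numeric(0), y = numeric(0),
                                     sigma = numeric(0), response = numeric(0)))
  thr <- threshold_rel * mx
  out <- NULL
  shift_max <- function(R) {   # max over the 8 spatial neighbors
    pad <- matrix(-Inf, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- R
    M <- matrix(-Inf, nr, nc)
    for (dy in -1:1) for (dx in -1:1) if (dy || dx)
      M <- pmax(M, pad[2:(nr + 1) + dy, 2:(nc + 1) + dx])
    M
  }
  for (k in seq_along(sigmas)) {
    R <- resp[, , k]
    is_max <- R > thr & R > shift_max(R)
    if (k > 1) is_max <- is_max & R >= resp[, , k - 1]
    if (k < length(sigmas)) is_max <- is_max & R >= resp[, , k + 1]
    is_max[c(1, nr), ] <- FALSE; is_max[, c(1, nc)] <- FALSE
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx))
      out <- rbind(out, data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                                   sigma = sigmas[k], response = R[idx]))
  }
  if (is.null(out)) out <- data.frame(x = numeric(0), y = numeric(0),
                                      sigma = numeric(0), response = numeric(0))
  out[order(-out$response), , drop = FALSE]
}

#' Keypoint density raster
#'
#' Indicator raster (1 at each keypoint) convolved with a Gaussian of width
#' \code{n}: high values mark feature-dense (signal) regions, low values
#' feature-sparse (noise-dominated) regions.
#'
#' @param image_shape (rows, cols).
#' @param keypoints data.frame with 0-based \code{x}, \code{y}.
#' @param n Gaussian standard deviation, px.
#' @return numeric matrix.
#' @export
feature_density <- function(image_shape, keypoints, n) {
  check_number(n, "n", positive = TRUE)
  ind <- matrix(0, image_shape[1], image_shape[2])
  if (nrow(keypoints) > 0) {
    r <- pmin(pmax(round(keypoints$y) + 1, 1), image_shape[1])
    c <- pmin(pmax(round(keypoints$x) + 1, 1), image_shape[2])
    for (i in seq_along(r)) ind[r[i], c[i]] <- ind[r[i], c[i]] + 1
  }
  gauss_blur(ind, n)
}

#' Select extreme-density regions with block exclusion
#'
#' Returns the \code{k} lowest-density and \code{k} highest-density positions;
#' after each selection a 2n x 2n block around it is excluded before resorting,
#' and a seeded shuffle breaks ties between equal density values. The two sets
#' are selected independently.
#'
#' @param density numeric matrix (keypoint density).
#' @param n block half-size, px.
#' @param k regions per extreme (default 10).
#' @param seed integer seed for the tie-breaking shuffle.
#' @return list with \code{p_low} and \code{p_high}, each a k x 2 matrix of
#'   0-based (x, y) positions (fewer, with a warning, if the image is small).
#' @export
select_extreme_regions <- function(density, n, k = 10, seed = 1) {
  nr <- nrow(density); nc <- ncol(density)
  rows <- 2:(nr - 1); cols <- 2:(nc - 1)   # keep 3x3 neighborhoods in-bounds
  xs <- rep(cols - 1, each = length(rows)); ys <- rep(rows - 1, times = length(cols))
  vals <- as.vector(density[rows, cols])
  tie <- with_seed(seed, sample.int(length(vals)))
  pick <- function(decreasing) {
    o <- order(if (decreasing) -vals else vals, tie)
    chosen <- matrix(numeric(0), 0, 2)
    for (i in o) {
      p <- c(xs[i], ys[i])
      if (nrow(chosen) &&
          any(abs(chosen[, 1] - p[1]) <= n & abs(chosen[, 2] - p[2]) <= n)) next
      chosen <- rbind(chosen, p)
      if (nrow(chosen) == k) break
    }
    chosen
  }
  p_low <- pick(FALSE); p_high <- pick(TRUE)
  if (nrow(p_low) < k || nrow(p_high) < k)
    warnf("image too small for %d non-overlapping 2n blocks; returning %d/%d",
          k, nrow(p_low), nrow(p_high))
  list(p_low = unname(p_low), p_high = unname(p_high))
}

#' Noise-dominated residual image
#'
#' Subtracts a 3x3 median-filtered copy from the image; structure is removed
#' and the residual is dominated by pixel noise.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @return numeric matrix \code{I - median3(I)}.
#' @export
noise_residual <- function(image) {
  if (nrow(image) < 3 || ncol(image) < 3) stopf("image must be at least 3x3")
  image - median3(image)
}

nbhd3 <- function(img, p) {   # 3x3 values around 0-based (x, y)
  r <- p[2] + 1; c <- p[1] + 1
  img[(r - 1):(r + 1), (c - 1):(c + 1)]
}

#' Feature-based signal-to-noise ratio
#'
#' Automated SNR estimate: blob keypoints are detected; their Gaussian-smoothed
#' density selects 10 feature-sparse positions (p_low, noise-dominated) and 10
#' feature-dense positions (p_high, signal). With I' the 3x3-median residual,
#' the noise N is the mean over p_low of the standard deviation of I' in the
#' 3x3 neighborhood; the background B is the mean over p_low of the 3x3 mean
#' of I; the signal S is the mean over p_high of |3x3 mean of I - B|; and
#' SNR = S / N.
#'
#' @param image numeric matrix.
#' @param n Gaussian density width (and exclusion half-block), px.
#' @param seed integer seed (tie-breaking shuffle in region selection).
#' @param k regions per extreme (default 10).
#' @return object of class \code{snr_estimate} with fields \code{snr},
#'   \code{signal}, \code{background}, \code{noise}, \code{p_low},
#'   \code{p_high}, \code{n}, \code{seed}, \code{method}.
#' @export
feature_based_snr <- function(image, n = 8, seed = 1, k = 10) {
  kp <- detect_features(image)
  dens <- feature_density(dim(image), kp, n)
  sel <- select_extreme_regions(dens, n, k = k, seed = seed)
  if (nrow(sel$p_low) == 0 || nrow(sel$p_high) == 0)
    stopf("degenerate input: no usable regions")
  Ir <- noise_residual(image)
  sds <- apply(sel$p_low, 1, function(p) sd(as.vector(nbhd3(Ir, p))))
  N <- mean(sds)
  if (!is.finite(N) || N <= 0)
    stopf("degenerate input: zero noise estimate (constant image?)")
  B <- mean(apply(sel$p_low, 1, function(p) mean(nbhd3(image, p))))
  S <- mean(apply(sel$p_high, 1, function(p) abs(mean(nbhd3(image, p)) - B)))
  structure(list(snr = S / N, signal = S, background = B, noise = N,
                 p_low = sel$p_low, p_high = sel$p_high, n = n, seed = seed,
                 method = "feature"), class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  cat(sprintf("<snr_estimate> method=%s snr=%.3f (S=%.2f, B=%.2f, N=%.2f)\n",
              x$method, x$snr, x$signal, x$background, x$noise))
  invisible(x)
}

#' Calibrate the density width n
#'
#' Evaluates the feature-based SNR for each candidate width over (up to) five
#' images sampled from the input set and returns the candidate maximizing the
#' mean SNR.
#'
#' @param images list of rasters.
#' @param candidate_ns candidate widths, px.
#' @param seed integer seed (image sampling and region tie-breaks).
#' @return the selected width (px).
#' @export
calibrate_n <- function(images, candidate_ns, seed = 1) {
  if (length(images) < 1 || length(candidate_ns) < 1)
    stopf("need at least one image and one candidate")
  candidate_ns <- sort(candidate_ns)
  idx <- if (length(images) > 5) with_seed(seed, sample(seq_along(images), 5))
         else seq_along(images)
  means <- vapply(candidate_ns, function(nn) {
    v <- vapply(idx, function(i)
      tryCatch(feature_based_snr(images[[i]], n = nn, seed = seed)$snr,
               error = function(e) NA_real_), 0)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  if (all(is.na(means))) stopf("all candidates degenerate")
  candidate_ns[which.max(means)]
}

#' Construct a line sample for the cell-membrane SNR
#'
#' @param kind \code{"signal"} (pixels on a stained membrane) or
#'   \code{"background"} (pixels on resin/interior).
#' @param positions m x 2 matrix of 0-based (x, y) pixel positions (m >= 2).
#' @return object of class \code{line_sample}.
#' @export
line_sample <- function(kind = c("signal", "background"), positions) {
  kind <- match.arg(kind)
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) < 2) stopf("a line sample needs at least 2 pixels")
  structure(list(kind = kind, positions = positions), class = "line_sample")
}

#' Cell-membrane signal-to-noise ratio
#'
#' The noise is the standard deviation of all background-line pixels pooled,
#' the background level their mean, and the signal the |mean of the
#' membrane-line pixels - background|; SNR = signal / noise. The sampling
#' protocol draws 10 signal and 10 background lines from distinct 100 x 100 px
#' regions (see \code{\link{membrane_line_samples}}).
#'
#' @param image numeric matrix.
#' @param samples list of \code{line_sample} with at least one of each kind.
#' @return \code{snr_estimate} (method \code{"membrane"}).
#' @export
membrane_snr <- function(image, samples) {
  kinds <- vapply(samples, function(s) s$kind, "")
  if (!any(kinds == "signal") || !any(kinds == "background"))
    stopf("need at least one signal and one background line sample")
  grab <- function(s) {
    pos <- s$positions
    if (any(pos[, 1] < 0 | pos[, 1] > ncol(image) - 1 |
            pos[, 2] < 0 | pos[, 2] > nrow(image) - 1))
      stopf("line sample positions out of bounds")
    image[cbind(pos[, 2] + 1, pos[, 1] + 1)]
  }
  bg <- unlist(lapply(samples[kinds == "background"], grab))
  sig <- unlist(lapply(samples[kinds == "signal"], grab))
  N <- sd(bg)
  if (!is.finite(N) || N <= 0) stopf("degenerate input: constant background")
  B <- mean(bg)
  S <- abs(mean(sig) - B)
  structure(list(snr = S / N, signal = S, background = B, noise = N,
                 p_low = NULL, p_high = NULL, n = NA_real_, seed = NA_integer_,
                 method = "membrane"), class = "snr_estimate")
}

#' Automatic membrane/background line selection from a ground-truth mask
#'
#' Test-support selector emulating the manual protocol: the image is divided
#' into \code{region} x \code{region} px regions; in each selected region one
#' run of membrane pixels (from the mask) becomes a signal line and one run of
#' mask-distant pixels a background line, until \code{n_regions} of each are
#' collected (regions lacking either are skipped).
#'
#' @param image numeric matrix (used for bounds only).
#' @param membrane_mask logical matrix marking membrane pixels.
#' @param avoid_mask optional logical matrix of additional structure (e.g.
#'   organelles) that neither line kind may touch.
#' @param n_regions regions to use (default 10).
#' @param region region side, px (default 100).
#' @param line_len pixels per line (default 20).
#' @param margin background must be at least this far (Chebyshev) from any
#'   membrane/structure pixel (default 3 px).
#' @param seed integer seed.
#' @return list of \code{line_sample} (2 per selected region).
#' @export
membrane_line_samples <- function(image, membrane_mask, avoid_mask = NULL,
                                  n_regions = 10, region = 100, line_len = 20,
                                  margin = 3, seed = 1) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(avoid_mask)) avoid_mask <- matrix(FALSE, nr, nc)
  brush <- EBImage::makeBrush(2 * margin + 1, "box")
  far <- !(EBImage::dilate((membrane_mask | avoid_mask) * 1, brush) > 0)
  membrane_mask <- membrane_mask & !avoid_mask
  ry <- seq(1, nr - region + 1, by = region); rx <- seq(1, nc - region + 1, by = region)
  cells <- expand.grid(r = ry, c = rx)
  with_seed(seed, {
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    out <- list()
    taken <- 0L
    for (i in seq_len(nrow(cells))) {
      if (taken >= n_regions) break
      rs <- cells$r[i]:(cells$r[i] + region - 1); cs <- cells$c[i]:(cells$c[i] + region - 1)
      mem <- which(membrane_mask[rs, cs], arr.ind = TRUE)
      bgp <- which(far[rs, cs], arr.ind = TRUE)
      if (nrow(mem) < line_len || nrow(bgp) < line_len) next
      run <- function(px) {   # contiguous-ish run: nearest neighbors of a seed pixel
        s <- px[sample.int(nrow(px), 1), ]
        d <- pmax(abs(px[, 1] - s[1]), abs(px[, 2] - s[2]))
        px[order(d)[seq_len(line_len)], , drop = FALSE]
      }
      m <- run(mem); b <- run(bgp)
      out <- c(out,
               list(line_sample("signal", cbind(cs[1] - 1 + m[, 2] - 1, rs[1] - 1 + m[, 1] - 1)),
                    line_sample("background", cbind(cs[1] - 1 + b[, 2] - 1, rs[1] - 1 + b[, 1] - 1))))
      taken <- taken + 1L
    }
    if (taken < n_regions)
      warnf("only %d of %d regions had usable membrane and background lines",
            taken, n_regions)
    out
  })
}

#' Normalize an SNR to a reference voxel size
#'
#' SNR values from different datasets are compared at a common voxel size by
#' scaling with the square root of the voxel-volume ratio (shot-noise
#' expectation for combined voxels).
#'
#' @param snr SNR value.
#' @param source_voxel (x, y, z) nm of the source data.
#' @param reference_voxel (x, y, z) nm of the reference (default 4 x 4 x 40).
#' @return normalized SNR.
#' @export
normalize_snr <- function(snr, source_voxel, reference_voxel = c(4, 4, 40)) {
  if (any(source_voxel <= 0) || any(reference_voxel <= 0))
    stopf("voxel dimensions must be positive")
  snr * sqrt(prod(reference_voxel) / prod(source_voxel))
}

#' Classify tiles as ok or degraded
#'
#' A tile is degraded if the standard deviation of its gray values exceeds 40
#' (precipitate, folds, correction artifacts) or is below 20 with a mean below
#' 50 (large-scale precipitate).
#'
#' @param tiles list of numeric matrices (8-bit gray range).
#' @return object of class \code{tile_qc_report}: data.frame with per-tile
#'   \code{mean}, \code{sd}, \code{status}; attributes \code{n} and
#'   \code{n_degraded}.
#' @export
classify_tiles <- function(tiles) {
  mu <- vapply(tiles, mean, 0)
  s <- vapply(tiles, sd, 0)
  degraded <- s > 40 | (s < 20 & mu < 50)
  rep <- data.frame(tile = seq_along(tiles), mean = mu, sd = s,
                    status = ifelse(degraded, "degraded", "ok"))
  structure(rep, class = c("tile_qc_report", "data.frame"),
            n = length(tiles), n_degraded = sum(degraded))
}

#' Flag sections with missing tiles
#'
#' A section is flagged when its tile count falls more than \code{threshold}
#' below the running median of the 11-section window centered on it (five
#' sections either side, the section itself included; truncated at the series
#' ends).
#'
#' @param tile_counts integer vector of per-section tile counts.
#' @param half_window sections either side (default 5).
#' @param threshold fraction below the running median (default 0.05).
#' @return integer indices of flagged sections.
#' @export
detect_missing_sections <- function(tile_counts, half_window = 5, threshold = 0.05) {
  S <- length(tile_counts)
  if (S < 2 * half_window + 1)
    stopf("need at least %d sections", 2 * half_window + 1)
  flagged <- vapply(seq_len(S), function(s) {
    win <- max(1, s - half_window):min(S, s + half_window)
    tile_counts[s] < (1 - threshold) * median(tile_counts[win])
  }, TRUE)
  which(flagged)
}
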