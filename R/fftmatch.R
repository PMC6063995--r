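# Masked, normalized FFT cross-correlation -----------------------------------
#
# The workhorse of all translation matching. For two rasters a and b with
# validity masks, computes the Pearson correlation of the overlapping pixels
# for every integer shift d (b shifted by d relative to a) using FFTs of the
# images, their squares and their masks, so that irregular overlap and masked
# (e.g. rotated-in) borders are normalized exactly.

# sum_p X(p) Y(p - d) for all shifts, via zero-padded FFTs.
xcorr_all <- function(FX, FYc, P) {
  Re(fft(FX * FYc, inverse = TRUE)) / prod(P)
}

# Full masked NCC surface. Returns list(ncc, n, dy, dx) where ncc[i, j] is the
# correlation at shift (dy[i], dx[j]) and n the overlap pixel count.
masked_ncc <- function(a, b, mask_a = NULL, mask_b = NULL, min_overlap = 16) {
  if (is.null(mask_a)) mask_a <- matrix(1, nrow(a), ncol(a))
  if (is.null(mask_b)) mask_b <- matrix(1, nrow(b), ncol(b))
  ma <- mask_a * 1; mb <- mask_b * 1
  a <- a * ma; b <- b * mb
  P <- c(nrow(a) + nrow(b) - 1L, ncol(a) + ncol(b) - 1L)
  pad <- function(x) { z <- matrix(0, P[1], P[2]); z[seq_len(nrow(x)), seq_len(ncol(x))] <- x; z }
  Fa  <- fft(pad(a));      Fma  <- fft(pad(ma));  Faa <- fft(pad(a * a))
  Fbc <- Conj(fft(pad(b))); Fmbc <- Conj(fft(pad(mb))); Fbbc <- Conj(fft(pad(b * b)))
  n   <- xcorr_all(Fma, Fmbc, P)
  Sa  <- xcorr_all(Fa,  Fmbc, P)
  Sb  <- xcorr_all(Fma, Fbc,  P)
  Sab <- xcorr_all(Fa,  Fbc,  P)
  Saa <- xcorr_all(Faa, Fmbc, P)
  Sbb <- xcorr_all(Fma, Fbbc, P)
  n <- pmax(round(n), 0)
  va <- pmax(Saa - Sa * Sa / pmax(n, 1), 0)
  vb <- pmax(Sbb - Sb * Sb / pmax(n, 1), 0)
  den <- sqrt(va * vb)
  ncc <- (Sab - Sa * Sb / pmax(n, 1))
  # constant overlap windows are defined as zero correlation (avoids 0/0)
  ok <- n >= min_overlap & den > 1e-6 * n
  ncc[ok] <- ncc[ok] / den[ok]
  ncc[!ok] <- 0
  ncc <- pmin(pmax(ncc, -1), 1)
  i <- 0:(P[1] - 1); j <- 0:(P[2] - 1)
  dy <- ifelse(i <= nrow(a) - 1, i, i - P[1])
  dx <- ifelse(j <= ncol(a) - 1, j, j - P[2])
  list(ncc = ncc, n = n, dy = dy, dx = dx)
}

# Peak of an NCC surface restricted to a disc of shifts around `prior`.
# Optional 3-point parabolic sub-pixel refinement per axis.
ncc_peak <- function(surf, prior = c(0, 0), radius = Inf, subpixel = FALSE) {
  DX <- matrix(surf$dx, length(surf$dy), length(surf$dx), byrow = TRUE)
  DY <- matrix(surf$dy, length(surf$dy), length(surf$dx))
  ok <- (DX - prior[1])^2 + (DY - prior[2])^2 <= radius^2
  v <- surf$ncc
  v[!ok] <- -Inf
  k <- which.max(v)
  i <- (k - 1) %% nrow(v) + 1; j <- (k - 1) %/% nrow(v) + 1
  peak <- surf$ncc[i, j]
  d <- c(surf$dx[j], surf$dy[i])
  if (subpixel) {
    ref1 <- function(idx, n, getv) {
      if (idx <= 1 || idx >= n) return(0)
      y0 <- getv(idx - 1); y1 <- getv(idx); y2 <- getv(idx + 1)
      den <- y0 - 2 * y1 + y2
      if (abs(den) < 1e-12) return(0)
      off <- 0.5 * (y0 - y2) / den
      if (abs(off) > 1) 0 else off
    }
    d[1] <- d[1] + ref1(j, ncol(v), function(t) surf$ncc[i, t])
    d[2] <- d[2] + ref1(i, nrow(v), function(t) surf$ncc[t, j])
  }
  list(translation = d, correlation = peak)
}

#' Best translation between two rasters by masked FFT cross-correlation
#'
#' Finds the integer (optionally sub-pixel) shift of \code{b} relative to
#' \code{a} that maximizes the normalized cross-correlation of their overlap,
#' restricted to a disc of shifts around a prior offset.
#'
#' @param a,b numeric matrices.
#' @param prior expected (x, y) shift of \code{b} relative to \code{a}, px.
#' @param radius disc radius around \code{prior}, px (\code{Inf} = unrestricted).
#' @param mask_a,mask_b optional logical validity masks.
#' @param min_overlap minimum overlap pixel count for a shift to be eligible.
#' @param subpixel parabolic sub-pixel peak refinement (default FALSE).
#' @return list with \code{translation} (x, y) and \code{correlation}.
#' @export
fft_translation <- function(a, b, prior = c(0, 0), radius = Inf,
                            mask_a = NULL, mask_b = NULL,
                            min_overlap = 16, subpixel = FALSE) {
  surf <- masked_ncc(a, b, mask_a, mask_b, min_overlap = min_overlap)
  ncc_peak(surf, prior = prior, radius = radius, subpixel = subpixel)
}
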