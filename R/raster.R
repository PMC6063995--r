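# Raster conventions ---------------------------------------------------------
#
# A raster is a plain numeric matrix in gray levels (nominally 0..255), indexed
# [row, col] with row = y (down) and col = x (right). Pixel centers sit at
# 0-based coordinates: the pixel at [r, c] is centered on (x, y) = (c-1, r-1).

raster_dim <- function(img) c(nrow(img), ncol(img))

#' Bilinearly sample a raster at continuous positions
#'
#' @param img numeric matrix.
#' @param x,y 0-based pixel-center coordinates (vectors of equal length).
#' @param fill value returned outside the image (default \code{NA}).
#' @return numeric vector of samples.
#' @export
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= -1 & x0 <= nc - 1 & y0 >= -1 & y0 <= nr - 1 &
    x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  xi <- x0[inside]; yi <- y0[inside]; fxi <- fx[inside]; fyi <- fy[inside]
  # clamp the 4 corners to valid indices (only matters exactly on the border)
  c00 <- img[cbind(pmin(yi, nr - 1) + 1, pmin(xi, nc - 1) + 1)]
  c01 <- img[cbind(pmin(yi, nr - 1) + 1, pmin(xi + 1, nc - 1) + 1)]
  c10 <- img[cbind(pmin(yi + 1, nr - 1) + 1, pmin(xi, nc - 1) + 1)]
  c11 <- img[cbind(pmin(yi + 1, nr - 1) + 1, pmin(xi + 1, nc - 1) + 1)]
  out[inside] <- (1 - fyi) * ((1 - fxi) * c00 + fxi * c01) +
    fyi * ((1 - fxi) * c10 + fxi * c11)
  out
}

#' Warp a raster by an affine transform
#'
#' \code{tf} maps input coordinates to output coordinates; each output pixel is
#' sampled from the input at \code{affine_invert(tf)}(p) by bilinear
#' interpolation.
#'
#' @param img numeric matrix.
#' @param tf \code{affine2d} mapping input to output coordinates.
#' @param out_dim output (rows, cols), default the input size.
#' @param fill value for pixels mapping outside the input.
#' @return list with \code{raster} and logical \code{mask} of valid pixels.
#' @export
warp_affine <- function(img, tf, out_dim = dim(img), fill = 0) {
  inv <- affine_invert(tf)
  nr <- out_dim[1]; nc <- out_dim[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  src <- affine_apply(inv, cbind(xs, ys))
  v <- bilinear_sample(img, src[, 1], src[, 2], fill = NA_real_)
  mask <- matrix(!is.na(v), nr, nc)
  v[is.na(v)] <- fill
  list(raster = matrix(v, nr, nc), mask = mask)
}

# Rotate about the image center, returning raster + validity mask.
rotate_raster <- function(img, angle_deg, fill = 0) {
  ctr <- c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
  warp_affine(img, rigid2d(angle_deg, c(0, 0), center = ctr), fill = fill)
}

#' Gaussian blur of a raster
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; \code{sigma <= 0} returns the
#'   input unchanged.
#' @return numeric matrix.
#' @export
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- 2 * ceiling(3 * sigma) + 1
  if (r <= min(dim(img))) return(EBImage::gblur(img, sigma = sigma))
  # kernel larger than the image: replicate-pad, blur, crop back
  p <- r
  ri <- c(rep(1, p), seq_len(nrow(img)), rep(nrow(img), p))
  ci <- c(rep(1, p), seq_len(ncol(img)), rep(ncol(img), p))
  out <- EBImage::gblur(img[ri, ci], sigma = sigma)
  out[p + seq_len(nrow(img)), p + seq_len(ncol(img))]
}

# 3x3 median filter. EBImage's constant-time median expects [0,1]; we
# range-normalize, filter, and restore, so the result commutes exactly with
# affine gray maps a*I + b (a > 0).
median3 <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] < .Machine$double.eps) return(img)
  z <- (img - rng[1]) / (rng[2] - rng[1])
  zf <- EBImage::medianFilter(z, size = 1)
  zf * (rng[2] - rng[1]) + rng[1]
}

# Anti-aliased resize by a scale factor (EBImage bilinear after low-pass).
resize_raster <- function(img, scale) {
  if (scale == 1) return(img)
  w <- max(1L, round(nrow(img) * scale))
  h <- max(1L, round(ncol(img) * scale))
  EBImage::resize(gauss_blur(img, sigma = if (scale < 1) 0.5 / scale else 0),
                  w = w, h = h)
}

#' Average non-overlapping f x f pixel blocks
#'
#' In-plane voxel combination: each output pixel is the mean of an f x f block
#' of input pixels (trailing rows/cols that do not fill a block are dropped).
#'
#' @param img numeric matrix.
#' @param f integer block side (default 2).
#' @return numeric matrix of size \code{floor(dim(img)/f)}.
#' @export
block_average <- function(img, f = 2L) {
  f <- as.integer(f)
  nr <- (nrow(img) %/% f) * f; nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(img, c(f, nr %/% f, f, nc %/% f))
  m <- colMeans(a)                       # average over dim 1 -> (nr/f, f, nc/f)
  colMeans(aperm(m, c(2, 1, 3)))         # average over block cols -> (nr/f, nc/f)
}

#' Read a grayscale raster from TIFF/PNG
#'
#' @param path file path (.tif/.tiff/.png).
#' @return numeric matrix in gray levels 0..255, rows = y, cols = x.
#' @export
read_raster <- function(path) {
  im <- EBImage::readImage(path)
  d <- EBImage::imageData(im)
  if (length(dim(d)) > 2) d <- d[, , 1]
  t(d) * 255
}

#' Write a raster as 8-bit TIFF/PNG
#'
#' @param img numeric matrix in gray levels 0..255.
#' @param path output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(img, path) {
  z <- pmin(pmax(img / 255, 0), 1)
  EBImage::writeImage(EBImage::Image(t(z)), path,
                      type = if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "tiff",
                      bits.per.sample = 8L)
  invisible(path)
}

#' Add i.i.d. Gaussian pixel noise
#'
#' @param img numeric matrix.
#' @param sigma noise standard deviation, gray levels.
#' @param seed integer seed.
#' @param clip clip the result to [0, 255] (default TRUE).
#' @return numeric matrix.
#' @export
add_gaussian_noise <- function(img, sigma, seed, clip = TRUE) {
  check_number(sigma, "sigma", nonneg = TRUE)
  out <- with_seed(seed, img + rnorm(length(img), 0, sigma))
  out <- matrix(out, nrow(img), ncol(img))
  if (clip) out <- pmin(pmax(out, 0), 255)
  out
}
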