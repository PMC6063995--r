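# Gradient-domain intensity correction ---------------------------------------

#' Build the seam-suppressed target gradient field of a mosaic
#'
#' Forward-difference gradients of the mosaic with every gradient that
#' crosses a tile boundary set to zero. Integrating an image against this
#' target removes the seams while keeping all interior texture.
#'
#' @param mosaic numeric matrix.
#' @param tile_footprints list of tile rectangles, each
#'   \code{c(x0, y0, x1, y1)} in 0-based pixel coordinates (inclusive).
#' @return object of class \code{seam_field}: \code{gx} (nr x (nc-1)),
#'   \code{gy} ((nr-1) x nc), logical \code{seam_x}, \code{seam_y}.
#' @export
build_seam_field <- function(mosaic, tile_footprints) {
  nr <- nrow(mosaic); nc <- ncol(mosaic)
  gx <- mosaic[, 2:nc, drop = FALSE] - mosaic[, 1:(nc - 1), drop = FALSE]
  gy <- mosaic[2:nr, , drop = FALSE] - mosaic[1:(nr - 1), , drop = FALSE]
  seam_x <- matrix(FALSE, nr, nc - 1); seam_y <- matrix(FALSE, nr - 1, nc)
  xs <- 0:(nc - 1); ys <- 0:(nr - 1)
  for (fp in tile_footprints) {
    if (fp[1] < 0 || fp[2] < 0 || fp[3] > nc - 1 || fp[4] > nr - 1)
      stopf("tile footprint (%g,%g,%g,%g) outside mosaic", fp[1], fp[2], fp[3], fp[4])
    inx <- xs >= fp[1] & xs <= fp[3]; iny <- ys >= fp[2] & ys <= fp[4]
    inside <- outer(iny, inx)   # nr x nc membership of this tile
    seam_x <- seam_x | xor(inside[, 1:(nc - 1), drop = FALSE],
                           inside[, 2:nc, drop = FALSE])
    seam_y <- seam_y | xor(inside[1:(nr - 1), , drop = FALSE],
                           inside[2:nr, , drop = FALSE])
  }
  gx[seam_x] <- 0; gy[seam_y] <- 0
  structure(list(gx = gx, gy = gy, seam_x = seam_x, seam_y = seam_y),
            class = "seam_field")
}

# Forward differences and their adjoints on matrices (matrix-free operators).
dx_op <- function(u) u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE]
dy_op <- function(u) u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE]
dxt_op <- function(g, nr, nc) {    # adjoint of dx_op
  u <- matrix(0, nr, nc)
  u[, 1:(nc - 1)] <- u[, 1:(nc - 1)] - g
  u[, 2:nc] <- u[, 2:nc] + g
  u
}
dyt_op <- function(g, nr, nc) {
  u <- matrix(0, nr, nc)
  u[1:(nr - 1), ] <- u[1:(nr - 1), ] - g
  u[2:nr, ] <- u[2:nr, ] + g
  u
}

#' Solve the screened-Poisson seam-removal system
#'
#' Finds the image whose forward-difference gradients best fit the target
#' field in least squares, with a small screening term toward \code{init}
#' that fixes the otherwise free global offset; solved by conjugate
#' gradients on the normal equations, then the global mean is anchored to
#' the mean of \code{init}.
#'
#' @param field \code{seam_field} from \code{\link{build_seam_field}}.
#' @param init initial mosaic (also the screening target).
#' @param max_iter conjugate-gradient iteration cap.
#' @param tol relative-residual stopping tolerance.
#' @param screen screening weight (default 1e-6; small enough that a
#'   zero-gradient target yields a constant image to well under a gray level).
#' @return corrected mosaic, numeric matrix.
#' @export
solve_gradient_domain <- function(field, init, max_iter = 2000, tol = 1e-10,
                                  screen = 1e-6) {
  nr <- nrow(init); nc <- ncol(init)
  if (!all(dim(field$gx) == c(nr, nc - 1)) || !all(dim(field$gy) == c(nr - 1, nc)))
    stopf("field dimensions inconsistent with init")
  Aop <- function(u) dxt_op(dx_op(u), nr, nc) + dyt_op(dy_op(u), nr, nc) + screen * u
  b <- dxt_op(field$gx, nr, nc) + dyt_op(field$gy, nr, nc) + screen * init
  u <- init
  r <- b - Aop(u); p <- r
  rs <- sum(r * r); b2 <- sum(b * b)
  converged <- rs <= max(tol^2 * b2, .Machine$double.xmin)
  for (it in seq_len(if (converged) 0 else max_iter)) {
    Ap <- Aop(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) { converged <- TRUE; break }
    alpha <- rs / pAp
    u <- u + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (rs_new <= tol^2 * b2) { converged <- TRUE; break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (!converged && max_iter > 0)
    warnf("gradient-domain solve did not reach tol %.1e in %d iterations", tol, max_iter)
  u + (mean(init) - mean(u))
}

#' Mean absolute gray step across seam pixels
#'
#' QC statistic: the mean |difference| over all seam-crossing pixel pairs;
#' strictly decreases when seam removal works.
#'
#' @param mosaic numeric matrix.
#' @param field \code{seam_field} carrying the seam masks.
#' @return scalar mean absolute seam step, gray levels.
#' @export
seam_step <- function(mosaic, field) {
  gx <- dx_op(mosaic); gy <- dy_op(mosaic)
  v <- c(abs(gx[field$seam_x]), abs(gy[field$seam_y]))
  if (length(v) == 0) 0 else mean(v)
}

#' Replace low-frequency content with the neighboring-section average
#'
#' \code{output = (mosaic - G(mosaic)) + G(mean(neighbors))} with \code{G} a
#' Gaussian low-pass of standard deviation \code{cutoff_sigma}; high-pass
#' content of the input is untouched, section-to-section intensity drift is
#' taken from the windowed neighbor average.
#'
#' @param mosaic numeric matrix.
#' @param neighbor_mosaics non-empty list of rasters registered to the mosaic
#'   frame (same size).
#' @param cutoff_sigma Gaussian low-pass sigma, px; default 1/8 of the mosaic
#'   width.
#' @return corrected mosaic.
#' @export
replace_low_frequency <- function(mosaic, neighbor_mosaics,
                                  cutoff_sigma = ncol(mosaic) / 8) {
  if (length(neighbor_mosaics) == 0) stopf("need at least one neighbor mosaic")
  check_number(cutoff_sigma, "cutoff_sigma", positive = TRUE)
  for (nb in neighbor_mosaics)
    if (!all(dim(nb) == dim(mosaic))) stopf("neighbors must match the mosaic size")
  avg <- Reduce(`+`, neighbor_mosaics) / length(neighbor_mosaics)
  mosaic - gauss_blur(mosaic, cutoff_sigma) + gauss_blur(avg, cutoff_sigma)
}
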