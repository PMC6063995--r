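# 2D affine transforms -------------------------------------------------------
#
# An affine transform maps a column vector (x, y, 1); pixel units, 0-based
# coordinates, x right / y down, pixel-center convention. Stored as a 2x3
# matrix m with p' = m %*% c(x, y, 1).

#' Construct a 2D affine transform
#'
#' Transforms map column vectors \code{(x, y, 1)}: \code{p' = m \%*\% c(x, y, 1)}
#' with \code{m} a 2x3 coefficient matrix. Coordinates are pixels (or nm where
#' stated), 0-based, x right / y down, pixel-center convention.
#'
#' @param m 2x3 numeric matrix, or a length-6 vector in row-major order
#'   \code{(a11, a12, a13, a21, a22, a23)}.
#' @return An object of class \code{affine2d}.
#' @export
affine2d <- function(m = cbind(diag(2), c(0, 0))) {
  if (is.numeric(m) && is.null(dim(m)) && length(m) == 6L)
    m <- matrix(m, 2, 3, byrow = TRUE)
  if (!is.matrix(m) || !all(dim(m) == c(2, 3)) || !all(is.finite(m)))
    stopf("affine2d needs a finite 2x3 matrix")
  if (abs(det(m[, 1:2])) < 1e-12)
    stopf("affine transform is singular (zero determinant)")
  structure(list(m = m), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d>\n"); print(x$m); invisible(x)
}

#' Rigid (rotation + translation) affine transform
#'
#' @param angle_deg rotation angle, degrees, counter-clockwise in an x-right /
#'   y-down frame (i.e. visually clockwise).
#' @param translation length-2 numeric, pixels.
#' @param center optional rotation center (default origin).
#' @return \code{affine2d}
#' @export
rigid2d <- function(angle_deg = 0, translation = c(0, 0), center = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t <- as.numeric(center) - R %*% as.numeric(center) + as.numeric(translation)
  affine2d(cbind(R, t))
}

#' Translation-only affine transform
#' @param translation length-2 numeric.
#' @return \code{affine2d}
#' @export
translate2d <- function(translation) rigid2d(0, translation)

#' Apply an affine transform to points
#' @param tf \code{affine2d}
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) points.
#' @return n x 2 matrix of transformed points.
#' @export
affine_apply <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  out <- cbind(pts, 1) %*% t(tf$m)
  colnames(out) <- c("x", "y")
  out
}

#' Compose affine transforms: (a %o% b)(p) = a(b(p))
#' @param a,b \code{affine2d}
#' @return \code{affine2d}
#' @export
affine_compose <- function(a, b) {
  A <- rbind(a$m, c(0, 0, 1)); B <- rbind(b$m, c(0, 0, 1))
  affine2d((A %*% B)[1:2, ])
}

#' Invert an affine transform
#' @param tf \code{affine2d}
#' @return \code{affine2d}
#' @export
affine_invert <- function(tf) {
  A <- tf$m[, 1:2]; t <- tf$m[, 3]
  Ai <- solve(A)
  affine2d(cbind(Ai, -Ai %*% t))
}

#' Conjugate a transform by an isotropic scale change
#'
#' Re-expresses a transform defined in a frame scaled by \code{s} (e.g. a
#' montage scape at scale 1/20) in the unscaled frame: linear part unchanged,
#' translation divided by \code{s}.
#'
#' @param tf \code{affine2d} in the scaled frame.
#' @param s scale of that frame relative to the target frame (0 < s <= 1).
#' @return \code{affine2d} in the target frame.
#' @export
affine_unscale <- function(tf, s) {
  check_number(s, "s", positive = TRUE)
  m <- tf$m; m[, 3] <- m[, 3] / s
  affine2d(m)
}

# Least-squares affine fit taking points a -> b; n >= 3 non-collinear points.
fit_affine <- function(pa, pb, w = NULL) {
  n <- nrow(pa)
  if (n < 3) return(NULL)
  X <- cbind(pa, 1)
  if (!is.null(w)) { sw <- sqrt(w); X <- X * sw; pb <- pb * sw }
  cf <- tryCatch(qr.solve(X, pb), error = function(e) NULL)
  if (is.null(cf) || !all(is.finite(cf))) return(NULL)
  m <- t(cf)  # 2x3: rows are x', y' coefficients
  if (abs(det(m[, 1:2])) < 1e-12) return(NULL)
  affine2d(m)
}

# Exact/LS rigid fit a -> b (Kabsch without scale); n >= 2 points.
fit_rigid <- function(pa, pb) {
  if (nrow(pa) < 2) return(NULL)
  ca <- colMeans(pa); cb <- colMeans(pb)
  A <- sweep(pa, 2, ca); B <- sweep(pb, 2, cb)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  affine2d(cbind(R, cb - R %*% ca))
}

fit_translation <- function(pa, pb) {
  translate2d(colMeans(pb) - colMeans(pa))
}
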