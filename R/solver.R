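# Regularized sparse affine solve --------------------------------------------
#
# All registration stages end in the same quadratic problem: find per-image
# affine transforms T_i minimizing
#     sum over matches  w * || T_a(p_a) - T_b(p_b) ||^2
#   + lambda * sum over images || T_i - prior_i ||^2   (coefficient-wise),
# a sparse least-squares system that decouples into identical x- and y-row
# subproblems sharing one design matrix.

#' @importFrom Matrix sparseMatrix Diagonal crossprod solve t
NULL

coef_vec <- function(tf) c(tf$m[1, ], tf$m[2, ])  # (a11,a12,a13,a21,a22,a23)

coefs_to_affine <- function(v) affine2d(matrix(v, 2, 3, byrow = TRUE))

# Build the match design matrix D (rows = weighted match equations, cols =
# 3 * n_tiles) shared by the x- and y-coefficient systems.
match_design <- function(match_sets, tile_ids) {
  idx <- setNames(seq_along(tile_ids), tile_ids)
  ii <- list(); jj <- list(); xx <- list(); row0 <- 0L
  for (ms in match_sets) {
    m <- n_matches(ms)
    if (m == 0) next
    if (!ms$tile_id_a %in% tile_ids || !ms$tile_id_b %in% tile_ids)
      stopf("match set references tile '%s' or '%s' absent from priors",
            ms$tile_id_a, ms$tile_id_b)
    ca <- (idx[[ms$tile_id_a]] - 1L) * 3L
    cb <- (idx[[ms$tile_id_b]] - 1L) * 3L
    sw <- sqrt(ms$weights)
    r <- row0 + seq_len(m)
    ii <- c(ii, list(rep(r, 6L)))
    jj <- c(jj, list(c(rep(ca + 1L, m), rep(ca + 2L, m), rep(ca + 3L, m),
                       rep(cb + 1L, m), rep(cb + 2L, m), rep(cb + 3L, m))))
    xx <- c(xx, list(c(sw * ms$pa[, 1], sw * ms$pa[, 2], sw,
                       -sw * ms$pb[, 1], -sw * ms$pb[, 2], -sw)))
    row0 <- row0 + m
  }
  if (row0 == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, 3L * length(tile_ids))))
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(row0, 3L * length(tile_ids)))
}

match_graph_components <- function(match_sets, tile_ids) {
  parent <- setNames(seq_along(tile_ids), tile_ids)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (ms in match_sets) {
    if (n_matches(ms) == 0) next
    ra <- find(match(ms$tile_id_a, tile_ids)); rb <- find(match(ms$tile_id_b, tile_ids))
    if (ra != rb) parent[[rb]] <- ra
  }
  vapply(seq_along(tile_ids), find, 0L)
}

solve_affine_system <- function(match_sets, priors, lambda_reg = NULL,
                                anchor = NULL, linear_weight = 1,
                                warn_disconnected = TRUE) {
  tile_ids <- names(priors)
  if (is.null(tile_ids) || anyDuplicated(tile_ids))
    stopf("priors must be a uniquely named list of affine2d")
  match_sets <- Filter(function(ms) n_matches(ms) > 0, match_sets)
  n_total <- sum(vapply(match_sets, n_matches, 0L))
  if (is.null(lambda_reg)) lambda_reg <- 1e-3 * max(1, n_total)
  if (lambda_reg < 0) stopf("lambda_reg must be >= 0")
  if (lambda_reg == 0 && is.null(anchor))
    stopf(paste("lambda_reg = 0 leaves the solution gauge-free;",
                "use a nonzero regularization or set `anchor` to a tile id"))
  comp <- match_graph_components(match_sets, tile_ids)
  if (warn_disconnected && length(unique(comp)) > 1L && length(tile_ids) > 1L)
    warnf("match graph has %d connected components; each is pinned by its priors",
          length(unique(comp)))
  D <- match_design(match_sets, tile_ids)
  nt <- length(tile_ids)
  P <- vapply(priors, coef_vec, numeric(6))     # 6 x nt
  px <- as.vector(P[1:3, ]); py <- as.vector(P[4:6, ])
  w3 <- rep(c(linear_weight, linear_weight, 1), nt)
  A <- Matrix::crossprod(D) + lambda_reg * Matrix::Diagonal(3L * nt, w3)
  bx <- lambda_reg * w3 * px; by <- lambda_reg * w3 * py
  free <- rep(TRUE, 3L * nt)
  if (!is.null(anchor)) {
    ai <- match(anchor, tile_ids)
    if (is.na(ai)) stopf("anchor tile '%s' not found", anchor)
    fix <- (ai - 1L) * 3L + 1:3
    free[fix] <- FALSE
    bx <- bx - as.vector(A[, fix, drop = FALSE] %*% px[fix])
    by <- by - as.vector(A[, fix, drop = FALSE] %*% py[fix])
  }
  ux <- px; uy <- py
  if (any(free)) {
    Af <- A[free, free, drop = FALSE]
    ux[free] <- as.vector(Matrix::solve(Af, bx[free]))
    uy[free] <- as.vector(Matrix::solve(Af, by[free]))
  }
  out <- vector("list", nt)
  for (i in seq_len(nt)) {
    k <- (i - 1L) * 3L
    out[[i]] <- coefs_to_affine(c(ux[k + 1:3], uy[k + 1:3]))
  }
  setNames(out, tile_ids)
}

#' Quadratic alignment objective
#'
#' The value minimized by \code{\link{solve_montage}} and
#' \code{\link{solve_volume}}: weighted squared match residuals plus
#' \code{lambda_reg} times the coefficient-wise squared deviation of each
#' transform from its prior.
#'
#' @param match_sets list of \code{point_match_set}.
#' @param transforms,priors named lists of \code{affine2d}.
#' @param lambda_reg regularization weight.
#' @param linear_weight extra weight on the linear (non-translation)
#'   coefficients; a value of (tile size)^2 makes a unit coefficient
#'   deviation cost as much as the pixel displacement it causes.
#' @return scalar objective value.
#' @export
alignment_objective <- function(match_sets, transforms, priors, lambda_reg,
                                linear_weight = 1) {
  obj <- 0
  for (ms in match_sets) {
    if (n_matches(ms) == 0) next
    ra <- affine_apply(transforms[[ms$tile_id_a]], ms$pa)
    rb <- affine_apply(transforms[[ms$tile_id_b]], ms$pb)
    obj <- obj + sum(ms$weights * rowSums((ra - rb)^2))
  }
  W <- matrix(c(linear_weight, linear_weight, linear_weight, linear_weight, 1, 1),
              2, 3)
  for (id in names(priors))
    obj <- obj + lambda_reg * sum(W * (transforms[[id]]$m - priors[[id]]$m)^2)
  obj
}

#' Solve a section montage
#'
#' Finds per-tile affine transforms (tile-local px to section px) minimizing
#' squared point-match residuals, regularized toward the stage-coordinate
#' priors, which also fixes the global gauge.
#'
#' @param match_sets list of intra-section \code{point_match_set}.
#' @param priors named list of \code{affine2d} per tile (see
#'   \code{\link{stage_priors}}).
#' @param lambda_reg regularization weight; default \code{1e-3 * n_matches}.
#' @param anchor optional tile id to pin exactly to its prior (required if
#'   \code{lambda_reg = 0}).
#' @param linear_weight regularization weight multiplier for the linear
#'   coefficients (see \code{\link{alignment_objective}}); the square of the
#'   tile size keeps the affine part pinned to the rigid prior unless the
#'   matches demand otherwise.
#' @return named list of \code{affine2d}, one per tile.
#' @export
solve_montage <- function(match_sets, priors, lambda_reg = NULL, anchor = NULL,
                          linear_weight = 1) {
  solve_affine_system(match_sets, priors, lambda_reg, anchor, linear_weight)
}

#' Solve the global volume alignment
#'
#' Joint version of \code{\link{solve_montage}} over all tiles of all
#' sections: intra-section and cross-section match sets enter one quadratic
#' objective, regularized toward priors composed from the rough (per-section)
#' alignment and the per-section montage transforms.
#'
#' @param intra list of intra-section \code{point_match_set}.
#' @param cross list of cross-section \code{point_match_set} (tile-local
#'   coordinates; see \code{\link{section_matches_to_tiles}}).
#' @param priors named list of per-tile \code{affine2d} in the global frame.
#' @param lambda_reg regularization weight (> 0).
#' @param cross_weight multiplier applied to cross-section match weights.
#' @param linear_weight as in \code{\link{solve_montage}}.
#' @return named list of per-tile global \code{affine2d}.
#' @export
solve_volume <- function(intra, cross, priors, lambda_reg = NULL, cross_weight = 1,
                         linear_weight = 1) {
  cross <- lapply(cross, function(ms) { ms$weights <- ms$weights * cross_weight; ms })
  solve_affine_system(c(intra, cross), priors, lambda_reg,
                      linear_weight = linear_weight)
}

#' RMS position error after removing the global affine gauge
#'
#' Relative matches determine transforms only up to one global affine; before
#' comparing a solution with ground truth, the best single affine mapping
#' solved positions onto true positions is removed. Each tile contributes its
#' transformed corner and center points.
#'
#' @param solved,truth named lists of per-tile \code{affine2d} (same names).
#' @param tile_dim (rows, cols) of a tile, used to place the probe points.
#' @return RMS residual in px after gauge removal.
#' @export
gauge_rms <- function(solved, truth, tile_dim) {
  pts <- cbind(x = c(0, tile_dim[2] - 1, 0, tile_dim[2] - 1, (tile_dim[2] - 1) / 2),
               y = c(0, 0, tile_dim[1] - 1, tile_dim[1] - 1, (tile_dim[1] - 1) / 2))
  S <- NULL; G <- NULL
  for (id in names(truth)) {
    S <- rbind(S, affine_apply(solved[[id]], pts))
    G <- rbind(G, affine_apply(truth[[id]], pts))
  }
  g <- fit_affine(S, G)
  r <- affine_apply(g, S) - G
  sqrt(mean(rowSums(r^2)))
}
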