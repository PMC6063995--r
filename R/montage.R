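# Intra-section stitching ----------------------------------------------------

as_raster <- function(x) if (inherits(x, "em_tile")) x$raster else x

#' Coarse rigid match between two overlapping tiles
#'
#' Sweeps rotation angles; at each angle the best translation is found by
#' masked, normalized FFT cross-correlation restricted to a disc of preferred
#' shifts around the stage-derived prior offset. Returns the best rigid
#' transform mapping tile-B pixel coordinates into the tile-A frame.
#'
#' @param tile_a,tile_b \code{em_tile} or plain rasters.
#' @param prior_offset expected (x, y) shift of B relative to A, px.
#' @param search_radius disc radius around the prior, px.
#' @param angle_range half-range of the rotation sweep, degrees (0 = pure
#'   translation).
#' @param angle_step sweep step, degrees.
#' @param corr_floor correlation below which the pair is declared unmatched.
#' @param subpixel parabolic sub-pixel refinement of the translation peak.
#' @return list with \code{angle} (deg), \code{translation} (x, y px),
#'   \code{correlation}, and \code{transform} (\code{affine2d}, B -> A).
#' @export
coarse_match <- function(tile_a, tile_b, prior_offset = c(0, 0), search_radius = 20,
                         angle_range = 0, angle_step = 0.5, corr_floor = 0.1,
                         subpixel = FALSE) {
  check_number(search_radius, "search_radius", positive = TRUE)
  a <- as_raster(tile_a); b <- as_raster(tile_b)
  angles <- if (angle_range > 0) seq(-angle_range, angle_range, by = angle_step) else 0
  best <- list(correlation = -Inf)
  for (th in angles) {
    if (th == 0) { br <- b; mb <- NULL }
    else { w <- rotate_raster(b, th); br <- w$raster; mb <- w$mask }
    pk <- fft_translation(a, br, prior = prior_offset, radius = search_radius,
                          mask_b = mb, subpixel = subpixel)
    if (pk$correlation > best$correlation)
      best <- list(angle = th, translation = pk$translation, correlation = pk$correlation)
  }
  if (!is.finite(best$correlation) || best$correlation < corr_floor)
    stopf("no correlation peak above %.2f within the search disc (best %.3f)",
          corr_floor, best$correlation)
  ctr <- c((ncol(b) - 1) / 2, (nrow(b) - 1) / 2)
  best$transform <- affine_compose(translate2d(best$translation),
                                   rigid2d(best$angle, c(0, 0), center = ctr))
  best
}

# Regular right-triangle lattice over a bounding box. Returns vertices (n x 2)
# and triangles (m x 3 vertex indices), counter-clockwise in the y-down frame.
make_mesh <- function(x0, x1, y0, y1, spacing) {
  nx <- max(1L, ceiling((x1 - x0) / spacing))
  ny <- max(1L, ceiling((y1 - y0) / spacing))
  xs <- seq(x0, x1, length.out = nx + 1)
  ys <- seq(y0, y1, length.out = ny + 1)
  V <- cbind(x = rep(xs, times = ny + 1), y = rep(ys, each = nx + 1))
  vid <- function(ix, iy) (iy - 1L) * (nx + 1L) + ix
  tri <- vector("list", 2L * nx * ny)
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    v00 <- vid(ix, iy); v10 <- vid(ix + 1L, iy)
    v01 <- vid(ix, iy + 1L); v11 <- vid(ix + 1L, iy + 1L)
    tri[[k <- k + 1L]] <- c(v00, v10, v11)
    tri[[k <- k + 1L]] <- c(v00, v11, v01)
  }
  list(vertices = V, triangles = do.call(rbind, tri), nx = nx, ny = ny,
       x0 = x0, y0 = y0, dx = (x1 - x0) / nx, dy = (y1 - y0) / ny)
}

tri_signed_area <- function(V, tri) {
  p1 <- V[tri[, 1], , drop = FALSE]; p2 <- V[tri[, 2], , drop = FALSE]
  p3 <- V[tri[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Deformable-mesh refinement of a coarse tile match
#'
#' Within the overlap implied by \code{rigid_init}, A-pixels stay fixed; a
#' regular triangle mesh is erected over the corresponding B region and every
#' overlap pixel is expressed in barycentric coordinates of its triangle. The
#' normalized cross-correlation of mesh-warped B against A then becomes a
#' function of the vertex positions, which are optimized by finite-difference
#' gradient ascent with backtracking step halving.
#'
#' @param tile_a,tile_b \code{em_tile} or rasters.
#' @param rigid_init \code{affine2d} mapping B coordinates into the A frame
#'   (e.g. from \code{\link{coarse_match}}).
#' @param mesh_spacing triangle lattice spacing, px (>= 16).
#' @param max_iterations gradient-ascent iteration cap.
#' @param step_size initial vertex step, px.
#' @param tolerance stop when the correlation gain of an iteration falls below
#'   this value (\code{Inf} returns the initial mesh untouched).
#' @return object of class \code{mesh_match}: \code{vertices_initial},
#'   \code{vertices_optimized} (B frame), \code{triangles}, \code{correlation},
#'   \code{correlation_initial}, \code{iterations}.
#' @export
refine_mesh <- function(tile_a, tile_b, rigid_init, mesh_spacing = 32,
                        max_iterations = 200, step_size = 1, tolerance = 1e-4) {
  if (mesh_spacing < 16) stopf("mesh_spacing must be >= 16 px")
  a <- as_raster(tile_a); b <- as_raster(tile_b)
  inv <- affine_invert(rigid_init)
  nrA <- nrow(a); ncA <- ncol(a)
  px <- rep(0:(ncA - 1), each = nrA); py <- rep(0:(nrA - 1), times = ncA)
  q <- affine_apply(inv, cbind(px, py))
  keep <- q[, 1] >= 0 & q[, 1] <= ncol(b) - 1 & q[, 2] >= 0 & q[, 2] <= nrow(b) - 1
  if (!any(keep)) stopf("empty overlap under rigid_init")
  px <- px[keep]; py <- py[keep]; q <- q[keep, , drop = FALSE]
  a_vals <- a[cbind(py + 1, px + 1)]

  mesh <- make_mesh(min(q[, 1]), max(q[, 1]), min(q[, 2]), max(q[, 2]), mesh_spacing)
  V0 <- mesh$vertices
  if (nrow(mesh$triangles) < 1) stopf("mesh has no triangles")

  # cell + half-of-quad assignment, then barycentric weights w.r.t. V0
  u <- (q[, 1] - mesh$x0) / mesh$dx; v <- (q[, 2] - mesh$y0) / mesh$dy
  ix <- pmin(pmax(floor(u), 0), mesh$nx - 1); iy <- pmin(pmax(floor(v), 0), mesh$ny - 1)
  fu <- u - ix; fv <- v - iy
  upper <- fv <= fu  # triangle (v00, v10, v11) holds fv <= fu
  tri_id <- 2L * (iy * mesh$nx + ix) + ifelse(upper, 1L, 2L)
  TRI <- mesh$triangles[tri_id, , drop = FALSE]
  # barycentric in the right triangles of the regular lattice (affine-exact)
  W <- matrix(0, length(px), 3)
  W[upper, ] <- cbind(1 - fu[upper], fu[upper] - fv[upper], fv[upper])
  W[!upper, ] <- cbind(1 - fv[!upper], fu[!upper], fv[!upper] - fu[!upper])

  sample_pix <- function(V, rows) {
    X <- rowSums(W[rows, , drop = FALSE] * matrix(V[TRI[rows, ], 1], ncol = 3))
    Y <- rowSums(W[rows, , drop = FALSE] * matrix(V[TRI[rows, ], 2], ncol = 3))
    # replicate-border sampling: keeps the objective smooth when border
    # vertices push sample positions slightly outside B
    X <- pmin(pmax(X, 0), ncol(b) - 1)
    Y <- pmin(pmax(Y, 0), nrow(b) - 1)
    bilinear_sample(b, X, Y)
  }
  n_pix <- length(a_vals)
  Sa <- sum(a_vals); Saa <- sum(a_vals^2)
  ncc_from <- function(bv) {
    Sb <- sum(bv); Sbb <- sum(bv^2); Sab <- sum(a_vals * bv)
    den <- sqrt(max(Saa - Sa^2 / n_pix, 0) * max(Sbb - Sb^2 / n_pix, 0))
    if (den < 1e-9) 0 else (Sab - Sa * Sb / n_pix) / den
  }
  bv <- sample_pix(V0, seq_len(n_pix))
  cc0 <- ncc_from(bv)
  res <- structure(list(vertices_initial = V0, vertices_optimized = V0,
                        triangles = mesh$triangles, correlation = cc0,
                        correlation_initial = cc0, rigid_init = rigid_init,
                        iterations = 0L), class = "mesh_match")
  if (is.infinite(tolerance)) return(res)

  # pixels touching each vertex (for local finite-difference updates); the
  # pixel count doubles as a diagonal preconditioner so weakly-supported
  # border vertices take comparably scaled steps
  vert_rows <- split(rep(seq_len(n_pix), 3), as.vector(TRI))
  vert_n <- vapply(as.character(seq_len(nrow(V0))),
                   function(k) length(vert_rows[[k]]), 0)
  vert_n[vert_n == 0] <- 1
  area_sign <- sign(tri_signed_area(V0, mesh$triangles))
  V <- V0; cc <- cc0; h <- 0.25; iter <- 0L
  nv <- nrow(V0)
  while (iter < max_iterations) {
    iter <- iter + 1L
    grad <- matrix(0, nv, 2)
    for (k in seq_len(nv)) {
      rows <- vert_rows[[as.character(k)]]
      if (is.null(rows)) next
      for (cdim in 1:2) {
        Vp <- V; Vp[k, cdim] <- Vp[k, cdim] + h
        bv_new <- sample_pix(Vp, rows)
        bv_p <- bv; bv_p[rows] <- bv_new
        grad[k, cdim] <- (ncc_from(bv_p) - cc) / h
      }
    }
    grad <- grad / vert_n
    g <- max(abs(grad))
    if (g < 1e-12) break
    improved <- FALSE; s <- step_size
    for (try in 1:8) {
      Vp <- V + (s / g) * grad
      if (any(sign(tri_signed_area(Vp, mesh$triangles)) * area_sign <= 0)) { s <- s / 2; next }
      bv_p <- sample_pix(Vp, seq_len(n_pix))
      cc_p <- ncc_from(bv_p)
      if (cc_p > cc) { V <- Vp; bv <- bv_p; dcc <- cc_p - cc; cc <- cc_p; improved <- TRUE; break }
      s <- s / 2
    }
    if (!improved || dcc < tolerance) break
  }
  res$vertices_optimized <- V
  res$correlation <- cc
  res$iterations <- iter
  res
}

#' Extract point pairs from an optimized mesh match
#'
#' One match per triangle: the A-point is the pre-optimization triangle
#' centroid mapped into the A frame through \code{rigid_init}; the B-point is
#' the per-triangle affine (initial to optimized vertices) applied to that
#' centroid.
#'
#' @param mesh \code{mesh_match} from \code{\link{refine_mesh}}.
#' @param rigid_init \code{affine2d} B -> A (defaults to the one stored in the
#'   mesh).
#' @param tile_id_a,tile_id_b ids recorded in the output set.
#' @return \code{point_match_set} (intra-section).
#' @export
mesh_to_point_pairs <- function(mesh, rigid_init = mesh$rigid_init,
                                tile_id_a = "A", tile_id_b = "B") {
  Vi <- mesh$vertices_initial; Vo <- mesh$vertices_optimized
  pa <- NULL; pb <- NULL; skipped <- 0L
  for (t in seq_len(nrow(mesh$triangles))) {
    id <- mesh$triangles[t, ]
    ti <- Vi[id, , drop = FALSE]; to <- Vo[id, , drop = FALSE]
    if (abs(tri_signed_area(to, matrix(1:3, 1))) < 1e-9) { skipped <- skipped + 1L; next }
    F <- fit_affine(ti, to)
    if (is.null(F)) { skipped <- skipped + 1L; next }
    cen <- colMeans(ti)
    pa <- rbind(pa, affine_apply(rigid_init, cen))
    pb <- rbind(pb, affine_apply(F, cen))
  }
  if (skipped > 0) warnf("%d degenerate optimized triangles skipped", skipped)
  if (is.null(pa)) pa <- pb <- matrix(numeric(0), 0, 2)
  point_match_set(tile_id_a, tile_id_b, pa, pb, provenance = "intra-section")
}

#' RANSAC filter for a point-match set
#'
#' Finds the largest consensus set whose matches fit a single transform (of
#' the chosen model class) with residual at most \code{max_displacement};
#' everything else is discarded as a wrong match. Deterministic for a given
#' seed; ties between equal-size consensus sets are broken by lower mean
#' residual.
#'
#' @param matches \code{point_match_set}.
#' @param model \code{"translation"}, \code{"rigid"} or \code{"affine"}
#'   (minimal samples 1 / 2 / 3).
#' @param max_displacement inlier residual threshold, px.
#' @param iterations number of random minimal samples.
#' @param min_inliers consensus below this size returns an empty, rejected set.
#' @param seed integer seed.
#' @return \code{point_match_set} of the retained matches, with attribute
#'   \code{rejected} (TRUE when no acceptable consensus was found) and
#'   attribute \code{model_transform} (\code{affine2d} fit to the inliers).
#' @export
filter_ransac <- function(matches, model = c("affine", "rigid", "translation"),
                          max_displacement = 4, iterations = 500,
                          min_inliers = 4, seed = 1) {
  model <- match.arg(model)
  if (iterations < 1) stopf("iterations must be >= 1")
  s_min <- switch(model, translation = 1L, rigid = 2L, affine = 3L)
  fit_fun <- switch(model, translation = fit_translation, rigid = fit_rigid,
                    affine = function(pa, pb) fit_affine(pa, pb))
  n <- n_matches(matches)
  empty <- function() {
    out <- point_match_set(matches$tile_id_a, matches$tile_id_b,
                           matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2),
                           provenance = matches$provenance)
    attr(out, "rejected") <- TRUE
    out
  }
  if (n < max(s_min, min_inliers)) return(empty())
  pa <- matches$pa; pb <- matches$pb
  resid <- function(tf) sqrt(rowSums((affine_apply(tf, pa) - pb)^2))
  best <- list(n = 0L, mr = Inf, inl = NULL)
  consider <- function(tf, best) {
    if (is.null(tf)) return(best)
    r <- resid(tf)
    inl <- which(r <= max_displacement)
    if (length(inl) == 0) return(best)
    mr <- mean(r[inl])
    if (length(inl) > best$n || (length(inl) == best$n && mr < best$mr))
      list(n = length(inl), mr = mr, inl = inl)
    else best
  }
  # global fit first: exact-consistency short-circuit, then seeded sampling
  best <- consider(fit_fun(pa, pb), best)
  if (best$n < n) {
    samples <- with_seed(seed, replicate(iterations, sample.int(n, s_min), simplify = FALSE))
    for (sm in samples)
      best <- consider(fit_fun(pa[sm, , drop = FALSE], pb[sm, , drop = FALSE]), best)
  }
  if (best$n >= s_min) {  # refit on the consensus, re-collect inliers
    best <- consider(fit_fun(pa[best$inl, , drop = FALSE], pb[best$inl, , drop = FALSE]), best)
  }
  if (best$n < min_inliers) return(empty())
  out <- point_match_set(matches$tile_id_a, matches$tile_id_b,
                         pa[best$inl, , drop = FALSE], pb[best$inl, , drop = FALSE],
                         weights = matches$weights[best$inl],
                         provenance = matches$provenance)
  attr(out, "rejected") <- FALSE
  attr(out, "model_transform") <- fit_fun(pa[best$inl, , drop = FALSE],
                                          pb[best$inl, , drop = FALSE])
  out
}

#' Match all overlapping tile pairs and solve one section montage
#'
#' The full intra-section pipeline: candidate pairs from stage-coordinate
#' priors, coarse FFT matching within a disc around the prior offset,
#' optional deformable-mesh refinement, point-pair extraction, RANSAC
#' filtering, and the regularized montage solve.
#'
#' @param tileset \code{em_tileset}.
#' @param search_radius matching disc radius around the stage prior, px
#'   (should exceed the worst stage error).
#' @param min_overlap_frac candidate pairs must overlap by at least this
#'   fraction of a tile (computed from priors, with \code{search_radius}
#'   slack).
#' @param mesh refine with a deformable mesh before extracting point pairs
#'   (default TRUE); otherwise point pairs are laid on a grid over the
#'   overlap under the coarse transform.
#' @param mesh_spacing triangle lattice spacing, px.
#' @param max_displacement RANSAC residual threshold, px.
#' @param lambda_reg regularization of the montage solve.
#' @param seed integer seed (RANSAC).
#' @return list with \code{transforms} (per-tile \code{affine2d}),
#'   \code{match_sets}, and \code{priors}.
#' @export
stitch_section <- function(tileset, search_radius = 12, min_overlap_frac = 0.04,
                           mesh = TRUE, mesh_spacing = 24, max_displacement = 4,
                           lambda_reg = NULL, seed = 1) {
  priors <- stage_priors(tileset)
  ids <- names(tileset$tiles)
  match_sets <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    ta <- tileset$tiles[[i]]; tb <- tileset$tiles[[j]]
    rel <- priors[[j]]$m[, 3] - priors[[i]]$m[, 3]
    dx <- max(0, abs(rel[1]) - search_radius)
    dy <- max(0, abs(rel[2]) - search_radius)
    ovx <- min(ncol(ta$raster), ncol(tb$raster)) - dx
    ovy <- min(nrow(ta$raster), nrow(tb$raster)) - dy
    if (ovx <= 0 || ovy <= 0 ||
        ovx * ovy < min_overlap_frac * length(ta$raster)) next
    cm <- tryCatch(coarse_match(ta, tb, prior_offset = rel,
                                search_radius = search_radius),
                   error = function(e) NULL)
    if (is.null(cm)) next
    if (mesh) {
      mmatch <- tryCatch(refine_mesh(ta, tb, cm$transform,
                                     mesh_spacing = mesh_spacing),
                         error = function(e) NULL)
      if (is.null(mmatch)) next
      pp <- mesh_to_point_pairs(mmatch, tile_id_a = ids[i], tile_id_b = ids[j])
    } else {
      inv <- affine_invert(cm$transform)
      gx <- seq(0, ncol(tb$raster) - 1, length.out = 6)
      gy <- seq(0, nrow(tb$raster) - 1, length.out = 6)
      pb <- as.matrix(expand.grid(x = gx, y = gy))
      pa <- affine_apply(cm$transform, pb)
      keep <- pa[, 1] >= 0 & pa[, 1] <= ncol(ta$raster) - 1 &
        pa[, 2] >= 0 & pa[, 2] <= nrow(ta$raster) - 1
      if (sum(keep) < 3) next
      pp <- point_match_set(ids[i], ids[j], pa[keep, , drop = FALSE],
                            pb[keep, , drop = FALSE])
    }
    pp <- filter_ransac(pp, model = "affine", max_displacement = max_displacement,
                        seed = seed + 13L * i + j)
    if (!isTRUE(attr(pp, "rejected")) && n_matches(pp) > 0)
      match_sets[[length(match_sets) + 1]] <- pp
  }
  tile_dim <- dim(tileset$tiles[[1]]$raster)
  list(transforms = solve_montage(match_sets, priors, lambda_reg = lambda_reg,
                                  linear_weight = sum(tile_dim^2)),
       match_sets = match_sets, priors = priors)
}
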