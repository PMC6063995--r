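# Cross-section alignment ----------------------------------------------------

#' Render a montage scape
#'
#' Warps all tiles of a section into the section frame using their solved
#' transforms, averages where tiles overlap, and downsamples to a reduced
#' scale (the paper-style working resolution for section-to-section matching,
#' default 1/20 at production scale; choose per data size).
#'
#' @param tileset \code{em_tileset}.
#' @param transforms named list of per-tile \code{affine2d} (tile px ->
#'   section px).
#' @param scale render scale in (0, 1].
#' @return object of class \code{montage_scape}: \code{raster}, \code{mask}
#'   (coverage), \code{scale}, \code{section_id}, \code{origin} (section-frame
#'   coordinates of scape pixel (0, 0) at full resolution).
#' @export
render_montage_scape <- function(tileset, transforms, scale = 1) {
  if (length(tileset$tiles) == 0) stopf("empty tile set")
  if (scale <= 0 || scale > 1) stopf("scale must be in (0, 1]")
  corners <- NULL
  for (t in tileset$tiles) {
    d <- dim(t$raster)
    cs <- cbind(c(0, d[2] - 1, 0, d[2] - 1), c(0, 0, d[1] - 1, d[1] - 1))
    tf <- transforms[[t$tile_id]]
    if (is.null(tf)) stopf("no transform for tile '%s'", t$tile_id)
    corners <- rbind(corners, affine_apply(tf, cs))
  }
  o <- floor(apply(corners, 2, min))           # (x, y) origin, section px
  hi <- ceiling(apply(corners, 2, max))
  nc <- hi[1] - o[1] + 1; nr <- hi[2] - o[2] + 1
  acc <- matrix(0, nr, nc); wt <- matrix(0, nr, nc)
  for (t in tileset$tiles) {
    tf <- affine_compose(translate2d(-o), transforms[[t$tile_id]])
    cs <- affine_apply(tf, cbind(c(0, ncol(t$raster) - 1, 0, ncol(t$raster) - 1),
                                 c(0, 0, nrow(t$raster) - 1, nrow(t$raster) - 1)))
    x0 <- max(0, floor(min(cs[, 1]))); x1 <- min(nc - 1, ceiling(max(cs[, 1])))
    y0 <- max(0, floor(min(cs[, 2]))); y1 <- min(nr - 1, ceiling(max(cs[, 2])))
    if (x1 < x0 || y1 < y0) next
    xs <- rep(x0:x1, each = y1 - y0 + 1); ys <- rep(y0:y1, times = x1 - x0 + 1)
    src <- affine_apply(affine_invert(tf), cbind(xs, ys))
    v <- bilinear_sample(t$raster, src[, 1], src[, 2])
    ok <- !is.na(v)
    idx <- cbind(ys + 1, xs + 1)[ok, , drop = FALSE]
    acc[idx] <- acc[idx] + v[ok]
    wt[idx] <- wt[idx] + 1
  }
  covered <- wt > 0
  acc[covered] <- acc[covered] / wt[covered]
  if (scale < 1) {
    raster <- resize_raster(acc, scale)
    mask <- resize_raster(covered * 1, scale) > 0.5
  } else { raster <- acc; mask <- covered }
  structure(list(raster = raster, mask = mask, scale = scale,
                 section_id = tileset$section_id, origin = o),
            class = "montage_scape")
}

as_scape <- function(x, section_id = NA_integer_) {
  if (inherits(x, "montage_scape")) return(x)
  structure(list(raster = x, mask = matrix(TRUE, nrow(x), ncol(x)), scale = 1,
                 section_id = section_id, origin = c(0, 0)), class = "montage_scape")
}

#' Match two montage scapes by FFT cross-correlation over angles
#'
#' @param scape_a,scape_b \code{montage_scape} (or plain rasters) at the same
#'   scale.
#' @param angle_range half-range of rotation sweep, degrees.
#' @param angle_step sweep step, degrees.
#' @param corr_floor peak correlation below this flags the pair unmatched
#'   (sections likely non-adjacent).
#' @param prior expected (x, y) shift of B relative to A, scape px.
#' @param search_radius disc radius around the prior (default 30% of the
#'   scape size; consecutive sections are roughly in register, and small
#'   overlaps breed spurious correlation peaks).
#' @return list of class \code{layer_match}: \code{section_a}, \code{section_b},
#'   \code{angle}, \code{translation} (scape px), \code{correlation},
#'   \code{no_match}, \code{transform} (B scape frame -> A scape frame),
#'   \code{dim_b}.
#' @export
match_scapes <- function(scape_a, scape_b, angle_range = 4, angle_step = 1,
                         corr_floor = 0.1, prior = c(0, 0),
                         search_radius = NULL) {
  sa <- as_scape(scape_a); sb <- as_scape(scape_b)
  if (sa$scale != sb$scale) stopf("scapes must share a scale")
  if (is.null(search_radius)) search_radius <- 0.3 * min(dim(sa$raster))
  angles <- if (angle_range > 0) seq(-angle_range, angle_range, by = angle_step) else 0
  best <- list(correlation = -Inf)
  for (th in angles) {
    if (th == 0) { br <- sb$raster; mb <- sb$mask }
    else {
      w <- rotate_raster(sb$raster, th)
      wm <- rotate_raster(sb$mask * 1, th)
      br <- w$raster; mb <- w$mask & (wm$raster > 0.5)
    }
    pk <- fft_translation(sa$raster, br, mask_a = sa$mask, mask_b = mb,
                          prior = prior, radius = search_radius,
                          min_overlap = 0.25 * length(sa$raster), subpixel = TRUE)
    if (pk$correlation > best$correlation)
      best <- list(angle = th, translation = pk$translation, correlation = pk$correlation)
  }
  ctr <- c((ncol(sb$raster) - 1) / 2, (nrow(sb$raster) - 1) / 2)
  structure(list(section_a = sa$section_id, section_b = sb$section_id,
                 angle = best$angle, translation = best$translation,
                 correlation = best$correlation,
                 no_match = best$correlation < corr_floor,
                 transform = affine_compose(translate2d(best$translation),
                                            rigid2d(best$angle, c(0, 0), center = ctr)),
                 dim_b = dim(sb$raster)),
            class = "layer_match")
}

# Blob features + normalized patch descriptors on a scape raster.
scape_features <- function(scape, patch = 8L, n_max = 400L) {
  s <- as_scape(scape)
  kp <- detect_features(s$raster)
  if (nrow(kp) == 0) return(list(xy = matrix(numeric(0), 0, 2), desc = NULL))
  nr <- nrow(s$raster); ncl <- ncol(s$raster)
  ok <- kp$x >= patch & kp$x < ncl - patch & kp$y >= patch & kp$y < nr - patch
  kp <- kp[ok, , drop = FALSE]
  if (nrow(kp) > n_max) kp <- kp[order(-kp$response)[seq_len(n_max)], , drop = FALSE]
  if (nrow(kp) == 0) return(list(xy = matrix(numeric(0), 0, 2), desc = NULL))
  off <- as.matrix(expand.grid(dy = -patch:patch, dx = -patch:patch))
  D <- matrix(0, nrow(kp), nrow(off))
  for (i in seq_len(nrow(off)))
    D[, i] <- s$raster[cbind(kp$y + 1 + off[i, "dy"], kp$x + 1 + off[i, "dx"])]
  D <- D - rowMeans(D)
  nn <- sqrt(rowSums(D^2)); nn[nn < 1e-9] <- 1
  list(xy = cbind(kp$x, kp$y), desc = D / nn)
}

match_features <- function(fa, fb, ratio = 0.9) {
  if (nrow(fa$xy) == 0 || nrow(fb$xy) == 0)
    return(list(pa = matrix(numeric(0), 0, 2), pb = matrix(numeric(0), 0, 2)))
  S <- fa$desc %*% t(fb$desc)           # cosine similarity of unit patches
  bj <- max.col(S)                      # best b for each a
  bi <- max.col(t(S))                   # best a for each b
  keep <- which(bi[bj] == seq_len(nrow(S)))   # mutual best
  if (ncol(S) >= 2) {                   # ratio test on distances
    d1 <- sqrt(pmax(2 - 2 * S[cbind(keep, bj[keep])], 0))
    S2 <- S[keep, , drop = FALSE]
    S2[cbind(seq_along(keep), bj[keep])] <- -Inf
    d2 <- sqrt(pmax(2 - 2 * apply(S2, 1, max), 0))
    keep <- keep[d1 <= ratio * pmax(d2, 1e-9)]
  }
  list(pa = fa$xy[keep, , drop = FALSE], pb = fb$xy[bj[keep], , drop = FALSE])
}

count_correspondences_impl <- function(fa, fb, max_displacement, seed,
                                       id_a = "A", id_b = "B") {
  mm <- match_features(fa, fb)
  if (nrow(mm$pa) < 4) return(0L)
  ms <- point_match_set(id_a, id_b, mm$pa, mm$pb, provenance = "cross-section")
  kept <- filter_ransac(ms, model = "affine", max_displacement = max_displacement,
                        iterations = 100, min_inliers = 4, seed = seed)
  if (isTRUE(attr(kept, "rejected"))) 0L else n_matches(kept)
}

#' Count filtered point correspondences between two scapes
#'
#' Detects blob features with patch descriptors on both scapes, matches them
#' by descriptor similarity (mutual best + ratio test) and keeps the RANSAC
#' affine-consistent subset. The surviving count is the similarity surrogate
#' used for section ordering.
#'
#' @param scape_a,scape_b \code{montage_scape} or rasters at one scale.
#' @param max_displacement RANSAC inlier residual threshold, px.
#' @param seed integer seed (RANSAC sampling).
#' @return integer correspondence count.
#' @export
count_correspondences <- function(scape_a, scape_b, max_displacement = 8, seed = 1) {
  count_correspondences_impl(scape_features(scape_a), scape_features(scape_b),
                             max_displacement, seed)
}

#' Build the section similarity matrix
#'
#' Correspondence counts for all section pairs within \code{window} of each
#' other (the expected range of ordering mistakes).
#'
#' @param scapes list of \code{montage_scape} or rasters, in current stack order.
#' @param window maximum |i - j| examined.
#' @param max_displacement RANSAC threshold passed to the pair counter.
#' @param seed integer seed.
#' @return S x S integer matrix of class \code{similarity_matrix} with
#'   attribute \code{window}; symmetric, zero diagonal, zero beyond the window.
#' @export
build_similarity <- function(scapes, window, max_displacement = 8, seed = 1) {
  if (window < 1) stopf("window must be >= 1")
  S <- length(scapes)
  feats <- lapply(scapes, scape_features)
  M <- matrix(0L, S, S)
  for (i in seq_len(S - 1)) for (j in (i + 1):min(S, i + window)) {
    M[i, j] <- M[j, i] <- count_correspondences_impl(
      feats[[i]], feats[[j]], max_displacement, seed + 131L * i + j)
  }
  structure(M, window = as.integer(window), class = c("similarity_matrix", "matrix"))
}

# Hamiltonian-path distance: counts are an inverse-distance surrogate.
sim_to_dist <- function(sim, big = 10) {
  S <- nrow(sim); w <- attr(sim, "window"); if (is.null(w)) w <- S
  D <- matrix(big, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) if (i != j && abs(i - j) <= w)
    D[i, j] <- 1 / (sim[i, j] + 1)
  diag(D) <- 0
  D
}

path_cost <- function(D, ord) sum(D[cbind(ord[-length(ord)], ord[-1])])

# Held-Karp minimum Hamiltonian path (any endpoints), S <= 12.
exact_path <- function(D) {
  S <- nrow(D)
  full <- bitwShiftL(1L, S) - 1L
  cost <- matrix(Inf, full, S); from <- matrix(0L, full, S)
  for (j in seq_len(S)) cost[bitwShiftL(1L, j - 1L), j] <- 0
  sets <- order(vapply(seq_len(full), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(S - 1))) != 0), 0))
  for (m in sets) {
    for (j in seq_len(S)) {
      bj <- bitwShiftL(1L, j - 1L)
      if (!bitwAnd(m, bj)) next
      rest <- bitwAnd(m, bitwNot(bj))
      if (rest == 0L) next
      for (i in seq_len(S)) {
        bi <- bitwShiftL(1L, i - 1L)
        if (!bitwAnd(rest, bi) || is.infinite(cost[rest, i])) next
        cand <- cost[rest, i] + D[i, j]
        if (cand < cost[m, j]) { cost[m, j] <- cand; from[m, j] <- i }
      }
    }
  }
  jend <- which.min(cost[full, ])
  ord <- integer(S); m <- full; j <- jend
  for (k in S:1) {
    ord[k] <- j
    pj <- from[m, j]
    m <- bitwAnd(m, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  ord
}

two_opt <- function(D, ord) {
  S <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      left <- if (i > 1) D[ord[i - 1], ord[i]] else 0
      right <- if (j < S) D[ord[j], ord[j + 1]] else 0
      nleft <- if (i > 1) D[ord[i - 1], ord[j]] else 0
      nright <- if (j < S) D[ord[i], ord[j + 1]] else 0
      if (nleft + nright < left + right - 1e-12) {
        ord[i:j] <- rev(ord[i:j]); improved <- TRUE
      }
    }
  }
  ord
}

# Split a path at expensive (beyond-window) edges and exhaustively reassemble
# the fragments (with orientations); repairs rotations and stranded blocks
# that 2-opt segment reversals cannot reach.
reassemble_fragments <- function(D, ord, big = 0.5) {
  S <- length(ord)
  ec <- D[cbind(ord[-S], ord[-1])]
  cuts <- which(ec >= big)
  if (!length(cuts) || length(cuts) > 5) return(ord)
  bounds <- c(0, cuts, S)
  frags <- lapply(seq_len(length(bounds) - 1),
                  function(i) ord[(bounds[i] + 1):bounds[i + 1]])
  f <- length(frags)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- ord; bestc <- path_cost(D, ord)
  for (p in perms(seq_len(f))) {
    for (mask in 0:(2^f - 1)) {
      cand <- unlist(lapply(seq_len(f), function(i) {
        fr <- frags[[p[i]]]
        if (bitwAnd(mask, bitwShiftL(1L, i - 1L))) rev(fr) else fr
      }))
      cc <- path_cost(D, cand)
      if (cc < bestc) { bestc <- cc; best <- cand }
    }
  }
  best
}

greedy_path <- function(D) {
  S <- nrow(D)
  best <- NULL; bestc <- Inf
  for (s in seq_len(S)) {
    ord <- s; left <- setdiff(seq_len(S), s)
    while (length(left)) {
      nxt <- left[which.min(D[ord[length(ord)], left])]
      ord <- c(ord, nxt); left <- setdiff(left, nxt)
    }
    cc <- path_cost(D, ord)
    if (cc < bestc) { bestc <- cc; best <- ord }
  }
  ord <- two_opt(D, best)
  ord <- reassemble_fragments(D, ord)
  two_opt(D, ord)
}

#' Recover the true section order from a similarity matrix
#'
#' Treats \code{1/(count+1)} as a distance surrogate and finds the shortest
#' Hamiltonian path visiting all sections (exact dynamic programming for
#' S <= 12, otherwise greedy nearest-neighbor followed by 2-opt). The
#' reversal ambiguity of a shortest path is resolved toward the input order
#' (larger Kendall correlation with 1..S).
#'
#' @param sim \code{similarity_matrix} (or symmetric count matrix).
#' @param method \code{"auto"}, \code{"exact"} or \code{"greedy_2opt"}.
#' @return integer permutation: position k gives the index (in the input
#'   stack) of the k-th section in recovered order.
#' @export
correct_section_order <- function(sim, method = c("auto", "exact", "greedy_2opt")) {
  method <- match.arg(method)
  if (!isSymmetric(unclass(unname(sim)))) stopf("similarity matrix must be symmetric")
  S <- nrow(sim)
  # connectivity over positive-count edges
  comp <- local({
    lab <- seq_len(S)
    repeat {
      ch <- FALSE
      for (i in seq_len(S)) for (j in seq_len(S)) if (sim[i, j] > 0 && lab[j] != lab[i]) {
        l <- min(lab[i], lab[j]); lab[lab == lab[i] | lab == lab[j]] <- l; ch <- TRUE
      }
      if (!ch) break
    }
    lab
  })
  if (length(unique(comp)) > 1L)
    stopf("similarity graph is disconnected; components: %s",
          paste(vapply(split(seq_len(S), comp), function(x) paste(x, collapse = ","), ""),
                collapse = " | "))
  if (method == "auto") method <- if (S <= 12) "exact" else "greedy_2opt"
  if (method == "exact" && S > 12) stopf("exact method limited to S <= 12")
  D <- sim_to_dist(sim)
  ord <- if (method == "exact") exact_path(D) else greedy_path(D)
  if (cor(ord, seq_len(S), method = "kendall") <
      cor(rev(ord), seq_len(S), method = "kendall")) ord <- rev(ord)
  ord
}

#' Rough per-section alignment from chained layer matches
#'
#' Turns each consecutive-pair scape match into dense synthetic point pairs
#' and solves the regularized affine system with the first section anchored to
#' identity; the regularization target is the composed rigid chain.
#'
#' @param layer_matches list of \code{layer_match} linking sections k-1, k in
#'   corrected order (element k-1 links k-1 to k).
#' @param lambda_reg regularization weight (default \code{1e-3 * n_points}).
#' @return named list of per-section \code{affine2d} ("s1".."sS"), scape frame.
#' @export
rough_align <- function(layer_matches, lambda_reg = NULL) {
  S <- length(layer_matches) + 1L
  ids <- paste0("s", seq_len(S))
  priors <- vector("list", S); priors[[1]] <- affine2d()
  match_sets <- vector("list", S - 1L)
  for (k in 2:S) {
    lm <- layer_matches[[k - 1L]]
    if (is.null(lm) || isTRUE(lm$no_match))
      stopf("alignment chain broken between sections %d and %d", k - 1L, k)
    M <- lm$transform
    priors[[k]] <- affine_compose(priors[[k - 1L]], M)
    gx <- seq(0, lm$dim_b[2] - 1, length.out = 4)
    gy <- seq(0, lm$dim_b[1] - 1, length.out = 4)
    pb <- as.matrix(expand.grid(x = gx, y = gy))
    match_sets[[k - 1L]] <- point_match_set(ids[k - 1L], ids[k],
                                            affine_apply(M, pb), pb,
                                            provenance = "cross-section")
  }
  names(priors) <- ids
  solve_affine_system(match_sets, priors, lambda_reg, anchor = "s1",
                      warn_disconnected = FALSE)
}

#' Block matching between two roughly aligned sections
#'
#' Subdivides the common frame into a grid of blocks and finds each block's
#' best translation from section A to section B by masked FFT
#' cross-correlation; low-correlation and featureless blocks are dropped.
#'
#' @param section_a,section_b rasters rendered into a common (rough-aligned)
#'   frame, same size.
#' @param block_grid (rows, cols) of the block array.
#' @param max_displacement search disc radius, px.
#' @param corr_floor blocks with peak correlation below this are dropped.
#' @param mask_a,mask_b optional coverage masks.
#' @return \code{point_match_set} (cross-section) in the common frame:
#'   \code{pa} block centers in A, \code{pb} matched positions in B.
#' @export
block_match <- function(section_a, section_b, block_grid = c(4, 4),
                        max_displacement = 20, corr_floor = 0.3,
                        mask_a = NULL, mask_b = NULL) {
  a <- as_raster(section_a); b <- as_raster(section_b)
  if (!all(dim(a) == dim(b))) stopf("sections must share the common frame size")
  ny <- block_grid[1]; nx <- block_grid[2]
  ybr <- round(seq(0, nrow(a), length.out = ny + 1))
  xbr <- round(seq(0, ncol(a), length.out = nx + 1))
  pa <- NULL; pb <- NULL; wts <- NULL
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    rs <- (ybr[iy] + 1):ybr[iy + 1]; cs <- (xbr[ix] + 1):xbr[ix + 1]
    blk_a <- a[rs, cs, drop = FALSE]; blk_b <- b[rs, cs, drop = FALSE]
    if (sd(blk_a) < 1e-6 || sd(blk_b) < 1e-6) next   # featureless block
    ma <- if (is.null(mask_a)) NULL else mask_a[rs, cs, drop = FALSE]
    mb <- if (is.null(mask_b)) NULL else mask_b[rs, cs, drop = FALSE]
    pk <- fft_translation(blk_b, blk_a, prior = c(0, 0), radius = max_displacement,
                          mask_a = mb, mask_b = ma,
                          min_overlap = 0.25 * length(blk_a), subpixel = TRUE)
    if (pk$correlation < corr_floor) next
    cen <- c(mean(range(cs)) - 1, mean(range(rs)) - 1)   # (x, y), 0-based
    pa <- rbind(pa, cen)
    pb <- rbind(pb, cen + pk$translation)
    wts <- c(wts, pk$correlation)
  }
  if (is.null(pa)) pa <- pb <- matrix(numeric(0), 0, 2)
  point_match_set("A", "B", pa, pb, weights = wts, provenance = "cross-section")
}

#' Re-express section-frame matches in tile-local coordinates
#'
#' Cross-section matches are produced in section (or common) frames; the
#' global solver works on tiles. Each match point is assigned to the first
#' tile whose footprint contains it and mapped through the inverse tile
#' transform.
#'
#' @param ms \code{point_match_set} with \code{pa} in section-A frame and
#'   \code{pb} in section-B frame.
#' @param tileset_a,tileset_b \code{em_tileset}.
#' @param transforms_a,transforms_b per-tile \code{affine2d} (tile -> section
#'   frame used by \code{ms}).
#' @return list of tile-level \code{point_match_set} (cross-section).
#' @export
section_matches_to_tiles <- function(ms, tileset_a, transforms_a,
                                     tileset_b, transforms_b) {
  locate <- function(p, tileset, transforms) {
    for (t in tileset$tiles) {
      q <- affine_apply(affine_invert(transforms[[t$tile_id]]), p)
      if (q[1] >= 0 && q[1] <= ncol(t$raster) - 1 &&
          q[2] >= 0 && q[2] <= nrow(t$raster) - 1)
        return(list(id = t$tile_id, q = q))
    }
    NULL
  }
  buckets <- list()
  for (i in seq_len(n_matches(ms))) {
    la <- locate(ms$pa[i, ], tileset_a, transforms_a)
    lb <- locate(ms$pb[i, ], tileset_b, transforms_b)
    if (is.null(la) || is.null(lb)) next
    key <- paste(la$id, lb$id, sep = "~")
    buckets[[key]] <- rbind(buckets[[key]], c(la$q, lb$q, ms$weights[i]))
  }
  out <- list()
  for (key in names(buckets)) {
    ids <- strsplit(key, "~", fixed = TRUE)[[1]]
    m <- buckets[[key]]
    out[[key]] <- point_match_set(ids[1], ids[2], m[, 1:2, drop = FALSE],
                                  m[, 3:4, drop = FALSE], weights = m[, 5],
                                  provenance = "cross-section")
  }
  unname(out)
}

# Render a section's tiles into the global frame under given transforms.
render_section_global <- function(tileset, transforms, dim_out) {
  acc <- matrix(0, dim_out[1], dim_out[2]); wt <- matrix(0, dim_out[1], dim_out[2])
  for (t in tileset$tiles) {
    w <- warp_affine(t$raster, transforms[[t$tile_id]], out_dim = dim_out)
    acc <- acc + w$raster * w$mask
    wt <- wt + w$mask
  }
  covered <- wt > 0
  acc[covered] <- acc[covered] / wt[covered]
  list(raster = acc, mask = covered)
}

#' Align an ordered stack of tiled sections into a volume
#'
#' The full cross-section pipeline on top of per-section stitching: montage
#' scapes are matched consecutively (FFT over angles) and chained into a
#' rough per-section alignment; each pass then renders sections into the
#' common frame under the current solution, block-matches consecutive
#' sections, maps the matches into tile-local coordinates and re-solves the
#' global regularized system (intra- and cross-section matches together).
#'
#' @param tilesets list of \code{em_tileset}, one per section, in corrected
#'   order. Tile ids must be unique across sections.
#' @param stitch list of per-section results from \code{\link{stitch_section}}
#'   (computed if NULL).
#' @param angle_range,angle_step scape rotation sweep (deg).
#' @param block_grid block array for cross-section matching.
#' @param max_displacement block search radius, px.
#' @param passes number of block-match/solve refinement passes (default 2).
#' @param lambda_reg regularization of the global solve.
#' @param cross_weight weight multiplier for cross-section matches.
#' @return list with \code{transforms} (per-tile global \code{affine2d}),
#'   \code{rough} (per-section scape-frame transforms), \code{intra},
#'   \code{cross} (last pass), \code{canvas} (global frame (rows, cols)).
#' @export
align_stack <- function(tilesets, stitch = NULL, angle_range = 4,
                        angle_step = 0.25, block_grid = c(5, 5),
                        max_displacement = 10, passes = 2,
                        lambda_reg = NULL, cross_weight = 1) {
  S <- length(tilesets)
  if (S < 2) stopf("need at least two sections")
  if (is.null(stitch)) stitch <- lapply(tilesets, stitch_section)
  montage_tf <- lapply(stitch, `[[`, "transforms")
  intra <- do.call(c, lapply(stitch, `[[`, "match_sets"))
  scapes <- lapply(seq_len(S), function(k)
    render_montage_scape(tilesets[[k]], montage_tf[[k]], 1))
  lms <- lapply(2:S, function(k)
    match_scapes(scapes[[k - 1]], scapes[[k]], angle_range = angle_range,
                 angle_step = angle_step))
  ra <- rough_align(lms)
  sec_to_global <- lapply(seq_len(S), function(k)
    affine_compose(ra[[k]], translate2d(-scapes[[k]]$origin)))
  current <- list()
  for (k in seq_len(S)) for (id in names(montage_tf[[k]]))
    current[[id]] <- affine_compose(sec_to_global[[k]], montage_tf[[k]][[id]])
  tile_dim <- dim(tilesets[[1]]$tiles[[1]]$raster)
  # global canvas bounding box
  lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
  for (k in seq_len(S)) for (t in tilesets[[k]]$tiles) {
    cs <- affine_apply(current[[t$tile_id]],
                       cbind(c(0, ncol(t$raster) - 1, 0, ncol(t$raster) - 1),
                             c(0, 0, nrow(t$raster) - 1, nrow(t$raster) - 1)))
    lo <- pmin(lo, apply(cs, 2, min)); hi <- pmax(hi, apply(cs, 2, max))
  }
  off <- floor(lo) - 2
  dim_out <- c(ceiling(hi[2] - off[2]) + 4, ceiling(hi[1] - off[1]) + 4)
  shift <- translate2d(-off)
  current <- lapply(current, function(tf) affine_compose(shift, tf))
  cross <- list()
  for (pass in seq_len(passes)) {
    cross <- list()
    rendered <- lapply(seq_len(S), function(k)
      render_section_global(tilesets[[k]], current, dim_out))
    for (k in 2:S) {
      bm <- block_match(rendered[[k - 1]]$raster, rendered[[k]]$raster,
                        block_grid = block_grid,
                        max_displacement = max_displacement,
                        mask_a = rendered[[k - 1]]$mask,
                        mask_b = rendered[[k]]$mask)
      cross <- c(cross, section_matches_to_tiles(
        bm, tilesets[[k - 1]], current[names(montage_tf[[k - 1]])],
        tilesets[[k]], current[names(montage_tf[[k]])]))
    }
    current <- solve_volume(intra, cross, current, lambda_reg = lambda_reg,
                            cross_weight = cross_weight,
                            linear_weight = sum(tile_dim^2))
  }
  list(transforms = current, rough = ra, intra = intra, cross = cross,
       canvas = dim_out)
}
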