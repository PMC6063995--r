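# Synthetic test data with complete ground truth -----------------------------
#
# Emulates the study conditions every solver is validated against: a
# tissue-like textured volume (Voronoi cells with darker membrane sheets),
# sectioned/permuted/warped/tiled image sets, and branching skeletons. All
# generators are bit-deterministic for a given seed.

#' Generate a tissue-like textured volume
#'
#' A 3D Voronoi tessellation: bright cell interiors (with small per-cell
#' brightness variation) separated by darker membrane sheets about
#' \code{membrane_thickness} in-plane voxels thick, plus band-limited
#' (Gaussian-smoothed) texture noise. Membrane voxels are recorded in a mask,
#' so mask-driven line sampling and SNR ground truth are available.
#'
#' @param shape (nx, ny, nz) voxels, all >= 16. The raster of slice k is
#'   \code{shape[2]} rows x \code{shape[1]} cols.
#' @param cell_diameter nominal cell size, nm (must exceed 2 in-plane voxels).
#' @param membrane_contrast gray-level drop of membranes vs interiors (>= 0).
#' @param seed integer seed.
#' @param voxel_size (x, y, z) nm per voxel (default 4, 4, 40).
#' @param base_gray mean interior gray (default 160).
#' @param texture_sd band-limited texture amplitude, gray (default 5).
#' @param cell_gray_sd per-cell brightness variation, gray (default 3).
#' @param membrane_thickness nominal sheet thickness, in-plane voxels
#'   (default 2).
#' @param texture_scale correlation length (Gaussian sigma, px) of the
#'   band-limited texture (default 3): texture lives below the noise band, so
#'   added pixel noise is the only high-frequency content, as the SNR
#'   estimators assume.
#' @param organelles_per_cell mean number of dark spherical organelles
#'   (mitochondria/vesicle clusters) per cell (default 1; 0 disables them).
#'   Organelles are the blob-like structures that feature detection keys on.
#' @param organelle_diameter diameter range, nm (default 80-240,
#'   mitochondrion/bouton scale: interiors stay dark under modest voxel
#'   combination).
#' @param organelle_contrast gray-level drop of organelles (default
#'   0.6 x membrane_contrast).
#' @return object of class \code{tissue_volume}: \code{voxels} (3D array
#'   indexed [row=y, col=x, z], float in [0,255]), \code{membrane_mask},
#'   \code{organelle_mask}, \code{voxel_size}, \code{seed}.
#' @export
generate_tissue_volume <- function(shape, cell_diameter, membrane_contrast, seed,
                                   voxel_size = c(4, 4, 40), base_gray = 160,
                                   texture_sd = 5, cell_gray_sd = 3,
                                   membrane_thickness = 2,
                                   texture_scale = 3,
                                   organelles_per_cell = 1,
                                   organelle_diameter = c(80, 240),
                                   organelle_contrast = 0.6 * membrane_contrast) {
  if (length(shape) != 3 || any(shape < 16)) stopf("shape must be 3 dims, all >= 16")
  if (any(shape <= 0) || membrane_contrast < 0) stopf("invalid shape or contrast")
  if (cell_diameter <= 2 * voxel_size[1]) stopf("cell_diameter must exceed 2 in-plane voxels")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ext <- shape * voxel_size               # physical extent, nm
  n_cells <- max(2L, round(prod(ext) / cell_diameter^3))
  with_seed(seed, {
    centers <- cbind(runif(n_cells, 0, ext[1]), runif(n_cells, 0, ext[2]),
                     runif(n_cells, 0, ext[3]))
    cell_gray <- base_gray + rnorm(n_cells, 0, cell_gray_sd)
    # organelles arrive in clusters (vesicle clouds / boutons): cluster
    # centers are uniform, members scatter around them
    n_clus <- max(1L, round(organelles_per_cell * n_cells / 3))
    n_org <- 0L
    org_c <- matrix(numeric(0), 0, 3)
    if (organelles_per_cell > 0) {
      cl <- cbind(runif(n_clus, 0, ext[1]), runif(n_clus, 0, ext[2]),
                  runif(n_clus, 0, ext[3]))
      sizes <- 1L + stats::rpois(n_clus, 2)
      org_c <- do.call(rbind, lapply(seq_len(n_clus), function(i)
        sweep(matrix(rnorm(sizes[i] * 3, 0, 100), ncol = 3), 2, cl[i, ], `+`)))
      n_org <- nrow(org_c)
    }
    org_r <- if (n_org > 0) runif(n_org, organelle_diameter[1] / 2,
                                  organelle_diameter[2] / 2) else numeric(0)
    vox <- array(0, c(ny, nx, nz))
    mem <- array(FALSE, c(ny, nx, nz))
    org <- array(FALSE, c(ny, nx, nz))
    thr <- membrane_thickness * voxel_size[1]
    xs <- (seq_len(nx) - 1) * voxel_size[1]
    ys <- (seq_len(ny) - 1) * voxel_size[2]
    blk <- 128L
    # texture / staining fields are continuous across sections (AR(1) along z
    # with unchanged N(0,1) marginals): features persist between neighboring
    # sections as they do in real tissue
    rho <- 0.85
    tex_f <- NULL; bump_f <- NULL; gran_f <- NULL
    evolve <- function(prev) {
      new <- matrix(rnorm(ny * nx), ny, nx)
      if (is.null(prev)) new else rho * prev + sqrt(1 - rho^2) * new
    }
    for (k in seq_len(nz)) {
      zc <- (k - 1) * voxel_size[3]
      dz2 <- (centers[, 3] - zc)^2
      slice_val <- matrix(0, ny, nx); slice_mem <- matrix(FALSE, ny, nx)
      for (bx in seq(1, nx, by = blk)) for (by in seq(1, ny, by = blk)) {
        ix <- bx:min(nx, bx + blk - 1L); iy <- by:min(ny, by + blk - 1L)
        margin <- 1.5 * cell_diameter
        cand <- which(centers[, 1] > xs[ix[1]] - margin & centers[, 1] < xs[ix[length(ix)]] + margin &
                        centers[, 2] > ys[iy[1]] - margin & centers[, 2] < ys[iy[length(iy)]] + margin)
        if (length(cand) < 2) cand <- seq_len(n_cells)
        X <- matrix(xs[ix], length(iy), length(ix), byrow = TRUE)
        Y <- matrix(ys[iy], length(iy), length(ix))
        d1 <- matrix(Inf, length(iy), length(ix)); d2 <- d1; w1 <- matrix(1L, length(iy), length(ix))
        for (ci in cand) {
          d <- (X - centers[ci, 1])^2 + (Y - centers[ci, 2])^2 + dz2[ci]
          d2 <- pmin(d2, pmax(d, d1))   # runner-up: the larger of (d, old best)
          w1[d < d1] <- ci
          d1 <- pmin(d1, d)
        }
        g <- sqrt(d2) - sqrt(d1)
        slice_mem[iy, ix] <- g < thr
        slice_val[iy, ix] <- matrix(cell_gray[w1], length(iy), length(ix))
      }
      slice_org <- matrix(FALSE, ny, nx)
      if (n_org > 0) {
        hit <- which(abs(org_c[, 3] - zc) < org_r)
        for (oi in hit) {
          rin <- sqrt(org_r[oi]^2 - (org_c[oi, 3] - zc)^2)   # in-plane radius, nm
          jx <- which(abs(xs - org_c[oi, 1]) <= rin)
          jy <- which(abs(ys - org_c[oi, 2]) <= rin)
          if (!length(jx) || !length(jy)) next
          DX2 <- outer(rep(1, length(jy)), (xs[jx] - org_c[oi, 1])^2)
          DY2 <- outer((ys[jy] - org_c[oi, 2])^2, rep(1, length(jx)))
          slice_org[jy, jx] <- slice_org[jy, jx] | (DX2 + DY2 <= rin^2)
        }
      }
      tex_f <- evolve(tex_f)
      tex <- gauss_blur(tex_f, texture_scale)
      tex <- tex * (texture_sd / max(sd(tex), 1e-9))
      # staining bumpiness along membranes (real sheets are not uniformly
      # dark); mean modulation is 1 so mask-wise contrast is preserved
      bump_f <- evolve(bump_f)
      bump <- gauss_blur(bump_f, 3)
      bump <- 1 + 0.3 * bump / max(sd(bump), 1e-9)
      # cristae-like internal granularity: organelles are the most
      # feature-dense objects in EM micrographs
      gran_f <- evolve(gran_f)
      gran <- gauss_blur(gran_f, 4)
      gran <- 1 + 0.5 * gran / max(sd(gran), 1e-9)
      v <- slice_val - membrane_contrast * slice_mem * pmax(bump, 0.1) -
        organelle_contrast * (slice_org & !slice_mem) * pmax(gran, 0.1) + tex
      vox[, , k] <- pmin(pmax(v, 0), 255)
      mem[, , k] <- slice_mem
      org[, , k] <- slice_org
    }
    structure(list(voxels = vox, membrane_mask = mem, organelle_mask = org,
                   voxel_size = as.numeric(voxel_size), seed = as.integer(seed)),
              class = "tissue_volume")
  })
}

#' @export
print.tissue_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tissue_volume> %dx%dx%d voxels (%g x %g x %g nm), %.1f%% membrane\n",
              d[2], d[1], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              100 * mean(x$membrane_mask)))
  invisible(x)
}

#' Extract one z-slice of a tissue volume
#' @param volume \code{tissue_volume}.
#' @param z 1-based slice index.
#' @return list with \code{raster} and logical \code{membrane_mask}.
#' @export
volume_slice <- function(volume, z) {
  list(raster = volume$voxels[, , z], membrane_mask = volume$membrane_mask[, , z])
}

#' Cut a volume into a (possibly misordered, jittered) section stack
#'
#' Consecutive z-slices are each warped by a random rigid jitter (rotation and
#' shift within the given bounds, uniform), then re-indexed by a permutation —
#' the misordered-series failure mode that section-order correction must
#' repair. Ground truth records the permutation and every transform.
#'
#' @param volume \code{tissue_volume}.
#' @param n_sections number of sections (<= z extent).
#' @param order_permutation \code{"random"}, or an integer permutation p such
#'   that stack position i holds source slice p[i].
#' @param per_section_jitter c(max rotation deg, max shift px).
#' @param seed integer seed.
#' @return list with \code{sections} (list of rasters, stack order) and
#'   \code{ground_truth} (\code{true_order}, \code{true_section_transforms}
#'   indexed by source slice, \code{jitter}).
#' @export
make_section_stack <- function(volume, n_sections, order_permutation = "random",
                               per_section_jitter = c(0, 0), seed = 1) {
  nz <- dim(volume$voxels)[3]
  if (n_sections > nz) stopf("n_sections exceeds volume z extent")
  with_seed(seed, {
    if (identical(order_permutation, "random")) {
      perm <- sample.int(n_sections)
    } else {
      perm <- as.integer(order_permutation)
      if (!identical(sort(perm), seq_len(n_sections)))
        stopf("order_permutation is not a bijection on 1..%d", n_sections)
    }
    maxrot <- per_section_jitter[1]; maxshift <- per_section_jitter[2]
    warped <- vector("list", n_sections)
    tfs <- vector("list", n_sections)
    for (k in seq_len(n_sections)) {
      sl <- volume$voxels[, , k]
      rot <- if (maxrot > 0) runif(1, -maxrot, maxrot) else 0
      sh <- if (maxshift > 0) runif(2, -maxshift, maxshift) else c(0, 0)
      ctr <- c((ncol(sl) - 1) / 2, (nrow(sl) - 1) / 2)
      tf <- rigid2d(rot, sh, center = ctr)
      tfs[[k]] <- tf
      warped[[k]] <- if (rot == 0 && all(sh == 0)) sl
                     else warp_affine(sl, tf, fill = mean(sl))$raster
    }
    list(sections = warped[perm],
         ground_truth = list(true_order = perm, true_section_transforms = tfs,
                             jitter = per_section_jitter))
  })
}

#' Cut a section into an overlapping tile grid with acquisition artifacts
#'
#' Crops a regular grid of overlapping tiles; recorded stage coordinates are
#' the true positions plus bounded uniform jitter (the stitching priors);
#' per-tile additive gray offsets and i.i.d. Gaussian noise emulate
#' camera/beam variation; selected tiles are degraded (precipitate, fold, or
#' blank) so that they satisfy the artifact-classifier rules by construction.
#'
#' @param section numeric matrix.
#' @param tile_shape tile side in px (scalar or c(rows, cols)).
#' @param overlap overlap fraction between neighboring tiles, in (0, 0.5).
#' @param stage_jitter_px max |recorded - true| stage error, px.
#' @param intensity_offsets per-tile additive gray offsets, or \code{"random"}
#'   (uniform in +-15).
#' @param noise_sigma Gaussian pixel noise sd, gray.
#' @param degrade list of \code{list(index, mode)} with mode one of
#'   \code{"precipitate"}, \code{"fold"}, \code{"blank"}.
#' @param seed integer seed.
#' @param section_id section id stored on the tiles (default 0).
#' @param pixel_size nm per px (default 4).
#' @return list with \code{tileset} (\code{em_tileset}) and
#'   \code{ground_truth} (\code{true_tile_transforms},
#'   \code{true_intensity_offsets}, \code{noise_sigma}, \code{degraded}).
#' @export
make_tile_set <- function(section, tile_shape, overlap = 0.1, stage_jitter_px = 0,
                          intensity_offsets = "random", noise_sigma = 0,
                          degrade = list(), seed = 1, section_id = 0L,
                          pixel_size = 4) {
  if (overlap <= 0 || overlap >= 0.5) stopf("overlap must be in (0, 0.5)")
  th <- if (length(tile_shape) == 1) c(tile_shape, tile_shape) else tile_shape
  if (th[1] >= nrow(section) || th[2] >= ncol(section))
    stopf("tile_shape must be smaller than the section")
  starts <- function(extent, tl) {
    step <- tl * (1 - overlap)
    n <- max(2L, round((extent - tl) / step) + 1L)
    round(seq(0L, extent - tl, length.out = n))
  }
  ys <- starts(nrow(section), th[1]); xs <- starts(ncol(section), th[2])
  with_seed(seed, {
    tiles <- list(); truth <- list(); offsets <- numeric(0); degraded <- character(0)
    idx <- 0L
    modes <- setNames(vapply(degrade, function(d) d[[2]], ""),
                      vapply(degrade, function(d) as.character(d[[1]]), ""))
    for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
      idx <- idx + 1L
      y0 <- ys[iy]; x0 <- xs[ix]
      ras <- section[(y0 + 1):(y0 + th[1]), (x0 + 1):(x0 + th[2]), drop = FALSE]
      off <- if (identical(intensity_offsets, "random")) runif(1, -15, 15)
             else intensity_offsets[idx]
      ras <- ras + off
      if (noise_sigma > 0) ras <- ras + matrix(rnorm(length(ras), 0, noise_sigma),
                                               nrow(ras), ncol(ras))
      mode <- modes[as.character(idx)]
      if (!is.na(mode)) {
        ras <- degrade_tile(ras, mode)
        degraded <- c(degraded, sprintf("t%03d", idx))
      }
      jit <- if (stage_jitter_px > 0) runif(2, -stage_jitter_px, stage_jitter_px)
             else c(0, 0)
      id <- sprintf("t%03d", idx)
      tiles[[id]] <- em_tile(pmin(pmax(ras, 0), 255), id, section_id,
                             stage_xy = (c(x0, y0) + jit) * pixel_size,
                             pixel_size = pixel_size)
      truth[[id]] <- translate2d(c(x0, y0))
      offsets <- c(offsets, off)
    }
    list(tileset = em_tileset(tiles, section_id),
         ground_truth = list(true_tile_transforms = truth,
                             true_intensity_offsets = setNames(offsets, names(truth)),
                             noise_sigma = noise_sigma, degraded = degraded,
                             tile_dim = th))
  })
}

# Degradation modes tuned to satisfy the tile-QC rules with certainty:
# precipitate/fold drive the gray sd above 40; blank drives sd below 20 and
# mean below 50. Draws from the surrounding seeded stream.
degrade_tile <- function(ras, mode) {
  nr <- nrow(ras); nc <- ncol(ras)
  if (mode == "blank") {
    out <- matrix(30 + rnorm(nr * nc, 0, 3), nr, nc)
    return(pmin(pmax(out, 0), 49))
  }
  if (mode == "precipitate") {
    out <- ras
    repeat {
      for (i in 1:6) {
        cx <- runif(1, 0, nc - 1); cy <- runif(1, 0, nr - 1)
        r <- runif(1, 0.1, 0.2) * min(nr, nc)
        X <- matrix(0:(nc - 1), nr, nc, byrow = TRUE); Y <- matrix(0:(nr - 1), nr, nc)
        out[(X - cx)^2 + (Y - cy)^2 <= r^2] <- 0
      }
      if (sd(out) > 41) return(out)
    }
  }
  if (mode == "fold") {
    out <- ras
    w <- 0.2
    repeat {
      x0 <- floor(nc * runif(1, 0.2, 0.6)); x1 <- min(nc, x0 + ceiling(w * nc))
      out[, x0:x1] <- 5
      if (sd(out) > 41) return(out)
      w <- w + 0.1
    }
  }
  stopf("unknown degrade mode '%s'", mode)
}

#' Generate a random branching skeleton
#'
#' A correlated-random-walk trunk with side branches, node spacing about
#' \code{segment_length}, confined to the given extent; coordinates are
#' rounded to 0.01 nm so SWC round trips are bit-identical.
#'
#' @param n_branches total branches including the trunk (>= 1; 1 = plain path).
#' @param segment_length step length, nm.
#' @param extent (x, y, z) bounding extent, nm.
#' @param seed integer seed.
#' @param radius node radius, nm (default 40).
#' @param tortuosity per-step direction perturbation (sd of the Gaussian added
#'   to the unit direction; default 0.35 = visibly wiggly, ~0.1 = neurite-like
#'   persistence over microns).
#' @return \code{skeleton}.
#' @export
make_synthetic_skeleton <- function(n_branches, segment_length, extent, seed,
                                    radius = 40, tortuosity = 0.35) {
  if (n_branches < 1) stopf("n_branches must be >= 1")
  check_number(segment_length, "segment_length", positive = TRUE)
  extent <- as.numeric(extent)
  with_seed(seed, {
    walk <- function(start, n_steps, dir0) {
      pos <- matrix(0, n_steps + 1, 3); pos[1, ] <- start
      dir <- dir0 / sqrt(sum(dir0^2))
      for (i in seq_len(n_steps)) {
        dir <- dir + tortuosity * rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        nxt <- pos[i, ] + dir * segment_length
        for (k in 1:3) {
          if (nxt[k] < 0) { nxt[k] <- -nxt[k]; dir[k] <- -dir[k] }
          if (nxt[k] > extent[k]) { nxt[k] <- 2 * extent[k] - nxt[k]; dir[k] <- -dir[k] }
        }
        pos[i + 1, ] <- nxt
      }
      pos
    }
    n_trunk <- max(10L, round(0.8 * max(extent) / segment_length))
    trunk <- walk(extent / 2, n_trunk, rnorm(3))
    ids <- seq_len(nrow(trunk)); parents <- c(-1L, ids[-length(ids)])
    coords <- trunk
    if (n_branches > 1) {
      for (b in seq_len(n_branches - 1L)) {
        at <- sample(2:(nrow(trunk) - 1), 1)
        n_b <- max(3L, round(n_trunk * runif(1, 0.25, 0.5)))
        br <- walk(trunk[at, ], n_b, rnorm(3))[-1, , drop = FALSE]
        new_ids <- length(ids) + seq_len(nrow(br))
        parents <- c(parents, at, new_ids[-length(new_ids)])
        ids <- c(ids, new_ids)
        coords <- rbind(coords, br)
      }
    }
    skeleton(data.frame(id = ids, type = 0, x = round(coords[, 1], 2),
                        y = round(coords[, 2], 2), z = round(coords[, 3], 2),
                        radius = radius, parent = parents))
  })
}
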