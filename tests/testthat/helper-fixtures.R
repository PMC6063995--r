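# Shared fixtures, built lazily once per test run and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# small tissue volume used across modules
fix_volume <- function() fixture("vol", function()
  generate_tissue_volume(c(160, 160, 16), cell_diameter = 200,
                         membrane_contrast = 60, seed = 101))

# one clean slice and a noisy copy
fix_slice <- function() fixture("slice", function() volume_slice(fix_volume(), 8))
fix_noisy <- function() fixture("noisy", function()
  add_gaussian_noise(fix_slice()$raster, 5, seed = 202))

# a small branching skeleton
fix_skel <- function() fixture("skel", function()
  make_synthetic_skeleton(4, 500, c(40000, 40000, 20000), seed = 7))

# random permutation with k disjoint adjacent swaps planted
plant_swaps <- function(S, k, seed) {
  emrecon:::with_seed(seed, {
    p <- seq_len(S)
    pos <- sample(seq_len(S - 1)); chosen <- integer(0)
    for (i in pos) {
      if (any(abs(chosen - i) <= 1)) next
      chosen <- c(chosen, i)
      if (length(chosen) == k) break
    }
    for (i in chosen) p[c(i, i + 1)] <- p[c(i + 1, i)]
    p
  })
}

# dense least-squares oracle for the regularized affine solve: builds the full
# design including the weighted prior rows and solves by QR. Independent of
# the package's sparse normal-equation path.
dense_affine_oracle <- function(match_sets, priors, lambda_reg, linear_weight = 1) {
  ids <- names(priors)
  nt <- length(ids)
  solve_axis <- function(axis) {   # axis 1 = x coefficients, 2 = y
    rows <- list(); rhs <- c()
    for (ms in match_sets) {
      if (nrow(ms$pa) == 0) next
      ia <- match(ms$tile_id_a, ids); ib <- match(ms$tile_id_b, ids)
      for (r in seq_len(nrow(ms$pa))) {
        row <- numeric(3 * nt)
        sw <- sqrt(ms$weights[r])
        row[(ia - 1) * 3 + 1:3] <- sw * c(ms$pa[r, ], 1)
        row[(ib - 1) * 3 + 1:3] <- -sw * c(ms$pb[r, ], 1)
        rows[[length(rows) + 1]] <- row
        rhs <- c(rhs, 0)
      }
    }
    for (i in seq_len(nt)) {
      p <- priors[[i]]$m[axis, ]
      for (k in 1:3) {
        row <- numeric(3 * nt)
        w <- sqrt(lambda_reg * if (k < 3) linear_weight else 1)
        row[(i - 1) * 3 + k] <- w
        rows[[length(rows) + 1]] <- row
        rhs <- c(rhs, w * p[k])
      }
    }
    X <- do.call(rbind, rows)
    qr.solve(X, rhs)
  }
  ux <- solve_axis(1); uy <- solve_axis(2)
  out <- lapply(seq_len(nt), function(i)
    affine2d(c(ux[(i - 1) * 3 + 1:3], uy[(i - 1) * 3 + 1:3])))
  setNames(out, ids)
}
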