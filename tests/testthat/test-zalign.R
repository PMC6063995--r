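test_that("montage scapes render tiles faithfully", {
  sec <- fix_slice()$raster
  ts <- make_tile_set(sec, 64, overlap = 0.2, stage_jitter_px = 0, noise_sigma = 0,
                      intensity_offsets = rep(0, 9), seed = 1)
  tr <- ts$ground_truth$true_tile_transforms
  # single untransformed tile at scale 1 reproduces the tile
  one <- em_tileset(list(ts$tileset$tiles[[1]]), 0L)
  sc1 <- render_montage_scape(one, tr[1], scale = 1)
  expect_equal(sc1$raster, ts$tileset$tiles[[1]]$raster, tolerance = 1e-9,
               ignore_attr = TRUE)
  # overlapping identical content averages to the common value
  sc <- render_montage_scape(ts$tileset, tr, scale = 1)
  expect_lt(mean(abs(sc$raster[sc$mask] - sec[sc$mask])), 1e-6)
  # anti-aliased half-scale render preserves the mean gray
  sc2 <- render_montage_scape(ts$tileset, tr, scale = 0.5)
  expect_lt(abs(mean(sc2$raster[sc2$mask]) - mean(sec)), 1.0)
  expect_error(render_montage_scape(em_tileset(list(), 0L), list(), 1), "empty")
})

test_that("scape matching recovers planted rotations and flags noise", {
  a <- fix_noisy()
  lm0 <- match_scapes(a, a, angle_range = 2, angle_step = 1)
  expect_equal(lm0$angle, 0)
  expect_lte(max(abs(lm0$translation)), 0.1)
  expect_gt(lm0$correlation, 0.99)

  b <- rotate_raster(a, 5)$raster
  b <- warp_affine(b, translate2d(c(3, 2)), fill = mean(a))$raster
  lm <- match_scapes(a, b, angle_range = 6, angle_step = 1)
  expect_lte(abs(lm$angle - (-5)), 1)
  expect_false(lm$no_match)

  n1 <- matrix(rnorm(160 * 160, 128, 20), 160, 160)
  n2 <- matrix(rnorm(160 * 160, 128, 20), 160, 160)
  lmn <- match_scapes(n1, n2)
  expect_lt(lmn$correlation, 0.1)
  expect_true(lmn$no_match)
})

test_that("correspondence counts separate identical, adjacent and unrelated content", {
  a <- fix_noisy()
  nf <- nrow(emrecon:::scape_features(a)$xy)
  self <- count_correspondences(a, a, 8, seed = 3)
  expect_gte(self, 0.8 * nf)

  n1 <- matrix(rnorm(160 * 160, 128, 20), 160, 160)
  n2 <- matrix(rnorm(160 * 160, 128, 20), 160, 160)
  expect_lte(count_correspondences(n1, n2, 8, seed = 3), 5)

  # monotone decay with z distance on an ordered stack
  vol <- fix_volume()
  st <- make_section_stack(vol, 10, order_permutation = 1:10,
                           per_section_jitter = c(1, 3), seed = 6)
  ok <- 0; tot <- 0
  feats <- lapply(st$sections, emrecon:::scape_features)
  for (i in 1:7) {
    c1 <- emrecon:::count_correspondences_impl(feats[[i]], feats[[i + 1]], 8, 100 + i)
    c3 <- emrecon:::count_correspondences_impl(feats[[i]], feats[[i + 3]], 8, 200 + i)
    tot <- tot + 1; ok <- ok + (c1 > c3)
  }
  expect_gte(ok / tot, 0.9)
})

test_that("similarity matrices are symmetric, windowed, and match a direct loop", {
  vol <- fix_volume()
  st <- make_section_stack(vol, 6, order_permutation = 1:6, seed = 7)
  sim <- build_similarity(st$sections, window = 2, max_displacement = 8, seed = 8)
  expect_true(isSymmetric(unname(unclass(sim))))
  expect_true(all(diag(sim) == 0))
  expect_true(all(sim[abs(row(sim) - col(sim)) > 2] == 0))
  # direct per-pair oracle with the same seeds
  feats <- lapply(st$sections, emrecon:::scape_features)
  for (i in 1:5) for (j in (i + 1):min(6, i + 2)) {
    expect_identical(sim[i, j],
                     emrecon:::count_correspondences_impl(feats[[i]], feats[[j]], 8,
                                                          8 + 131L * i + j))
  }

  # three identical sections: all in-window entries equal
  sec <- st$sections[[1]]
  sim3 <- build_similarity(list(sec, sec, sec), window = 2, seed = 9)
  off <- sim3[upper.tri(sim3)]
  expect_true(all(off == off[1]))
})

test_that("section order is recovered from counts (exact = heuristic at S = 8)", {
  # synthetic banded counts: decay with true distance
  S <- 8
  perm <- plant_swaps(S, 2, seed = 31)
  counts <- matrix(0L, S, S)
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    d <- abs(perm[i] - perm[j])
    counts[i, j] <- counts[j, i] <- if (d <= 3) c(40L, 15L, 6L)[d] else 0L
  }
  sim <- structure(counts, window = 3L, class = c("similarity_matrix", "matrix"))
  orde <- correct_section_order(sim, method = "exact")
  ordg <- correct_section_order(sim, method = "greedy_2opt")
  D <- emrecon:::sim_to_dist(sim)
  expect_equal(emrecon:::path_cost(D, orde), emrecon:::path_cost(D, ordg))
  expect_true(identical(orde, order(perm)) || identical(rev(orde), order(perm)))
  # returned order is never worse than the input (stack) order
  expect_lte(emrecon:::path_cost(D, orde), emrecon:::path_cost(D, seq_len(S)))

  # exhaustive oracle over all paths for S = 6
  S2 <- 6
  set.seed(12)
  M <- matrix(0L, S2, S2)
  for (i in 1:(S2 - 1)) for (j in (i + 1):S2)
    M[i, j] <- M[j, i] <- sample.int(30, 1)
  sim2 <- structure(M, window = S2, class = c("similarity_matrix", "matrix"))
  D2 <- emrecon:::sim_to_dist(sim2)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- min(vapply(perms(seq_len(S2)), function(p) emrecon:::path_cost(D2, p), 0))
  expect_equal(emrecon:::path_cost(D2, correct_section_order(sim2, "exact")), best)

  # relabeling equivariance
  rl <- sample(S2)
  sim_rl <- structure(M[rl, rl], window = S2, class = c("similarity_matrix", "matrix"))
  o1 <- correct_section_order(sim2, "exact")
  o2 <- correct_section_order(sim_rl, "exact")
  got <- rl[o2]
  expect_true(identical(got, o1) || identical(rev(got), o1))
})

test_that("a planted swap in a real stack is repaired", {
  vol <- fixture("vol_z", function()
    generate_tissue_volume(c(192, 192, 16), 200, 60, seed = 77))
  perm <- c(1:9, 11, 10, 12)
  st <- make_section_stack(vol, 12, order_permutation = perm,
                           per_section_jitter = c(1, 3), seed = 78)
  sim <- build_similarity(st$sections, window = 3, max_displacement = 8, seed = 79)
  ord <- correct_section_order(sim)
  expect_true(identical(ord, order(perm)) || identical(rev(ord), order(perm)))
})

test_that("rough alignment chains layer matches correctly", {
  # identity matches -> identity transforms
  mk_lm <- function(tf, dim_b = c(100, 100)) {
    structure(list(section_a = 0L, section_b = 1L, angle = NA, translation = NA,
                   correlation = 1, no_match = FALSE, transform = tf,
                   dim_b = dim_b), class = "layer_match")
  }
  ra0 <- rough_align(list(mk_lm(affine2d()), mk_lm(affine2d())))
  for (tf in ra0) expect_equal(tf$m, affine2d()$m, tolerance = 1e-8)

  # constant per-step shift telescopes
  d <- 7.5
  ra1 <- rough_align(lapply(1:4, function(k) mk_lm(translate2d(c(d, 0)))))
  for (k in 1:5)
    expect_equal(ra1[[k]]$m[, 3], c((k - 1) * d, 0), tolerance = 0.1)

  # planted per-step rotations recovered after anchoring
  ths <- c(1.5, -2, 3)
  ra2 <- rough_align(lapply(ths, function(th) mk_lm(rigid2d(th, c(0, 0), center = c(50, 50)))))
  cum <- cumsum(c(0, ths))
  for (k in 1:4) {
    ang <- atan2(ra2[[k]]$m[2, 1], ra2[[k]]$m[1, 1]) * 180 / pi
    expect_lt(abs(ang - cum[k]), 0.2)
  }
  expect_error(rough_align(list(mk_lm(affine2d()), NULL)), "chain")
})

test_that("block matching recovers planted displacement fields", {
  a <- fix_noisy()
  bm0 <- block_match(a, a, block_grid = c(3, 3), max_displacement = 8)
  expect_gt(n_matches(bm0), 0)
  expect_lt(max(abs(bm0$pb - bm0$pa)), 0.5)

  # planted smooth warp: block displacements match the field at block centers
  nr <- nrow(a); nc <- ncol(a)
  xs <- rep(0:(nc - 1), each = nr); ys <- rep(0:(nr - 1), times = nc)
  fx <- 2 * sin(2 * pi * xs / nc); fy <- -2 * cos(2 * pi * ys / nr)
  b <- matrix(bilinear_sample(a, pmin(pmax(xs + fx, 0), nc - 1),
                              pmin(pmax(ys + fy, 0), nr - 1)), nr, nc)
  bm <- block_match(a, b, block_grid = c(4, 4), max_displacement = 6)
  d <- bm$pb - bm$pa
  want <- cbind(-2 * sin(2 * pi * bm$pa[, 1] / nc), 2 * cos(2 * pi * bm$pa[, 2] / nr))
  expect_lt(sqrt(mean(rowSums((d - want)^2))), 1)

  # featureless blocks are dropped
  flat <- matrix(100, 120, 120)
  expect_equal(n_matches(block_match(flat, flat, c(2, 2), 5)), 0)
})

test_that("solve_volume reduces to the montage solve and matches the dense oracle", {
  set.seed(21)
  truth <- list(a = translate2d(c(0, 0)), b = translate2d(c(80, 0)),
                c = translate2d(c(0, 80)), d = translate2d(c(80, 80)))
  pri <- lapply(truth, function(tf) translate2d(tf$m[, 3] + runif(2, -3, 3)))
  ms <- list()
  for (p in list(c("a", "b"), c("c", "d"), c("a", "c"), c("b", "d"))) {
    pb <- cbind(runif(6, 0, 40), runif(6, 0, 40))
    rel <- truth[[p[2]]]$m[, 3] - truth[[p[1]]]$m[, 3]
    ms[[length(ms) + 1]] <- point_match_set(p[1], p[2], sweep(pb, 2, rel, `+`), pb)
  }
  s1 <- solve_montage(ms, pri, lambda_reg = 0.01, linear_weight = 50)
  s2 <- solve_volume(ms, list(), pri, lambda_reg = 0.01, linear_weight = 50)
  for (id in names(pri)) expect_equal(s1[[id]]$m, s2[[id]]$m, tolerance = 1e-10)

  # with cross weights -> 0 the volume solve equals the per-section solves
  cross <- list(point_match_set("b", "c", cbind(1, 1), cbind(2, 2),
                                provenance = "cross-section"))
  s3 <- solve_volume(ms, cross, pri, lambda_reg = 0.01, cross_weight = 1e-12,
                     linear_weight = 50)
  for (id in names(pri)) expect_equal(s3[[id]]$m, s1[[id]]$m, tolerance = 1e-5)

  # dense oracle equality on the joint system
  s4 <- solve_volume(ms, cross, pri, lambda_reg = 0.01, linear_weight = 50)
  oracle <- dense_affine_oracle(c(ms, cross), pri, 0.01, linear_weight = 50)
  o1 <- alignment_objective(c(ms, cross), s4, pri, 0.01, linear_weight = 50)
  o2 <- alignment_objective(c(ms, cross), oracle, pri, 0.01, linear_weight = 50)
  expect_lt(abs(o1 - o2) / o2, 1e-6)
})
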