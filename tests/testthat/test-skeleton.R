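line_skel <- function(n, step = 1000, dir = c(1, 0, 0)) {
  xyz <- outer(0:(n - 1), dir) * step
  skeleton(data.frame(id = 1:n, type = 0, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], radius = 40, parent = c(-1, 1:(n - 1))))
}

test_that("SWC I/O round-trips and rejects malformed trees", {
  p <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 0 0 0 0 40 -1", "2 0 100 0 0 40 1",
               "3 0 200 0 0 40 2"), p)
  s <- read_swc(p)
  expect_equal(nrow(s$nodes), 3)
  expect_equal(nrow(emrecon:::skel_edges(s)), 2)

  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 40 -1", "2 0 1 1 1 40 99"), bad)
  expect_error(read_swc(bad), "parent")

  sk <- fix_skel()
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(sk, f)
  expect_identical(read_swc(f)$nodes, sk$nodes)
})

test_that("resampling respects spacing, endpoints and cable length", {
  ln <- line_skel(11, 1000)            # straight 10 um line
  rs <- resample_skeleton(ln, 1000)
  expect_equal(nrow(rs$nodes), 11)
  d <- diff(sort(rs$nodes$x))
  expect_true(all(abs(d - 1000) < 1e-6))

  short <- resample_skeleton(ln, 1e6)  # interval beyond total length
  expect_equal(nrow(short$nodes), 2)
  expect_equal(range(short$nodes$x), c(0, 10000))

  for (seed in 1:3) {
    sk <- make_synthetic_skeleton(3, 400, c(3e4, 3e4, 1.5e4), seed = seed)
    rs2 <- resample_skeleton(sk, 80)
    expect_lt(abs(cable_length(rs2) - cable_length(sk)) / cable_length(sk), 0.01)
    # branch/leaf counts preserved
    deg <- function(s) {
      ch <- table(s$nodes$parent[s$nodes$parent != -1])
      c(branches = sum(ch >= 2), leaves = sum(!(s$nodes$id %in% s$nodes$parent)))
    }
    expect_equal(deg(rs2), deg(sk))
  }
})

test_that("arc-length smoothing attenuates waves by the Gaussian response", {
  ln <- line_skel(101, 500)
  sm <- smooth_skeleton(ln, sigma = 12000)
  expect_lt(max(abs(as.matrix(sm$nodes[, c("x", "y", "z")]) -
                    as.matrix(ln$nodes[, c("x", "y", "z")]))), 1)

  # sinusoidal zigzag: amplitude shrinks by exp(-2 pi^2 sigma^2 / lambda^2)
  n <- 400; step <- 500; lam <- 40000; A <- 1500; sig <- 4000
  x <- (0:(n - 1)) * step
  y <- A * sin(2 * pi * x / lam)
  zz <- skeleton(data.frame(id = 1:n, type = 0, x = x, y = y, z = 0,
                            radius = 40, parent = c(-1, 1:(n - 1))))
  sm2 <- smooth_skeleton(zz, sigma = sig)
  core <- 100:300
  got_amp <- max(abs(sm2$nodes$y[core]))
  want_amp <- A * exp(-2 * pi^2 * sig^2 / lam^2)
  expect_lt(abs(got_amp - want_amp) / want_amp, 0.1)

  tiny <- smooth_skeleton(zz, sigma = 1)
  expect_lt(max(abs(tiny$nodes$y - zz$nodes$y)), 1)

  # smoothing never lengthens a curve (line and circular arc)
  th <- seq(0, pi, length.out = 100)
  arc <- skeleton(data.frame(id = 1:100, type = 0, x = 20000 * cos(th),
                             y = 20000 * sin(th), z = 0, radius = 40,
                             parent = c(-1, 1:99)))
  expect_lte(cable_length(smooth_skeleton(arc, 5000)), cable_length(arc))
  expect_lte(cable_length(smooth_skeleton(ln, 12000)), cable_length(ln) + 1e-6)
})

test_that("section displacement spikes exactly at a planted shift", {
  # gentle neurite-like curve: 50 nm lateral wiggle, steady z slope so every
  # 35 nm section holds a few nodes
  n <- 1000
  t <- 0:(n - 1)
  sk <- skeleton(data.frame(id = 1:n, type = 0,
                            x = t * 100,
                            y = 50 * sin(2 * pi * t * 100 / 20000),
                            z = t * 10, radius = 40,
                            parent = c(-1, 1:(n - 1))))
  ds0 <- section_displacement(sk, section_thickness = 35, sigma = 12000)
  base <- median(ds0$displacements$displacement_um)
  expect_lt(base, 0.05)

  # plant a 1 um in-plane shift on every node of one section
  secs <- round(sk$nodes$z / 35)
  target <- 140L
  shifted <- sk
  shifted$nodes$y[secs == target] <- shifted$nodes$y[secs == target] + 1000
  ds <- section_displacement(shifted, section_thickness = 35, sigma = 12000)
  at <- ds$displacements$displacement_um[ds$displacements$section %in%
                                           c(target, target + 1)]
  expect_gte(length(at), 1)
  expect_gt(max(at), 5 * base)
  peak <- ds$displacements$section[which.max(ds$displacements$displacement_um)]
  expect_true(peak %in% c(target, target + 1))
  far <- ds$displacements$displacement_um[abs(ds$displacements$section - target) > 2]
  expect_lt(max(far), 0.2)

  # independent oracle: recompute the target-section mean distance directly
  # from a hand-rolled quadrature Gaussian smoother on the same construction
  sm_or <- local({
    P <- as.matrix(shifted$nodes[, c("x", "y", "z")])
    cs <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    sapply(which(secs == target), function(i) {
      w <- exp(-(cs - cs[i])^2 / (2 * 12000^2))
      w[abs(cs - cs[i]) > 3 * 12000] <- 0
      q <- c(diff(cs)[1] / 2, (diff(cs)[-1] + diff(cs)[-(n - 1)]) / 2,
             diff(cs)[n - 1] / 2)
      sm <- colSums(P * (w * q)) / sum(w * q)
      sqrt(sum((P[i, ] - sm)^2)) / 1000
    })
  })
  got <- ds$sections$mean_dist_um[ds$sections$section == target]
  expect_lt(abs(got - mean(sm_or)) / mean(sm_or), 0.05)

  # doubling sigma never decreases per-section mean distances on a fixed
  # tortuous skeleton
  d1 <- section_displacement(sk, sigma = 6000)$sections$mean_dist_um
  d2 <- section_displacement(sk, sigma = 12000)$sections$mean_dist_um
  expect_true(all(d2 - d1 > -1e-9))
})

test_that("agreement errors count planted deletions with oracle lengths", {
  sk <- fix_skel()
  self <- skeleton_agreement(sk, sk)
  expect_equal(self$n_errors, 0)
  expect_equal(self$n_inconsistent_test, 0)

  # gold: trunk with 3 perpendicular branches of 3, 5, 7 um
  trunk_n <- 61
  gold_df <- data.frame(id = 1:trunk_n, type = 0, x = (0:(trunk_n - 1)) * 500,
                        y = 0, z = 0, radius = 40,
                        parent = c(-1, 1:(trunk_n - 1)))
  nid <- trunk_n
  for (b in 1:3) {
    len_um <- c(3, 5, 7)[b]
    at <- c(11, 31, 51)[b]
    n_b <- len_um * 2           # 500 nm steps
    for (i in 1:n_b) {
      nid <- nid + 1
      gold_df <- rbind(gold_df, data.frame(
        id = nid, type = 0, x = (at - 1) * 500, y = i * 500,
        z = 0, radius = 40, parent = if (i == 1) at else nid - 1))
    }
  }
  gold <- skeleton(gold_df)
  test_sk <- skeleton(gold_df[1:trunk_n, ])   # branches deleted
  rep <- skeleton_agreement(test_sk, gold, resample_interval = 80,
                            match_radius = 800)
  expect_equal(rep$n_errors, 3)
  # each missed branch loses its cable beyond the 800 nm reach of the trunk
  expect_equal(sort(rep$missed_lengths_um), c(3, 5, 7) - 0.8,
               tolerance = 0.1)
  expect_equal(rep$um_per_error, rep$total_gold_cable_um / 3)

  # per-class split: trunk nodes labeled backbone
  rep2 <- skeleton_agreement(test_sk, gold, backbone_labels = 1:trunk_n)
  expect_equal(rep2$by_class$errors, c(0, 3))

  # threshold semantics: 700 nm displaced node is consistent, 900 nm is not
  g2 <- line_skel(26, 400)
  t_ok <- g2; t_ok$nodes$y <- t_ok$nodes$y + 700
  t_bad <- g2; t_bad$nodes$y <- t_bad$nodes$y + 900
  expect_equal(skeleton_agreement(t_ok, g2)$n_inconsistent_test, 0)
  expect_gt(skeleton_agreement(t_bad, g2)$n_inconsistent_test, 0)
})

test_that("pairwise arbor distance is symmetric and matches brute force", {
  sk <- fix_skel()
  expect_lt(pairwise_arbor_distance(sk, sk), 1e-6)

  # two parallel 20 um lines separated by d
  a <- line_skel(21, 1000)
  b <- a; b$nodes$y <- b$nodes$y + 3000
  expect_lt(abs(pairwise_arbor_distance(a, b) - 3), 0.01)

  # extra branch inflates only the forward direction; brute-force oracle
  a2 <- make_synthetic_skeleton(2, 600, c(2e4, 2e4, 1e4), seed = 31)
  b2 <- make_synthetic_skeleton(3, 600, c(2e4, 2e4, 1e4), seed = 32)
  got <- pairwise_arbor_distance(a2, b2)
  ra <- resample_skeleton(a2, 1000); rb <- resample_skeleton(b2, 1000)
  A <- as.matrix(ra$nodes[, c("x", "y", "z")])
  B <- as.matrix(rb$nodes[, c("x", "y", "z")])
  fwd <- mean(apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2)))))
  rev_ <- mean(apply(B, 1, function(p) min(sqrt(colSums((t(A) - p)^2)))))
  expect_equal(got, min(fwd, rev_) / 1000, tolerance = 1e-9)
  expect_equal(pairwise_arbor_distance(b2, a2), got, tolerance = 1e-9)
})

test_that("box clipping cuts edges at the boundary and re-roots components", {
  sk <- fix_skel()
  xyz <- as.matrix(sk$nodes[, c("x", "y", "z")])
  big <- c(range(xyz[, 1]) + c(-1, 1), range(xyz[, 2]) + c(-1, 1),
           range(xyz[, 3]) + c(-1, 1))
  all_in <- clip_to_box(sk, big)
  expect_false(all_in$empty)
  expect_equal(sum(vapply(all_in$components, function(c) nrow(c$nodes), 0)),
               nrow(sk$nodes))
  expect_equal(sum(vapply(all_in$components, cable_length, 0)), cable_length(sk))

  # straight 10 um segment half inside
  ln <- line_skel(11, 1000)
  half <- clip_to_box(ln, c(-100, 5000, -100, 100, -100, 100))
  expect_equal(sum(vapply(half$components, cable_length, 0)), 5000,
               tolerance = 1)

  # box touching no nodes but crossed by one edge
  seg <- skeleton(data.frame(id = 1:2, type = 0, x = c(-2000, 2000), y = 0,
                             z = 0, radius = 40, parent = c(-1, 1)))
  thin <- clip_to_box(seg, c(-500, 500, -100, 100, -100, 100))
  expect_false(thin$empty)
  expect_equal(length(thin$components), 1)
  expect_equal(cable_length(thin$components[[1]]), 1000, tolerance = 1e-6)

  empty <- clip_to_box(seg, c(5000, 6000, 0, 10, 0, 10))
  expect_true(empty$empty)
})

test_that("active bouts follow the 3-minute rule and sum per user", {
  ev <- data.frame(user = "u", timestamp = c(0, 120, 600))
  expect_equal(active_bout_time(ev) * 3600, 120)
  expect_equal(active_bout_time(data.frame(user = "u", timestamp = 5)), 0)
  expect_equal(active_bout_time(ev[0, ]), 0)

  # two interleaved users: total equals the sum of per-user bout sums
  ev2 <- data.frame(user = c("a", "b", "a", "b", "a", "b"),
                    timestamp = c(0, 50, 100, 130, 500, 1000))
  per_user <- sum(vapply(c("a", "b"), function(u)
    active_bout_time(ev2[ev2$user == u, ]), 0))
  expect_equal(active_bout_time(ev2), per_user)
  # tracing-speed accounting on a constructed rate: 90 um in 0.05 h
  sk <- line_skel(10, 10000)
  t_h <- active_bout_time(data.frame(user = "u", timestamp = c(0, 180)))
  expect_equal((cable_length(sk) / 1000) / t_h, 90 / 0.05)
})
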