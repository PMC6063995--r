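planted_blob_image <- function(amp, sigma_n = 4, seed = 5) {
  emrecon:::with_seed(seed, {
    img <- matrix(rnorm(128 * 128, 120, sigma_n), 128, 128)
    centers <- cbind(x = c(20, 60, 100, 20, 60, 100, 20, 60, 100, 40),
                     y = c(20, 20, 20, 64, 64, 64, 108, 108, 108, 88))
    xs <- rep(0:127, each = 128); ys <- rep(0:127, times = 128)
    for (i in seq_len(nrow(centers)))
      img <- img - matrix(amp * exp(-((xs - centers[i, 1])^2 +
                                        (ys - centers[i, 2])^2) / (2 * 3^2)),
                          128, 128)
    list(img = img, centers = centers)
  })
}

test_that("blob detection finds planted blobs and responds monotonically", {
  expect_equal(nrow(detect_features(matrix(100, 64, 64))), 0)
  pb <- planted_blob_image(amp = 20)   # 5x the noise sd
  kp <- detect_features(pb$img)
  hits <- 0
  for (i in seq_len(nrow(pb$centers))) {
    d <- sqrt((kp$x - pb$centers[i, 1])^2 + (kp$y - pb$centers[i, 2])^2)
    if (any(d <= 2)) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # recall of the planted blobs grows with amplitude over {1, 2, 4} x noise
  recall <- vapply(c(1, 2, 4), function(m) {
    pbm <- planted_blob_image(amp = 4 * m)
    kpm <- detect_features(pbm$img)
    sum(vapply(seq_len(nrow(pbm$centers)), function(i)
      any(sqrt((kpm$x - pbm$centers[i, 1])^2 +
                 (kpm$y - pbm$centers[i, 2])^2) <= 2), TRUE))
  }, 0)
  expect_true(all(diff(recall) >= 0))
  expect_error(detect_features(matrix(0, 16, 16)), "32")
})

test_that("feature density matches direct convolution and handles extremes", {
  expect_true(all(feature_density(c(40, 40), data.frame(x = numeric(0),
                                                        y = numeric(0)), 4) == 0))
  one <- feature_density(c(41, 41), data.frame(x = 20, y = 20), 4)
  expect_equal(as.vector(which(one == max(one), arr.ind = TRUE)), c(21, 21))

  kp <- data.frame(x = c(10, 30, 50, 12), y = c(15, 40, 20, 50))
  dens <- feature_density(c(64, 64), kp, 5)
  # direct truncated-Gaussian convolution oracle (same kernel support as the
  # separable filter: radius 3 sigma within the frame)
  ind <- matrix(0, 64, 64); for (i in 1:4) ind[kp$y[i] + 1, kp$x[i] + 1] <- 1
  oracle <- EBImage::filter2(ind, EBImage::makeBrush(2 * ceiling(3 * 5) + 1,
                                                     "gaussian", sigma = 5))
  expect_lt(max(abs(dens - oracle)), 1e-6)
})

test_that("extreme-region selection excludes blocks and is seed-deterministic", {
  set.seed(8)
  dens <- matrix(runif(100 * 100), 100, 100)
  s1 <- select_extreme_regions(dens, n = 8, k = 10, seed = 3)
  s2 <- select_extreme_regions(dens, n = 8, k = 10, seed = 3)
  expect_identical(s1, s2)
  # pairwise block separation (Chebyshev > n)
  for (set in s1) {
    dd <- as.matrix(dist(set, method = "maximum"))
    diag(dd) <- Inf
    expect_true(all(dd > 8))
  }
  # single global max is picked first
  dens2 <- matrix(0, 50, 50); dens2[25, 30] <- 1
  sh <- select_extreme_regions(dens2, n = 4, k = 3, seed = 1)
  expect_equal(sh$p_high[1, ], c(29, 24))

  # brute-force iterative argmax-with-exclusion oracle (same tie-break seed)
  oracle_pick <- function(dens, n, k, seed, decreasing) {
    nr <- nrow(dens); nc <- ncol(dens)
    rows <- 2:(nr - 1); cols <- 2:(nc - 1)
    xs <- rep(cols - 1, each = length(rows)); ys <- rep(rows - 1, times = length(cols))
    vals <- as.vector(dens[rows, cols])
    tie <- emrecon:::with_seed(seed, sample.int(length(vals)))
    o <- order(if (decreasing) -vals else vals, tie)
    chosen <- matrix(numeric(0), 0, 2)
    for (i in o) {
      p <- c(xs[i], ys[i])
      if (nrow(chosen) && any(abs(chosen[, 1] - p[1]) <= n &
                                abs(chosen[, 2] - p[2]) <= n)) next
      chosen <- rbind(chosen, p)
      if (nrow(chosen) == k) break
    }
    unname(chosen)
  }
  expect_equal(s1$p_high, oracle_pick(dens, 8, 10, 3, TRUE))
  expect_equal(s1$p_low, oracle_pick(dens, 8, 10, 3, FALSE))
})

test_that("the median residual isolates impulses and pixel noise", {
  expect_true(all(noise_residual(matrix(42, 10, 10)) == 0))
  imp <- matrix(100, 21, 21); imp[11, 11] <- 180
  r <- noise_residual(imp)
  expect_equal(r[11, 11], 80)
  expect_lt(max(abs(r[-11, ])), 1e-9)

  # Monte-Carlo oracle for i.i.d. Gaussian noise at sigma = 10
  sd_pkg <- emrecon:::with_seed(9, sd(noise_residual(matrix(rnorm(256^2, 128, 10), 256, 256))))
  sd_mc <- emrecon:::with_seed(10, {   # independent realization, direct 3x3 median
    x <- matrix(rnorm(128^2, 128, 10), 128, 128)
    med <- x
    for (r in 2:127) for (cc in 2:127)
      med[r, cc] <- median(x[(r - 1):(r + 1), (cc - 1):(cc + 1)])
    sd((x - med)[2:127, 2:127])
  })
  expect_lt(abs(sd_pkg - sd_mc) / sd_mc, 0.15)
})

test_that("the feature-based SNR is gray-affine invariant and tracks signal", {
  pb <- planted_blob_image(amp = 60, sigma_n = 5)
  est <- feature_based_snr(pb$img, n = 8, seed = 2)
  est2 <- feature_based_snr(2 * pb$img + 30, n = 8, seed = 2)
  expect_lt(abs(est2$snr - est$snr) / est$snr, 1e-6)

  # ground-truth-region oracle: evaluate the same statistics with p_low on
  # known background and p_high at the planted blob centers
  emrecon:::with_seed(11, {
    bg <- cbind(sample(c(5:12, 116:123), 10, TRUE), sample(c(35:55), 10, TRUE))
    Ir <- noise_residual(pb$img)
    N <- mean(apply(bg, 1, function(p) sd(as.vector(Ir[p[2] + 0:2, p[1] + 0:2]))))
    B <- mean(apply(bg, 1, function(p) mean(pb$img[p[2] + 0:2, p[1] + 0:2])))
    S <- mean(apply(pb$centers, 1, function(p)
      abs(mean(pb$img[p[2] + 0:2, p[1] + 0:2]) - B)))
    oracle <- S / N
    expect_lt(abs(est$snr - oracle) / oracle, 0.25)
  })

  # doubling the blob amplitude doubles the SNR
  pb2 <- planted_blob_image(amp = 120, sigma_n = 5)
  est3 <- feature_based_snr(pb2$img, n = 8, seed = 2)
  expect_lt(abs(est3$snr / est$snr - 2), 0.2 * 2)
  expect_error(feature_based_snr(matrix(50, 64, 64)), "degenerate")
})

test_that("calibrate_n maximizes the mean SNR over candidates", {
  imgs <- lapply(1:3, function(i) planted_blob_image(amp = 50, seed = 20 + i)$img)
  expect_equal(calibrate_n(imgs, 6), 6)
  cand <- c(4, 8, 16)
  pick <- calibrate_n(imgs, cand, seed = 2)
  means <- vapply(cand, function(nn)
    mean(vapply(imgs, function(im) feature_based_snr(im, n = nn, seed = 2)$snr, 0)), 0)
  expect_equal(pick, cand[which.max(means)])
  expect_equal(calibrate_n(imgs, rev(cand), seed = 2), pick)
})

test_that("the membrane SNR matches direct arithmetic on drawn samples", {
  emrecon:::with_seed(14, {
    img <- matrix(rnorm(200 * 200, 100, 5), 200, 200)
      img[, 97:101] <- 160
    bg_lines <- lapply(1:10, function(i)
      line_sample("background", cbind(5 + i, 10:149)))
    sig_lines <- lapply(1:10, function(i)
      line_sample("signal", cbind(96 + (i %% 5), 10:29)))
    est <- membrane_snr(img, c(bg_lines, sig_lines))
    bg_px <- unlist(lapply(bg_lines, function(s) img[cbind(s$positions[, 2] + 1,
                                                           s$positions[, 1] + 1)]))
    expect_equal(est$noise, sd(bg_px))
    expect_equal(est$background, mean(bg_px))
    expect_lt(abs(est$snr - 60 / 5) / 12, 0.1)

    # signal pixels exactly at the background mean -> snr 0
    img2 <- img
    img2[61:80, 31] <- mean(bg_px)
    est0 <- membrane_snr(img2, c(bg_lines, list(line_sample("signal", cbind(30, 60:79)))))
    expect_equal(est0$snr, 0)

    const <- matrix(80, 120, 120)
    expect_error(membrane_snr(const, c(list(line_sample("background", cbind(3, 1:20))),
                                       list(line_sample("signal", cbind(50, 1:20))))),
                 "degenerate")
  })
})

test_that("voxel-size normalization follows the square-root volume rule", {
  expect_equal(normalize_snr(5, c(4, 4, 40)), 5)
  expect_equal(normalize_snr(3, c(4, 4, 10)), 3 * 2)  # quarter volume -> x2
  expect_equal(normalize_snr(1, c(3, 3, 30)), sqrt(640 / 270))
  expect_error(normalize_snr(1, c(0, 4, 40)), "positive")
})

test_that("tile and section artifact classifiers implement the threshold rules", {
  mk <- function(mean, sdv, seed) emrecon:::with_seed(seed, {
    x <- rnorm(64 * 64, mean, sdv)
    matrix(mean + (x - mean(x)) * sdv / sd(x), 64, 64)  # exact mean/sd
  })
  rep <- classify_tiles(list(mk(128, 45, 1), mk(40, 15, 2), mk(128, 30, 3)))
  expect_equal(rep$status, c("degraded", "degraded", "ok"))

  # oracle equivalence on 1000 random mean/sd cases
  emrecon:::with_seed(15, {
    mus <- runif(1000, 0, 255); sds <- runif(1000, 1, 60)
    tiles <- lapply(1:1000, function(i) {
      x <- rnorm(100, mus[i], 1)
      matrix(mus[i] + (x - mean(x)) * sds[i] / sd(x), 10, 10)
    })
    got <- classify_tiles(tiles)$status == "degraded"
    want <- vapply(tiles, function(t) {
      s <- sd(t); m <- mean(t)
      s > 40 || (s < 20 && m < 50)
    }, TRUE)
    expect_identical(got, want)
  })

  counts <- rep(100, 21); counts[11] <- 94
  expect_equal(detect_missing_sections(counts), 11L)
  counts[11] <- 96
  expect_length(detect_missing_sections(counts), 0)

  # brute-force rule oracle on 1000 random series
  emrecon:::with_seed(16, {
    for (trial in 1:50) {
      cs <- sample(50:150, 25, TRUE)
      got <- detect_missing_sections(cs)
      want <- which(vapply(seq_along(cs), function(s) {
        win <- max(1, s - 5):min(25, s + 5)
        cs[s] < 0.95 * median(cs[win])
      }, TRUE))
      expect_identical(got, want)
    }
  })
})
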