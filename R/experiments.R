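# Reproducible SNR validation studies ----------------------------------------
#
# The two simulation studies used to validate the SNR machinery: the
# voxel-combination scaling check (additive Gaussian noise predicts the SNR to
# grow by sqrt(n) when n voxels are averaged) and the cross-method agreement
# check (feature-based vs cell-membrane SNR on the same images). Both build
# their imagery from the synthetic tissue generator.

snr_study_images <- function(n_images, seed, membrane_contrast = 60,
                             noise_sigma = 8, image_size = 512) {
  per_vol <- 3L
  zs <- c(4L, 9L, 14L)
  n_vol <- ceiling(n_images / per_vol)
  out <- vector("list", n_images)
  k <- 0L
  for (v in seq_len(n_vol)) {
    vol <- generate_tissue_volume(c(image_size, image_size, 16),
                                  cell_diameter = 200,
                                  membrane_contrast = membrane_contrast,
                                  seed = seed * 1000L + v)
    for (z in zs) {
      if (k >= n_images) break
      k <- k + 1L
      sl <- volume_slice(vol, z)
      out[[k]] <- list(
        image = add_gaussian_noise(sl$raster, noise_sigma,
                                   seed = seed * 1000L + 100L * v + z),
        membrane_mask = sl$membrane_mask,
        organelle_mask = vol$organelle_mask[, , z])
    }
  }
  out
}

#' Voxel-combination SNR scaling study
#'
#' For each synthetic textured image (Voronoi tissue + additive Gaussian
#' noise), computes the feature-based SNR at native resolution and after
#' averaging non-overlapping 2x2 pixel blocks. Under the additive-noise model
#' the ratio should be sqrt(4) = 2; the study reports each image's relative
#' deviation from that expectation and their mean absolute value in percent.
#'
#' @param n_images number of images (>= 20 for the validation claim).
#' @param seed integer seed.
#' @param noise_sigma added Gaussian noise, gray (default 8).
#' @param n density width for the SNR estimator (default 8).
#' @return list: \code{ratios}, \code{deviation_percent} (per image),
#'   \code{mard_percent} (mean absolute relative deviation, %), \code{n_images}.
#' @export
snr_voxel_scaling_study <- function(n_images = 20, seed = 1, noise_sigma = 8,
                                    n = 8) {
  imgs <- snr_study_images(n_images, seed, noise_sigma = noise_sigma)
  ratios <- vapply(seq_along(imgs), function(i) {
    img <- imgs[[i]]$image
    native <- feature_based_snr(img, n = n, seed = seed + i)$snr
    combined <- feature_based_snr(block_average(img, 2), n = n, seed = seed + i)$snr
    combined / native
  }, 0)
  dev <- 100 * (ratios / 2 - 1)
  list(ratios = ratios, deviation_percent = dev,
       mard_percent = mean(abs(dev)), n_images = n_images)
}

#' Cross-method SNR agreement study
#'
#' Computes the feature-based and the cell-membrane SNR on the same synthetic
#' membrane images; membrane and background lines (10 each, from distinct
#' 100x100 px regions) are drawn from the generator's ground-truth masks. The
#' study reports the mean signed relative difference between the methods in
#' percent (the systematic disagreement; its absolute value is the headline
#' number).
#'
#' @param n_images number of images (>= 10 for the validation claim).
#' @param seed integer seed.
#' @param membrane_contrast gray (default 60).
#' @param noise_sigma gray (default 8).
#' @return list: \code{feature}, \code{membrane} (per-image SNRs),
#'   \code{rel_diff_percent} (per image, signed),
#'   \code{mean_rel_diff_percent} (abs of signed mean, %), \code{n_images}.
#' @export
snr_method_agreement_study <- function(n_images = 10, seed = 1,
                                       membrane_contrast = 60, noise_sigma = 8) {
  imgs <- snr_study_images(n_images, seed, membrane_contrast = membrane_contrast,
                           noise_sigma = noise_sigma)
  f <- numeric(n_images); m <- numeric(n_images)
  for (i in seq_len(n_images)) {
    img <- imgs[[i]]$image
    f[i] <- feature_based_snr(img, n = 8, seed = seed + i)$snr
    lines <- membrane_line_samples(img, imgs[[i]]$membrane_mask,
                                   avoid_mask = imgs[[i]]$organelle_mask,
                                   n_regions = 10, region = 100,
                                   seed = seed + 31L * i)
    m[i] <- membrane_snr(img, lines)$snr
  }
  rd <- 100 * (f - m) / m
  list(feature = f, membrane = m, rel_diff_percent = rd,
       mean_rel_diff_percent = abs(mean(rd)), n_images = n_images)
}
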