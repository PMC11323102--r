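# Synthetic imbalanced-lesion phantom generator. Emulates the regime the
# method targets: a large textured background with a few small,
# brighter, elliptical lesions occupying a small fraction of the image.

#' Configuration of the synthetic lesion generator
#'
#' @param n_samples number of images to generate.
#' @param image_size square image side in pixels (default 64, the
#'   desk-scale working size).
#' @param foreground_fraction target mean fraction of lesion pixels per
#'   image, in `(0, 0.5)` (default 0.03, i.e. a 3\% foreground typical of
#'   lesion segmentation).
#' @param n_lesions_range integer pair: lesions per image are drawn
#'   uniformly from this range (default 1 to 3).
#' @param noise_sd standard deviation of additive per-pixel Gaussian
#'   noise on the final image (default 0.05, on the `[0, 1]` intensity
#'   scale).
#' @param blur_sigma Gaussian smoothing of the background texture, in
#'   pixels (default 1.5).
#' @param lesion_contrast intensity offset of lesion pixels over the
#'   background (default 0.45).
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_samples, image_size = 64L,
                         foreground_fraction = 0.03,
                         n_lesions_range = c(1L, 3L), noise_sd = 0.05,
                         blur_sigma = 1.5, lesion_contrast = 0.45,
                         seed = 1L) {
  if (n_samples <= 0L) stop("n_samples must be positive")
  if (foreground_fraction >= 0.5)
    stop("foreground_fraction >= 0.5 contradicts the class-imbalance premise")
  if (foreground_fraction <= 0) stop("foreground_fraction must be positive")
  if (noise_sd < 0 || blur_sigma < 0) stop("noise_sd and blur_sigma must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size),
                 foreground_fraction = foreground_fraction,
                 n_lesions_range = as.integer(n_lesions_range),
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 lesion_contrast = lesion_contrast,
                 seed = as.integer(seed)),
            class = "synth_config")
}

rasterize_ellipse <- function(size, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic imbalanced-lesion dataset
#'
#' Each image is a smoothed Gaussian-noise background with 1 or more
#' brighter elliptical lesions; the mask is their union. Lesion areas are
#' drawn so the dataset-mean foreground fraction tracks
#' `foreground_fraction`; lesion centres keep the full ellipse inside the
#' image.
#'
#' @param config a [synth_config()].
#' @return List of [image_sample()] objects with intensities in `[0, 1]`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  size <- config$image_size
  target_area <- config$foreground_fraction * size^2
  out <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    bg <- matrix(stats::rnorm(size^2), size, size)
    if (config$blur_sigma > 0) {
      bg <- EBImage::imageData(EBImage::gblur(EBImage::Image(bg),
                                              sigma = config$blur_sigma))
    }
    bg <- (bg - mean(bg)) / (stats::sd(as.vector(bg)) + 1e-12)
    bg <- 0.35 + 0.08 * bg
    nl <- if (config$n_lesions_range[1] == config$n_lesions_range[2]) {
      config$n_lesions_range[1]
    } else {
      base::sample(seq(config$n_lesions_range[1], config$n_lesions_range[2]), 1L)
    }
    wts <- stats::runif(nl, 0.6, 1.4)
    areas <- target_area * wts / sum(wts)
    mask <- matrix(FALSE, size, size)
    for (l in seq_len(nl)) {
      ecc <- stats::runif(1, 0.55, 1)
      a <- sqrt(areas[l] / (pi * ecc))
      b <- a * ecc
      margin <- ceiling(a) + 1
      if (2 * margin >= size) margin <- size %/% 4
      cx <- stats::runif(1, margin, size - margin)
      cy <- stats::runif(1, margin, size - margin)
      theta <- stats::runif(1, 0, pi)
      mask <- mask | rasterize_ellipse(size, cx, cy, a, b, theta)
    }
    img <- bg + config$lesion_contrast * mask
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(size^2, sd = config$noise_sd), size, size)
    img <- pmin(pmax(img, 0), 1)
    out[[i]] <- image_sample(sprintf("synth%04d", i), img,
                             matrix(as.integer(mask), size, size))
  }
  out
}
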