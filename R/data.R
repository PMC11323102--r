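# Image/mask samples, dataset I/O (PNG/TIFF pairs and NIfTI volumes),
# the preprocessing chain (resize, optional CLAHE, Z-score), geometric
# augmentation, and k-fold assignment.

#' Construct an image sample
#'
#' @param id sample identifier.
#' @param image numeric array `h x w x c` (a matrix is promoted to one
#'   channel).
#' @param mask integer matrix of class labels in `0..L-1`, same spatial
#'   shape as the image.
#' @param fold non-negative integer fold assignment.
#' @return Object of class `image_sample`. Samples whose mask is entirely
#'   background carry `empty_mask = TRUE`.
#' @export
image_sample <- function(id, image, mask, fold = 0L) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  mask <- matrix(as.integer(round(mask)), nrow(mask), ncol(mask))
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask shapes differ for '", id, "': ",
         paste(dim(image)[1:2], collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  structure(list(id = as.character(id), image = image, mask = mask,
                 fold = as.integer(fold), empty_mask = all(mask == 0L)),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<image_sample '%s'> %dx%dx%d, fold %d, foreground %.2f%%%s\n",
              x$id, d[1], d[2], d[3], x$fold, 100 * mean(x$mask > 0),
              if (x$empty_mask) " [empty mask]" else ""))
  invisible(x)
}

read_image_file <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
}

#' Load an image/mask dataset
#'
#' Two layouts are supported. `png_pairs`: a directory of `<stem>.png`
#' (or `.tif`) images, each with a `<stem>_mask.png` companion.
#' `nifti_slices`: a NIfTI image volume plus a mask volume of the same
#' shape, sliced independently along the last axis (the networks are
#' 2-D). Slices or images with empty masks are retained and flagged, not
#' dropped.
#'
#' @param path directory (png_pairs) or NIfTI image file (nifti_slices).
#' @param layout `"png_pairs"` or `"nifti_slices"`.
#' @param mask_path mask volume path, required for `nifti_slices`.
#' @param n_classes number of label values encoded in the masks
#'   (default 2); mask intensities are mapped to integers `0..L-1`.
#' @return List of [image_sample()] objects.
#' @export
load_dataset <- function(path, layout = c("png_pairs", "nifti_slices"),
                         mask_path = NULL, n_classes = 2L) {
  layout <- match.arg(layout)
  if (layout == "png_pairs") {
    if (!dir.exists(path)) stop("directory not found: ", path)
    files <- list.files(path, pattern = "\\.(png|tiff?)$", ignore.case = TRUE)
    imgs <- files[!grepl("_mask\\.", files)]
    if (length(imgs) == 0L) stop("no images found under ", path)
    missing <- character()
    samples <- list()
    for (f in sort(imgs)) {
      stem <- sub("\\.(png|tiff?)$", "", f, ignore.case = TRUE)
      mf <- list.files(path, pattern = paste0("^", stem, "_mask\\."),
                       full.names = TRUE)
      if (length(mf) == 0L) { missing <- c(missing, stem); next }
      img <- read_image_file(file.path(path, f))
      msk <- read_image_file(mf[1L])
      if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
      if (!identical(dim(img)[1:2], dim(msk)))
        stop("shape mismatch for '", stem, "': image ",
             paste(dim(img)[1:2], collapse = "x"), " vs mask ",
             paste(dim(msk), collapse = "x"))
      samples[[length(samples) + 1L]] <-
        image_sample(stem, img, round(msk * (n_classes - 1L)))
    }
    if (length(missing))
      stop("missing mask file for: ", paste(missing, collapse = ", "))
    return(samples)
  }
  # nifti_slices
  if (is.null(mask_path)) stop("mask_path is required for nifti_slices")
  vol <- as.array(RNifti::readNifti(path))
  msk <- as.array(RNifti::readNifti(mask_path))
  if (!identical(dim(vol), dim(msk)))
    stop("shape mismatch: image volume ", paste(dim(vol), collapse = "x"),
         " vs mask volume ", paste(dim(msk), collapse = "x"))
  nz <- dim(vol)[3]
  stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lapply(seq_len(nz), function(i) {
    image_sample(sprintf("%s_slice%03d", stem, i), vol[, , i], msk[, , i])
  })
}

#' Preprocess a sample: resize, optional CLAHE, Z-score normalization
#'
#' The image is resized bilinearly to `target_size` square and the mask
#' with nearest-neighbour interpolation (labels stay integral).
#' Contrast-limited adaptive histogram equalization, when enabled, is
#' applied before normalization on the `[0, 1]`-rescaled image. Z-score
#' normalization runs last, per channel; a constant channel is centred
#' and divided by 1, so blank slices map to all zeros rather than NaN.
#'
#' @param sample an [image_sample()].
#' @param target_size output side length in pixels (default 512, the
#'   conventional size for full-resolution medical images; synthetic
#'   desk-scale data uses 64).
#' @param clahe apply CLAHE before normalization.
#' @param clip_limit CLAHE clip limit (default 2).
#' @param tile_grid CLAHE tile grid (default 8, i.e. 8x8 tiles).
#' @param replicate_channels replicate a single-channel image to 3
#'   channels (for pipelines expecting RGB input).
#' @return A preprocessed [image_sample()].
#' @export
preprocess <- function(sample, target_size = 512L, clahe = FALSE,
                       clip_limit = 2, tile_grid = 8L,
                       replicate_channels = FALSE) {
  stopifnot(inherits(sample, "image_sample"), target_size > 0)
  img <- sample$image
  if (!all(is.finite(img))) stop("non-finite pixels in sample '", sample$id, "'")
  d <- dim(img)
  if (d[1] != target_size || d[2] != target_size) {
    img <- EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                              w = target_size, h = target_size))
    img <- array(img, c(target_size, target_size, d[3]))
    msk <- EBImage::imageData(EBImage::resize(EBImage::Image(sample$mask),
                                              w = target_size, h = target_size,
                                              filter = "none"))
    msk <- matrix(as.integer(round(msk)), target_size, target_size)
  } else {
    msk <- sample$mask
  }
  if (replicate_channels && dim(img)[3] == 1L) {
    img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  }
  if (clahe) {
    for (ch in seq_len(dim(img)[3])) {
      z <- img[, , ch]
      rng <- range(z)
      z01 <- if (diff(rng) > 0) (z - rng[1]) / diff(rng) else z * 0
      img[, , ch] <- EBImage::imageData(
        EBImage::clahe(EBImage::Image(z01), nx = tile_grid, limit = clip_limit))
    }
  }
  for (ch in seq_len(dim(img)[3])) {
    z <- img[, , ch]
    s <- stats::sd(as.vector(z))
    if (!is.finite(s) || s < 1e-12) s <- 1  # constant-channel convention
    img[, , ch] <- (z - mean(z)) / s
  }
  image_sample(sample$id, img, msk, sample$fold)
}

rot90_mat <- function(m) {
  mt <- t(m)
  mt[rev(seq_len(nrow(mt))), , drop = FALSE]
}

rot90_arr <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    d <- dim(a)
    out <- array(0, c(d[2], d[1], d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- rot90_mat(a[, , ch])
    a <- out
  }
  a
}

#' Geometric augmentation of a sample
#'
#' Applies the identical transform to image and mask: rotation by a
#' multiple of 90 degrees (exact, label-preserving) and/or a random
#' square crop. Fully deterministic under `rng_seed`.
#'
#' @param sample an [image_sample()].
#' @param ops subset of `c("rotation", "random_crop")`.
#' @param rng_seed integer seed for the transform draws.
#' @param angle rotation in degrees (multiple of 90); drawn uniformly
#'   from {0, 90, 180, 270} when `NULL`.
#' @param crop_size side of the crop window; defaults to 7/8 of the
#'   shorter image side. Must not exceed the image.
#' @return Augmented [image_sample()].
#' @export
augment <- function(sample, ops = c("rotation", "random_crop"),
                    rng_seed = 0L, angle = NULL, crop_size = NULL) {
  stopifnot(inherits(sample, "image_sample"))
  ops <- match.arg(ops, several.ok = TRUE)
  set.seed(rng_seed)
  img <- sample$image; msk <- sample$mask
  if ("rotation" %in% ops) {
    if (is.null(angle)) angle <- base::sample(c(0L, 90L, 180L, 270L), 1L)
    if (angle %% 90L != 0L) stop("rotation must be a multiple of 90 degrees")
    k <- (angle %/% 90L) %% 4L
    img <- rot90_arr(img, k)
    msk <- if (k == 0L) msk else {
      m <- msk
      for (i in seq_len(k)) m <- rot90_mat(m)
      m
    }
  }
  if ("random_crop" %in% ops) {
    d <- dim(img)
    if (is.null(crop_size)) crop_size <- floor(min(d[1:2]) * 7 / 8)
    if (crop_size > min(d[1:2])) stop("crop size exceeds image size")
    i0 <- base::sample.int(d[1] - crop_size + 1L, 1L) - 1L
    j0 <- base::sample.int(d[2] - crop_size + 1L, 1L) - 1L
    img <- img[i0 + seq_len(crop_size), j0 + seq_len(crop_size), , drop = FALSE]
    msk <- msk[i0 + seq_len(crop_size), j0 + seq_len(crop_size), drop = FALSE]
  }
  image_sample(sample$id, img, msk, sample$fold)
}

#' Assign cross-validation folds
#'
#' Permutation-based partition into k folds whose sizes differ by at most
#' one, deterministic under the seed.
#'
#' @param samples list of [image_sample()] objects.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return The samples with `fold` set to `0..k-1`.
#' @export
split_folds <- function(samples, k = 5L, seed = 0L) {
  n <- length(samples)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the ", n, " available samples")
  set.seed(seed)
  perm <- sample.int(n)
  ids <- rep(seq_len(k) - 1L, length.out = n)
  for (i in seq_len(n)) samples[[perm[i]]]$fold <- ids[i]
  samples
}

#' Write a dataset as PNG pairs with a JSON manifest
#'
#' Images are linearly rescaled to `[0, 1]`; masks are scaled by
#' `1/(L-1)` so labels survive the round trip.
#'
#' @param samples list of [image_sample()] objects.
#' @param dir output directory (created if needed).
#' @param manifest list stored as `manifest.json` (e.g. the generating
#'   config and seed).
#' @param n_classes number of label values in the masks.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, manifest = list(), n_classes = 2L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    img <- s$image
    rng <- range(img)
    img01 <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    if (dim(img01)[3] == 1L) img01 <- img01[, , 1L]
    png::writePNG(img01, file.path(dir, paste0(s$id, ".png")))
    png::writePNG(s$mask / max(1L, n_classes - 1L),
                  file.path(dir, paste0(s$id, "_mask.png")))
  }
  manifest$n_samples <- length(samples)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
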