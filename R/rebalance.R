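# Region-level rebalancing: tile label maps into fixed-size regions,
# count dataset-level region class frequencies once per training fold,
# and weight an auxiliary region classification loss by those counts.
# The module only exists at training time; inference never touches it.

#' Cut a label map (and aligned features) into fixed-size regions
#'
#' Tiles the mask into non-overlapping r-by-r regions in row-major
#' order (top row of tiles first, left to right), padding with background
#' when the mask size is not divisible by `r`. Each region receives an
#' integer label: under `"any_foreground"` (the binary-task default) a
#' region is labelled 1 when any foreground pixel falls inside it; under
#' `"majority"` the modal class of the tile wins (ties to the smaller
#' class id).
#'
#' @param mask integer matrix of class labels in `0..L-1`.
#' @param feature optional numeric array `h x w x c` aligned with the
#'   mask; tiled the same way and carried along as region features.
#' @param r region side length in pixels (default 32).
#' @param label_rule `"any_foreground"` or `"majority"`.
#' @return Object of class `region_batch`: list with `labels` (integer
#'   vector, one per region), `features` (list of r-by-r-by-c arrays or
#'   `NULL`), `r`, and the tile grid dimensions.
#' @export
extract_regions <- function(mask, feature = NULL, r = 32L,
                            label_rule = c("any_foreground", "majority")) {
  label_rule <- match.arg(label_rule)
  r <- as.integer(r)
  if (r <= 0L) stop("region size r must be positive")
  h <- nrow(mask); w <- ncol(mask)
  hp <- ceiling(h / r) * r; wp <- ceiling(w / r) * r
  if (hp != h || wp != w) {
    padded <- matrix(0L, hp, wp)
    padded[seq_len(h), seq_len(w)] <- mask
    mask <- padded
    if (!is.null(feature)) {
      fp <- array(0, c(hp, wp, dim(feature)[3]))
      fp[seq_len(h), seq_len(w), ] <- feature
      feature <- fp
    }
  }
  nr <- hp %/% r; nc <- wp %/% r
  labels <- integer(nr * nc)
  feats <- if (is.null(feature)) NULL else vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      tile <- mask[(i - 1L) * r + seq_len(r), (j - 1L) * r + seq_len(r)]
      labels[k] <- region_label(tile, label_rule)
      if (!is.null(feature))
        feats[[k]] <- feature[(i - 1L) * r + seq_len(r),
                              (j - 1L) * r + seq_len(r), , drop = FALSE]
    }
  }
  structure(list(labels = labels, features = feats, r = r,
                 grid = c(nr, nc), label_rule = label_rule),
            class = "region_batch")
}

region_label <- function(tile, label_rule) {
  if (label_rule == "any_foreground") {
    as.integer(any(tile > 0L))
  } else {
    tab <- tabulate(as.integer(tile) + 1L)
    which.max(tab) - 1L
  }
}

#' Dataset-level region class frequencies
#'
#' Counts, over every r-by-r tile of every mask in the dataset, how many
#' regions contain each class: `F(C) = sum over regions of 1[C in
#' region]`. A tile holding both classes increments both counts. Computed
#' once on the training fold before training and kept fixed.
#'
#' @param dataset_masks list of integer label matrices.
#' @param r region side length.
#' @param n_classes number of classes L (default 2).
#' @param label_rule counting rule: `"presence"` (alias
#'   `"any_foreground"`) is the literal class-membership indicator;
#'   `"majority"` counts each tile once for its modal class.
#' @param smoothing additive pseudo-count applied when the frequencies
#'   are used as loss weights (default 1), guarding classes that never
#'   occur.
#' @return Object of class `region_frequencies`: integer `counts` (one
#'   per class) plus the smoothing constant.
#' @export
region_frequencies <- function(dataset_masks, r = 32L, n_classes = 2L,
                               label_rule = c("presence", "any_foreground",
                                              "majority"),
                               smoothing = 1) {
  label_rule <- match.arg(label_rule)
  if (label_rule == "any_foreground") label_rule <- "presence"
  if (length(dataset_masks) == 0L) stop("dataset_masks must be nonempty")
  counts <- integer(n_classes)
  for (mask in dataset_masks) {
    h <- nrow(mask); w <- ncol(mask)
    hp <- ceiling(h / r) * r; wp <- ceiling(w / r) * r
    if (hp != h || wp != w) {
      padded <- matrix(0L, hp, wp)
      padded[seq_len(h), seq_len(w)] <- mask
      mask <- padded
    }
    for (i in seq_len(hp %/% r)) {
      for (j in seq_len(wp %/% r)) {
        tile <- mask[(i - 1L) * r + seq_len(r), (j - 1L) * r + seq_len(r)]
        if (label_rule == "presence") {
          present <- unique(as.integer(tile))
          counts[present + 1L] <- counts[present + 1L] + 1L
        } else {
          m <- region_label(tile, "majority")
          counts[m + 1L] <- counts[m + 1L] + 1L
        }
      }
    }
  }
  structure(list(counts = counts, smoothing = smoothing),
            class = "region_frequencies")
}

region_weights <- function(freq) {
  w <- freq$counts + freq$smoothing
  if (any(w <= 0))
    stop("zero region frequency for a class; use smoothing > 0")
  w
}

#' Frequency-weighted region classification loss
#'
#' For region logits A and ground-truth class y, the loss is the mean of
#' \deqn{-\log\frac{F(y)\,e^{A_y}}{\sum_k F(k)\,e^{A_k}}}
#' over regions, where F are the (smoothed) dataset-level region class
#' frequencies. With uniform F the loss reduces exactly to softmax
#' cross-entropy. Stabilized by max-subtraction.
#'
#' @param logits numeric matrix (regions x L) or list of length-L vectors.
#' @param labels integer region labels in `0..L-1`.
#' @param freq a [region_frequencies()] object.
#' @return Scalar mean loss.
#' @export
region_loss <- function(logits, labels, freq) {
  stopifnot(inherits(freq, "region_frequencies"))
  if (is.list(logits)) logits <- do.call(rbind, logits)
  logits <- as.matrix(logits)
  labels <- as.integer(labels)
  if (nrow(logits) != length(labels)) stop("one label per region required")
  w <- region_weights(freq)
  if (length(w) != ncol(logits)) stop("frequency length must equal L")
  z <- sweep(logits, 2L, log(w), `+`)
  z <- z - apply(z, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  -mean(log(p[cbind(seq_len(nrow(p)), labels + 1L)]))
}

#' Combined pixel + region segmentation loss
#'
#' `Loss_all = Loss_pixel + w * Loss_region` with unit region weight by
#' default.
#'
#' @param pixel_loss,region_loss finite scalars.
#' @param region_weight multiplier on the region term.
#' @return Scalar.
#' @export
combined_seg_loss <- function(pixel_loss, region_loss, region_weight = 1) {
  stopifnot(is.finite(pixel_loss), is.finite(region_loss))
  pixel_loss + region_weight * region_loss
}
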