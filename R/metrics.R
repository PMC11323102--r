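# Confusion-count evaluation of binary segmentations, per-sample metrics
# aggregated as mean +/- sd, and an overlay renderer for visual checks.

#' Pixel confusion counts for a binary segmentation
#'
#' Foreground (1) is the positive class. Inputs must be binary matrices
#' of identical shape.
#'
#' @param pred_mask,truth binary matrices.
#' @return Object of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `fn`, `tn` summing to the pixel count.
#' @export
confusion <- function(pred_mask, truth) {
  if (!identical(dim(pred_mask), dim(truth))) stop("shape mismatch")
  if (!all(pred_mask %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  p <- pred_mask > 0; t <- truth > 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN), Jaccard = TP/(TP+FP+FN),
#' precision = TP/(TP+FP), recall = TP/(TP+FN). When both masks are empty
#' every metric is 1 by convention (perfect agreement) and the result is
#' flagged `degenerate`; an empty prediction against a nonempty truth has
#' precision 1 by convention (no false positives) and is flagged too.
#'
#' @param c a [confusion()] result.
#' @return List with `dice`, `jaccard`, `precision`, `recall` and a
#'   `degenerate` flag.
#' @export
seg_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  both_empty <- (c$tp + c$fp + c$fn) == 0
  if (both_empty) {
    return(list(dice = 1, jaccard = 1, precision = 1, recall = 1,
                degenerate = TRUE))
  }
  dice <- 2 * c$tp / (2 * c$tp + c$fp + c$fn)
  jac <- c$tp / (c$tp + c$fp + c$fn)
  prec <- if (c$tp + c$fp == 0) 1 else c$tp / (c$tp + c$fp)
  rec <- if (c$tp + c$fn == 0) 1 else c$tp / (c$tp + c$fn)
  list(dice = dice, jaccard = jac, precision = prec, recall = rec,
       degenerate = (c$tp + c$fp == 0) || (c$tp + c$fn == 0))
}

#' Aggregate per-sample metrics into a mean +/- sd table
#'
#' One row per fold plus a pooled `overall` row; the sd is the sample
#' standard deviation over samples. Metrics are averaged per sample, not
#' over pooled pixels.
#'
#' @param per_sample data.frame with columns `dice`, `jaccard`,
#'   `precision`, `recall` (e.g. rows of [seg_metrics()] results).
#' @param folds integer fold id per row (optional).
#' @param file optional CSV path to write the table to.
#' @return data.frame with columns `fold`, `n`, and `<metric>_mean` /
#'   `<metric>_sd` for each metric.
#' @export
aggregate_metrics <- function(per_sample, folds = NULL, file = NULL) {
  stopifnot(nrow(per_sample) > 0)
  cols <- c("dice", "jaccard", "precision", "recall")
  groups <- if (is.null(folds)) list() else split(seq_len(nrow(per_sample)),
                                                  folds)
  summarize <- function(idx, label) {
    row <- list(fold = label, n = length(idx))
    for (m in cols) {
      v <- per_sample[[m]][idx]
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_sd")]] <- if (length(v) > 1) stats::sd(v) else 0
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(names(groups), function(g) summarize(groups[[g]], g)),
    list(summarize(seq_len(nrow(per_sample)), "overall"))
  ))
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Render an overlay of prediction against truth
#'
#' Correctly segmented foreground is drawn green, missed foreground
#' (false negatives) red, and spurious foreground (false positives) blue
#' over the grayscale image; mis-segmented regions are therefore the red
#' and blue ones. Purely a visualization aid.
#'
#' @param image numeric matrix (grayscale) or `h x w x 3` array.
#' @param truth,pred binary matrices.
#' @param file output PNG path.
#' @return The file path, invisibly.
#' @export
overlay <- function(image, truth, pred, file) {
  if (length(dim(image)) == 3L) image <- image[, , 1L]
  if (!identical(dim(image), dim(truth)) || !identical(dim(truth), dim(pred)))
    stop("shape mismatch")
  rng <- range(image)
  g <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  rgb <- array(rep(g, 3L), c(dim(g), 3L))
  tpm <- pred > 0 & truth > 0
  fnm <- pred == 0 & truth > 0
  fpm <- pred > 0 & truth == 0
  paint <- function(rgb, m, col) {
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[m] <- col[k]
      rgb[, , k] <- ch
    }
    rgb
  }
  rgb <- paint(rgb, tpm, c(0.1, 0.8, 0.1))
  rgb <- paint(rgb, fnm, c(0.9, 0.1, 0.1))
  rgb <- paint(rgb, fpm, c(0.1, 0.2, 0.9))
  png::writePNG(rgb, file)
  invisible(file)
}
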