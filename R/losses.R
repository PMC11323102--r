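# The bespoke training objectives, as plain functions of arrays. The
# differentiable twins used inside the training graph live in
# nn-losses.R; tests hold the two implementations together.

#' Bundle projection embeddings and class embeddings for the 2C loss
#'
#' @param image_proj numeric matrix, one row per sample: the projection
#'   `l(I_i)` of each image produced by the discriminator head.
#' @param class_embed numeric matrix with one row per class: the learned
#'   class embeddings `e(M)`.
#' @param labels integer vector of class ids in `0..L-1`, one per sample.
#' @param temperature positive scalar temperature dividing every
#'   similarity before exponentiation (default 3).
#' @return An object of class `embedding_batch`.
#' @export
embedding_batch <- function(image_proj, class_embed, labels, temperature = 3) {
  image_proj <- as.matrix(image_proj)
  class_embed <- as.matrix(class_embed)
  labels <- as.integer(labels)
  if (temperature <= 0) stop("temperature must be > 0")
  if (!all(is.finite(image_proj)) || !all(is.finite(class_embed)))
    stop("embeddings must be finite")
  if (ncol(image_proj) != ncol(class_embed))
    stop("image projections and class embeddings must share dimension d")
  if (length(labels) != nrow(image_proj))
    stop("one label per projection row required")
  if (any(labels < 0) || any(labels >= nrow(class_embed)))
    stop("labels must index rows of class_embed (0-based)")
  structure(list(image_proj = image_proj, class_embed = class_embed,
                 labels = labels, temperature = temperature),
            class = "embedding_batch")
}

#' Conditional contrastive (2C) loss
#'
#' For anchor i with projection l_i, label y_i and class embedding e_{y_i},
#' the loss is
#' \deqn{-\log\frac{e^{\langle l_i, e_{y_i}\rangle/t} +
#'   \sum_{j \ne i, y_j = y_i} e^{\langle l_i, l_j\rangle/t}}
#'  {e^{\langle l_i, e_{y_i}\rangle/t} + \sum_{j \ne i}
#'   e^{\langle l_i, l_j\rangle/t}}}
#' i.e. the same-class similarity mass over the all-pairs mass, so the
#' loss is zero when no cross-class similarity term contributes. With
#' `anchor = NULL` the batch loss is the mean over all anchors.
#' Log-sum-exp stabilized.
#'
#' @param batch an [embedding_batch()].
#' @param anchor 1-based anchor index, or `NULL` for the batch mean.
#' @return Non-negative scalar.
#' @export
two_c_loss <- function(batch, anchor = NULL) {
  stopifnot(inherits(batch, "embedding_batch"))
  P <- batch$image_proj; E <- batch$class_embed
  y <- batch$labels; t <- batch$temperature
  n <- nrow(P)
  S <- tcrossprod(P) / t
  se <- rowSums(P * E[y + 1L, , drop = FALSE]) / t
  lse <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }
  one <- function(i) {
    others <- setdiff(seq_len(n), i)
    same <- others[y[others] == y[i]]
    lse(c(se[i], S[i, others])) - lse(c(se[i], S[i, same]))
  }
  if (!is.null(anchor)) {
    if (anchor < 1 || anchor > n) stop("anchor out of range")
    return(one(anchor))
  }
  mean(vapply(seq_len(n), one, 0))
}

#' Mean absolute (L1) segmentation loss
#'
#' Mean absolute difference between a predicted per-class probability map
#' and its target, normalized by the element count so the value is
#' resolution-independent.
#'
#' @param pred,target numeric arrays of identical shape.
#' @return Non-negative scalar.
#' @export
l1_seg_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(target), collapse = "x"))
  mean(abs(pred - target))
}

#' Adversarial segmentation objective
#'
#' Combines the conditional contrastive term with the L1 term,
#' `m_seg = 2C + lambda_l1 * L1`. The unweighted form (`lambda_l1 = 1`)
#' is the default.
#'
#' @param two_c scalar 2C loss value.
#' @param l1 scalar L1 loss value.
#' @param lambda_l1 weight on the L1 term.
#' @return Scalar.
#' @export
adversarial_seg_loss <- function(two_c, l1, lambda_l1 = 1) {
  stopifnot(is.finite(two_c), is.finite(l1))
  two_c + lambda_l1 * l1
}

#' Supervised contrastive loss of the correction network
#'
#' Attraction of an anchor embedding to a positive set and repulsion from
#' a negative set:
#' \deqn{-\log\frac{\sum_p e^{sim(F_i,F_p)}}{\sum_p e^{sim(F_i,F_p)} +
#'   \sum_n e^{sim(F_i,F_n)}}}
#' `as_printed = TRUE` switches to the literal product-of-softmaxes form
#' \eqn{\log(\mathrm{pos\ softmax} \cdot \mathrm{neg\ softmax})}, which
#' lacks the minus sign and rewards similarity to negatives; it is kept
#' only for comparison and is not used in training.
#'
#' @param anchor numeric vector embedding.
#' @param positives,negatives lists of numeric vectors (nonempty).
#' @param sim similarity: cosine (default) or dot product.
#' @param as_printed use the literal product form (see Details).
#' @return Scalar.
#' @export
scoln_contrastive_loss <- function(anchor, positives, negatives,
                                   sim = c("cosine", "dot"),
                                   as_printed = FALSE) {
  sim <- match.arg(sim)
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("positives and negatives must both be nonempty")
  s <- function(a, b) {
    if (sim == "cosine") sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)) + 1e-12)
    else sum(a * b)
  }
  sp <- vapply(positives, s, 0, a = anchor)
  sn <- vapply(negatives, s, 0, a = anchor)
  mx <- max(c(sp, sn))
  ep <- exp(sp - mx); en <- exp(sn - mx)
  if (as_printed) {
    # literal form: log of (first-positive softmax over all) times
    # (first-negative softmax over negatives)
    all_ <- c(ep, en)
    log(ep[1L] / sum(all_)) + log(en[1L] / sum(en))
  } else {
    -log(sum(ep) / (sum(ep) + sum(en)))
  }
}

#' False-negative / false-positive correction maps
#'
#' Given a foreground probability map and the binary ground truth g, the
#' missed-foreground map is `clamp(g - pred, 0, 1)` and the spurious-
#' foreground map is `clamp(pred - g, 0, 1)`. For binary `pred` the two
#' maps have disjoint support.
#'
#' @param pred numeric matrix in `[0, 1]`.
#' @param g binary matrix of the same shape.
#' @return Object of class `correction_maps` with elements `fn_map` and
#'   `fp_map`.
#' @export
correction_maps <- function(pred, g) {
  if (!identical(dim(pred), dim(g))) stop("pred and g shapes differ")
  if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]")
  fn_map <- pmin(pmax(g - pred, 0), 1)
  fp_map <- pmin(pmax(pred - g, 0), 1)
  structure(list(fn_map = fn_map, fp_map = fp_map), class = "correction_maps")
}

#' Final corrected objective
#'
#' Adds the false-negative mass and subtracts the false-positive mass
#' from the adversarial segmentation objective:
#' `loss = m_seg - FP + FN`. By default the two map "counts" enter as
#' spatial means so the term does not grow with image resolution; set
#' `reduce = "count"` for raw pixel counts.
#'
#' @param m_seg scalar adversarial segmentation loss.
#' @param maps a [correction_maps()] object.
#' @param reduce `"mean"` (default) or `"count"`.
#' @return Scalar.
#' @export
final_objective <- function(m_seg, maps, reduce = c("mean", "count")) {
  reduce <- match.arg(reduce)
  stopifnot(is.finite(m_seg), inherits(maps, "correction_maps"))
  red <- if (reduce == "mean") mean else sum
  m_seg - red(maps$fp_map) + red(maps$fn_map)
}

#' Apply correction maps to a predicted mask
#'
#' The corrected score is `clamp(pred + fn_map - fp_map, 0, 1)`,
#' binarized at `threshold`. With oracle maps computed from the ground
#' truth this reproduces the truth exactly for any binary prediction.
#'
#' @param pred numeric matrix of foreground scores.
#' @param maps a [correction_maps()] object.
#' @param threshold binarization threshold (default 0.5).
#' @return Binary integer matrix.
#' @export
corrected_mask <- function(pred, maps, threshold = 0.5) {
  stopifnot(inherits(maps, "correction_maps"))
  if (!identical(dim(pred), dim(maps$fn_map))) stop("shape mismatch")
  score <- pmin(pmax(pred + maps$fn_map - maps$fp_map, 0), 1)
  out <- matrix(as.integer(score >= threshold), nrow(pred), ncol(pred))
  out
}
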