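# Class-specific channel attention. Channels of the transformed map are
# grouped contiguously by class: with x channels per class, class j
# (0-based j in 0..L-1) owns channels j*x + 1 .. j*x + x. Each class gets
# a score (mean of global-max-pooled channels) and a semantic map (mean
# of its channels); the score-weighted average of semantic maps is the
# attention map that reweights the block input.

#' Attention configuration
#'
#' @param channels_per_class number of transformed channels dedicated to
#'   each class (x >= 1).
#' @param num_classes total classes L (>= 2 for segmentation; 1 is
#'   permitted for degenerate checks).
#' @param levels integer block indices of the generator at which the
#'   attention block is inserted; blocks are numbered 1..2*levels with
#'   the encoder first, and the default (2 and 6) places attention in the
#'   second encoder block and the sixth block overall.
#' @return Object of class `attention_config`.
#' @export
attention_config <- function(channels_per_class = 4L, num_classes = 2L,
                             levels = c(2L, 6L)) {
  stopifnot(channels_per_class >= 1L, num_classes >= 1L)
  structure(list(x = as.integer(channels_per_class),
                 L = as.integer(num_classes),
                 levels = as.integer(levels)),
            class = "attention_config")
}

#' Initialize attention transform parameters
#'
#' Depthwise 3x3 filters (one per input channel), a pointwise projection
#' to `x * L` channels, and channel-normalization gain/bias. Uses the
#' caller's RNG stream.
#'
#' @param c_in input channel count.
#' @param cfg an [attention_config()].
#' @return Parameter list consumed by [attention_transform()].
#' @export
attention_params <- function(c_in, cfg) {
  stopifnot(inherits(cfg, "attention_config"))
  list(
    dw_w = array(stats::rnorm(9 * c_in, sd = sqrt(2 / 9)), c(3, 3, c_in)),
    dw_b = rep(0, c_in),
    pw_w = array(stats::rnorm(c_in * cfg$x * cfg$L, sd = sqrt(2 / c_in)),
                 c(1, 1, c_in, cfg$x * cfg$L)),
    pw_b = rep(0, cfg$x * cfg$L),
    gamma = rep(1, cfg$x * cfg$L),
    beta = rep(0, cfg$x * cfg$L)
  )
}

as_batch <- function(x3) array(x3, c(dim(x3), 1L))
drop_batch <- function(x4) array(x4, dim(x4)[1:3])

#' Depthwise-separable transform of the attention block
#'
#' Computes `ReLU(Norm(DepthwiseSeparableConv3x3(input)))`: a depthwise
#' 3x3 convolution followed by a pointwise projection to `x * L`
#' channels, per-channel normalization (skipped when
#' `normalize = FALSE`), and a ReLU, so every output entry is
#' non-negative.
#'
#' @param input numeric array `h x w x c`.
#' @param cfg an [attention_config()].
#' @param params parameter list from [attention_params()].
#' @param normalize apply channel normalization (default TRUE).
#' @return Numeric array `h x w x (x*L)`.
#' @export
attention_transform <- function(input, cfg, params, normalize = TRUE) {
  stopifnot(inherits(cfg, "attention_config"))
  if (!all(is.finite(input))) stop("input must be finite")
  d <- dim(input)
  x4 <- as_batch(input)
  cols <- im2col_cpp(x4, d[1], d[2], d[3], 1L, 3L, 1L, 1L)
  dw <- matrix(0, nrow(cols), d[3])
  for (c in seq_len(d[3])) {
    block <- (c - 1L) * 9L + seq_len(9L)
    dw[, c] <- cols[, block, drop = FALSE] %*% as.vector(params$dw_w[, , c]) +
      params$dw_b[c]
  }
  pw <- dw %*% matrix(params$pw_w, d[3]) +
    rep(params$pw_b, each = nrow(dw))
  if (normalize) {
    mu <- colMeans(pw)
    sdv <- sqrt(colMeans(sweep(pw, 2L, mu)^2) + 1e-5)
    pw <- sweep(sweep(pw, 2L, mu), 2L, sdv, `/`)
    pw <- sweep(sweep(pw, 2L, params$gamma, `*`), 2L, params$beta, `+`)
  }
  array(pmax(pw, 0), c(d[1], d[2], cfg$x * cfg$L))
}

check_grouping <- function(transformed, cfg) {
  ch <- dim(transformed)[3]
  if (ch %% cfg$L != 0L)
    stop("channel count ", ch, " is not divisible by L = ", cfg$L)
  if (ch != cfg$x * cfg$L)
    stop("transformed map must have x*L = ", cfg$x * cfg$L, " channels")
  invisible(NULL)
}

#' Per-class scores from a transformed map
#'
#' `C_j = (1/x) * sum_k globalmax(channel (j,k))`: global maximum pooling
#' over the spatial grid, averaged over the x channels of each class.
#'
#' @param transformed array `h x w x (x*L)` from [attention_transform()].
#' @param cfg an [attention_config()].
#' @return Numeric vector of length L.
#' @export
class_scores <- function(transformed, cfg) {
  check_grouping(transformed, cfg)
  d <- dim(transformed)
  m <- matrix(transformed, d[1] * d[2], d[3])
  mx <- apply(m, 2L, max)
  colMeans(matrix(mx, cfg$x, cfg$L))
}

#' Per-class semantic maps
#'
#' The semantic map of class j is the mean of its x channels,
#' yielding an `h x w x L` array.
#'
#' @inheritParams class_scores
#' @return Numeric array `h x w x L`.
#' @export
class_semantic_map <- function(transformed, cfg) {
  check_grouping(transformed, cfg)
  d <- dim(transformed)
  arr <- array(transformed, c(d[1] * d[2], cfg$x, cfg$L))
  out <- array(0, c(d[1], d[2], cfg$L))
  for (j in seq_len(cfg$L)) {
    out[, , j] <- rowMeans(matrix(arr[, , j], d[1] * d[2], cfg$x))
  }
  out
}

#' Class-specific attention map
#'
#' Score-weighted mean of the class semantic maps:
#' `C_A = (1/L) * sum_j scores[j] * semantic[,,j]`.
#'
#' @param scores numeric vector of length L from [class_scores()].
#' @param semantic array `h x w x L` from [class_semantic_map()].
#' @return Numeric matrix `h x w`.
#' @export
attention_map <- function(scores, semantic) {
  L <- dim(semantic)[3]
  if (length(scores) != L)
    stop("length(scores) = ", length(scores), " but semantic has ", L,
         " class planes")
  d <- dim(semantic)
  matrix(matrix(semantic, d[1] * d[2], L) %*% scores / L, d[1], d[2])
}

#' Reweight a feature map by an attention map
#'
#' Element-wise product broadcast over channels:
#' `out[,,c] = input[,,c] * att`.
#'
#' @param input array `h x w x c`.
#' @param att matrix `h x w`.
#' @return Array with the shape of `input`.
#' @export
apply_attention <- function(input, att) {
  d <- dim(input)
  if (!identical(d[1:2], dim(att)))
    stop("spatial shapes differ: ", paste(d[1:2], collapse = "x"), " vs ",
         paste(dim(att), collapse = "x"))
  input * as.vector(att)
}

#' Run a full attention block on a feature map
#'
#' Transform, score, build the attention map and reweight the input; the
#' output has the input's shape, so the block composes residually inside
#' the generator.
#'
#' @inheritParams attention_transform
#' @return Array with the shape of `input`.
#' @export
attention_block <- function(input, cfg, params, normalize = TRUE) {
  tr <- attention_transform(input, cfg, params, normalize)
  s <- class_scores(tr, cfg)
  sem <- class_semantic_map(tr, cfg)
  apply_attention(input, attention_map(s, sem))
}

#' Export an attention map as a PNG heatmap
#'
#' Utility for visual inspection; linearly rescales the map to `[0, 1]`.
#'
#' @param att numeric matrix.
#' @param file output PNG path.
#' @return The file path, invisibly.
#' @export
write_attention_png <- function(att, file) {
  rng <- range(att)
  z <- if (diff(rng) > 0) (att - rng[1]) / diff(rng) else att * 0
  png::writePNG(z, file)
  invisible(file)
}
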