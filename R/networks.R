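# The three networks: a conditional encoder-decoder generator with skip
# connections, class-specific attention blocks and a training-only region
# classification head; a convolutional discriminator with a projection
# head for the 2C loss; and the SCoLN corrector, a small UNet predicting
# false-negative / false-positive maps.
#
# Blocks are numbered 1..2*levels, encoder first; the attention defaults
# (blocks 2 and 6) put one block in the second encoder stage and one in
# the decoder.

#' Generator configuration
#'
#' @param levels encoder depth; each level halves the spatial size
#'   (default 4).
#' @param base_filters channels of the first encoder level, doubled per
#'   level (default 16).
#' @param attention_levels block indices receiving a class-specific
#'   attention block (default `c(2, 6)`), or `integer(0)` for none.
#' @param rrm_enabled attach the region-rebalance classifier head at the
#'   deepest encoder level (training only).
#' @param dropout_rate train-time dropout in the decoder; this is the
#'   generator's stochastic input `n` (default 0.25).
#' @param channels_per_class attention channels per class (default 4).
#' @param region_size region side in input pixels for the RRM head
#'   (default 32); must be divisible by `2^levels`.
#' @param proj_dim dimension of the discriminator projection and class
#'   embeddings (default 64).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(levels = 4L, base_filters = 16L,
                             attention_levels = c(2L, 6L),
                             rrm_enabled = TRUE, dropout_rate = 0.25,
                             channels_per_class = 4L, region_size = 32L,
                             proj_dim = 64L) {
  stopifnot(levels >= 1L, base_filters >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  attention_levels <- as.integer(attention_levels)
  if (length(attention_levels) && any(attention_levels < 1L |
                                      attention_levels > 2L * levels))
    stop("attention_levels must lie in 1..", 2L * levels)
  if (region_size %% 2L^levels != 0L)
    stop("region_size must be divisible by 2^levels")
  structure(list(levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 attention_levels = attention_levels,
                 rrm_enabled = isTRUE(rrm_enabled),
                 dropout_rate = dropout_rate,
                 channels_per_class = as.integer(channels_per_class),
                 region_size = as.integer(region_size),
                 proj_dim = as.integer(proj_dim)),
            class = "generator_config")
}

enc_filters <- function(cfg) cfg$base_filters * 2L^(seq_len(cfg$levels) - 1L)

new_attention_block <- function(c_in, xc, L, name) {
  list(dw_w = init_depthwise(3L, c_in, paste0(name, ".dw_w")),
       dw_b = init_bias(c_in, paste0(name, ".dw_b")),
       pw_w = init_conv(1L, c_in, xc * L, paste0(name, ".pw_w")),
       pw_b = init_bias(xc * L, paste0(name, ".pw_b")),
       norm = norm_param(xc * L, paste0(name, ".norm")))
}

#' Build the conditional generator
#'
#' Encoder: a 5x5 stride-2 convolution, then 3x3 stride-2 convolutions,
#' each followed by channel normalization and ReLU. Decoder: nearest
#' 2x resize, concatenation of the matching encoder features (block l
#' with block t-l), 3x3 stride-1 convolution, normalization, ReLU, with
#' train-time dropout as the stochastic input. A final 1x1 convolution
#' and channel softmax emit per-pixel class probabilities.
#'
#' @param cfg a [generator_config()].
#' @param L number of classes (output channels).
#' @param c_in input image channels.
#' @param seed optional seed for weight initialization.
#' @return Object of class `ccgan_generator`.
#' @export
build_generator <- function(cfg, L = 2L, c_in = 1L, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  f <- enc_filters(cfg)
  p <- list()
  prev <- c_in
  for (l in seq_len(cfg$levels)) {
    k <- if (l == 1L) 5L else 3L
    p[[paste0("enc", l, "_w")]] <- init_conv(k, prev, f[l], paste0("enc", l))
    p[[paste0("enc", l, "_b")]] <- init_bias(f[l])
    p[[paste0("enc", l, "_n")]] <- norm_param(f[l])
    prev <- f[l]
  }
  for (l in seq_len(cfg$levels)) {
    skip_c <- if (l < cfg$levels) f[cfg$levels - l] else c_in
    out_c <- if (l < cfg$levels) f[cfg$levels - l] else cfg$base_filters
    p[[paste0("dec", l, "_w")]] <- init_conv(3L, prev + skip_c, out_c,
                                             paste0("dec", l))
    p[[paste0("dec", l, "_b")]] <- init_bias(out_c)
    p[[paste0("dec", l, "_n")]] <- norm_param(out_c)
    prev <- out_c
  }
  p$head_w <- init_conv(1L, prev, L, "head")
  p$head_b <- init_bias(L)
  att <- list()
  for (b in cfg$attention_levels) {
    ch <- block_channels(cfg, b, L, c_in)
    att[[as.character(b)]] <- new_attention_block(ch, cfg$channels_per_class,
                                                  L, paste0("att", b))
  }
  rrm <- NULL
  if (cfg$rrm_enabled) {
    cb <- f[cfg$levels]
    rrm <- list(conv_w = init_conv(3L, cb, cb, "rrm.conv"),
                conv_b = init_bias(cb),
                fc_w = init_dense(cb, L, "rrm.fc"),
                fc_b = init_bias(L))
  }
  structure(list(cfg = cfg, L = L, c_in = c_in, params = p,
                 attention = att, rrm = rrm),
            class = "ccgan_generator")
}

block_channels <- function(cfg, b, L, c_in) {
  f <- enc_filters(cfg)
  if (b <= cfg$levels) f[b]
  else {
    l <- b - cfg$levels
    if (l < cfg$levels) f[cfg$levels - l] else cfg$base_filters
  }
}

#' Flat list of a network's trainable parameters
#'
#' Used by the optimizer and by parameter snapshots; normalization gains
#' and biases are included.
#' @param net a built network.
#' @return List of parameter environments.
#' @export
network_params <- function(net) {
  out <- list()
  grab <- function(x) {
    if (is.environment(x)) {
      if (!is.null(x$gamma)) { out[[length(out) + 1L]] <<- x$gamma
                               out[[length(out) + 1L]] <<- x$beta }
      else out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) lapply(x, grab)
    invisible(NULL)
  }
  grab(net$params); grab(net$attention); grab(net$rrm); grab(net$embed)
  out
}

#' Snapshot all parameter values of a network
#' @param net a built network.
#' @return List of numeric copies, aligned with [network_params()].
#' @export
snapshot_params <- function(net) lapply(network_params(net), function(p) p$val)

network_norms <- function(net) {
  out <- list()
  grab <- function(x) {
    if (is.environment(x)) {
      if (!is.null(x$gamma)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) lapply(x, grab)
    invisible(NULL)
  }
  grab(net$params); grab(net$attention); grab(net$rrm)
  out
}

# Full state snapshot (weights plus normalization running moments) and
# its inverse, used to restore the best-epoch checkpoint.
snapshot_network <- function(net) {
  list(params = snapshot_params(net),
       norms = lapply(network_norms(net), function(n)
         list(m = n$run_mean, v = n$run_var)))
}

restore_network <- function(net, snap) {
  ps <- network_params(net)
  for (j in seq_along(ps)) ps[[j]]$val <- snap$params[[j]]
  ns <- network_norms(net)
  for (j in seq_along(ns)) {
    ns[[j]]$run_mean <- snap$norms[[j]]$m
    ns[[j]]$run_var <- snap$norms[[j]]$v
  }
  invisible(net)
}

run_attention_block <- function(tape, x, blk, xc, L) {
  h <- op_depthwise_conv(tape, x, blk$dw_w, blk$dw_b)
  h <- op_conv(tape, h, blk$pw_w, blk$pw_b)
  h <- op_norm(tape, h, blk$norm)
  h <- op_relu(tape, h)
  op_class_attention(tape, h, x, xc, L)
}

#' Generator forward pass
#'
#' @param gen a [build_generator()] network.
#' @param x input images, `h x w x c x n` array.
#' @param tape a tape from `new_tape()`; its `training` flag controls
#'   dropout and normalization statistics.
#' @param ablation character subset of `c("attention", "rrm")`: modules
#'   to bypass.
#' @param with_rrm also compute the region head features (training only).
#' @return List with nodes `logits`, `probs` (`h x w x L x n`) and, when
#'   requested, `rrm_pooled` (region features ready for the classifier).
#' @export
forward_generator <- function(gen, x, tape, ablation = character(),
                              with_rrm = FALSE) {
  cfg <- gen$cfg; p <- gen$params
  use_att <- !("attention" %in% ablation)
  xn <- if (inherits(x, "environment")) x else op_input(tape, x)
  cur <- xn
  skips <- list()
  for (l in seq_len(cfg$levels)) {
    skips[[l]] <- cur
    cur <- op_conv(tape, cur, p[[paste0("enc", l, "_w")]],
                   p[[paste0("enc", l, "_b")]], stride = 2L)
    cur <- op_norm(tape, cur, p[[paste0("enc", l, "_n")]])
    cur <- op_relu(tape, cur)
    key <- as.character(l)
    if (use_att && !is.null(gen$attention[[key]]))
      cur <- run_attention_block(tape, cur, gen$attention[[key]],
                                 cfg$channels_per_class, gen$L)
  }
  rrm_pooled <- NULL
  if (with_rrm && !is.null(gen$rrm) && !("rrm" %in% ablation)) {
    rf <- cfg$region_size %/% 2L^cfg$levels
    rh <- op_conv(tape, cur, gen$rrm$conv_w, gen$rrm$conv_b)
    rh <- op_relu(tape, rh)
    pooled <- op_region_pool(tape, rh, rf)
    rrm_pooled <- op_dense(tape, pooled, gen$rrm$fc_w, gen$rrm$fc_b)
  }
  for (l in seq_len(cfg$levels)) {
    cur <- op_upsample2x(tape, cur)
    skip <- skips[[cfg$levels - l + 1L]]
    cur <- op_concat_channels(tape, list(cur, skip))
    cur <- op_conv(tape, cur, p[[paste0("dec", l, "_w")]],
                   p[[paste0("dec", l, "_b")]])
    cur <- op_norm(tape, cur, p[[paste0("dec", l, "_n")]])
    cur <- op_relu(tape, cur)
    if (cfg$dropout_rate > 0) cur <- op_dropout(tape, cur, cfg$dropout_rate)
    key <- as.character(cfg$levels + l)
    if (use_att && !is.null(gen$attention[[key]]))
      cur <- run_attention_block(tape, cur, gen$attention[[key]],
                                 cfg$channels_per_class, gen$L)
  }
  logits <- op_conv(tape, cur, p$head_w, p$head_b)
  probs <- op_softmax_channels(tape, logits)
  list(logits = logits, probs = probs, rrm_logits = rrm_pooled, input = xn)
}

#' Build the discriminator
#'
#' Same structure as the generator's encoder, on the concatenation of the
#' input image and a per-pixel class probability map; global average
#' pooling feeds a real/fake head and a `proj_dim` projection used by the
#' 2C loss. Owns the learned class embeddings.
#'
#' @inheritParams build_generator
#' @return Object of class `ccgan_discriminator`.
#' @export
build_discriminator <- function(cfg, L = 2L, c_in = 1L, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  f <- enc_filters(cfg)
  p <- list()
  prev <- c_in + L
  for (l in seq_len(cfg$levels)) {
    k <- if (l == 1L) 5L else 3L
    p[[paste0("enc", l, "_w")]] <- init_conv(k, prev, f[l], paste0("d.enc", l))
    p[[paste0("enc", l, "_b")]] <- init_bias(f[l])
    p[[paste0("enc", l, "_n")]] <- norm_param(f[l])
    prev <- f[l]
  }
  p$out_w <- init_dense(prev, 1L, "d.out")
  p$out_b <- init_bias(1L)
  p$proj_w <- init_dense(prev, cfg$proj_dim, "d.proj")
  p$proj_b <- init_bias(cfg$proj_dim)
  embed <- nn_param(matrix(stats::rnorm(L * cfg$proj_dim,
                                        sd = 1 / sqrt(cfg$proj_dim)),
                           L, cfg$proj_dim), "d.class_embed")
  structure(list(cfg = cfg, L = L, c_in = c_in, params = p, embed = embed),
            class = "ccgan_discriminator")
}

#' Discriminator forward pass
#'
#' @param disc a [build_discriminator()] network.
#' @param x image node or array `h x w x c x n`.
#' @param probs mask-probability node or array `h x w x L x n`.
#' @param tape tape.
#' @return List with `logit` (N x 1 real/fake logit node), `prob`
#'   (sigmoid values), and `proj` (row-normalized N x d projection node).
#' @export
forward_discriminator <- function(disc, x, probs, tape) {
  xn <- if (is.environment(x)) x else op_input(tape, x)
  pn <- if (is.environment(probs)) probs else op_input(tape, probs)
  cur <- op_concat_channels(tape, list(xn, pn))
  p <- disc$params
  for (l in seq_len(disc$cfg$levels)) {
    cur <- op_conv(tape, cur, p[[paste0("enc", l, "_w")]],
                   p[[paste0("enc", l, "_b")]], stride = 2L)
    cur <- op_norm(tape, cur, p[[paste0("enc", l, "_n")]])
    cur <- op_relu(tape, cur)
  }
  pooled <- op_gap(tape, cur)
  logit <- op_dense(tape, pooled, p$out_w, p$out_b)
  proj <- op_l2_rows(tape, op_dense(tape, pooled, p$proj_w, p$proj_b))
  list(logit = logit, prob = 1 / (1 + exp(-logit$val)), proj = proj)
}

#' Build the SCoLN correction network
#'
#' A compact UNet on the concatenation of the image and the generator's
#' foreground probability map: two stride-2 encoder stages, bilinear
#' upsampling with skip concatenation in the decoder, and a 1x1 head
#' emitting two sigmoid maps (predicted false-negative and
#' false-positive maps). The bottleneck's pooled embedding feeds the
#' supervised contrastive term.
#'
#' @inheritParams build_generator
#' @return Object of class `ccgan_scoln`.
#' @export
build_scoln <- function(cfg, c_in = 1L, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  fb <- cfg$base_filters
  p <- list(
    enc1_w = init_conv(3L, c_in + 1L, fb, "s.enc1"), enc1_b = init_bias(fb),
    enc1_n = norm_param(fb),
    enc2_w = init_conv(3L, fb, 2L * fb, "s.enc2"), enc2_b = init_bias(2L * fb),
    enc2_n = norm_param(2L * fb),
    dec1_w = init_conv(3L, 3L * fb, fb, "s.dec1"), dec1_b = init_bias(fb),
    dec1_n = norm_param(fb),
    dec2_w = init_conv(3L, fb + c_in + 1L, fb, "s.dec2"),
    dec2_b = init_bias(fb), dec2_n = norm_param(fb),
    head_w = init_conv(1L, fb, 2L, "s.head"), head_b = init_bias(2L)
  )
  structure(list(cfg = cfg, c_in = c_in, params = p), class = "ccgan_scoln")
}

#' SCoLN forward pass
#'
#' @param sc a [build_scoln()] network.
#' @param x image node or array.
#' @param fg_prob foreground probability node or array `h x w x 1 x n`.
#' @param tape tape.
#' @return List with `logits` (`h x w x 2 x n` node), `maps` (sigmoid
#'   node: channel 1 the predicted false-negative map, channel 2 the
#'   false-positive map) and `embed` (row-normalized bottleneck
#'   embedding node).
#' @export
forward_scoln <- function(sc, x, fg_prob, tape) {
  xn <- if (is.environment(x)) x else op_input(tape, x)
  fn <- if (is.environment(fg_prob)) fg_prob else op_input(tape, fg_prob)
  inp <- op_concat_channels(tape, list(xn, fn))
  p <- sc$params
  e1 <- op_relu(tape, op_norm(tape, op_conv(tape, inp, p$enc1_w, p$enc1_b,
                                            stride = 2L), p$enc1_n))
  e2 <- op_relu(tape, op_norm(tape, op_conv(tape, e1, p$enc2_w, p$enc2_b,
                                            stride = 2L), p$enc2_n))
  embed <- op_l2_rows(tape, op_gap(tape, e2))
  d1 <- op_upsample_bilinear2x(tape, e2)
  d1 <- op_concat_channels(tape, list(d1, e1))
  d1 <- op_relu(tape, op_norm(tape, op_conv(tape, d1, p$dec1_w, p$dec1_b),
                              p$dec1_n))
  d2 <- op_upsample_bilinear2x(tape, d1)
  d2 <- op_concat_channels(tape, list(d2, inp))
  d2 <- op_relu(tape, op_norm(tape, op_conv(tape, d2, p$dec2_w, p$dec2_b),
                              p$dec2_n))
  logits <- op_conv(tape, d2, p$head_w, p$head_b)
  maps <- op_sigmoid(tape, logits)
  list(logits = logits, maps = maps, embed = embed)
}
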