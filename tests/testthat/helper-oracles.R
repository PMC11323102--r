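# Independent brute-force oracles: plain scalar loops, no shared code with
# the package internals they check.

oracle_two_c <- function(P, E, y, t) {
  n <- nrow(P)
  total <- 0
  for (i in seq_len(n)) {
    num <- exp(sum(P[i, ] * E[y[i] + 1L, ]) / t)
    den <- num
    for (j in seq_len(n)) {
      if (j == i) next
      s <- exp(sum(P[i, ] * P[j, ]) / t)
      den <- den + s
      if (y[j] == y[i]) num <- num + s
    }
    total <- total - log(num / den)
  }
  total / n
}

oracle_scon <- function(anchor, positives, negatives, sim = "cosine") {
  s <- function(a, b) {
    if (sim == "cosine") sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)) + 1e-12)
    else sum(a * b)
  }
  sp <- 0; sn <- 0
  for (p in positives) sp <- sp + exp(s(anchor, p))
  for (q in negatives) sn <- sn + exp(s(anchor, q))
  -log(sp / (sp + sn))
}

oracle_region_loss <- function(logits, labels, w) {
  total <- 0
  for (i in seq_len(nrow(logits))) {
    den <- 0
    for (k in seq_len(ncol(logits))) den <- den + w[k] * exp(logits[i, k])
    total <- total - log(w[labels[i] + 1L] * exp(logits[i, labels[i] + 1L]) / den)
  }
  total / nrow(logits)
}

oracle_softmax_ce <- function(logits, labels) {
  total <- 0
  for (i in seq_len(nrow(logits))) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    total <- total - log(p[labels[i] + 1L])
  }
  total / nrow(logits)
}

oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] > 0 && truth[i, j] > 0) tp <- tp + 1L
      else if (pred[i, j] > 0) fp <- fp + 1L
      else if (truth[i, j] > 0) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Plain nested-loop depthwise-separable 3x3 convolution (zero padding).
oracle_dwsep_conv <- function(x, dw_w, dw_b, pw_w, pw_b) {
  d <- dim(x)
  mid <- array(0, d)
  for (c in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- dw_b[c]
        for (ki in 1:3) {
          for (kj in 1:3) {
            ii <- i + ki - 2L; jj <- j + kj - 2L
            if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
              acc <- acc + x[ii, jj, c] * dw_w[ki, kj, c]
          }
        }
        mid[i, j, c] <- acc
      }
    }
  }
  f <- dim(pw_w)[4]
  out <- array(0, c(d[1], d[2], f))
  for (k in seq_len(f)) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- pw_b[k]
        for (c in seq_len(d[3])) acc <- acc + mid[i, j, c] * pw_w[1, 1, c, k]
        out[i, j, k] <- acc
      }
    }
  }
  out
}

fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

random_embedding_batch <- function(n, d, L, t = 3) {
  P <- matrix(rnorm(n * d), n, d)
  P <- P / sqrt(rowSums(P^2))
  E <- matrix(rnorm(L * d), L, d)
  E <- E / sqrt(rowSums(E^2))
  y <- sample(0:(L - 1L), n, replace = TRUE)
  embedding_batch(P, E, y, t)
}

tiny_dataset <- function(n = 10, size = 16, frac = 0.06, seed = 42) {
  ds <- generate_synthetic(synth_config(n, size, frac,
                                        n_lesions_range = c(1, 2),
                                        seed = seed))
  lapply(ds, preprocess, target_size = size)
}

tiny_gen_cfg <- function(...) {
  generator_config(levels = 2L, base_filters = 4L, attention_levels = c(2L, 4L),
                   channels_per_class = 2L, region_size = 8L, proj_dim = 8L,
                   ...)
}

tiny_train_cfg <- function(...) {
  args <- utils::modifyList(
    list(epochs = 1L, batch_size = 4L, optimizer = "adam", lr = 0.002,
         folds = 2L, early_stop_patience = 3L, seed = 7L),
    list(...))
  do.call(train_config, args)
}
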