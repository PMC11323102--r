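# Scalar loss nodes with analytic gradients. Each has a pure-R oracle twin
# in losses.R / rebalance.R; tests assert the two agree.

# Pixel-wise softmax cross-entropy from logits (H x W x L x N) against an
# integer mask array (H x W x N, values 0..L-1).
loss_pixel_ce <- function(tape, logits, masks) {
  d <- dim(logits$val)
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(logits$val, c(1L, 2L, 4L, 3L)), m, d[3])
  xm <- xm - apply(xm, 1L, max)
  p <- exp(xm)
  p <- p / rowSums(p)
  y <- as.integer(aperm(masks, c(1L, 2L, 3L))) + 1L  # flattened (h,w,n)
  val <- -mean(log(pmax(p[cbind(seq_len(m), y)], 1e-12)))
  tape_node(tape, val, parents = list(logits), backward = function(node) {
    dp <- p
    dp[cbind(seq_len(m), y)] <- dp[cbind(seq_len(m), y)] - 1
    dp <- dp * (node$grad / m)
    list(aperm(array(dp, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L)))
  })
}

# Mean absolute difference between two same-shape nodes/arrays.
loss_l1_node <- function(tape, pred, target) {
  diff <- pred$val - target
  m <- length(diff)
  val <- mean(abs(diff))
  tape_node(tape, val, parents = list(pred), backward = function(node) {
    list(array(sign(diff) * (node$grad / m), dim(diff)))
  })
}

# Binary cross-entropy from logits against targets in [0, 1]; works for
# scalar discriminator heads (N x 1) and correction maps (H x W x 1 x N).
loss_bce_logits <- function(tape, z, target) {
  zv <- z$val
  m <- length(zv)
  s <- 1 / (1 + exp(-zv))
  # stable softplus(z) - z*t
  val <- mean(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv))))
  tape_node(tape, val, parents = list(z), backward = function(node) {
    g <- (s - target) * (node$grad / m)
    if (!is.null(dim(zv))) g <- array(g, dim(zv))
    list(g)
  })
}

# Conditional contrastive (2C) loss node over a batch of projections
# (N x d), learned class embeddings (L x d) and integer labels, mean over
# anchors. Log-sum-exp stabilized; gradients via softmax weights.
loss_two_c_node <- function(tape, proj, embed, labels, temperature) {
  P <- proj$val; E <- embed$val
  n <- nrow(P); t <- temperature
  y <- as.integer(labels)
  S <- tcrossprod(P) / t              # pairwise projection similarities
  se <- rowSums(P * E[y + 1L, , drop = FALSE]) / t
  Gs <- matrix(0, n, n)               # d loss / d S[i, j]
  ge <- numeric(n)                    # d loss / d se[i]
  val <- 0
  lse <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }
  smx <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    den_t <- c(se[i], S[i, others])
    same <- others[y[others] == y[i]]
    num_t <- c(se[i], S[i, same])
    val <- val + (lse(den_t) - lse(num_t))
    wd <- smx(den_t); wn <- smx(num_t)
    ge[i] <- ge[i] + wd[1L] - wn[1L]
    if (length(others)) Gs[i, others] <- Gs[i, others] + wd[-1L]
    if (length(same)) Gs[i, same] <- Gs[i, same] - wn[-1L]
  }
  val <- val / n
  tape_node(tape, val, parents = list(proj, embed), backward = function(node) {
    sc <- node$grad / (n * t)
    dP <- (Gs + t(Gs)) %*% P * sc + (ge * E[y + 1L, , drop = FALSE]) * sc
    dE <- matrix(0, nrow(E), ncol(E))
    for (i in seq_len(n)) {
      dE[y[i] + 1L, ] <- dE[y[i] + 1L, ] + ge[i] * P[i, ] * sc
    }
    list(dP, dE)
  })
}

# Frequency-weighted region classification loss node (logits R x L,
# integer labels, positive class weights F).
loss_region_node <- function(tape, logits, labels, freq_weights) {
  z <- sweep(logits$val, 2L, log(freq_weights), `+`)
  z <- z - apply(z, 1L, max)
  p <- exp(z); p <- p / rowSums(p)
  r <- nrow(p)
  idx <- cbind(seq_len(r), as.integer(labels) + 1L)
  val <- -mean(log(pmax(p[idx], 1e-12)))
  tape_node(tape, val, parents = list(logits), backward = function(node) {
    dz <- p
    dz[idx] <- dz[idx] - 1
    list(dz * (node$grad / r))
  })
}

# Supervised contrastive loss node on row-normalized embeddings (N x d):
# for each anchor, attract the positives, repel the negatives.
loss_scon_node <- function(tape, emb, anchors, pos_sets, neg_sets, scale = 1) {
  E <- emb$val
  n <- nrow(E)
  S <- tcrossprod(E) * scale
  Gs <- matrix(0, n, n)
  val <- 0
  na <- length(anchors)
  for (k in seq_len(na)) {
    a <- anchors[k]; ps <- pos_sets[[k]]; ns <- neg_sets[[k]]
    mx <- max(S[a, c(ps, ns)])
    ep <- exp(S[a, ps] - mx); en <- exp(S[a, ns] - mx)
    sp <- sum(ep); sn <- sum(en)
    val <- val - log(sp / (sp + sn))
    Gs[a, ps] <- Gs[a, ps] + (ep / (sp + sn) - ep / sp)
    Gs[a, ns] <- Gs[a, ns] + en / (sp + sn)
  }
  val <- val / na
  tape_node(tape, val, parents = list(emb), backward = function(node) {
    sc <- node$grad * scale / na
    list((Gs + t(Gs)) %*% E * sc)
  })
}
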