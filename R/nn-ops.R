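# Differentiable tensor operations used by the generator, discriminator
# and correction network. Convolutions run as im2col (C++) + GEMM; the
# backward pass uses the adjoint col2im scatter.

op_input <- function(tape, x) tape_node(tape, x)

# 2-D convolution, zero padding, square kernel. W: K x K x Cin x F, b: F.
op_conv <- function(tape, x, Wp, bp, stride = 1L, pad = NULL) {
  Wn <- param_node(tape, Wp); bn <- param_node(tape, bp)
  d <- dim(x$val)
  K <- dim(Wp$val)[1L]
  if (is.null(pad)) pad <- (K - 1L) %/% 2L
  cols <- im2col_cpp(x$val, d[1], d[2], d[3], d[4], K, stride, pad)
  Wm <- matrix(Wn$val, nrow = K * K * d[3])
  f <- ncol(Wm)
  ho <- (d[1] + 2L * pad - K) %/% stride + 1L
  wo <- (d[2] + 2L * pad - K) %/% stride + 1L
  outm <- cols %*% Wm
  outm <- outm + rep(bn$val, each = nrow(outm))
  val <- aperm(array(outm, c(ho, wo, d[4], f)), c(1L, 2L, 4L, 3L))
  tape_node(tape, val, parents = list(x, Wn, bn), backward = function(node) {
    dym <- matrix(aperm(node$grad, c(1L, 2L, 4L, 3L)), ho * wo * d[4], f)
    dW <- array(crossprod(cols, dym), dim = dim(Wp$val))
    db <- colSums(dym)
    dcols <- tcrossprod(dym, Wm)
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], K, stride, pad)
    list(dx, dW, db)
  })
}

# Depthwise 3x3 convolution (one spatial filter per input channel),
# the first half of the depthwise-separable transform in the attention
# block. W: K x K x C, b: C.
op_depthwise_conv <- function(tape, x, Wp, bp, stride = 1L, pad = NULL) {
  Wn <- param_node(tape, Wp); bn <- param_node(tape, bp)
  d <- dim(x$val)
  K <- dim(Wp$val)[1L]
  if (is.null(pad)) pad <- (K - 1L) %/% 2L
  cols <- im2col_cpp(x$val, d[1], d[2], d[3], d[4], K, stride, pad)
  ho <- (d[1] + 2L * pad - K) %/% stride + 1L
  wo <- (d[2] + 2L * pad - K) %/% stride + 1L
  kk <- K * K
  outm <- matrix(0, nrow(cols), d[3])
  for (c in seq_len(d[3])) {
    block <- (c - 1L) * kk + seq_len(kk)
    outm[, c] <- cols[, block, drop = FALSE] %*% as.vector(Wn$val[, , c]) + bn$val[c]
  }
  val <- aperm(array(outm, c(ho, wo, d[4], d[3])), c(1L, 2L, 4L, 3L))
  tape_node(tape, val, parents = list(x, Wn, bn), backward = function(node) {
    dym <- matrix(aperm(node$grad, c(1L, 2L, 4L, 3L)), ho * wo * d[4], d[3])
    dW <- array(0, dim = dim(Wp$val))
    dcols <- matrix(0, nrow(cols), ncol(cols))
    for (c in seq_len(d[3])) {
      block <- (c - 1L) * kk + seq_len(kk)
      dW[, , c] <- crossprod(cols[, block, drop = FALSE], dym[, c])
      dcols[, block] <- tcrossprod(dym[, c], as.vector(Wn$val[, , c]))
    }
    db <- colSums(dym)
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], K, stride, pad)
    list(dx, dW, db)
  })
}

# Channel normalization (batch-norm statistics over height, width and
# batch), with learned gain/bias and running moments for inference.
op_norm <- function(tape, x, np, eps = 1e-5, momentum = 0.1) {
  gn <- param_node(tape, np$gamma); bn <- param_node(tape, np$beta)
  d <- dim(x$val)
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x$val, c(1L, 2L, 4L, 3L)), m, d[3])
  if (tape$training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc * xc)
    np$run_mean <- (1 - momentum) * np$run_mean + momentum * mu
    np$run_var <- (1 - momentum) * np$run_var + momentum * va
  } else {
    mu <- np$run_mean
    xc <- sweep(xm, 2L, mu)
    va <- np$run_var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, ivar, `*`)
  ym <- sweep(sweep(xhat, 2L, gn$val, `*`), 2L, bn$val, `+`)
  val <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
  training <- tape$training
  tape_node(tape, val, parents = list(x, gn, bn), backward = function(node) {
    dym <- matrix(aperm(node$grad, c(1L, 2L, 4L, 3L)), m, d[3])
    dgamma <- colSums(dym * xhat)
    dbeta <- colSums(dym)
    dxhat <- sweep(dym, 2L, gn$val, `*`)
    if (training) {
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), `*`)
      dxm <- sweep(t1 - t2, 2L, ivar, `*`)
    } else {
      dxm <- sweep(dxhat, 2L, ivar, `*`)
    }
    dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
    list(dx, dgamma, dbeta)
  })
}

norm_param <- function(channels, name = "") {
  p <- new.env(parent = emptyenv())
  p$gamma <- nn_param(rep(1, channels), paste0(name, ".gamma"))
  p$beta <- nn_param(rep(0, channels), paste0(name, ".beta"))
  p$run_mean <- rep(0, channels)
  p$run_var <- rep(1, channels)
  p
}

op_relu <- function(tape, x) {
  val <- pmax(x$val, 0)
  tape_node(tape, val, parents = list(x), backward = function(node) {
    list(node$grad * (val > 0))
  })
}

op_sigmoid <- function(tape, x) {
  val <- 1 / (1 + exp(-x$val))
  tape_node(tape, val, parents = list(x), backward = function(node) {
    list(node$grad * val * (1 - val))
  })
}

# Softmax across the channel dimension at every pixel.
op_softmax_channels <- function(tape, x) {
  d <- dim(x$val)
  xm <- matrix(aperm(x$val, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
  xm <- xm - apply(xm, 1L, max)
  p <- exp(xm)
  p <- p / rowSums(p)
  val <- aperm(array(p, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
  tape_node(tape, val, parents = list(x), backward = function(node) {
    dym <- matrix(aperm(node$grad, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
    dxm <- p * (dym - rowSums(dym * p))
    list(aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L)))
  })
}

# Nearest-neighbour 2x upsampling (decoder resize-then-convolve path).
op_upsample2x <- function(tape, x) {
  d <- dim(x$val)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  val <- x$val[ri, ci, , , drop = FALSE]
  tape_node(tape, val, parents = list(x), backward = function(node) {
    g <- node$grad
    o1 <- seq(1L, 2L * d[1], by = 2L); o2 <- o1 + 1L
    p1 <- seq(1L, 2L * d[2], by = 2L); p2 <- p1 + 1L
    dx <- g[o1, p1, , , drop = FALSE] + g[o2, p1, , , drop = FALSE] +
      g[o1, p2, , , drop = FALSE] + g[o2, p2, , , drop = FALSE]
    list(dx)
  })
}

# Dense interpolation matrix for 1-D bilinear resampling (half-pixel
# centres); 2x bilinear upsampling applies it along rows then columns.
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale + 0.5
    lo <- floor(s); w <- s - lo
    lo <- min(max(lo, 1L), n_in); hi <- min(lo + 1L, n_in)
    A[i, lo] <- A[i, lo] + (1 - w)
    A[i, hi] <- A[i, hi] + w
  }
  A
}

op_upsample_bilinear2x <- function(tape, x) {
  d <- dim(x$val)
  A <- interp_matrix(2L * d[1], d[1])
  B <- interp_matrix(2L * d[2], d[2])
  y1 <- array(A %*% matrix(x$val, d[1], d[2] * d[3] * d[4]),
              c(2L * d[1], d[2], d[3], d[4]))
  y1p <- aperm(y1, c(2L, 1L, 3L, 4L))
  y2 <- array(B %*% matrix(y1p, d[2], 2L * d[1] * d[3] * d[4]),
              c(2L * d[2], 2L * d[1], d[3], d[4]))
  val <- aperm(y2, c(2L, 1L, 3L, 4L))
  tape_node(tape, val, parents = list(x), backward = function(node) {
    g <- aperm(node$grad, c(2L, 1L, 3L, 4L))
    g1 <- array(crossprod(B, matrix(g, 2L * d[2], 2L * d[1] * d[3] * d[4])),
                c(d[2], 2L * d[1], d[3], d[4]))
    g1 <- aperm(g1, c(2L, 1L, 3L, 4L))
    dx <- array(crossprod(A, matrix(g1, 2L * d[1], d[2] * d[3] * d[4])),
                c(d[1], d[2], d[3], d[4]))
    list(dx)
  })
}

# Channel concatenation (UNet skip connections).
op_concat_channels <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$val))
  cc <- vapply(ds, function(d) d[3], 0)
  d1 <- ds[[1L]]
  total <- sum(cc)
  val <- array(0, c(d1[1], d1[2], total, d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    val[, , at + seq_len(cc[i]), ] <- xs[[i]]$val
    at <- at + cc[i]
  }
  tape_node(tape, val, parents = xs, backward = function(node) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- node$grad[, , at + seq_len(cc[i]), , drop = FALSE]
      at <- at + cc[i]
    }
    out
  })
}

# Train-time multiplicative dropout; the generator's stochastic input.
op_dropout <- function(tape, x, rate) {
  if (!tape$training || rate <= 0) return(x)
  keep <- (array(stats::runif(length(x$val)), dim(x$val)) >= rate) / (1 - rate)
  tape_node(tape, x$val * keep, parents = list(x), backward = function(node) {
    list(node$grad * keep)
  })
}

# Global average pooling: H x W x C x N -> N x C.
op_gap <- function(tape, x) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  cm <- colMeans(matrix(x$val, hw, d[3] * d[4]))  # ordered c fastest? no: (c,n)
  val <- t(matrix(cm, d[3], d[4]))
  tape_node(tape, val, parents = list(x), backward = function(node) {
    g <- t(node$grad) / hw  # C x N
    dx <- array(rep(as.vector(g), each = hw), d)
    list(dx)
  })
}

# Fully-connected layer on N x p inputs.
op_dense <- function(tape, x, Wp, bp) {
  Wn <- param_node(tape, Wp); bn <- param_node(tape, bp)
  val <- x$val %*% Wn$val
  val <- sweep(val, 2L, bn$val, `+`)
  tape_node(tape, val, parents = list(x, Wn, bn), backward = function(node) {
    list(tcrossprod(node$grad, Wn$val), crossprod(x$val, node$grad),
         colSums(node$grad))
  })
}

# Row-wise L2 normalization (projection embeddings before contrastive
# similarities).
op_l2_rows <- function(tape, x, eps = 1e-8) {
  nrm <- sqrt(rowSums(x$val^2)) + eps
  val <- x$val / nrm
  tape_node(tape, val, parents = list(x), backward = function(node) {
    g <- node$grad
    dx <- (g - val * rowSums(g * val)) / nrm
    list(dx)
  })
}

# Mean over non-overlapping rf x rf spatial tiles, emitting one row per
# tile per sample in row-major tile order (the region classifier input).
op_region_pool <- function(tape, x, rf) {
  d <- dim(x$val)
  nr <- d[1] %/% rf; nc <- d[2] %/% rf
  tiles_per <- nr * nc
  val <- matrix(0, tiles_per * d[4], d[3])
  row <- 0L
  for (n in seq_len(d[4])) {
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        row <- row + 1L
        blk <- x$val[(i - 1L) * rf + seq_len(rf), (j - 1L) * rf + seq_len(rf), , n,
                     drop = FALSE]
        val[row, ] <- colMeans(matrix(blk, rf * rf, d[3]))
      }
    }
  }
  tape_node(tape, val, parents = list(x), backward = function(node) {
    dx <- array(0, d)
    row <- 0L
    for (n in seq_len(d[4])) {
      for (i in seq_len(nr)) {
        for (j in seq_len(nc)) {
          row <- row + 1L
          g <- node$grad[row, ] / (rf * rf)
          dx[(i - 1L) * rf + seq_len(rf), (j - 1L) * rf + seq_len(rf), , n] <-
            rep(g, each = rf * rf)
        }
      }
    }
    list(dx)
  })
}

# Class-specific attention: from the transformed map x_hat (x*L channels,
# grouped contiguously by class) compute per-class scores (mean of global
# max over each class's channels), per-class semantic maps (channel
# means), their score-weighted average, and reweight the block input.
op_class_attention <- function(tape, xhat, x, x_per_class, L) {
  dh <- dim(xhat$val); dx_ <- dim(x$val)
  H <- dh[1]; W <- dh[2]; N <- dh[4]; xc <- x_per_class
  stopifnot(dh[3] == xc * L)
  hw <- H * W
  xm <- matrix(xhat$val, hw, xc * L * N)
  amax <- max.col(t(xm), ties.method = "first")
  vmax <- xm[cbind(amax, seq_len(ncol(xm)))]
  scores <- matrix(colMeans(matrix(vmax, xc, L * N)), L, N)
  # semantic maps: mean over the xc channels of each class
  arrp <- aperm(array(xhat$val, c(hw, xc, L, N)), c(2L, 1L, 3L, 4L))
  sem <- array(colMeans(matrix(arrp, xc, hw * L * N)), c(hw, L, N))
  att <- matrix(0, hw, N)
  for (n in seq_len(N)) att[, n] <- sem[, , n] %*% scores[, n] / L
  xp <- aperm(x$val, c(1L, 2L, 4L, 3L))
  outp <- xp * as.vector(att)
  val <- aperm(outp, c(1L, 2L, 4L, 3L))
  tape_node(tape, val, parents = list(xhat, x), backward = function(node) {
    go <- node$grad
    gop <- aperm(go, c(1L, 2L, 4L, 3L))
    dxv <- aperm(gop * as.vector(att), c(1L, 2L, 4L, 3L))
    datt <- matrix(rowSums(matrix(gop * xp, hw * N, dx_[3])), hw, N)
    dscores <- matrix(0, L, N)
    dsem <- array(0, c(hw, L, N))
    for (n in seq_len(N)) {
      dscores[, n] <- crossprod(sem[, , n], datt[, n]) / L
      dsem[, , n] <- tcrossprod(datt[, n], scores[, n]) / L
    }
    # spread semantic-map gradient uniformly over the class's channels
    dxh_m <- matrix(0, hw, xc * L * N)
    col <- 0L
    for (n in seq_len(N)) {
      for (j in seq_len(L)) {
        g <- dsem[, j, n] / xc
        for (k in seq_len(xc)) {
          col <- col + 1L
          dxh_m[, col] <- g
        }
      }
    }
    # score gradient routes to each channel's argmax location
    ds_per_chan <- rep(as.vector(dscores), each = xc) / xc
    idx <- cbind(amax, seq_len(ncol(xm)))
    dxh_m[idx] <- dxh_m[idx] + ds_per_chan
    list(array(dxh_m, dh), dxv)
  })
}

# Weighted sum of scalar loss nodes.
op_add_scalars <- function(tape, nodes, weights = rep(1, length(nodes))) {
  val <- 0
  for (i in seq_along(nodes)) val <- val + weights[i] * nodes[[i]]$val
  tape_node(tape, val, parents = nodes, backward = function(node) {
    lapply(weights, function(w) node$grad * w)
  })
}
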