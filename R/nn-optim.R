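# Parameter updates. Adadelta follows the usual accumulator form with an
# explicit learning-rate multiplier (as in modern framework
# implementations); Adam is offered for faster desk-scale convergence.

optim_step <- function(params, cfg) {
  if (identical(cfg$optimizer, "adam")) adam_step(params, cfg)
  else adadelta_step(params, cfg)
  invisible(NULL)
}

adadelta_step <- function(params, cfg, rho = 0.95, eps = 1e-6) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + cfg$weight_decay * p$val
    if (is.null(p$s1)) { p$s1 <- g * 0; p$s2 <- g * 0 }
    p$s1 <- rho * p$s1 + (1 - rho) * g * g
    upd <- sqrt(p$s2 + eps) / sqrt(p$s1 + eps) * g
    p$s2 <- rho * p$s2 + (1 - rho) * upd * upd
    p$val <- p$val - cfg$lr * upd
  }
}

adam_step <- function(params, cfg, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + cfg$weight_decay * p$val
    if (is.null(p$s1)) { p$s1 <- g * 0; p$s2 <- g * 0; p$t <- 0L }
    p$t <- p$t + 1L
    p$s1 <- beta1 * p$s1 + (1 - beta1) * g
    p$s2 <- beta2 * p$s2 + (1 - beta2) * g * g
    m_hat <- p$s1 / (1 - beta1^p$t)
    v_hat <- p$s2 / (1 - beta2^p$t)
    p$val <- p$val - cfg$lr * m_hat / (sqrt(v_hat) + eps)
  }
}

# He-style initializers, driven by the caller's RNG stream.
init_conv <- function(k, cin, cout, name = "") {
  sd <- sqrt(2 / (k * k * cin))
  nn_param(array(stats::rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
           name)
}

init_depthwise <- function(k, c, name = "") {
  sd <- sqrt(2 / (k * k))
  nn_param(array(stats::rnorm(k * k * c, sd = sd), c(k, k, c)), name)
}

init_dense <- function(p, q, name = "") {
  sd <- sqrt(2 / p)
  nn_param(matrix(stats::rnorm(p * q, sd = sd), p, q), name)
}

init_bias <- function(n, name = "") nn_param(rep(0, n), name)
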