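# Class-specific attention: transform, scores, semantic maps, attention
# map and reweighting, each against a brute-force oracle plus the
# module's structural properties.

identity_params <- function(c_in) {
  dw <- array(0, c(3, 3, c_in))
  for (c in seq_len(c_in)) dw[2, 2, c] <- 1
  pw <- array(0, c(1, 1, c_in, c_in))
  for (c in seq_len(c_in)) pw[1, 1, c, c] <- 1
  list(dw_w = dw, dw_b = rep(0, c_in), pw_w = pw, pw_b = rep(0, c_in),
       gamma = rep(1, c_in), beta = rep(0, c_in))
}

test_that("identity-initialized transform with normalization bypassed is the identity", {
  set.seed(1)
  x <- array(runif(5 * 5 * 2), c(5, 5, 2))   # non-negative input
  cfg <- attention_config(channels_per_class = 1, num_classes = 2)
  out <- attention_transform(x, cfg, identity_params(2), normalize = FALSE)
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("transform output is always non-negative and shaped h x w x xL", {
  set.seed(2)
  cfg <- attention_config(channels_per_class = 3, num_classes = 2)
  pars <- attention_params(4, cfg)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  out <- attention_transform(x, cfg, pars)
  expect_equal(dim(out), c(6L, 6L, 6L))
  expect_gte(min(out), 0)
})

test_that("transform matches a nested-loop depthwise-separable oracle", {
  set.seed(3)
  cfg <- attention_config(channels_per_class = 2, num_classes = 2)
  pars <- attention_params(2, cfg)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  got <- attention_transform(x, cfg, pars, normalize = FALSE)
  want <- pmax(oracle_dwsep_conv(x, pars$dw_w, pars$dw_b, pars$pw_w,
                                 pars$pw_b), 0)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("class scores implement mean-of-global-max per class group", {
  cfg <- attention_config(2, 2)
  ones <- array(1, c(4, 4, 4))
  expect_equal(class_scores(ones, cfg), c(1, 1))
  split <- array(0, c(4, 4, 4))
  split[, , 3:4] <- 5
  expect_equal(class_scores(split, cfg), c(0, 5))
  set.seed(4)
  cfg2 <- attention_config(3, 2)
  tr <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  want <- numeric(2)
  for (j in 1:2) {
    acc <- 0
    for (k in 1:3) {
      mx <- -Inf
      ch <- (j - 1) * 3 + k
      for (i in 1:4) for (l in 1:4) mx <- max(mx, tr[i, l, ch])
      acc <- acc + mx
    }
    want[j] <- acc / 3
  }
  expect_identical(class_scores(tr, cfg2), want)
  expect_error(class_scores(array(0, c(4, 4, 5)), cfg2), "divisible")
})

test_that("semantic maps average the channels of each class", {
  cfg1 <- attention_config(1, 3)
  tr <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  expect_equal(class_semantic_map(tr, cfg1), tr)
  cfg2 <- attention_config(2, 1)
  two <- array(0, c(3, 3, 2)); two[, , 1] <- 2; two[, , 2] <- 4
  expect_equal(class_semantic_map(two, cfg2)[, , 1], matrix(3, 3, 3))
  set.seed(5)
  cfg3 <- attention_config(2, 2)
  tr3 <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  want <- array(0, c(3, 3, 2))
  for (j in 1:2) for (i in 1:3) for (l in 1:3)
    want[i, l, j] <- (tr3[i, l, (j - 1) * 2 + 1] + tr3[i, l, (j - 1) * 2 + 2]) / 2
  expect_identical(class_semantic_map(tr3, cfg3), want)
})

test_that("attention map is the score-weighted class average", {
  sem1 <- array(rnorm(9), c(3, 3, 1))
  expect_equal(attention_map(1, sem1), sem1[, , 1])
  sem3 <- array(rnorm(27), c(3, 3, 3))
  expect_equal(attention_map(c(0, 0, 0), sem3), matrix(0, 3, 3))
  sc <- rnorm(3)
  want <- matrix(0, 3, 3)
  for (j in 1:3) want <- want + sc[j] * sem3[, , j]
  expect_lt(max(abs(attention_map(sc, sem3) - want / 3)), 1e-6)
  expect_error(attention_map(c(1, 2), sem3), "class planes")
})

test_that("applying attention broadcasts the elementwise product over channels", {
  set.seed(6)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  att <- matrix(rnorm(16), 4, 4)
  expect_equal(apply_attention(x, matrix(1, 4, 4)), x)
  expect_equal(apply_attention(x, matrix(0, 4, 4)), x * 0)
  got <- apply_attention(x, att)
  for (c in 1:3) expect_equal(got[, , c], x[, , c] * att)
  expect_error(apply_attention(x, matrix(1, 3, 3)), "spatial")
})

test_that("class scores are invariant to spatial permutation", {
  set.seed(7)
  cfg <- attention_config(2, 2)
  tr <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  base <- class_scores(tr, cfg)
  for (rep in 1:5) {
    perm <- sample(25)
    shuffled <- apply(tr, 3, function(m) matrix(as.vector(m)[perm], 5, 5))
    shuffled <- array(shuffled, c(5, 5, 4))
    expect_identical(class_scores(shuffled, cfg), base)
  }
})

test_that("outputs scale as lambda, lambda and lambda squared", {
  set.seed(8)
  cfg <- attention_config(2, 3)
  tr <- array(abs(rnorm(4 * 4 * 6)), c(4, 4, 6))
  lam <- 2.5
  expect_equal(class_scores(lam * tr, cfg), lam * class_scores(tr, cfg))
  expect_equal(class_semantic_map(lam * tr, cfg),
               lam * class_semantic_map(tr, cfg))
  a1 <- attention_map(class_scores(tr, cfg), class_semantic_map(tr, cfg))
  a2 <- attention_map(class_scores(lam * tr, cfg),
                      class_semantic_map(lam * tr, cfg))
  expect_equal(a2, lam^2 * a1, tolerance = 1e-10)
})

test_that("a full attention block preserves the input shape", {
  set.seed(9)
  cfg <- attention_config(4, 2)
  pars <- attention_params(5, cfg)
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  out <- attention_block(x, cfg, pars)
  expect_equal(dim(out), dim(x))
})

test_that("attention heatmaps export as readable PNGs", {
  f <- withr::local_tempfile(fileext = ".png")
  write_attention_png(matrix(rnorm(64), 8, 8), f)
  expect_true(file.exists(f))
  expect_equal(dim(png::readPNG(f)), c(8L, 8L))
})
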