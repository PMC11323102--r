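# The bespoke objectives against brute-force oracles, their degenerate
# limits, and the correction-map algebra.

test_that("2C loss vanishes for single-sample and single-class batches", {
  set.seed(21)
  b1 <- random_embedding_batch(1, 8, 2)
  expect_equal(two_c_loss(b1), 0)
  P <- matrix(rnorm(4 * 8), 4, 8)
  E <- matrix(rnorm(2 * 8), 2, 8)
  bsame <- embedding_batch(P, E, rep(1L, 4), 3)
  expect_equal(two_c_loss(bsame), 0, tolerance = 1e-12)
})

test_that("2C loss equals the double-loop oracle", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    b <- random_embedding_batch(n, 8, 2)
    expect_lt(abs(two_c_loss(b) -
                  oracle_two_c(b$image_proj, b$class_embed, b$labels, 3)),
              1e-6)
    a <- sample(n, 1)
    num <- exp(sum(b$image_proj[a, ] * b$class_embed[b$labels[a] + 1, ]) / 3)
    den <- num
    for (j in setdiff(1:n, a)) {
      s <- exp(sum(b$image_proj[a, ] * b$image_proj[j, ]) / 3)
      den <- den + s
      if (b$labels[j] == b$labels[a]) num <- num + s
    }
    expect_lt(abs(two_c_loss(b, anchor = a) + log(num / den)), 1e-8)
  }
})

test_that("2C loss is non-negative on many random batches and invariant to class relabeling", {
  set.seed(23)
  nonneg <- numeric(1000)
  for (rep in 1:1000) {
    b <- random_embedding_batch(sample(2:8, 1), 4, sample(2:3, 1))
    nonneg[rep] <- two_c_loss(b)
  }
  expect_gte(min(nonneg), -1e-12)
  for (rep in 1:100) {
    b <- random_embedding_batch(sample(2:6, 1), 4, sample(2:3, 1))
    v <- two_c_loss(b)
    expect_gte(v, -1e-12)
    L <- nrow(b$class_embed)
    perm <- sample(L) - 1L
    relabeled <- embedding_batch(b$image_proj,
                                 b$class_embed[order(perm), , drop = FALSE],
                                 perm[b$labels + 1L], b$temperature)
    expect_equal(two_c_loss(relabeled), v, tolerance = 1e-10)
  }
})

test_that("temperature must be positive and shapes must agree", {
  expect_error(embedding_batch(matrix(1, 2, 3), matrix(1, 2, 3), c(0, 1), 0),
               "temperature")
  expect_error(embedding_batch(matrix(1, 2, 3), matrix(1, 2, 4), c(0, 1)),
               "dimension")
})

test_that("L1 loss is the mean absolute difference", {
  a <- array(runif(4 * 4 * 2), c(4, 4, 2))
  expect_equal(l1_seg_loss(a, a), 0)
  expect_equal(l1_seg_loss(a + 0.5, a), 0.5, tolerance = 1e-12)
  set.seed(24)
  b <- array(runif(4 * 4 * 2), c(4, 4, 2))
  want <- 0
  for (i in seq_along(a)) want <- want + abs(a[i] - b[i])
  expect_equal(l1_seg_loss(a, b), want / length(a), tolerance = 1e-12)
  expect_error(l1_seg_loss(a, array(0, c(4, 4, 3))), "shapes differ")
})

test_that("the adversarial segmentation objective combines 2C and L1 linearly", {
  expect_equal(adversarial_seg_loss(1.0, 0.2, 1), 1.2)
  expect_equal(adversarial_seg_loss(0.7, 0, 1), 0.7)
  expect_equal(adversarial_seg_loss(0.3, 0.4, 10), 4.3)
})

test_that("the supervised contrastive loss attracts positives and repels negatives", {
  a <- c(1, 0, 0, 0)
  pos <- list(a, a)
  neg <- list(c(0, 1, 0, 0), c(0, 0, 1, 0))
  near_zero <- scoln_contrastive_loss(10 * a, lapply(pos, function(p) 10 * p),
                                      neg, sim = "dot")
  expect_lt(near_zero, 1e-6)
  swapped <- scoln_contrastive_loss(10 * a, neg,
                                    lapply(pos, function(p) 10 * p),
                                    sim = "dot")
  expect_gt(swapped, near_zero)
  set.seed(25)
  for (rep in 1:20) {
    anc <- rnorm(8)
    ps <- replicate(3, rnorm(8), simplify = FALSE)
    ns <- replicate(3, rnorm(8), simplify = FALSE)
    expect_lt(abs(scoln_contrastive_loss(anc, ps, ns) -
                  oracle_scon(anc, ps, ns)), 1e-8)
    expect_lt(abs(scoln_contrastive_loss(anc, ps, ns, sim = "dot") -
                  oracle_scon(anc, ps, ns, sim = "dot")), 1e-8)
  }
  expect_error(scoln_contrastive_loss(a, list(), neg), "nonempty")
})

test_that("the literal printed form is exposed but differs from the corrected form", {
  set.seed(26)
  anc <- rnorm(4)
  ps <- replicate(2, rnorm(4), simplify = FALSE)
  ns <- replicate(2, rnorm(4), simplify = FALSE)
  lit <- scoln_contrastive_loss(anc, ps, ns, as_printed = TRUE)
  cor <- scoln_contrastive_loss(anc, ps, ns)
  expect_true(is.finite(lit))
  expect_false(isTRUE(all.equal(lit, cor)))
})

test_that("correction maps isolate missed and spurious foreground", {
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(correction_maps(g, g)$fn_map, g * 0)
  expect_equal(correction_maps(g, g)$fp_map, g * 0)
  pred <- matrix(0, 2, 2)
  cm <- correction_maps(pred, g)
  expect_equal(cm$fn_map, g)
  expect_equal(cm$fp_map, g * 0)
  set.seed(27)
  for (rep in 1:20) {
    p <- matrix(as.numeric(runif(36) < 0.5), 6, 6)
    t <- matrix(as.numeric(runif(36) < 0.3), 6, 6)
    cm <- correction_maps(p, t)
    expect_equal(cm$fn_map + cm$fp_map, abs(p - t))
    expect_true(all(cm$fn_map * cm$fp_map == 0))
  }
  expect_error(correction_maps(matrix(1.5, 2, 2), matrix(1, 2, 2)), "\\[0, 1\\]")
})

test_that("the final objective adds FN mass and subtracts FP mass", {
  cm0 <- correction_maps(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(final_objective(0.8, cm0), 0.8)
  cm <- structure(list(fn_map = matrix(0.2, 2, 2), fp_map = matrix(0.1, 2, 2)),
                  class = "correction_maps")
  expect_equal(final_objective(1, cm), 1.1)
  expect_equal(final_objective(1, cm, reduce = "count"), 1 + 0.8 - 0.4)
  set.seed(28)
  fn <- matrix(runif(9), 3, 3); fp <- matrix(runif(9), 3, 3)
  cmr <- structure(list(fn_map = fn, fp_map = fp), class = "correction_maps")
  expect_equal(final_objective(0.5, cmr), 0.5 - mean(fp) + mean(fn))
})

test_that("oracle correction maps reproduce the ground truth exactly", {
  set.seed(29)
  g <- matrix(as.integer(runif(9) < 0.4), 3, 3)
  for (code in 0:511) {
    pred <- matrix(as.numeric(bitwAnd(bitwShiftR(code, 0:8), 1L)), 3, 3)
    out <- corrected_mask(pred, correction_maps(pred, g))
    expect_identical(out, matrix(as.integer(g), 3, 3))
  }
  # zero maps reduce to plain thresholding
  p <- matrix(runif(9), 3, 3)
  cm0 <- structure(list(fn_map = p * 0, fp_map = p * 0),
                   class = "correction_maps")
  expect_identical(corrected_mask(p, cm0, 0.5),
                   matrix(as.integer(p >= 0.5), 3, 3))
})
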