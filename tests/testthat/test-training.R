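# Phase isolation, loss bookkeeping, early stopping, fold orchestration
# and prediction semantics.

make_nets <- function(gcfg = tiny_gen_cfg(), seed = 100) {
  list(generator = build_generator(gcfg, 2, 1, seed = seed),
       discriminator = build_discriminator(gcfg, 2, 1, seed = seed + 1),
       scoln = build_scoln(gcfg, 1, seed = seed + 2))
}

test_that("each phase updates only its own network's parameters", {
  ds <- tiny_dataset(4, 16)
  for (phase in c("discriminator", "generator", "scoln")) {
    nets <- make_nets()
    cfg <- tiny_train_cfg(phase_order = phase)
    before <- lapply(nets, snapshot_params)
    set.seed(1)
    train_step(ds, nets, cfg, train_state())
    after <- lapply(nets, snapshot_params)
    owner <- switch(phase, discriminator = "discriminator",
                    generator = "generator", scoln = "scoln")
    for (nm in names(nets)) {
      if (nm == owner) {
        expect_false(identical(before[[nm]], after[[nm]]),
                     info = paste(phase, "should update", nm))
      } else {
        expect_identical(before[[nm]], after[[nm]])
      }
    }
  }
})

test_that("one step logs a finite loss for every phase", {
  ds <- tiny_dataset(4, 16)
  nets <- make_nets()
  st <- train_state()
  set.seed(2)
  train_step(ds[1:2], nets, tiny_train_cfg(), st)
  expect_length(st$loss_d, 1L)
  expect_length(st$loss_g, 1L)
  expect_length(st$loss_s, 1L)
  expect_true(all(is.finite(c(st$loss_d, st$loss_g, st$loss_s))))
})

test_that("ablating SCoLN skips its phase entirely", {
  ds <- tiny_dataset(4, 16)
  nets <- make_nets()
  st <- train_state()
  set.seed(3)
  train_step(ds, nets, tiny_train_cfg(ablation = "scoln"), st)
  expect_length(st$loss_s, 0L)
  expect_length(st$loss_g, 1L)
})

test_that("early stopping halts after patience epochs without improvement", {
  ds <- tiny_dataset(8, 16)
  # near-frozen weights: only normalization statistics can drift, so the
  # validation Dice plateaus quickly and patience must cut training short
  cfg <- tiny_train_cfg(epochs = 30L, lr = 1e-12, early_stop_patience = 2L,
                        folds = 2L)
  gcfg <- tiny_gen_cfg(dropout_rate = 0)
  fit <- fit_ccgan(ds, cfg, gcfg, folds_to_run = 0)
  h <- fit$folds[["0"]]$history
  expect_lt(nrow(h), 30L)
  n <- nrow(h)
  # the stopping rule: the final `patience` epochs did not improve on the
  # best of the earlier ones
  expect_true(all(h$val_dice[(n - 1):n] <= max(h$val_dice[1:(n - 2)])))
  expect_equal(fit$folds[["0"]]$best_epoch, which.max(h$val_dice))
})

test_that("cross-validation bookkeeping covers every fold", {
  ds <- tiny_dataset(10, 16)
  cfg <- tiny_train_cfg(folds = 5L, epochs = 1L, batch_size = 4L)
  fit <- fit_ccgan(ds, cfg, tiny_gen_cfg())
  expect_length(fit$folds, 5L)
  expect_equal(nrow(fit$metrics), 6L)  # 5 folds + overall
  expect_equal(nrow(fit$per_sample), 10L)
  expect_true(all(is.finite(fit$per_sample$dice)))
  best <- vapply(fit$folds, function(f) f$state$best_val_dsc, 0)
  expect_true(all(is.finite(best)))
})

test_that("training is reproducible under a fixed seed", {
  ds <- tiny_dataset(6, 16)
  cfg <- tiny_train_cfg(folds = 3L, epochs = 2L, seed = 99L)
  f1 <- fit_ccgan(ds, cfg, tiny_gen_cfg(), folds_to_run = 0)
  f2 <- fit_ccgan(ds, cfg, tiny_gen_cfg(), folds_to_run = 0)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$folds[["0"]]$history, f2$folds[["0"]]$history)
})

test_that("prediction semantics: thresholding, zero-map identity, determinism", {
  ds <- tiny_dataset(5, 16)
  nets <- make_nets(seed = 200)
  res_plain <- predict_ccgan(nets$generator, NULL, ds, use_correction = FALSE)
  for (i in seq_along(ds)) {
    fg <- res_plain[[i]]$prob[, , 2]
    expect_identical(res_plain[[i]]$mask,
                     matrix(as.integer(fg >= 0.5), 16, 16))
    expect_null(res_plain[[i]]$correction)
  }
  # SCoLN forced to emit (numerically) zero maps leaves masks unchanged
  nets$scoln$params$head_w$val[] <- 0
  nets$scoln$params$head_b$val[] <- -60
  res_corr <- predict_ccgan(nets$generator, nets$scoln, ds,
                            use_correction = TRUE)
  for (i in seq_along(ds)) {
    expect_identical(res_corr[[i]]$mask, res_plain[[i]]$mask)
    expect_s3_class(res_corr[[i]]$correction, "correction_maps")
  }
  r1 <- predict_ccgan(nets$generator, nets$scoln, ds)
  r2 <- predict_ccgan(nets$generator, nets$scoln, ds)
  expect_identical(r1, r2)
})

test_that("prediction pads and crops inputs not divisible by 2^levels", {
  nets <- make_nets(seed = 300)
  s <- tiny_dataset(1, 15)[[1]]  # 15 is not divisible by 4
  res <- predict_ccgan(nets$generator, NULL, list(s), use_correction = FALSE)
  expect_equal(dim(res[[1]]$mask), c(15L, 15L))
  expect_equal(dim(res[[1]]$prob), c(15L, 15L, 2L))
})

test_that("a NaN loss aborts with a phase-labelled diagnostic", {
  ds <- tiny_dataset(2, 16)
  nets <- make_nets(seed = 400)
  nets$generator$params$head_w$val[] <- NaN
  expect_error(
    train_step(ds, nets, tiny_train_cfg(phase_order = "generator"),
               train_state()),
    "generator phase")
})
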