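# Three-phase adversarial training (discriminator, generator, SCoLN),
# k-fold orchestration with early stopping on validation Dice, and
# prediction with optional SCoLN correction.

#' Training configuration
#'
#' @param epochs maximum epochs per fold (default 30 at desk scale; 450
#'   is the full-scale setting).
#' @param batch_size samples per step (default 32).
#' @param lr learning rate (default 0.001).
#' @param weight_decay L2 penalty (default 1e-4).
#' @param temperature contrastive temperature t (default 3).
#' @param optimizer `"adadelta"` (default) or `"adam"`; Adadelta at this
#'   learning rate is slow on small problems, where Adam is the practical
#'   choice.
#' @param early_stop_patience epochs without validation-Dice improvement
#'   before stopping (default 20).
#' @param seed master RNG seed.
#' @param folds cross-validation folds (default 5).
#' @param lambda_l1 weight of the L1 term in the generator objective
#'   (default 1, the unweighted form).
#' @param ablation character subset of `c("attention", "rrm", "scoln")`:
#'   modules to disable.
#' @param region_weight weight of the region loss inside the generator
#'   objective (default 1).
#' @param scon_weight weight of the supervised contrastive term in the
#'   SCoLN objective (default 0.1).
#' @param threshold binarization threshold for predictions (default 0.5).
#' @param phase_order order of the per-batch phases; discriminator first
#'   by default.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, lr = 0.001,
                         weight_decay = 1e-4, temperature = 3,
                         optimizer = c("adadelta", "adam"),
                         early_stop_patience = 20L, seed = 1L, folds = 5L,
                         lambda_l1 = 1, ablation = character(),
                         region_weight = 1, scon_weight = 0.1,
                         threshold = 0.5,
                         phase_order = c("discriminator", "generator",
                                         "scoln")) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, weight_decay >= 0,
            temperature > 0, early_stop_patience >= 1L, folds >= 2L)
  if (!all(ablation %in% c("attention", "rrm", "scoln")))
    stop("ablation must be a subset of {attention, rrm, scoln}")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, temperature = temperature,
                 optimizer = optimizer,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), folds = as.integer(folds),
                 lambda_l1 = lambda_l1, ablation = ablation,
                 region_weight = region_weight, scon_weight = scon_weight,
                 threshold = threshold, phase_order = phase_order),
            class = "train_config")
}

#' Fresh training state
#'
#' Tracks the epoch counter, per-phase loss histories and the best
#' validation Dice seen so far (non-decreasing over epochs).
#' @return Environment of class `train_state`.
#' @export
train_state <- function() {
  st <- new.env(parent = emptyenv())
  st$epoch <- 0L
  st$loss_d <- numeric(); st$loss_g <- numeric(); st$loss_s <- numeric()
  st$best_val_dsc <- -Inf
  st$region_freq <- NULL
  class(st) <- "train_state"
  st
}

batch_arrays <- function(batch) {
  d <- dim(batch[[1L]]$image)
  n <- length(batch)
  x <- array(0, c(d[1], d[2], d[3], n))
  masks <- array(0L, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    x[, , , i] <- batch[[i]]$image
    masks[, , i] <- batch[[i]]$mask
  }
  list(x = x, masks = masks)
}

one_hot_masks <- function(masks, L) {
  d <- dim(masks)
  out <- array(0, c(d[1], d[2], L, d[3]))
  for (k in seq_len(L)) out[, , k, ] <- as.numeric(masks == (k - 1L))
  out
}

# Image-level class id used by the 2C loss: lesion present vs absent.
image_labels <- function(masks) {
  apply(masks, 3L, function(m) as.integer(any(m > 0L)))
}

check_finite_loss <- function(value, phase) {
  if (!is.finite(value))
    stop("non-finite loss in ", phase, " phase (value: ", value, ")")
  invisible(value)
}

#' One three-phase training step
#'
#' Per batch: (1) discriminator phase, maximizing the real/fake
#' discrimination of (image, mask) pairs with the 2C loss computed on
#' real images; (2) generator phase, minimizing the 2C loss on generated
#' outputs plus the L1 term, the pixel cross-entropy, and (when the RRM
#' is enabled) the frequency-weighted region loss; (3) SCoLN phase,
#' supervising the predicted correction maps against
#' [correction_maps()] of the generator output with pixel-wise binary
#' cross-entropy plus the supervised contrastive term. Each phase
#' updates only its own network's parameters.
#'
#' @param batch list of [image_sample()] objects.
#' @param nets list with elements `generator`, `discriminator`, `scoln`.
#' @param cfg a [train_config()].
#' @param state a [train_state()].
#' @return The updated state, invisibly.
#' @export
train_step <- function(batch, nets, cfg, state) {
  stopifnot(length(batch) > 0L)
  ba <- batch_arrays(batch)
  L <- nets$generator$L
  onehot <- one_hot_masks(ba$masks, L)
  labels <- image_labels(ba$masks)
  gp <- network_params(nets$generator)
  dp <- network_params(nets$discriminator)
  sp <- network_params(nets$scoln)
  g_probs_val <- NULL

  for (phase in cfg$phase_order) {
    if (phase == "discriminator") {
      tape <- new_tape(training = TRUE)
      fake <- forward_generator(nets$generator, ba$x, tape,
                                ablation = cfg$ablation)
      fake_probs <- fake$probs$val  # constant for the D phase
      tape <- new_tape(training = TRUE)
      zero_grads(dp)
      real_out <- forward_discriminator(nets$discriminator, ba$x, onehot, tape)
      fake_out <- forward_discriminator(nets$discriminator, ba$x, fake_probs,
                                        tape)
      embed_node <- param_node(tape, nets$discriminator$embed)
      l_real <- loss_bce_logits(tape, real_out$logit, rep(1, length(batch)))
      l_fake <- loss_bce_logits(tape, fake_out$logit, rep(0, length(batch)))
      l_2c <- loss_two_c_node(tape, real_out$proj, embed_node, labels,
                              cfg$temperature)
      total <- op_add_scalars(tape, list(l_real, l_fake, l_2c))
      check_finite_loss(total$val, "discriminator")
      tape_backward(tape, total)
      optim_step(dp, cfg)
      zero_grads(dp)
      state$loss_d <- c(state$loss_d, total$val)
    } else if (phase == "generator") {
      tape <- new_tape(training = TRUE)
      zero_grads(c(gp, dp))
      use_rrm <- nets$generator$cfg$rrm_enabled && !("rrm" %in% cfg$ablation)
      gout <- forward_generator(nets$generator, ba$x, tape,
                                ablation = cfg$ablation, with_rrm = use_rrm)
      g_probs_val <- gout$probs$val
      dout <- forward_discriminator(nets$discriminator, gout$input,
                                    gout$probs, tape)
      embed_node <- param_node(tape, nets$discriminator$embed)
      l_2c <- loss_two_c_node(tape, dout$proj, embed_node, labels,
                              cfg$temperature)
      l_l1 <- loss_l1_node(tape, gout$probs, onehot)
      l_pix <- loss_pixel_ce(tape, gout$logits, ba$masks)
      losses <- list(l_2c, l_l1, l_pix)
      weights <- c(1, cfg$lambda_l1, 1)
      if (use_rrm) {
        labs <- unlist(lapply(seq_len(dim(ba$masks)[3]), function(i) {
          extract_regions(ba$masks[, , i],
                          r = nets$generator$cfg$region_size)$labels
        }))
        freq <- state$region_freq
        if (is.null(freq)) {
          freq <- region_frequencies(
            lapply(seq_len(dim(ba$masks)[3]), function(i) ba$masks[, , i]),
            r = nets$generator$cfg$region_size, n_classes = L)
        }
        l_reg <- loss_region_node(tape, gout$rrm_logits, labs,
                                  region_weights(freq))
        losses <- c(losses, list(l_reg))
        weights <- c(weights, cfg$region_weight)
      }
      total <- op_add_scalars(tape, losses, weights)
      check_finite_loss(total$val, "generator")
      tape_backward(tape, total)
      optim_step(gp, cfg)       # discriminator gradients are discarded
      zero_grads(c(gp, dp))
      state$loss_g <- c(state$loss_g, total$val)
    } else if (phase == "scoln") {
      if ("scoln" %in% cfg$ablation) next
      if (is.null(g_probs_val)) {
        tape <- new_tape(training = TRUE)
        g_probs_val <- forward_generator(nets$generator, ba$x, tape,
                                         ablation = cfg$ablation)$probs$val
      }
      n <- length(batch)
      fg <- g_probs_val[, , 2L, , drop = FALSE]
      targets <- array(0, c(dim(fg)[1], dim(fg)[2], 2L, n))
      errs <- numeric(n)
      for (i in seq_len(n)) {
        cm <- correction_maps(matrix(fg[, , 1L, i], dim(fg)[1]),
                              ba$masks[, , i])
        targets[, , 1L, i] <- cm$fn_map
        targets[, , 2L, i] <- cm$fp_map
        errs[i] <- mean(abs(fg[, , 1L, i] - ba$masks[, , i]))
      }
      tape <- new_tape(training = TRUE)
      zero_grads(sp)
      sout <- forward_scoln(nets$scoln, ba$x, fg, tape)
      l_bce <- loss_bce_logits(tape, sout$logits, targets)
      losses <- list(l_bce); weights <- 1
      hi <- which(errs > stats::median(errs))
      lo <- setdiff(seq_len(n), hi)
      if (length(hi) >= 2L && length(lo) >= 1L) {
        l_scon <- loss_scon_node(tape, sout$embed, anchors = hi,
                                 pos_sets = lapply(hi, function(a)
                                   setdiff(hi, a)),
                                 neg_sets = lapply(hi, function(a) lo),
                                 scale = 1 / cfg$temperature)
        losses <- c(losses, list(l_scon))
        weights <- c(weights, cfg$scon_weight)
      }
      total <- op_add_scalars(tape, losses, weights)
      check_finite_loss(total$val, "scoln")
      tape_backward(tape, total)
      optim_step(sp, cfg)
      zero_grads(sp)
      state$loss_s <- c(state$loss_s, total$val)
    }
  }
  invisible(state)
}

pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  hp <- ceiling(d[1] / mult) * mult
  wp <- ceiling(d[2] / mult) * mult
  if (hp == d[1] && wp == d[2]) return(list(x = x, h = d[1], w = d[2]))
  out <- array(0, c(hp, wp, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = out, h = d[1], w = d[2])
}

#' Segment samples with a trained generator (and optional correction)
#'
#' Runs the generator in inference mode (dropout off, stored
#' normalization statistics, region head never executed). With
#' `use_correction`, SCoLN's predicted false-negative map is added to and
#' its false-positive map subtracted from the foreground probability
#' before thresholding. Inputs whose size is not divisible by
#' `2^levels` are zero-padded and the output cropped back.
#'
#' @param gen trained [build_generator()] network.
#' @param scoln trained [build_scoln()] network, or `NULL`.
#' @param samples list of [image_sample()] objects (already preprocessed).
#' @param use_correction apply the SCoLN correction (default TRUE when a
#'   network is supplied).
#' @param threshold binarization threshold (default 0.5).
#' @return List of `seg_result` objects: `prob` (`h x w x L`), binary
#'   `mask`, and `correction` ([correction_maps()] or `NULL`).
#' @export
predict_ccgan <- function(gen, scoln = NULL, samples, use_correction = !is.null(scoln),
                          threshold = 0.5) {
  mult <- 2L^gen$cfg$levels
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    x <- array(s$image, c(dim(s$image), 1L))
    padded <- pad_to_multiple(x, mult)
    tape <- new_tape(training = FALSE)
    g <- forward_generator(gen, padded$x, tape)
    prob <- g$probs$val[seq_len(padded$h), seq_len(padded$w), , 1L]
    fg <- prob[, , 2L]
    correction <- NULL
    if (use_correction && !is.null(scoln)) {
      tape2 <- new_tape(training = FALSE)
      sc <- forward_scoln(scoln, padded$x,
                          g$probs$val[, , 2L, , drop = FALSE], tape2)
      mv <- sc$maps$val[seq_len(padded$h), seq_len(padded$w), , 1L]
      correction <- structure(list(fn_map = mv[, , 1L], fp_map = mv[, , 2L]),
                              class = "correction_maps")
      mask <- corrected_mask(fg, correction, threshold)
    } else {
      mask <- matrix(as.integer(fg >= threshold), nrow(fg), ncol(fg))
    }
    out[[i]] <- structure(list(id = s$id, prob = prob, mask = mask,
                               correction = correction),
                          class = "seg_result")
  }
  out
}

#' Per-sample evaluation of segmentation results
#'
#' @param results list of `seg_result` from [predict_ccgan()].
#' @param samples matching list of [image_sample()] with ground truth.
#' @return data.frame with one metrics row per sample.
#' @export
evaluate_samples <- function(results, samples) {
  rows <- lapply(seq_along(results), function(i) {
    m <- seg_metrics(confusion(results[[i]]$mask, samples[[i]]$mask))
    data.frame(id = samples[[i]]$id, fold = samples[[i]]$fold,
               dice = m$dice, jaccard = m$jaccard, precision = m$precision,
               recall = m$recall, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train with k-fold cross-validation and early stopping
#'
#' For each requested fold, trains on the remaining folds and validates
#' on the held-out one, monitoring mean validation Dice; training stops
#' early when the Dice has not improved for `early_stop_patience` epochs,
#' and the best-epoch parameters are restored.
#'
#' @param dataset list of [image_sample()] objects.
#' @param cfg a [train_config()].
#' @param gen_cfg a [generator_config()] shared by the three networks.
#' @param folds_to_run integer fold ids to run (default: all).
#' @param verbose print per-epoch progress.
#' @return List with `folds` (per fold: `nets`, `state`, `best_dice`,
#'   `best_epoch`, `history`) and `metrics` (per-fold and pooled
#'   mean +/- sd table over held-out samples, via [aggregate_metrics()]).
#' @export
fit_ccgan <- function(dataset, cfg, gen_cfg = generator_config(),
                      folds_to_run = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(dataset) < cfg$folds) stop("fewer samples than folds")
  fold_ids <- vapply(dataset, function(s) s$fold, 0L)
  if (length(unique(fold_ids)) < 2L)
    dataset <- split_folds(dataset, cfg$folds, cfg$seed)
  fold_ids <- vapply(dataset, function(s) s$fold, 0L)
  if (is.null(folds_to_run)) folds_to_run <- sort(unique(fold_ids))
  L <- max(vapply(dataset, function(s) max(s$mask), 0L)) + 1L
  L <- max(L, 2L)
  c_in <- dim(dataset[[1L]]$image)[3]
  fold_out <- list()
  all_eval <- NULL
  for (f in folds_to_run) {
    train_set <- dataset[fold_ids != f]
    val_set <- dataset[fold_ids == f]
    if (length(train_set) == 0L || length(val_set) == 0L)
      stop("fold ", f, " leaves an empty train or validation set")
    seed_f <- cfg$seed + 1000L * (f + 1L)
    nets <- list(
      generator = build_generator(gen_cfg, L, c_in, seed = seed_f),
      discriminator = build_discriminator(gen_cfg, L, c_in, seed = seed_f + 1L),
      scoln = build_scoln(gen_cfg, c_in, seed = seed_f + 2L)
    )
    state <- train_state()
    state$region_freq <- region_frequencies(
      lapply(train_set, function(s) s$mask), r = gen_cfg$region_size,
      n_classes = L)
    best <- list(dice = -Inf, epoch = 0L, snap = NULL)
    history <- data.frame()
    stale <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      set.seed(seed_f + epoch)
      ord <- base::sample(length(train_set))
      starts <- seq(1L, length(ord), by = cfg$batch_size)
      for (b in starts) {
        idx <- ord[b:min(b + cfg$batch_size - 1L, length(ord))]
        train_step(train_set[idx], nets, cfg, state)
      }
      state$epoch <- epoch
      use_corr <- !("scoln" %in% cfg$ablation)
      res <- predict_ccgan(nets$generator,
                           if (use_corr) nets$scoln else NULL,
                           val_set, use_correction = use_corr,
                           threshold = cfg$threshold)
      ev <- evaluate_samples(res, val_set)
      dice <- mean(ev$dice)
      state$best_val_dsc <- max(state$best_val_dsc, dice)
      history <- rbind(history, data.frame(epoch = epoch, val_dice = dice))
      if (verbose)
        message(sprintf("fold %d epoch %d: val dice %.4f", f, epoch, dice))
      if (dice > best$dice) {
        best <- list(dice = dice, epoch = epoch,
                     snap = lapply(nets, snapshot_network))
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$early_stop_patience) break
      }
    }
    # restore best-epoch weights and normalization statistics
    for (nm in names(nets)) restore_network(nets[[nm]], best$snap[[nm]])
    use_corr <- !("scoln" %in% cfg$ablation)
    res <- predict_ccgan(nets$generator, if (use_corr) nets$scoln else NULL,
                         val_set, use_correction = use_corr,
                         threshold = cfg$threshold)
    ev <- evaluate_samples(res, val_set)
    all_eval <- rbind(all_eval, ev)
    fold_out[[as.character(f)]] <- list(nets = nets, state = state,
                                        best_dice = best$dice,
                                        best_epoch = best$epoch,
                                        history = history)
  }
  list(folds = fold_out,
       metrics = aggregate_metrics(all_eval, folds = all_eval$fold),
       per_sample = all_eval)
}
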