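#' Training configuration
#'
#' The optimisation recipe: binary cross-entropy loss minimised with Adam
#' (initial learning rate 0.01, beta1 = 0.9, beta2 = 0.999), batch size 8,
#' at most 300 epochs. The learning rate is multiplied by 0.3 whenever 10
#' consecutive epochs pass without a new strict minimum of the monitored
#' loss; after 20 such epochs training stops and the best-loss weights are
#' restored. The monitored loss is the training loss by default (set
#' `monitor = "validation"` and pass `holdout` to [train()] to monitor a
#' held-out split instead).
#'
#' @param lr_init Initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Images per gradient step.
#' @param max_epochs Epoch cap.
#' @param lr_factor Multiplicative learning-rate drop on plateau.
#' @param lr_patience_epochs Plateau length triggering a drop.
#' @param stop_patience_epochs Plateau length triggering early stop.
#' @param restore_best Restore the weights of the lowest-loss epoch.
#' @param monitor `"training"` or `"validation"`.
#' @param rng_seed Seed for shuffling, augmentation and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr_init = 0.01, beta1 = 0.9, beta2 = 0.999,
                            batch_size = 8L, max_epochs = 300L,
                            lr_factor = 0.3, lr_patience_epochs = 10L,
                            stop_patience_epochs = 20L, restore_best = TRUE,
                            monitor = c("training", "validation"),
                            rng_seed = 1L) {
  assert_that(lr_patience_epochs > 0 && stop_patience_epochs > 0,
              "patience values must be positive")
  assert_that(batch_size >= 1 && max_epochs >= 1, "sizes must be positive")
  structure(list(loss = "binary_cross_entropy", lr_init = lr_init,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_factor = lr_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 stop_patience_epochs = as.integer(stop_patience_epochs),
                 restore_best = isTRUE(restore_best),
                 monitor = match.arg(monitor),
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

# Plateau scheduler as a pure function so the schedule contract is testable
# without running a network: feed the per-epoch monitored loss, read back the
# learning rate and the stop flag. A "new minimum" is strict.
plateau_init <- function(lr, lr_factor, lr_patience, stop_patience) {
  list(lr = lr, lr_factor = lr_factor, lr_patience = lr_patience,
       stop_patience = stop_patience, best = Inf, best_epoch = 0L,
       since_best = 0L, epoch = 0L, stop = FALSE)
}

plateau_step <- function(state, loss) {
  state$epoch <- state$epoch + 1L
  if (loss < state$best) {
    state$best <- loss
    state$best_epoch <- state$epoch
    state$since_best <- 0L
  } else {
    state$since_best <- state$since_best + 1L
    if (state$since_best %% state$lr_patience == 0L) {
      state$lr <- state$lr * state$lr_factor
    }
    if (state$since_best >= state$stop_patience) state$stop <- TRUE
  }
  state
}

# Accept either a tibble with image/mask (or truth) list-columns, or a plain
# list of list(image =, mask =) pairs.
as_pair_list <- function(dataset) {
  if (is.data.frame(dataset)) {
    mask_col <- intersect(c("mask", "truth"), names(dataset))[1]
    assert_that(!is.na(mask_col) && "image" %in% names(dataset),
                "dataset needs 'image' and 'mask'/'truth' columns")
    pairs <- purrr::map2(dataset$image, dataset[[mask_col]],
                         function(i, m) list(image = as_image(i),
                                             mask = as_mask(m)))
  } else {
    pairs <- lapply(dataset, function(p) list(image = as_image(p$image),
                                              mask = as_mask(p$mask)))
  }
  assert_that(length(pairs) > 0, "dataset is empty")
  pairs
}

#' Train the stochastic network
#'
#' Minimises pixelwise binary cross-entropy with Adam under the plateau
#' learning-rate schedule and early stopping of [training_config()]. The loss
#' is computed with dropout active: by construction the network has no
#' deterministic evaluation mode, so training mode and inference mode see the
#' same model. Augmentation, when configured, is applied on the fly, so every
#' epoch sees a different warp of each image. Fully reproducible under a
#' fixed `rng_seed`.
#'
#' @param model A `patmc_model` from [build_network()].
#' @param dataset Training pairs: a tibble with `image` and `mask` (or
#'   `truth`) list-columns, or a list of `list(image =, mask =)`.
#' @param tcfg A [training_config()].
#' @param acfg Optional [augmentation_config()]; `NULL` disables
#'   augmentation.
#' @param holdout Optional validation pairs (same formats); required when
#'   `tcfg$monitor == "validation"`.
#' @param verbose Print a line per epoch.
#' @return An object of class `patmc_fit`: the trained model plus the
#'   per-epoch log (see `tidy()`/`glance()` methods).
#' @export
train <- function(model, dataset, tcfg = training_config(), acfg = NULL,
                  holdout = NULL, verbose = FALSE) {
  pairs <- as_pair_list(dataset)
  val_pairs <- if (!is.null(holdout)) as_pair_list(holdout)
  assert_that(tcfg$monitor == "training" || !is.null(val_pairs),
              "validation monitoring requires a holdout set")
  set.seed(tcfg$rng_seed)
  shape <- dim(pairs[[1]]$image$pixels)

  P <- model$params
  pn <- ls(P)
  adam <- new.env(parent = emptyenv())
  for (nm in pn) adam[[nm]] <- list(m = P[[nm]] * 0, v = P[[nm]] * 0)
  tstep <- 0

  sched <- plateau_init(tcfg$lr_init, tcfg$lr_factor, tcfg$lr_patience_epochs,
                        tcfg$stop_patience_epochs)
  best_snap <- NULL
  log <- vector("list", tcfg$max_epochs)

  for (epoch in seq_len(tcfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample(length(pairs))
    ep_loss <- 0
    n_seen <- 0
    for (start in seq(1, length(ord), by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1, length(ord))]
      nb <- length(idx)
      xb <- array(0, c(shape, 1L, nb))
      yb <- array(0, c(shape, 1L, nb))
      for (k in seq_len(nb)) {
        p <- pairs[[idx[k]]]
        if (!is.null(acfg)) {
          tr <- sample_transform(acfg, shape)
          p <- apply_transform(p$image, p$mask, tr)
        }
        xb[, , 1L, k] <- p$image$pixels
        yb[, , 1L, k] <- p$mask$pixels * 1
      }
      tape <- ag_tape()
      logits <- run_net(model, xb, tape, training = TRUE)
      loss <- ag_bce_loss(tape, logits, yb)
      if (!is.finite(loss$value)) {
        stop(sprintf("non-finite loss at epoch %d (lr = %g); aborting",
                     epoch, sched$lr), call. = FALSE)
      }
      ag_backward(tape, loss)
      tstep <- tstep + 1
      for (nm in pn) {
        node <- tape$pnodes[[nm]]
        if (is.null(node) || is.null(node$grad)) next
        st <- adam[[nm]]
        st$m <- tcfg$beta1 * st$m + (1 - tcfg$beta1) * node$grad
        st$v <- tcfg$beta2 * st$v + (1 - tcfg$beta2) * node$grad^2
        adam[[nm]] <- st
        mhat <- st$m / (1 - tcfg$beta1^tstep)
        vhat <- st$v / (1 - tcfg$beta2^tstep)
        P[[nm]] <- P[[nm]] - sched$lr * mhat / (sqrt(vhat) + 1e-8)
      }
      ep_loss <- ep_loss + loss$value * nb
      n_seen <- n_seen + nb
    }
    ep_loss <- ep_loss / n_seen

    monitored <- ep_loss
    if (tcfg$monitor == "validation") {
      monitored <- validation_loss(model, val_pairs)
    }
    lr_now <- sched$lr
    sched <- plateau_step(sched, monitored)
    if (sched$best_epoch == epoch && tcfg$restore_best) {
      best_snap <- snapshot_model(model)
    }
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss, monitored = monitored, lr = lr_now,
      seconds = proc.time()[["elapsed"]] - t0)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  lr %.5g  (%.1fs)", epoch,
                      ep_loss, lr_now, log[[epoch]]$seconds))
    }
    if (sched$stop) break
  }

  if (tcfg$restore_best && !is.null(best_snap)) restore_model(model, best_snap)
  structure(list(model = model,
                 log = dplyr::bind_rows(log[!vapply(log, is.null, TRUE)]),
                 best_epoch = sched$best_epoch, best_loss = sched$best,
                 stopped_early = sched$stop, tcfg = tcfg),
            class = "patmc_fit")
}

# Mean BCE over a holdout set, dropout active (the network has no other mode).
validation_loss <- function(model, pairs) {
  tot <- 0
  for (p in pairs) {
    d <- dim(p$image$pixels)
    x <- array(p$image$pixels, c(d, 1L, 1L))
    logits <- run_net(model, x, tape = NULL, training = FALSE)
    pr <- clip01(sigmoid(logits$value))
    y <- p$mask$pixels * 1
    eps <- 1e-12
    tot <- tot - mean(y * log(pr + eps) + (1 - y) * log(1 - pr + eps))
  }
  tot / length(pairs)
}

#' @export
print.patmc_fit <- function(x, ...) {
  cat(sprintf("<patmc_fit> %d epochs, best loss %.5f at epoch %d%s\n",
              nrow(x$log), x$best_loss, x$best_epoch,
              if (x$stopped_early) " (early stop)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.patmc_fit <- function(x, ...) x$log

#' @importFrom generics glance
#' @export
glance.patmc_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_loss = x$best_loss, final_lr = x$log$lr[nrow(x$log)],
                 stopped_early = x$stopped_early)
}

#' Mean consensus Dice over a holdout set
#'
#' For each holdout pair, draws `n_mc` Monte Carlo samples, forms the
#' consensus mask and scores it against the truth; returns the mean Dice.
#'
#' @param model A `patmc_model`, a `patmc_fit`, or (for testing) a function
#'   mapping an image to a probability matrix.
#' @param holdout Labelled pairs (tibble or list, as in [train()]).
#' @param n_mc Number of Monte Carlo samples per image.
#' @return Numeric scalar mean Dice.
#' @export
evaluate_epoch <- function(model, holdout, n_mc = 15L) {
  pairs <- as_pair_list(holdout)
  assert_that(length(pairs) > 0, "holdout is empty")
  mean(vapply(pairs, function(p) {
    s <- draw_mc_samples(model, p$image, n_mc)
    dice(consensus(s), p$mask)
  }, numeric(1)))
}

#' Random train/test split
#'
#' Mirrors an 80/20 random split (the convention used to carve a 432-subject
#' ground-truth set into 345 training and 87 test cases), seeded for
#' reproducibility.
#'
#' @param dataset A tibble of labelled cases.
#' @param test_frac Fraction assigned to the test set.
#' @param seed RNG seed for the split.
#' @return A list with `train` and `test` tibbles.
#' @export
train_test_split <- function(dataset, test_frac = 0.2, seed = 1L) {
  assert_that(is.data.frame(dataset), "dataset must be a data frame")
  n <- nrow(dataset)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  test_idx <- sample(n, round(test_frac * n))
  list(train = dataset[setdiff(seq_len(n), test_idx), ],
       test = dataset[test_idx, ])
}
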