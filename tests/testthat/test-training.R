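pm <- asNamespace("patmc")

test_that("the plateau schedule drops the rate at 10 and stops at 20 stagnant epochs", {
  st <- pm$plateau_init(0.01, 0.3, 10L, 20L)
  st <- pm$plateau_step(st, 1.0)   # epoch 1: new best
  for (k in 1:19) st <- pm$plateau_step(st, 1.0)  # flat
  expect_false(st$stop)            # 19 stagnant epochs: not yet
  expect_equal(st$lr, 0.01 * 0.3)  # one drop at 10
  st <- pm$plateau_step(st, 1.0)   # 20th stagnant epoch
  expect_true(st$stop)
  expect_equal(st$lr, 0.01 * 0.3^2)  # second drop coincides with the stop
  expect_equal(st$best_epoch, 1L)

  # strictly decreasing loss: never drops, never stops
  st2 <- pm$plateau_init(0.01, 0.3, 10L, 20L)
  for (k in 1:50) st2 <- pm$plateau_step(st2, 1 / k)
  expect_equal(st2$lr, 0.01)
  expect_false(st2$stop)
  expect_equal(st2$best_epoch, 50L)

  # a new minimum resets both patiences
  st3 <- pm$plateau_init(0.01, 0.3, 10L, 20L)
  st3 <- pm$plateau_step(st3, 1.0)
  for (k in 1:9) st3 <- pm$plateau_step(st3, 1.0)
  st3 <- pm$plateau_step(st3, 0.5)
  expect_equal(st3$since_best, 0L)
  expect_equal(st3$best_epoch, 11L)
})

test_that("training defaults mirror the published recipe", {
  tc <- training_config()
  expect_equal(tc$loss, "binary_cross_entropy")
  expect_equal(tc$lr_init, 0.01)
  expect_equal(tc$beta1, 0.9)
  expect_equal(tc$beta2, 0.999)
  expect_equal(tc$batch_size, 8L)
  expect_equal(tc$max_epochs, 300L)
  expect_equal(tc$lr_factor, 0.3)
  expect_equal(tc$lr_patience_epochs, 10L)
  expect_equal(tc$stop_patience_epochs, 20L)
  expect_true(tc$restore_best)
  expect_error(training_config(lr_patience_epochs = 0), "positive")
})

test_that("evaluate_epoch agrees with the metrics module on stub models", {
  set.seed(30)
  truth <- matrix(runif(16 * 16) > 0.6, 16, 16)
  pairs <- list(list(image = grayscale_image(truth * 1),
                     mask = binary_mask(truth)))
  perfect <- function(img) img$pixels  # echoes the truth as probabilities
  expect_equal(evaluate_epoch(perfect, pairs, n_mc = 3), 1.0)

  background <- function(img) matrix(0, nrow(img$pixels), ncol(img$pixels))
  expect_equal(evaluate_epoch(background, pairs, n_mc = 3), 0.0)

  flipped <- function(img) {
    p <- img$pixels
    k <- which(p >= 0.5)[1]
    p[k] <- 0
    p
  }
  fmask <- truth; fmask[which(truth)[1]] <- FALSE
  expect_equal(evaluate_epoch(flipped, pairs, n_mc = 3),
               dice(binary_mask(fmask), binary_mask(truth)))

  expect_error(evaluate_epoch(perfect, list(), n_mc = 3), "empty")
})

test_that("a tiny run learns, logs, restores the best epoch and reproduces", {
  set.seed(31)
  truth <- matrix(FALSE, 16, 16)
  truth[5:11, 6:12] <- TRUE
  mk_pair <- function(seed) {
    set.seed(seed)
    img <- 0.2 + 0.6 * truth + matrix(rnorm(256, sd = 0.05), 16, 16)
    list(image = grayscale_image(pmin(pmax(img, 0), 1)),
         mask = binary_mask(truth))
  }
  ds <- lapply(1:4, mk_pair)
  tc <- training_config(batch_size = 2L, max_epochs = 6L, rng_seed = 5L)

  set.seed(32); m1 <- build_network(tiny_network_config())
  fit1 <- train(m1, ds, tc)
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_equal(nrow(fit1$log), 6L)
  expect_lt(fit1$log$loss[6], fit1$log$loss[1])
  expect_true(all(diff(fit1$log$lr) <= 0))  # monotone non-increasing LR
  g <- glance(fit1)
  expect_equal(g$best_loss, min(fit1$log$monitored))

  # bit-identical re-run under the same seeds
  set.seed(32); m2 <- build_network(tiny_network_config())
  fit2 <- train(m2, ds, tc)
  expect_identical(fit1$log$loss, fit2$log$loss)
  nm <- ls(m1$params)[1]
  expect_identical(m1$params[[nm]], m2$params[[nm]])

  expect_error(train(m1, list(), tc), "empty")
})

test_that("train_test_split mirrors an 80/20 partition", {
  ds <- tibble::tibble(id = 1:432)
  sp <- train_test_split(ds, test_frac = 0.2, seed = 3)
  expect_equal(nrow(sp$test), 86)  # round(0.2 * 432)
  expect_equal(nrow(sp$train), 346)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- train_test_split(ds, test_frac = 0.2, seed = 3)
  expect_identical(sp$test$id, sp2$test$id)
})
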