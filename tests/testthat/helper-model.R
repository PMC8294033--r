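# The desk-scale study conditions used by the heavyweight end-to-end tests:
# 64 x 64 phantoms at 1.82 mm, a reduced-width network, 200 easy training
# phantoms and a 50-phantom matched holdout. Training happens once per test
# run and is cached for every test that needs the trained model.

study_conditions <- function() {
  list(
    phantom = phantom_config(image_shape = c(64L, 64L)),
    network = network_config(base_filters_U = c(6, 12, 24, 48),
                             respath_filters_F = c(6, 12, 24, 48),
                             respath_length_L = c(4, 3, 2, 1)),
    training = training_config(max_epochs = 30L, rng_seed = 11L),
    augment = augmentation_config(),
    easy_spectrum = c(0, 0.1, 0.2, 0.3),
    full_spectrum = c(0, 0.25, 0.5, 0.75, 1),
    n_train = 200L, n_holdout = 50L, n_val = 60L, n_test = 120L,
    seed_train = 101L, seed_holdout = 202L, seed_val = 303L,
    seed_test = 404L, seed_init = 7L, seed_cal = 13L, seed_eval = 17L,
    seed_sweep = 19L)
}

.model_cache <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.model_cache$fix)) return(.model_cache$fix)
  sc <- study_conditions()
  train_ds <- generate_dataset(sc$phantom, sc$n_train, sc$easy_spectrum,
                               sc$seed_train)
  hold_ds <- generate_dataset(sc$phantom, sc$n_holdout, sc$easy_spectrum,
                              sc$seed_holdout)
  set.seed(sc$seed_init)
  model <- build_network(sc$network)
  fit <- train(model, train_ds, sc$training, sc$augment)
  .model_cache$fix <- list(fit = fit, holdout = hold_ds, sc = sc)
  .model_cache$fix
}

# Calibration on the validation spectrum plus per-case predicted/true Dice on
# the mixed-difficulty test set; computed once and shared by the tests that
# look at QC correlation and difficulty-graded degradation.
spectrum_eval <- function() {
  if (!is.null(.model_cache$eval)) return(.model_cache$eval)
  fix <- trained_fixture()
  sc <- fix$sc
  val_ds <- generate_dataset(sc$phantom, sc$n_val, sc$full_spectrum,
                             sc$seed_val)
  test_ds <- generate_dataset(sc$phantom, sc$n_test, sc$full_spectrum,
                              sc$seed_test)
  cal <- cmd_calibrate(fix$fit$model, val_ds, n_mc = 15, seed = sc$seed_cal)
  set.seed(sc$seed_eval)
  res <- purrr::map_dfr(seq_len(nrow(test_ds)), function(k) {
    s <- draw_mc_samples(fix$fit$model, test_ds$image[[k]], 15)
    tibble::tibble(difficulty = test_ds$difficulty[k],
                   d_mc = mean_pairwise_dice(s),
                   true_dice = dice(consensus(s), test_ds$truth[[k]]))
  })
  res$predicted_dice <- predict_dice(cal, res$d_mc)
  .model_cache$eval <- list(cal = cal, results = res)
  .model_cache$eval
}
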