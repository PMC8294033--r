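#' Draw Monte Carlo segmentation samples
#'
#' Runs `n` independent stochastic forward passes (dropout active) and caches
#' both the probability maps and their 0.5-thresholded Boolean maps. The
#' threshold uses `>=`, matching the consensus rule's boundary semantics.
#'
#' @param model A `patmc_model`, or (for testing) a function mapping a
#'   [grayscale_image()] to a probability matrix.
#' @param img A preprocessed [grayscale_image()].
#' @param n Number of samples, default 15.
#' @param rng_seed Optional seed making the whole set reproducible.
#' @return An object of class `mc_sample_set`.
#' @export
draw_mc_samples <- function(model, img, n = 15L, rng_seed = NULL) {
  assert_that(n >= 1, "n must be >= 1")
  img <- as_image(img)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  prob_maps <- lapply(seq_len(n), function(i) {
    if (is.function(model)) {
      probability_map(model(img), img$spacing_mm)
    } else {
      forward_sample(model, img)
    }
  })
  bool_maps <- lapply(prob_maps, function(p) {
    binary_mask(p$pixels >= 0.5, p$spacing_mm)
  })
  structure(list(prob_maps = prob_maps, bool_maps = bool_maps,
                 n = as.integer(n), spacing_mm = img$spacing_mm,
                 source_id = img$source_id),
            class = "mc_sample_set")
}

#' @export
print.mc_sample_set <- function(x, ...) {
  cat(sprintf("<mc_sample_set> n = %d, %d x %d px ('%s')\n", x$n,
              nrow(x$bool_maps[[1]]$pixels), ncol(x$bool_maps[[1]]$pixels),
              x$source_id))
  invisible(x)
}

#' Consensus segmentation by voxelwise majority
#'
#' A pixel is foreground when the mean of the Boolean sample maps reaches
#' 0.5: `S(x) = 1` iff `sum_i S_i(x) / N >= 0.5`, with `>=` at the boundary,
#' so with an even N a split vote counts as foreground.
#'
#' @param samples An `mc_sample_set`.
#' @return A [binary_mask()].
#' @export
consensus <- function(samples) {
  acc <- Reduce(`+`, lapply(samples$bool_maps, function(m) m$pixels * 1))
  binary_mask(acc / samples$n >= 0.5, samples$spacing_mm)
}

#' PAT area with Monte Carlo uncertainty
#'
#' Per-sample area is the foreground pixel count times the physical pixel
#' area, in cm^2; reported are the mean and the sample standard deviation
#' across the N samples (the paper-style area readout and its uncertainty).
#' With a single sample the sd is reported as 0 with a warning.
#'
#' @param samples An `mc_sample_set`.
#' @return A one-row tibble with `area_mean_cm2` and `area_sd_cm2`.
#' @export
area_with_uncertainty <- function(samples) {
  areas <- vapply(samples$bool_maps, mask_area_cm2, numeric(1))
  if (length(areas) == 1) {
    warning("single MC sample: area sd reported as 0")
    return(tibble::tibble(area_mean_cm2 = areas, area_sd_cm2 = 0))
  }
  tibble::tibble(area_mean_cm2 = mean(areas), area_sd_cm2 = stats::sd(areas))
}

#' Mean pairwise Dice across Monte Carlo samples (d^MC)
#'
#' `d_mc = 2 / (N (N - 1)) * sum_{i<j} Dice(S_i, S_j)` — the agreement
#' statistic used to predict the true Dice of the consensus segmentation.
#'
#' @param samples An `mc_sample_set` with `n >= 2`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
mean_pairwise_dice <- function(samples) {
  assert_that(samples$n >= 2, "mean pairwise Dice requires n >= 2")
  prs <- utils::combn(samples$n, 2)
  mean(apply(prs, 2, function(ij) {
    dice(samples$bool_maps[[ij[1]]], samples$bool_maps[[ij[2]]])
  }))
}

#' Global intersection-over-union across Monte Carlo samples (IoU^G)
#'
#' The intersection of all sample masks divided by their union; defined as 1
#' when the union is empty. The alternative quality statistic that the mean
#' pairwise Dice outperformed.
#'
#' @param samples An `mc_sample_set` with `n >= 2`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
global_iou <- function(samples) {
  assert_that(samples$n >= 2, "global IoU requires n >= 2")
  inter <- Reduce(`&`, lapply(samples$bool_maps, function(m) m$pixels))
  uni <- Reduce(`|`, lapply(samples$bool_maps, function(m) m$pixels))
  if (sum(uni) == 0) return(1)
  sum(inter) / sum(uni)
}

#' Fit the linear quality-control calibration
#'
#' Ordinary least squares of the true Dice on the mean pairwise Dice of the
#' Monte Carlo samples: the linear correction that maps the raw agreement
#' statistic d^MC onto a predicted true Dice. Fit on held-out validation
#' pairs, never on the test set.
#'
#' @param pairs A data frame with numeric columns `d_mc` and `true_dice`
#'   (at least 3 rows, `d_mc` not constant).
#' @return An object of class `qc_calibration` with `slope`, `intercept`,
#'   `fit_n` and `fit_r` (Pearson correlation of the fit).
#' @export
fit_qc_calibration <- function(pairs) {
  assert_that(is.data.frame(pairs) &&
                all(c("d_mc", "true_dice") %in% names(pairs)),
              "pairs must have columns d_mc and true_dice")
  assert_that(nrow(pairs) >= 3, "need at least 3 calibration pairs")
  assert_that(stats::sd(pairs$d_mc) > 0,
              "d_mc is constant: slope not identifiable")
  fit <- stats::lm(true_dice ~ d_mc, data = pairs)
  co <- stats::coef(fit)
  structure(list(slope = unname(co["d_mc"]),
                 intercept = unname(co["(Intercept)"]),
                 fit_n = nrow(pairs),
                 fit_r = stats::cor(pairs$d_mc, pairs$true_dice),
                 data = tibble::as_tibble(pairs[c("d_mc", "true_dice")])),
            class = "qc_calibration")
}

#' @export
print.qc_calibration <- function(x, ...) {
  cat(sprintf("<qc_calibration> predicted_dice = %.4f + %.4f * d_mc  (n = %d, r = %.3f)\n",
              x$intercept, x$slope, x$fit_n, x$fit_r))
  invisible(x)
}

#' @export
tidy.qc_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.qc_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, fit_n = x$fit_n,
                 fit_r = x$fit_r)
}

#' Predicted Dice from the calibration
#'
#' `clip(intercept + slope * d_mc, 0, 1)`.
#'
#' @param cal A `qc_calibration`.
#' @param d_mc Numeric vector of raw mean pairwise Dice values.
#' @return Numeric vector of predicted Dice scores in `[0, 1]`.
#' @export
predict_dice <- function(cal, d_mc) clip01(cal$intercept + cal$slope * d_mc)

#' Quality class from a predicted Dice score
#'
#' Poor below 0.6, good at or above 0.8, medium in between (lower bounds
#' inclusive).
#'
#' @param predicted_dice Numeric vector.
#' @return Character vector in `{"poor", "medium", "good"}`.
#' @export
quality_class <- function(predicted_dice) {
  dplyr::case_when(predicted_dice < 0.6 ~ "poor",
                   predicted_dice >= 0.8 ~ "good",
                   TRUE ~ "medium")
}

#' Full quality-controlled segmentation result
#'
#' Combines an `mc_sample_set` with a fitted calibration into the per-image
#' result: consensus mask, area mean and sd, raw d^MC, global IoU, predicted
#' Dice and quality class.
#'
#' @param samples An `mc_sample_set` with `n >= 2`.
#' @param cal A `qc_calibration`.
#' @return An object of class `segmentation_result`.
#' @export
predict_quality <- function(samples, cal) {
  assert_that(inherits(cal, "qc_calibration"), "cal must be a qc_calibration")
  ar <- area_with_uncertainty(samples)
  d_mc <- mean_pairwise_dice(samples)
  pd <- predict_dice(cal, d_mc)
  structure(list(consensus = consensus(samples),
                 area_mean_cm2 = ar$area_mean_cm2,
                 area_sd_cm2 = ar$area_sd_cm2,
                 d_mc = d_mc, iou_g = global_iou(samples),
                 predicted_dice = pd, quality = quality_class(pd),
                 n = samples$n, source_id = samples$source_id),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> '%s': area %.2f (sd %.2f) cm^2, d_mc %.3f, predicted Dice %.3f [%s]\n",
    x$source_id, x$area_mean_cm2, x$area_sd_cm2, x$d_mc, x$predicted_dice,
    x$quality))
  invisible(x)
}

#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble::tibble(source_id = x$source_id, area_mean_cm2 = x$area_mean_cm2,
                 area_sd_cm2 = x$area_sd_cm2, d_mc = x$d_mc, iou_g = x$iou_g,
                 predicted_dice = x$predicted_dice, quality = x$quality,
                 n = x$n)
}

#' Segment one image end to end
#'
#' Preprocess to the analysis grid, draw `n` Monte Carlo samples, and return
#' the quality-controlled result. The consensus mask mapped back to the
#' source geometry is attached as `$consensus_source`.
#'
#' @param model A `patmc_model`.
#' @param img A raw [grayscale_image()] in any geometry.
#' @param cal A `qc_calibration`.
#' @param n Number of Monte Carlo samples (default 15).
#' @param spec A [grid_spec()].
#' @param rng_seed Optional seed for the sample draws.
#' @return A `segmentation_result`.
#' @export
segment_image <- function(model, img, cal, n = 15L, spec = grid_spec(),
                          rng_seed = NULL) {
  pre <- preprocess_image(img, spec)
  samples <- draw_mc_samples(model, pre, n, rng_seed)
  res <- predict_quality(samples, cal)
  res$consensus_source <- mask_to_source_geometry(res$consensus, pre)
  res
}
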