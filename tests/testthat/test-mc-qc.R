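test_that("draw_mc_samples caches thresholded maps and honours seeds", {
  set.seed(40)
  m <- build_network(tiny_network_config())
  img <- grayscale_image(matrix(runif(16 * 16), 16, 16))
  s <- draw_mc_samples(m, img, n = 4, rng_seed = 9)
  expect_equal(s$n, 4L)
  for (k in 1:4) {
    expect_identical(s$bool_maps[[k]]$pixels, s$prob_maps[[k]]$pixels >= 0.5)
  }
  s2 <- draw_mc_samples(m, img, n = 4, rng_seed = 9)
  expect_identical(lapply(s$bool_maps, `[[`, "pixels"),
                   lapply(s2$bool_maps, `[[`, "pixels"))
  expect_error(draw_mc_samples(m, img, n = 0), ">= 1")

  # a deterministic stub yields n identical maps
  stub <- function(im) (im$pixels > 0.5) * 1
  sd <- draw_mc_samples(stub, img, n = 3)
  expect_identical(sd$bool_maps[[1]]$pixels, sd$bool_maps[[3]]$pixels)
})

test_that("consensus implements the voxelwise-mean threshold exactly", {
  # pixel on in 2 of 3 samples: mean 0.667 >= 0.5 -> foreground
  m0 <- matrix(FALSE, 2, 2)
  m1 <- m0; m1[1, 1] <- TRUE
  s <- sample_set_from(list(m1, m1, m0))
  expect_true(consensus(s)$pixels[1, 1])

  # exactly N/2 of N: boundary uses >= so the pixel is foreground
  s2 <- sample_set_from(list(m1, m0))
  expect_true(consensus(s2)$pixels[1, 1])

  # idempotence on identical samples
  set.seed(41)
  mm <- matrix(runif(16) > 0.5, 4, 4)
  s3 <- sample_set_from(list(mm, mm, mm))
  expect_identical(consensus(s3)$pixels, mm)

  # 500 random sample sets against an independent per-pixel loop
  set.seed(42)
  for (trial in 1:500) {
    n <- sample(2:9, 1)
    mats <- lapply(seq_len(n), function(i) matrix(runif(64) < 0.5, 8, 8))
    got <- consensus(sample_set_from(mats))$pixels
    want <- matrix(FALSE, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + mats[[k]][i, j]
      want[i, j] <- (acc / n) >= 0.5
    }
    expect_identical(got, want)
  }
})

test_that("area mean and sd follow closed-form pixel arithmetic", {
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE  # 100 px
  s1 <- sample_set_from(list(m))
  expect_warning(ar <- area_with_uncertainty(s1), "single")
  expect_equal(ar$area_mean_cm2, 100 * 1.82 * 1.82 / 100)  # 3.3124 exactly
  expect_equal(ar$area_sd_cm2, 0)

  empty <- matrix(FALSE, 20, 20)
  s0 <- sample_set_from(list(empty, empty))
  ar0 <- area_with_uncertainty(s0)
  expect_equal(ar0$area_mean_cm2, 0)
  expect_equal(ar0$area_sd_cm2, 0)

  # areas 3.0 and 5.0 cm^2 -> mean 4, sd sqrt(2)
  px_area <- 1.82 * 1.82 / 100
  n3 <- round(3 / px_area); n5 <- round(5 / px_area)
  a3 <- matrix(FALSE, 40, 40); a3[seq_len(n3)] <- TRUE
  a5 <- matrix(FALSE, 40, 40); a5[seq_len(n5)] <- TRUE
  s35 <- sample_set_from(list(a3, a5))
  ar35 <- area_with_uncertainty(s35)
  areas <- c(n3, n5) * px_area
  expect_equal(ar35$area_mean_cm2, mean(areas))
  expect_equal(ar35$area_sd_cm2, stats::sd(areas))
})

test_that("d_mc matches a brute-force pair average and handles extremes", {
  set.seed(43)
  mm <- matrix(runif(16) > 0.4, 4, 4)
  expect_equal(mean_pairwise_dice(sample_set_from(list(mm, mm, mm))), 1)

  d1 <- matrix(FALSE, 4, 4); d1[1, 1] <- TRUE
  d2 <- matrix(FALSE, 4, 4); d2[4, 4] <- TRUE
  expect_equal(mean_pairwise_dice(sample_set_from(list(d1, d2))), 0)

  for (trial in 1:50) {
    mats <- lapply(1:3, function(i) matrix(runif(16) > 0.5, 4, 4))
    s <- sample_set_from(mats)
    brute <- mean(c(dice(mask_from(mats[[1]]), mask_from(mats[[2]])),
                    dice(mask_from(mats[[1]]), mask_from(mats[[3]])),
                    dice(mask_from(mats[[2]]), mask_from(mats[[3]]))))
    expect_equal(mean_pairwise_dice(s), brute)
  }
  expect_error(mean_pairwise_dice(sample_set_from(list(d1))), "n >= 2")
})

test_that("global IoU is intersection over union of the whole set", {
  set.seed(44)
  mm <- matrix(runif(16) > 0.4, 4, 4)
  expect_equal(global_iou(sample_set_from(list(mm, mm))), 1)

  # nested A within B: |A| / |B|
  A <- matrix(FALSE, 6, 6); A[2:3, 2:3] <- TRUE
  B <- A; B[2:5, 2:5] <- TRUE
  expect_equal(global_iou(sample_set_from(list(A, B))), sum(A) / sum(B))

  d1 <- matrix(FALSE, 4, 4); d1[1, 1] <- TRUE
  d2 <- matrix(FALSE, 4, 4); d2[4, 4] <- TRUE
  expect_equal(global_iou(sample_set_from(list(d1, d2, d1))), 0)

  e <- matrix(FALSE, 4, 4)
  expect_equal(global_iou(sample_set_from(list(e, e))), 1)
})

test_that("for two samples Dice and IoU obey D = 2J/(1+J) exactly", {
  set.seed(45)
  for (trial in 1:100) {
    a <- matrix(runif(64) > 0.5, 8, 8)
    b <- matrix(runif(64) > 0.5, 8, 8)
    s <- sample_set_from(list(a, b))
    J <- global_iou(s)
    D <- mean_pairwise_dice(s)
    expect_equal(D, 2 * J / (1 + J))
  }
})

test_that("QC calibration recovers a linear relation", {
  d <- seq(0.3, 0.95, length.out = 20)
  cal_id <- fit_qc_calibration(tibble::tibble(d_mc = d, true_dice = d))
  expect_equal(cal_id$slope, 1, tolerance = 1e-12)
  expect_equal(cal_id$intercept, 0, tolerance = 1e-12)

  cal <- fit_qc_calibration(tibble::tibble(d_mc = d,
                                           true_dice = 0.5 * d + 0.2))
  expect_equal(cal$slope, 0.5, tolerance = 1e-10)
  expect_equal(cal$intercept, 0.2, tolerance = 1e-10)
  expect_equal(cal$fit_r, 1, tolerance = 1e-10)
  expect_equal(cal$fit_n, 20L)

  set.seed(46)
  noisy <- tibble::tibble(d_mc = runif(200),
                          true_dice = 0.7 * d_mc + 0.1 + rnorm(200, sd = 0.05))
  caln <- fit_qc_calibration(noisy)
  expect_lt(abs(caln$slope - 0.7), 0.05)

  expect_error(fit_qc_calibration(tibble::tibble(d_mc = rep(0.5, 5),
                                                 true_dice = runif(5))),
               "constant")
  expect_error(fit_qc_calibration(tibble::tibble(d_mc = 1:2 / 2,
                                                 true_dice = 1:2 / 2)),
               "3 calibration pairs")
})

test_that("predicted Dice drives the quality classes with inclusive bounds", {
  id_cal <- structure(list(slope = 1, intercept = 0, fit_n = 10, fit_r = 1),
                      class = "qc_calibration")
  expect_equal(quality_class(predict_dice(id_cal, c(0.59, 0.60, 0.79, 0.80))),
               c("poor", "medium", "medium", "good"))

  half <- structure(list(slope = 0.5, intercept = 0.2, fit_n = 10, fit_r = 1),
                    class = "qc_calibration")
  expect_equal(predict_dice(half, 0.9), 0.65)
  expect_equal(quality_class(predict_dice(half, 0.9)), "medium")
  # clipping keeps predictions in [0, 1]
  expect_equal(predict_dice(structure(list(slope = 2, intercept = 0.5),
                                      class = "qc_calibration"), 0.9), 1)

  set.seed(47)
  mm <- matrix(runif(64) > 0.5, 8, 8)
  s <- sample_set_from(list(mm, mm, mm))
  res <- predict_quality(s, id_cal)
  expect_equal(res$predicted_dice, 1)
  expect_equal(res$quality, "good")
  expect_equal(res$d_mc, 1)
  expect_identical(res$consensus$pixels, mm)
  row <- tidy(res)
  expect_equal(row$area_mean_cm2, sum(mm) * 1.82^2 / 100)
})

test_that("area statistics recomputed from stored maps match the report", {
  set.seed(48)
  m <- build_network(tiny_network_config())
  img <- grayscale_image(matrix(runif(16 * 16), 16, 16))
  s <- draw_mc_samples(m, img, n = 5, rng_seed = 3)
  ar <- area_with_uncertainty(s)
  areas <- vapply(s$bool_maps, mask_area_cm2, numeric(1))
  expect_identical(ar$area_mean_cm2, mean(areas))
  expect_identical(ar$area_sd_cm2, stats::sd(areas))
})
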