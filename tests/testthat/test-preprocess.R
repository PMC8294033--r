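test_that("resampling halves a double-resolution grid and preserves constants", {
  set.seed(1)
  img <- grayscale_image(matrix(runif(416 * 416), 416, 416),
                         spacing_mm = c(0.91, 0.91))
  out <- resample_to_spacing(img, grid_spec())
  expect_equal(dim(out$pixels), c(208L, 208L))  # 416 * 0.91 / 1.82
  expect_equal(out$spacing_mm, c(1.82, 1.82))

  # identity when already at target spacing
  same <- grayscale_image(matrix(runif(64 * 64), 64, 64), c(1.82, 1.82))
  out2 <- resample_to_spacing(same, grid_spec())
  expect_equal(dim(out2$pixels), dim(same$pixels))
  expect_equal(out2$pixels, same$pixels, tolerance = 1e-12)

  # constants stay constant (edge-clamped interpolation)
  const <- grayscale_image(matrix(0.7, 100, 60), c(1.0, 2.5))
  out3 <- resample_to_spacing(const, grid_spec())
  expect_true(all(abs(out3$pixels - 0.7) < 1e-12))

  tiny <- grayscale_image(matrix(1, 2, 2), c(0.01, 0.01))
  expect_error(resample_to_spacing(tiny, grid_spec()), "collapse")
})

test_that("crop_or_pad centres with the extra pixel trailing", {
  img <- grayscale_image(matrix(seq_len(200 * 220), 200, 220), c(1.82, 1.82))
  out <- crop_or_pad(img, grid_spec())
  expect_equal(dim(out$pixels), c(208L, 208L))
  # rows: 4 px pad each side; cols: 6 px crop each side
  expect_true(all(out$pixels[1:4, ] == 0))
  expect_true(all(out$pixels[205:208, ] == 0))
  expect_equal(out$pixels[5:204, ], img$pixels[, 7:214])

  # odd difference: leading pad floor, trailing gets the extra pixel
  odd <- grayscale_image(matrix(1, 5, 208), c(1.82, 1.82))
  oo <- crop_or_pad(odd, grid_spec())
  lead_pad <- floor((208 - 5) / 2)
  expect_true(all(oo$pixels[lead_pad + (1:5), 1] == 1))
  expect_true(all(oo$pixels[seq_len(lead_pad), 1] == 0))

  ident <- grayscale_image(matrix(runif(208 * 208), 208, 208), c(1.82, 1.82))
  expect_equal(crop_or_pad(ident, grid_spec())$pixels, ident$pixels)

  zero <- grayscale_image(matrix(0, 100, 100), c(1.82, 1.82))
  expect_true(all(crop_or_pad(zero, grid_spec())$pixels == 0))
})

test_that("intensity normalisation is min-max with a degenerate fallback", {
  img <- grayscale_image(matrix(c(10, 20, 30, 20), 2, 2))
  out <- normalize_intensity(img)
  expect_equal(sort(unique(as.vector(out$pixels))), c(0, 0.5, 1))

  spanning <- grayscale_image(matrix(c(0, 0.25, 0.5, 1), 2, 2))
  expect_equal(normalize_intensity(spanning)$pixels, spanning$pixels)

  expect_warning(z <- normalize_intensity(grayscale_image(matrix(5, 3, 3))),
                 "constant")
  expect_true(all(z$pixels == 0))
})

test_that("full preprocessing lands on the target grid in [0, 1]", {
  set.seed(2)
  shapes <- list(c(190, 230), c(256, 256), c(120, 180))
  spacings <- list(c(1.4, 1.9), c(2.2, 2.2), c(1.82, 1.82))
  for (k in seq_along(shapes)) {
    img <- grayscale_image(matrix(runif(prod(shapes[[k]]), 10, 500),
                                  shapes[[k]][1], shapes[[k]][2]),
                           spacings[[k]])
    pre <- preprocess_image(img, grid_spec())
    expect_equal(dim(pre$pixels), c(208L, 208L))
    expect_true(all(pre$pixels >= 0 & pre$pixels <= 1))
    expect_equal(length(attr(pre, "provenance")), 2L)
  }
})

test_that("masks round-trip to source geometry", {
  # pad-only: exact foreground restoration
  img <- grayscale_image(matrix(runif(200 * 208), 200, 208), c(1.82, 1.82))
  pre <- preprocess_image(img, grid_spec())
  m <- matrix(FALSE, 208, 208)
  m[100:120, 80:110] <- TRUE
  back <- mask_to_source_geometry(binary_mask(m, c(1.82, 1.82)), pre)
  expect_equal(dim(back$pixels), c(200L, 208L))
  expect_equal(sum(back$pixels), sum(m))

  # un-cropped, un-resampled: identical mask
  same <- grayscale_image(matrix(runif(208 * 208), 208, 208), c(1.82, 1.82))
  pre2 <- preprocess_image(same, grid_spec())
  back2 <- mask_to_source_geometry(binary_mask(m, c(1.82, 1.82)), pre2)
  expect_equal(back2$pixels, m)

  # empty mask stays empty
  empty <- binary_mask(matrix(FALSE, 208, 208), c(1.82, 1.82))
  expect_equal(sum(mask_to_source_geometry(empty, pre)$pixels), 0)

  # with resampling: area in cm^2 preserved within 5% for a >= 1 cm^2 mask
  aniso <- grayscale_image(matrix(runif(300 * 300), 300, 300), c(1.2, 1.2))
  pre3 <- preprocess_image(aniso, grid_spec())
  disc <- matrix(FALSE, 208, 208)
  for (i in 90:120) for (j in 90:120) {
    if ((i - 105)^2 + (j - 105)^2 <= 14^2) disc[i, j] <- TRUE
  }
  dm <- binary_mask(disc, c(1.82, 1.82))
  back3 <- mask_to_source_geometry(dm, pre3)
  expect_equal(back3$spacing_mm, c(1.2, 1.2))
  expect_lt(abs(mask_area_cm2(back3) - mask_area_cm2(dm)) / mask_area_cm2(dm),
            0.05)

  wrong <- binary_mask(matrix(FALSE, 10, 10), c(1.82, 1.82))
  expect_error(mask_to_source_geometry(wrong, pre), "provenance")
})
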