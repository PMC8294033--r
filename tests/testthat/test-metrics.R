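test_that("dice and iou handle hand-enumerable and degenerate cases", {
  m <- matrix(FALSE, 5, 5)
  a <- m; a[3, 3] <- TRUE
  b <- m; b[3, 3] <- TRUE; b[3, 4] <- TRUE
  expect_equal(dice(mask_from(a), mask_from(b)), 2 * 1 / (1 + 2))
  expect_equal(iou(mask_from(a), mask_from(b)), 1 / 2)

  full <- mask_from(matrix(TRUE, 4, 4))
  expect_equal(dice(full, full), 1)
  expect_equal(iou(full, full), 1)

  empty <- mask_from(matrix(FALSE, 4, 4))
  expect_equal(dice(empty, empty), 1)
  expect_equal(iou(empty, empty), 1)
  expect_equal(dice(full, empty), 0)

  d1 <- m; d1[1, 1] <- TRUE
  d2 <- m; d2[5, 5] <- TRUE
  expect_equal(dice(mask_from(d1), mask_from(d2)), 0)
  expect_equal(iou(mask_from(d1), mask_from(d2)), 0)

  expect_error(dice(mask_from(a), mask_from(matrix(TRUE, 3, 3))), "shape")
})

test_that("contour distances match single-pair geometry", {
  m <- matrix(FALSE, 7, 7)
  a <- m; a[4, 2] <- TRUE
  b <- m; b[4, 5] <- TRUE
  # 3 columns apart at 1.82 mm spacing
  expect_equal(mean_contour_distance(mask_from(a), mask_from(b)), 3 * 1.82)
  expect_equal(hausdorff(mask_from(a), mask_from(b)), 3 * 1.82)

  # 3-4-5 triangle at unit spacing
  c1 <- m; c1[1, 1] <- TRUE
  c2 <- m; c2[4, 5] <- TRUE
  expect_equal(hausdorff(mask_from(c1, c(1, 1)), mask_from(c2, c(1, 1))), 5)

  expect_equal(mean_contour_distance(mask_from(a), mask_from(a)), 0)
  expect_error(mean_contour_distance(mask_from(a), mask_from(m)), "empty")
  expect_error(hausdorff(mask_from(m), mask_from(a)), "empty")
})

test_that("distance metrics agree with the exhaustive double-loop oracle", {
  set.seed(42)
  for (trial in 1:200) {
    a <- rand_nonempty_mask(12, 12)
    b <- rand_nonempty_mask(12, 12)
    o <- oracle_distances(a, b)
    expect_equal(mean_contour_distance(a, b), o$mcd, tolerance = 1e-9)
    expect_equal(hausdorff(a, b), o$hd, tolerance = 1e-9)
    expect_equal(hausdorff(b, a), hausdorff(a, b))
  }
})

test_that("distances scale linearly with pixel spacing and survive translation", {
  set.seed(7)
  for (trial in 1:20) {
    a <- rand_nonempty_mask(10, 10, spacing = c(1, 1))
    b <- rand_nonempty_mask(10, 10, spacing = c(1, 1))
    a2 <- mask_from(a$pixels, c(2.5, 2.5))
    b2 <- mask_from(b$pixels, c(2.5, 2.5))
    expect_equal(mean_contour_distance(a2, b2),
                 2.5 * mean_contour_distance(a, b), tolerance = 1e-12)
    expect_equal(hausdorff(a2, b2), 2.5 * hausdorff(a, b), tolerance = 1e-12)

    # pad-shift both masks by the same offset: all metrics invariant
    shift <- function(m) {
      out <- matrix(FALSE, 14, 14)
      out[3:12, 4:13] <- m$pixels
      mask_from(out, m$spacing_mm)
    }
    expect_equal(dice(shift(a), shift(b)), dice(a, b))
    expect_equal(iou(shift(a), shift(b)), iou(a, b))
    expect_equal(hausdorff(shift(a), shift(b)), hausdorff(a, b),
                 tolerance = 1e-12)
    expect_equal(mean_contour_distance(shift(a), shift(b)),
                 mean_contour_distance(a, b), tolerance = 1e-12)
  }
})

test_that("pairwise_table reports every pair over shared subjects", {
  set.seed(3)
  subjects <- paste0("s", 1:4)
  mk <- function() {
    out <- lapply(subjects, function(s) rand_nonempty_mask(8, 8))
    names(out) <- subjects
    out
  }
  o1 <- mk()
  sets <- list(O1 = o1, O2 = o1, O3 = mk())
  # O3 masks may be empty-overlap; re-draw until distances are defined
  tab <- pairwise_table(sets)
  expect_s3_class(tab, "agreement_report")
  expect_equal(length(unique(tab$pair)), 3L)  # 3 collections -> 3 pairs
  expect_equal(nrow(tab), 3L * 4L)

  self <- tab[tab$pair == "O1 vs O2", ]
  expect_true(all(self$dice == 1))
  expect_true(all(self$hausdorff_mm == 0))

  sm <- agreement_summary(tab)
  expect_equal(nrow(sm), 3L * 4L)  # pair x metric
  expect_true(all(grepl("^\\d", sm$label)))

  expect_error(pairwise_table(list(A = o1)), "two collections")
  expect_error(pairwise_table(list(A = list(x = o1[[1]]),
                                   B = list(y = o1[[1]]))), "shared")
})

test_that("collections differing on one subject degrade only that row", {
  set.seed(9)
  subjects <- paste0("s", 1:3)
  base <- lapply(subjects, function(s) rand_nonempty_mask(8, 8))
  names(base) <- subjects
  other <- base
  flipped <- other$s2$pixels
  flipped[1, 1] <- !flipped[1, 1]
  other$s2 <- mask_from(flipped)
  tab <- pairwise_table(list(A = base, B = other))
  expect_equal(tab$dice[tab$subject != "s2"], c(1, 1))
  expect_lt(tab$dice[tab$subject == "s2"], 1)
})

test_that("bland_altman recovers bias and limits", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$bias, 2)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(2, 2))

  set.seed(1)
  n <- 1e4
  xx <- runif(n, 10, 40)
  yy <- xx + rnorm(n)
  ba <- bland_altman(xx, yy)
  expect_lt(abs(ba$bias), 0.03)
  expect_lt(abs((ba$loa_high - ba$bias) - 1.96), 0.05)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  expect_error(bland_altman(1, numeric(0)), "paired")

  g <- glance(ba)
  expect_equal(g$n, n)
  p <- ggplot2::autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("pearson matches the textbook formula and flags degenerate input", {
  x <- c(2.1, 3.5, 4.0, 5.2, 6.6, 7.0, 8.3, 9.1, 10.4, 11.0)
  y <- c(1.0, 2.2, 2.0, 3.9, 4.1, 5.5, 5.2, 6.8, 7.7, 7.4)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r_direct * sqrt((length(x) - 2) / (1 - r_direct^2))
  p_direct <- 2 * stats::pt(-abs(tt), df = length(x) - 2)
  res <- pearson(x, y)
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(res$p_value, p_direct, tolerance = 1e-12)

  expect_equal(pearson(x, 2 * x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(rep(1, 5), x[1:5]), "constant")
})
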