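check_pair <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  assert_that(all(dim(a$pixels) == dim(b$pixels)), "mask shapes differ")
  list(a = a, b = b)
}

#' Dice score between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks score 1 (both observers agree on
#' absence); one empty and one not scores 0.
#'
#' @param a,b Binary masks ([binary_mask()] or logical matrices) of equal
#'   shape.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  p <- check_pair(a, b)
  na <- sum(p$a$pixels); nb <- sum(p$b$pixels)
  if (na + nb == 0) return(1)
  2 * sum(p$a$pixels & p$b$pixels) / (na + nb)
}

#' Intersection-over-union (Jaccard index) between two masks
#'
#' `|A n B| / |A u B|`; 1 if both masks are empty.
#'
#' @inheritParams dice
#' @return Numeric scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  p <- check_pair(a, b)
  u <- sum(p$a$pixels | p$b$pixels)
  if (u == 0) return(1)
  sum(p$a$pixels & p$b$pixels) / u
}

# Boundary pixels: foreground with a 4-neighbour outside the foreground
# (the image edge counts as outside). Returns an n x 2 matrix of physical
# coordinates in mm, anisotropy-aware.
boundary_points_mm <- function(mask) {
  m <- mask$pixels
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  idx <- which(m & !interior, arr.ind = TRUE)
  cbind((idx[, 1] - 1) * mask$spacing_mm[1], (idx[, 2] - 1) * mask$spacing_mm[2])
}

#' Mean contour distance between two masks, in mm
#'
#' Symmetric mean over the boundary pixels of both masks of the Euclidean
#' distance to the nearest boundary pixel of the other mask (directed sums
#' pooled, i.e. weighted by boundary size). Boundaries are foreground pixels
#' with a 4-neighbour outside the foreground. Undefined (error) if either
#' mask is empty.
#'
#' @inheritParams dice
#' @return Numeric scalar, mm.
#' @export
mean_contour_distance <- function(a, b) {
  p <- check_pair(a, b)
  assert_that(all(abs(p$a$spacing_mm - p$b$spacing_mm) < 1e-9),
              "mask spacings differ")
  assert_that(sum(p$a$pixels) > 0 && sum(p$b$pixels) > 0,
              "contour distance undefined for empty masks")
  pa <- boundary_points_mm(p$a)
  pb <- boundary_points_mm(p$b)
  dab <- min_dists(pa, pb)
  dba <- min_dists(pb, pa)
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

#' Symmetric Hausdorff distance between two masks, in mm
#'
#' The maximum of the two directed Hausdorff distances between the boundary
#' pixel sets, Euclidean in mm. Errors if either mask is empty.
#'
#' @inheritParams dice
#' @return Numeric scalar, mm.
#' @export
hausdorff <- function(a, b) {
  p <- check_pair(a, b)
  assert_that(all(abs(p$a$spacing_mm - p$b$spacing_mm) < 1e-9),
              "mask spacings differ")
  assert_that(sum(p$a$pixels) > 0 && sum(p$b$pixels) > 0,
              "Hausdorff distance undefined for empty masks")
  pa <- boundary_points_mm(p$a)
  pb <- boundary_points_mm(p$b)
  max(max(min_dists(pa, pb)), max(min_dists(pb, pa)))
}

#' Pairwise agreement table across observers or methods
#'
#' Computes all four agreement metrics (IoU, Dice, mean contour distance,
#' Hausdorff) for every subject shared by every pair of mask collections —
#' the layout used for inter-observer variability tables.
#'
#' @param mask_sets Named list of collections; each collection is a named
#'   list of masks keyed by subject id.
#' @return A tibble of class `agreement_report` with one row per pair and
#'   subject; see [agreement_summary()] for the mean (sd) roll-up.
#' @export
pairwise_table <- function(mask_sets) {
  assert_that(length(mask_sets) >= 2, "need at least two collections")
  assert_that(!is.null(names(mask_sets)), "collections must be named")
  shared <- Reduce(intersect, lapply(mask_sets, names))
  assert_that(length(shared) >= 1, "no shared subjects across collections")
  pairs <- utils::combn(names(mask_sets), 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(shared, function(s) {
      a <- mask_sets[[pr[1]]][[s]]
      b <- mask_sets[[pr[2]]][[s]]
      tibble::tibble(
        pair = paste(pr[1], "vs", pr[2]),
        set_a = pr[1], set_b = pr[2], subject = s,
        iou = iou(a, b), dice = dice(a, b),
        mean_contour_distance_mm = mean_contour_distance(a, b),
        hausdorff_mm = hausdorff(a, b))
    })
  })
  class(rows) <- c("agreement_report", class(rows))
  rows
}

#' Summarise an agreement report as mean (sd) per metric and pair
#'
#' @param report An `agreement_report` from [pairwise_table()].
#' @return A tibble with one row per pair and metric, columns `mean`, `sd`
#'   and a formatted `label`.
#' @export
agreement_summary <- function(report) {
  report |>
    tidyr::pivot_longer(c("iou", "dice", "mean_contour_distance_mm",
                          "hausdorff_mm"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$pair, .data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::mutate(label = sprintf("%.3f (%.3f)", .data$mean, .data$sd))
}

#' Bland-Altman agreement analysis of paired area measurements
#'
#' Differences are `y - x`; bias is their mean and the limits of agreement
#' are bias +/- 1.96 standard deviations of the differences.
#'
#' @param x,y Equal-length numeric vectors of paired measurements (e.g. PAT
#'   areas in cm^2), `n >= 2`.
#' @return An object of class `bland_altman`; see [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
bland_altman <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must be paired (equal length)")
  assert_that(length(x) >= 2, "need at least two pairs")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(data = tibble::tibble(mean = (x + y) / 2, difference = d),
                 bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(x)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: n = %d, bias = %.4g, limits of agreement [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Pearson correlation with a t-distribution p-value
#'
#' Thin wrapper over [stats::cor.test()] returning a tidy row; errors on
#' constant input, where the correlation is undefined.
#'
#' @param x,y Numeric vectors, `n >= 3`, neither constant.
#' @return A one-row tibble with `r`, `p_value`, `n`, `conf_low`, `conf_high`.
#' @export
pearson <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need paired vectors with n >= 3")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), conf_low = ct$conf.int[1],
                 conf_high = ct$conf.int[2])
}
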