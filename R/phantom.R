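#' Synthetic four-chamber phantom configuration
#'
#' The phantom emulates the appearance the segmentation pipeline is built
#' for: a mid-intensity multi-lobed cardiac blob on a dark background, a
#' bright crescentic fat band hugging the inferior/apical epicardial border
#' (the segmentation target, with exact ground truth), and optionally a
#' bright sub-diaphragmatic "liver" distractor below the heart that must
#' never be labelled. A single `difficulty` knob in `[0, 1]` degrades the
#' image: 0 gives high fat contrast, little blur and little noise; 1 gives
#' fat barely brighter than myocardium, strong blur and strong noise.
#'
#' Geometric defaults scale with the image so the same configuration renders
#' plausible phantoms at full (208 px) or reduced grids.
#'
#' @param image_shape Length-2 integer (rows, cols), default `c(208, 208)`.
#' @param spacing_mm Length-2 pixel spacing in mm, default 1.82 x 1.82.
#' @param fat_thickness_px Integer range (min, max) of fat band thickness in
#'   px; default scales with the image.
#' @param fat_arc_deg Range of the angular extent of the fat crescent,
#'   degrees.
#' @param heart_axes_px Ranges for the heart's semi-axes, as
#'   `list(a = c(min, max), b = c(min, max))` in px; default scales with the
#'   image.
#' @param liver_present Probability that the liver distractor is rendered.
#' @param noise_sigma,blur_sigma Optional explicit overrides; when `NULL`
#'   both are derived from `difficulty` (noise `0.02 + 0.12 d`, blur
#'   `0.4 + 1.6 d` px).
#' @param difficulty Real in `[0, 1]`.
#' @param rng_seed Optional default seed for [generate_phantom()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_shape = c(208L, 208L),
                           spacing_mm = c(1.82, 1.82),
                           fat_thickness_px = NULL,
                           fat_arc_deg = c(120, 200),
                           heart_axes_px = NULL,
                           liver_present = 0.7,
                           noise_sigma = NULL, blur_sigma = NULL,
                           difficulty = 0, rng_seed = NULL) {
  s <- min(image_shape)
  fat_thickness_px <- fat_thickness_px %||% pmax(2L, round(c(0.055, 0.085) * s))
  heart_axes_px <- heart_axes_px %||%
    list(a = round(c(0.16, 0.21) * s), b = round(c(0.19, 0.25) * s))
  assert_that(difficulty >= 0 && difficulty <= 1, "difficulty must be in [0, 1]")
  assert_that(all(fat_thickness_px > 0) && all(unlist(heart_axes_px) > 0),
              "geometry ranges must be positive")
  structure(list(image_shape = as.integer(image_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 fat_thickness_px = fat_thickness_px,
                 fat_arc_deg = fat_arc_deg, heart_axes_px = heart_axes_px,
                 liver_present = liver_present, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma, difficulty = difficulty,
                 rng_seed = rng_seed),
            class = "phantom_config")
}

# Filled rotated ellipse on the pixel grid.
ellipse_mask <- function(shape, centre, a, b, theta = 0) {
  i <- matrix(seq_len(shape[1]) - centre[1], shape[1], shape[2])
  j <- matrix(rep(seq_len(shape[2]) - centre[2], each = shape[1]),
              shape[1], shape[2])
  u <- cos(theta) * i + sin(theta) * j
  v <- -sin(theta) * i + cos(theta) * j
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one phantom with exact ground truth
#'
#' Deterministic given `(cfg, seed)`. The returned truth mask is the fat
#' crescent before blurring and noise, so `true_area_cm2` is exactly the
#' foreground count times the pixel area. Liver distractor pixels are never
#' part of the truth, by construction. Geometries whose fat band would leave
#' the frame are re-drawn (bounded retries).
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer seed (falls back to `cfg$rng_seed`).
#' @return An object of class `phantom_sample`: list with `image`
#'   ([grayscale_image()]), `truth` ([binary_mask()]), `true_area_cm2`,
#'   `difficulty`, `seed`.
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = NULL) {
  seed <- seed %||% cfg$rng_seed
  assert_that(!is.null(seed), "a seed is required")
  set.seed(seed)
  shape <- cfg$image_shape
  d <- cfg$difficulty
  noise_sigma <- cfg$noise_sigma %||% (0.02 + 0.12 * d)
  blur_sigma <- cfg$blur_sigma %||% (0.4 + 1.6 * d)
  fat_int <- 0.92 - 0.38 * d
  heart_int <- 0.45

  for (attempt in 1:20) {
    centre <- c(stats::runif(1, 0.38, 0.46) * shape[1],
                stats::runif(1, 0.46, 0.54) * shape[2])
    a <- stats::runif(1, cfg$heart_axes_px$a[1], cfg$heart_axes_px$a[2])
    b <- stats::runif(1, cfg$heart_axes_px$b[1], cfg$heart_axes_px$b[2])
    th <- stats::runif(1, -20, 20) * pi / 180
    heart <- ellipse_mask(shape, centre, a, b, th)
    # atrial lobe: smaller ellipse overlapping the upper part of the blob
    c2 <- centre + c(-0.55 * a, stats::runif(1, -0.25, 0.25) * b)
    heart <- heart | ellipse_mask(shape, c2, 0.55 * a, 0.6 * b, th)

    thick <- stats::runif(1, cfg$fat_thickness_px[1], cfg$fat_thickness_px[2])
    arc <- stats::runif(1, cfg$fat_arc_deg[1], cfg$fat_arc_deg[2]) * pi / 180
    arc_centre <- stats::runif(1, -20, 20) * pi / 180  # about "straight down"

    hb <- which_boundary_px(heart)
    ii <- matrix(seq_len(shape[1]), shape[1], shape[2])
    jj <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
    ang <- atan2(jj - centre[2], ii - centre[1])  # 0 points down (+rows)
    dang <- atan2(sin(ang - arc_centre), cos(ang - arc_centre))
    cand <- !heart & abs(dang) <= arc / 2 &
      ii >= min(hb[, 1]) - thick - 1 & ii <= max(hb[, 1]) + thick + 1 &
      jj >= min(hb[, 2]) - thick - 1 & jj <= max(hb[, 2]) + thick + 1
    ci <- which(cand)
    dists <- min_dists(cbind(ii[ci], jj[ci]), hb)
    truth <- matrix(FALSE, shape[1], shape[2])
    truth[ci[dists <= thick]] <- TRUE

    # feasibility: a non-trivial band fully inside the frame
    touches <- any(truth[1, ]) || any(truth[shape[1], ]) ||
      any(truth[, 1]) || any(truth[, shape[2]])
    if (sum(truth) >= 20 && !touches) break
    if (attempt == 20) stop("could not render a feasible phantom geometry",
                            call. = FALSE)
  }

  img <- matrix(0.08, shape[1], shape[2])
  img[heart] <- heart_int
  # thin dark septa across the blob
  sept_th <- th + stats::runif(1, -0.3, 0.3)
  sept <- abs(cos(sept_th) * (jj - centre[2]) - sin(sept_th) * (ii - centre[1])) <= 1 & heart
  img[sept] <- 0.28
  img[truth] <- fat_int

  liver <- matrix(FALSE, shape[1], shape[2])
  if (stats::runif(1) < cfg$liver_present) {
    lc <- c(min(shape[1] - 2, max(which(rowSums(truth | heart) > 0)) +
                  0.12 * shape[1]),
            centre[2] + stats::runif(1, -0.08, 0.08) * shape[2])
    liver <- ellipse_mask(shape, lc, 0.11 * shape[1], 0.24 * shape[2],
                          stats::runif(1, -10, 10) * pi / 180)
    liver <- liver & !truth & !heart
    img[liver] <- fat_int
  }

  img <- gaussian_blur(img, blur_sigma)
  if (noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sigma),
                        shape[1], shape[2])
  }
  img <- clip01(img)

  truth_mask <- binary_mask(truth, cfg$spacing_mm)
  structure(list(
    image = grayscale_image(img, cfg$spacing_mm, 0L,
                            sprintf("phantom-%d", seed)),
    truth = truth_mask,
    true_area_cm2 = mask_area_cm2(truth_mask),
    difficulty = d, seed = as.integer(seed),
    heart = binary_mask(heart, cfg$spacing_mm),
    liver = binary_mask(liver, cfg$spacing_mm)),
    class = "phantom_sample")
}

# Boundary pixel indices (row, col) of a logical matrix, 4-connectivity.
which_boundary_px <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m & !interior, arr.ind = TRUE)
}

#' Generate a stratified phantom dataset
#'
#' Renders `n` phantoms with per-sample seeds derived from a master seed.
#' When a `difficulty_spectrum` is given the samples are split evenly across
#' its strata (in order); otherwise all samples use `cfg$difficulty`.
#'
#' @param cfg A [phantom_config()].
#' @param n Number of phantoms.
#' @param difficulty_spectrum Optional numeric vector of difficulty strata.
#' @param seed Master seed.
#' @return A tibble (the manifest) with columns `id`, `seed`, `difficulty`,
#'   `true_area_cm2` and list-columns `image` and `truth`.
#' @export
generate_dataset <- function(cfg = phantom_config(), n,
                             difficulty_spectrum = NULL, seed = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  seeds <- derive_seeds(seed, n)
  diffs <- if (is.null(difficulty_spectrum)) rep(cfg$difficulty, n) else {
    rep(difficulty_spectrum, length.out = n)  # cyclic => strata as even as possible
  }
  rows <- purrr::map(seq_len(n), function(k) {
    ck <- cfg
    ck$difficulty <- diffs[k]
    ph <- generate_phantom(ck, seeds[k])
    tibble::tibble(id = sprintf("phantom-%03d", k), seed = ph$seed,
                   difficulty = ph$difficulty,
                   true_area_cm2 = ph$true_area_cm2,
                   image = list(ph$image), truth = list(ph$truth))
  })
  dplyr::bind_rows(rows)
}
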