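#' On-the-fly augmentation configuration
#'
#' The four geometric transforms applied jointly to every training pair:
#' rotation up to 25 degrees, isotropic resizing up to 20%, shearing up to
#' 20%, and per-axis panning up to 25% of the image dimension. Each draw
#' samples uniformly within the symmetric bounds; with all maxima zero the
#' transform is the identity.
#'
#' @param max_rotation_deg Maximum absolute rotation, degrees.
#' @param max_resize_frac Maximum resize fraction; scale is drawn from
#'   `[1 - f, 1 + f]`.
#' @param max_shear_frac Maximum absolute shear factor.
#' @param max_pan_frac Maximum pan as a fraction of each image dimension.
#' @param rng_seed Optional seed recorded in the config (training seeds the
#'   session RNG; the sampler itself always draws from the current stream).
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(max_rotation_deg = 25,
                                max_resize_frac = 0.20,
                                max_shear_frac = 0.20,
                                max_pan_frac = 0.25,
                                rng_seed = NULL) {
  vals <- c(max_rotation_deg, max_resize_frac, max_shear_frac, max_pan_frac)
  assert_that(all(vals >= 0), "augmentation maxima must be >= 0")
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_resize_frac = max_resize_frac,
                 max_shear_frac = max_shear_frac,
                 max_pan_frac = max_pan_frac,
                 rng_seed = rng_seed),
            class = "augmentation_config")
}

#' Draw one affine augmentation transform
#'
#' Samples rotation, scale, shear and per-axis pan from the configured
#' uniform bounds and composes them into a single affine map about the image
#' centre (forward model: `dst = R S H (src - c) + c + pan`, with rotation R,
#' scale S, shear H). Uses the session RNG, so a fixed seed reproduces the
#' draw.
#'
#' @param cfg An [augmentation_config()].
#' @param shape Length-2 integer image shape (rows, cols); needed to convert
#'   pan fractions to pixels.
#' @return A list with the sampled parameters and the forward 2x2 matrix `M`.
#' @export
sample_transform <- function(cfg, shape) {
  rot_deg <- stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg)
  scale <- stats::runif(1, 1 - cfg$max_resize_frac, 1 + cfg$max_resize_frac)
  shear <- stats::runif(1, -cfg$max_shear_frac, cfg$max_shear_frac)
  pan_px <- stats::runif(2, -cfg$max_pan_frac, cfg$max_pan_frac) * shape
  th <- rot_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  H <- matrix(c(1, 0, shear, 1), 2, 2)
  M <- R %*% H %*% diag(c(scale, scale))
  list(rotation_deg = rot_deg, scale = scale, shear = shear, pan_px = pan_px,
       M = M)
}

#' Apply an affine transform to an image/mask pair
#'
#' The same affine map is applied to both: bilinear interpolation for the
#' image, nearest-neighbour for the mask (masks stay Boolean). Pixels mapped
#' from outside the frame are filled with 0 / background. Output shape is
#' unchanged.
#'
#' @param img A [grayscale_image()].
#' @param mask A [binary_mask()] with the same shape.
#' @param params A transform from [sample_transform()].
#' @return A list with elements `image` and `mask`.
#' @export
apply_transform <- function(img, mask, params) {
  img <- as_image(img)
  mask <- as_mask(mask)
  assert_that(all(dim(img$pixels) == dim(mask$pixels)),
              "image and mask shapes differ")
  shape <- dim(img$pixels)
  centre <- (shape - 1) / 2
  Ainv <- solve(params$M)
  cdst <- centre + params$pan_px
  im <- warp_affine(img$pixels, Ainv, cdst, centre, shape[1], shape[2],
                    bilinear = TRUE, fill = 0, clamp = FALSE)
  mk <- warp_affine(mask$pixels * 1, Ainv, cdst, centre, shape[1], shape[2],
                    bilinear = FALSE, fill = 0, clamp = FALSE)
  list(image = grayscale_image(im, img$spacing_mm, img$frame_index,
                               img$source_id),
       mask = binary_mask(mk != 0, mask$spacing_mm))
}
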