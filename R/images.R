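#' Grayscale image with physical pixel spacing
#'
#' The unit every stage of the pipeline consumes: a 2-D intensity matrix with
#' its pixel spacing in millimetres. Row and column spacing are carried
#' independently, so anisotropic acquisitions are representable.
#'
#' @param pixels Numeric matrix of intensities.
#' @param spacing_mm Length-2 positive numeric, (row, col) pixel spacing in mm.
#' @param frame_index Zero-based index of the cine frame this image came from.
#' @param source_id Opaque identifier carried through to reports.
#' @return An object of class `grayscale_image`.
#' @export
grayscale_image <- function(pixels, spacing_mm = c(1.82, 1.82),
                            frame_index = 0L, source_id = "image") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  assert_that(length(pixels) > 0, "image grid must be non-empty")
  assert_that(length(spacing_mm) == 2 && all(is.finite(spacing_mm)) &&
                all(spacing_mm > 0),
              "spacing_mm must be two positive numbers (row, col)")
  assert_that(frame_index >= 0, "frame_index must be >= 0")
  structure(
    list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
         frame_index = as.integer(frame_index),
         source_id = as.character(source_id)),
    class = "grayscale_image"
  )
}

#' Binary segmentation mask sharing an image's geometry
#'
#' @param pixels Logical matrix (or coercible); `TRUE` marks foreground
#'   (pericardial adipose tissue).
#' @param spacing_mm Length-2 positive numeric, (row, col) spacing in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, spacing_mm = c(1.82, 1.82)) {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) pixels <- pixels != 0
  assert_that(length(pixels) > 0, "mask grid must be non-empty")
  assert_that(length(spacing_mm) == 2 && all(spacing_mm > 0),
              "spacing_mm must be two positive numbers (row, col)")
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm)),
            class = "binary_mask")
}

#' Target analysis geometry
#'
#' The fixed grid every input is mapped onto before entering the network:
#' uniform 1.82 x 1.82 mm spacing on a 208 x 208 grid by default. The grid
#' side must be divisible by 16 because the encoder halves resolution four
#' times.
#'
#' @param target_spacing_mm Length-2 numeric, (row, col) spacing in mm.
#' @param target_shape Length-2 integer, (rows, cols).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(target_spacing_mm = c(1.82, 1.82),
                      target_shape = c(208L, 208L)) {
  assert_that(all(target_spacing_mm > 0), "target spacing must be positive")
  assert_that(all(target_shape >= 16) && all(target_shape %% 16 == 0),
              "target_shape must be divisible by 16 (4-level encoder)")
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 target_shape = as.integer(target_shape)),
            class = "grid_spec")
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image> %d x %d px, %.3g x %.3g mm, frame %d, '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2],
              x$frame_index, x$source_id))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.3g x %.3g mm, %d foreground (%.2f cm^2)\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2],
              sum(x$pixels), mask_area_cm2(x)))
  invisible(x)
}

#' Foreground area of a mask in square centimetres
#'
#' Area is the foreground pixel count times the physical pixel area
#' (`spacing_row * spacing_col` mm^2), divided by 100 to convert to cm^2.
#'
#' @param mask A `binary_mask`.
#' @return Numeric scalar, cm^2.
#' @export
mask_area_cm2 <- function(mask) {
  mask <- as_mask(mask)
  sum(mask$pixels) * prod(mask$spacing_mm) / 100
}

# Coercion helpers used across modules: accept the class or a bare matrix.
as_image <- function(x, spacing_mm = c(1.82, 1.82)) {
  if (inherits(x, "grayscale_image")) x else grayscale_image(x, spacing_mm)
}

as_mask <- function(x, spacing_mm = c(1.82, 1.82)) {
  if (inherits(x, "binary_mask")) x else binary_mask(x, spacing_mm)
}

#' Probability map produced by one stochastic forward pass
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param spacing_mm Length-2 positive numeric (row, col), mm.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(pixels, spacing_mm = c(1.82, 1.82)) {
  pixels <- as.matrix(pixels)
  assert_that(all(pixels >= 0 & pixels <= 1), "probabilities must lie in [0, 1]")
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm)),
            class = "probability_map")
}
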