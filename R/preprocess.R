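#' Resample an image onto a uniform pixel spacing
#'
#' Maps the image onto the target spacing of a [grid_spec()] by bilinear
#' interpolation (pixel-centre convention, edge-clamped so constant images
#' stay constant). Output shape is `round(input_shape * input_spacing /
#' target_spacing)`. Row and column spacing are handled independently, so
#' anisotropic inputs become isotropic here.
#'
#' @param img A [grayscale_image()] (or matrix).
#' @param spec A [grid_spec()].
#' @return A `grayscale_image` at the target spacing, carrying a `provenance`
#'   attribute used by [mask_to_source_geometry()].
#' @export
resample_to_spacing <- function(img, spec = grid_spec()) {
  img <- as_image(img)
  in_shape <- dim(img$pixels)
  ratio <- spec$target_spacing_mm / img$spacing_mm  # dst px -> src px
  out_shape <- as.integer(round(in_shape / ratio))
  assert_that(all(out_shape > 1), "resampling would collapse the image (<= 1 px)")
  px <- warp_resample(img$pixels, ratio, out_shape, bilinear = TRUE)
  out <- grayscale_image(px, spec$target_spacing_mm, img$frame_index,
                         img$source_id)
  step <- list(op = "resample", in_shape = in_shape,
               in_spacing = img$spacing_mm, out_shape = out_shape,
               out_spacing = spec$target_spacing_mm)
  attr(out, "provenance") <- c(provenance_of(img), list(step))
  out
}

# Shared scale-warp: src = (dst + 0.5) * ratio - 0.5 per axis.
warp_resample <- function(mat, ratio, out_shape, bilinear, fill = 0) {
  Ainv <- diag(ratio)
  warp_affine(mat, Ainv, cdst = c(-0.5, -0.5), csrc = c(-0.5, -0.5),
              out_h = out_shape[1], out_w = out_shape[2],
              bilinear = bilinear, fill = fill, clamp = bilinear)
}

provenance_of <- function(img) attr(img, "provenance") %||% list()

#' Centre-crop or zero-pad an image to the target grid
#'
#' Symmetric crop/pad to `spec$target_shape`; when the difference is odd the
#' extra padded pixel goes to the trailing side. Padding fills with 0, the
#' post-normalisation background level. The applied per-axis offset is
#' recorded in the provenance so masks can be mapped back to the source
#' geometry.
#'
#' @inheritParams resample_to_spacing
#' @return A `grayscale_image` with `target_shape` pixels.
#' @export
crop_or_pad <- function(img, spec = grid_spec()) {
  img <- as_image(img)
  n <- dim(img$pixels)
  t <- spec$target_shape
  off <- floor((t - n) / 2)  # >0: leading pad; <0: leading crop
  out <- matrix(0, t[1], t[2])
  src_r <- seq_len(n[1]) + off[1]
  src_c <- seq_len(n[2]) + off[2]
  keep_r <- src_r >= 1 & src_r <= t[1]
  keep_c <- src_c >= 1 & src_c <= t[2]
  out[src_r[keep_r], src_c[keep_c]] <- img$pixels[keep_r, keep_c]
  res <- grayscale_image(out, img$spacing_mm, img$frame_index, img$source_id)
  step <- list(op = "crop_pad", in_shape = n, out_shape = t, offset = off)
  attr(res, "provenance") <- c(provenance_of(img), list(step))
  res
}

#' Min-max normalise intensities to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant image maps to all zeros with a
#' warning.
#'
#' @inheritParams resample_to_spacing
#' @return A `grayscale_image` with values in `[0, 1]`.
#' @export
normalize_intensity <- function(img) {
  img <- as_image(img)
  rng <- range(img$pixels)
  if (rng[1] == rng[2]) {
    warning("constant-intensity image; normalised to all zeros")
    px <- matrix(0, nrow(img$pixels), ncol(img$pixels))
  } else {
    px <- (img$pixels - rng[1]) / (rng[2] - rng[1])
  }
  out <- grayscale_image(px, img$spacing_mm, img$frame_index, img$source_id)
  attr(out, "provenance") <- provenance_of(img)
  out
}

#' Full preprocessing: resample, crop/pad, normalise
#'
#' The fixed mapping every input receives before segmentation: resample to
#' the target spacing, centre crop/pad to the target shape, then min-max
#' normalise. The returned image always has `spec$target_shape` pixels and
#' values in `[0, 1]`.
#'
#' @inheritParams resample_to_spacing
#' @return A preprocessed `grayscale_image` with provenance.
#' @export
preprocess_image <- function(img, spec = grid_spec()) {
  normalize_intensity(crop_or_pad(resample_to_spacing(img, spec), spec))
}

#' Map a mask from the analysis grid back to the source geometry
#'
#' Inverts the crop/pad and resampling steps recorded in an image's
#' provenance, using nearest-neighbour interpolation so the mask stays
#' Boolean. When no resampling occurred the foreground pixel count is
#' restored exactly (up to pixels lost to cropping); with resampling, the
#' foreground area in cm^2 is preserved to within a few percent for
#' non-trivial masks.
#'
#' @param mask A [binary_mask()] on the analysis grid.
#' @param provenance A provenance list from [preprocess_image()] (or the
#'   preprocessed image itself).
#' @return A `binary_mask` in the source geometry.
#' @export
mask_to_source_geometry <- function(mask, provenance) {
  mask <- as_mask(mask)
  if (inherits(provenance, "grayscale_image")) {
    provenance <- provenance_of(provenance)
  }
  px <- mask$pixels
  spacing <- mask$spacing_mm
  for (step in rev(provenance)) {
    if (step$op == "crop_pad") {
      assert_that(all(dim(px) == step$out_shape),
                  "mask shape does not match provenance")
      n <- step$in_shape
      off <- step$offset
      out <- matrix(FALSE, n[1], n[2])
      dst_r <- seq_len(n[1]) + off[1]
      dst_c <- seq_len(n[2]) + off[2]
      keep_r <- dst_r >= 1 & dst_r <= step$out_shape[1]
      keep_c <- dst_c >= 1 & dst_c <= step$out_shape[2]
      out[keep_r, keep_c] <- px[dst_r[keep_r], dst_c[keep_c]]
      px <- out
    } else if (step$op == "resample") {
      assert_that(all(dim(px) == step$out_shape),
                  "mask shape does not match provenance")
      ratio <- step$out_spacing / step$in_spacing  # src-grid px -> dst-grid px
      px <- warp_resample(px * 1, 1 / ratio, step$in_shape,
                          bilinear = FALSE) != 0
      spacing <- step$in_spacing
    }
  }
  binary_mask(px, spacing)
}
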