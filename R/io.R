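#' Load a cine frame from DICOM, NIfTI or PNG
#'
#' Reads one 2-D frame. For cine inputs the analysis frame defaults to frame 0
#' ("phase 1" of the imaging cycle, approximately end-diastole). Pixel spacing
#' is taken from the file metadata where the format carries it (DICOM
#' PixelSpacing, NIfTI header zooms); PNG carries no spacing, so `spacing_mm`
#' must be supplied.
#'
#' @param path Path to a `.dcm`, `.nii`/`.nii.gz` or `.png` file.
#' @param frame_index Zero-based frame to extract (NIfTI third dimension or
#'   DICOM NumberOfFrames). Must be less than the number of frames.
#' @param spacing_mm Optional length-2 (row, col) spacing override in mm;
#'   required for PNG.
#' @return A [grayscale_image()].
#' @export
load_image <- function(path, frame_index = 0L, spacing_mm = NULL) {
  assert_that(file.exists(path), sprintf("cannot read '%s'", path))
  frame_index <- as.integer(frame_index)
  ext <- tolower(sub(".*\\.(nii\\.gz|[[:alnum:]]+)$", "\\1", path))
  if (ext %in% c("nii", "nii.gz", "gz")) {
    vol <- RNifti::readNifti(path)
    zooms <- RNifti::pixdim(vol)
    d <- dim(vol)
    n_frames <- if (length(d) >= 3) d[3] else 1L
    assert_that(frame_index < n_frames,
                sprintf("frame_index %d out of range (%d frames)",
                        frame_index, n_frames))
    px <- if (length(d) >= 3) vol[, , frame_index + 1L] else vol[, ]
    sp <- spacing_mm %||% zooms[1:2]
    grayscale_image(as.matrix(px), sp, frame_index, basename(path))
  } else if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    assert_that(frame_index == 0L, "PNG inputs are single-frame")
    assert_that(!is.null(spacing_mm),
                "PNG carries no pixel spacing; supply spacing_mm")
    grayscale_image(px, spacing_mm, 0L, basename(path))
  } else if (ext %in% c("dcm", "dicom", "ima")) {
    dcm <- read_dicom(path)
    n_frames <- dcm$n_frames
    assert_that(frame_index < n_frames,
                sprintf("frame_index %d out of range (%d frames)",
                        frame_index, n_frames))
    sp <- spacing_mm %||% dcm$pixel_spacing
    assert_that(!is.null(sp),
                "DICOM lacks PixelSpacing; supply spacing_mm")
    grayscale_image(dcm$frames[[frame_index + 1L]], sp, frame_index,
                    basename(path))
  } else {
    stop(sprintf("unsupported image format: '%s'", ext), call. = FALSE)
  }
}

#' Load a binary mask from NIfTI or PNG
#'
#' Nonzero pixels are foreground.
#'
#' @inheritParams load_image
#' @return A [binary_mask()].
#' @export
load_mask <- function(path, spacing_mm = NULL) {
  img <- load_image(path, 0L,
                    spacing_mm = spacing_mm %||%
                      if (grepl("\\.png$", path, ignore.case = TRUE)) c(1.82, 1.82) else NULL)
  binary_mask(img$pixels != 0, img$spacing_mm)
}

#' Write a mask (or image) to NIfTI or PNG
#'
#' @param x A `binary_mask` or `grayscale_image`.
#' @param path Output path ending in `.png`, `.nii` or `.nii.gz`. NIfTI output
#'   stores the pixel spacing in the header; PNG does not carry spacing.
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path) {
  px <- if (inherits(x, "binary_mask")) x$pixels * 1 else x$pixels
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(clip01(px), path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- array(px, c(dim(px), 1L))
    nif <- RNifti::asNifti(arr)
    RNifti::pixdim(nif) <- c(x$spacing_mm, 1)
    RNifti::writeNifti(nif, path)
  } else {
    stop("unsupported output format (use .png or .nii/.nii.gz)", call. = FALSE)
  }
  invisible(path)
}
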