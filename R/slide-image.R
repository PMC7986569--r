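#' Slide image container
#'
#' Wraps an 8-bit RGB raster together with a slide identifier and the
#' microns-per-pixel resolution. The raster is stored as a
#' `height x width x 3` integer array with channel values in `[0, 255]`.
#'
#' @param pixels height x width x 3 array of 8-bit RGB values.
#' @param slide_id character scalar identifying the slide.
#' @param mpp microns per pixel; 0.5 corresponds to x20 magnification.
#' @return An object of class `slide_image` with fields `pixels`,
#'   `slide_id`, `mpp`, `height`, `width`.
#' @export
slide_image <- function(pixels, slide_id = "slide", mpp = 0.5) {
  check_raster8(pixels, "slide pixels")
  storage.mode(pixels) <- "integer"
  stopifnot(is.character(slide_id), length(slide_id) == 1L,
            is.numeric(mpp), mpp > 0)
  structure(
    list(pixels = pixels, slide_id = slide_id, mpp = mpp,
         height = dim(pixels)[1L], width = dim(pixels)[2L]),
    class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image> %s: %d x %d px, %.2f um/px\n",
              x$slide_id, x$height, x$width, x$mpp))
  invisible(x)
}

#' Read a slide image from a PNG or TIFF file
#'
#' Pyramidal vendor formats are deliberately not handled here; export a
#' single level to PNG/TIFF, or plug a region reader in upstream of
#' [slide_image()].
#'
#' @param path file path; format decided by extension (.png, .tif, .tiff).
#' @param slide_id identifier, default the file name without extension.
#' @param mpp microns per pixel recorded on the object.
#' @return A [slide_image()].
#' @export
read_slide <- function(path, slide_id = NULL, mpp = 0.5) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported slide format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  px <- round(raw * 255)
  slide_image(px, slide_id %||% sub("\\.[^.]+$", "", basename(path)),
              mpp = mpp)
}

#' Write a slide image to PNG
#'
#' @param slide a [slide_image()].
#' @param path output path ending in .png.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_image"))
  png::writePNG(slide$pixels / 255, target = path)
  invisible(path)
}

#' Convert an RGB raster to 8-bit grayscale
#'
#' Uses the ITU-R BT.601 luma weights
#' `round(0.299 R + 0.587 G + 0.114 B)`, clamped to `[0, 255]`.
#'
#' @param patch_pixels height x width x 3 RGB array (8-bit).
#' @return Integer matrix of grayscale levels.
#' @export
to_grayscale <- function(patch_pixels) {
  check_raster8(patch_pixels, "patch")
  luma <- 0.299 * patch_pixels[, , 1L] + 0.587 * patch_pixels[, , 2L] +
    0.114 * patch_pixels[, , 3L]
  out <- clamp(round(luma), 0, 255)
  storage.mode(out) <- "integer"
  out
}
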