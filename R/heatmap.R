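#' Render per-patch confidence as a heatmap layer
#'
#' One intensity cell per patch, equal to the confidence score (a monotone
#' mapping: brighter means higher confidence of cancer); non-tissue cells
#' are `NA` and render transparent in overlays.
#'
#' @param sg a `score_grid`.
#' @param colormap `"white"` (monochrome white-on-dark, matching the usual
#'   presentation of predicted cancer regions) is currently the single
#'   built-in map.
#' @return A `heatmap_layer`: `intensity` matrix in `[0, 1]` with `NA` for
#'   non-tissue, `colormap`, `n_rows`, `n_cols`, `slide_id`.
#' @export
render_heatmap <- function(sg, colormap = "white") {
  stopifnot(inherits(sg, "score_grid"))
  colormap <- match.arg(colormap, "white")
  structure(list(intensity = sg$scores, colormap = colormap,
                 n_rows = sg$n_rows, n_cols = sg$n_cols,
                 slide_id = sg$slide_id),
            class = "heatmap_layer")
}

#' @export
print.heatmap_layer <- function(x, ...) {
  cat(sprintf("<heatmap_layer> %s: %d x %d cells (%s colormap)\n",
              x$slide_id, x$n_rows, x$n_cols, x$colormap))
  invisible(x)
}

# patch (i, j) -> pixel rows/cols at integer upscale factor f
patch_footprint <- function(i, j, f) {
  list(rows = ((i - 1L) * f + 1L):(i * f),
       cols = ((j - 1L) * f + 1L):(j * f))
}

# pixel (r, c) -> generating patch coordinate
pixel_to_patch <- function(r, c, f) {
  c((r - 1L) %/% f + 1L, (c - 1L) %/% f + 1L)
}

#' Overlay a heatmap on a slide thumbnail
#'
#' Each patch cell is mapped exactly onto its pixel footprint in the
#' thumbnail (the thumbnail sides must be the same integer multiple of the
#' grid dims). Tissue pixels blend linearly:
#' `(1 - alpha) * thumbnail + alpha * heat`, where `heat` is the white
#' colormap value `255 * intensity` on all three channels; non-tissue
#' pixels pass the thumbnail through unchanged. `alpha = 0` returns the
#' thumbnail bit-for-bit, `alpha = 1` the pure heatmap in tissue cells.
#'
#' @param layer a [render_heatmap()] result.
#' @param thumbnail a [slide_image()] aligned to the same slide.
#' @param alpha blend weight in `[0, 1]`.
#' @return A [slide_image()] of the blended raster.
#' @export
overlay_heatmap <- function(layer, thumbnail, alpha = 0.5) {
  stopifnot(inherits(layer, "heatmap_layer"),
            inherits(thumbnail, "slide_image"))
  check_probability(alpha, "alpha")
  fr <- thumbnail$height / layer$n_rows
  fc <- thumbnail$width / layer$n_cols
  if (fr != floor(fr) || fc != floor(fc) || fr != fc || fr < 1)
    stop("thumbnail dims (", thumbnail$height, " x ", thumbnail$width,
         ") are not an integer multiple of the heatmap grid (",
         layer$n_rows, " x ", layer$n_cols, "); resample the thumbnail")
  f <- as.integer(fr)
  big <- kronecker(layer$intensity, matrix(1, f, f))
  tissue_px <- !is.na(big)
  heat <- big * 255
  out <- thumbnail$pixels
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[tissue_px] <- round((1 - alpha) * plane[tissue_px] +
                                alpha * heat[tissue_px])
    out[, , ch] <- plane
  }
  slide_image(out, slide_id = paste0(thumbnail$slide_id, "_overlay"),
              mpp = thumbnail$mpp)
}
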