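#' Background-filter criteria
#'
#' A patch is flagged as non-informative background when either of two
#' clauses fires:
#'
#' 1. *Low colour saturation*: the per-pixel channel range
#'    `max(R,G,B) - min(R,G,B)`, maximized over the patch, is below
#'    `channel_range_max`. Near-white (and any grey) regions have almost no
#'    channel separation, whereas stained tissue does.
#' 2. *Bright surface*: the fraction of pixels whose grayscale level is at
#'    least `brightness_threshold` exceeds `surface_fraction`. Slide
#'    background is near-white, so bright patches are background. Setting
#'    `bright_is_background = FALSE` flips the clause to flag patches whose
#'    *dark* fraction exceeds `surface_fraction` (a strict literal reading,
#'    kept for sensitivity experiments; it would discard dark tissue).
#'
#' @param channel_range_max per-pixel channel-range threshold (default 20).
#' @param brightness_threshold grayscale level separating bright from dark
#'   (default 220).
#' @param surface_fraction fraction of the patch surface, in (0, 1)
#'   (default 0.5).
#' @param bright_is_background direction of the brightness clause.
#' @return An object of class `background_criteria`.
#' @export
background_criteria <- function(channel_range_max = 20,
                                brightness_threshold = 220,
                                surface_fraction = 0.5,
                                bright_is_background = TRUE) {
  stopifnot(channel_range_max >= 0, channel_range_max <= 255,
            brightness_threshold >= 0, brightness_threshold <= 255,
            surface_fraction > 0, surface_fraction < 1,
            is.logical(bright_is_background))
  structure(list(channel_range_max = channel_range_max,
                 brightness_threshold = brightness_threshold,
                 surface_fraction = surface_fraction,
                 bright_is_background = bright_is_background),
            class = "background_criteria")
}

new_patch_grid <- function(slide_id, n_rows, n_cols, patch_size_px,
                           tissue_mask = NULL) {
  tissue_mask <- tissue_mask %||% matrix(TRUE, n_rows, n_cols)
  stopifnot(nrow(tissue_mask) == n_rows, ncol(tissue_mask) == n_cols)
  structure(list(slide_id = slide_id, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 patch_size_px = as.integer(patch_size_px),
                 tissue_mask = tissue_mask),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %s: %d x %d patches of %d px, %d tissue\n",
              x$slide_id, x$n_rows, x$n_cols, x$patch_size_px,
              sum(x$tissue_mask)))
  invisible(x)
}

#' Tile a slide into a non-overlapping patch grid
#'
#' The slide raster is partitioned into `floor(height / p)` by
#' `floor(width / p)` patches of `p = patch_size_px` pixels; partial strips
#' at the right/bottom edges are dropped. Patch `(i, j)` (1-based in R
#' objects) covers pixel rows `(i-1)*p + 1 .. i*p` and the analogous
#' columns; file outputs record the equivalent 0-based half-open convention.
#' The tissue mask is initialized to all-`TRUE`; apply
#' [filter_background()] to mark background patches.
#'
#' @param slide a [slide_image()].
#' @param patch_size_px patch side length in pixels (default 300, the size
#'   used at x20 magnification).
#' @return A `patch_grid`.
#' @export
tile_slide <- function(slide, patch_size_px = 300) {
  stopifnot(inherits(slide, "slide_image"),
            patch_size_px >= 1, patch_size_px == floor(patch_size_px))
  n_rows <- slide$height %/% patch_size_px
  n_cols <- slide$width %/% patch_size_px
  if (n_rows < 1L || n_cols < 1L)
    stop("slide (", slide$height, " x ", slide$width,
         " px) is smaller than one ", patch_size_px,
         "-px patch; the grid would be empty")
  new_patch_grid(slide$slide_id, n_rows, n_cols, patch_size_px)
}

#' Extract the pixel block of one patch
#'
#' @param slide a [slide_image()].
#' @param grid the `patch_grid` tiled from `slide`.
#' @param row,col 1-based patch coordinates.
#' @return An 8-bit RGB array of side `grid$patch_size_px`.
#' @export
get_patch <- function(slide, grid, row, col) {
  stopifnot(row >= 1, row <= grid$n_rows, col >= 1, col <= grid$n_cols)
  p <- grid$patch_size_px
  slide$pixels[((row - 1L) * p + 1L):(row * p),
               ((col - 1L) * p + 1L):(col * p), , drop = FALSE]
}

#' Decide whether a patch is non-informative background
#'
#' Pure function of the pixel values and the criteria; see
#' [background_criteria()] for the two clauses. Both clauses are pixel-set
#' statistics, so the decision is invariant to rearranging pixels within
#' the patch.
#'
#' @param patch_pixels 8-bit RGB array.
#' @param criteria a [background_criteria()].
#' @return `TRUE` if the patch is background.
#' @export
is_background <- function(patch_pixels, criteria = background_criteria()) {
  check_raster8(patch_pixels, "patch")
  r <- patch_pixels[, , 1L]; g <- patch_pixels[, , 2L]; b <- patch_pixels[, , 3L]
  channel_range <- pmax(r, g, b) - pmin(r, g, b)
  low_saturation <- max(channel_range) < criteria$channel_range_max
  luma <- to_grayscale(patch_pixels)
  frac <- if (criteria$bright_is_background)
    mean(luma >= criteria$brightness_threshold)
  else
    mean(luma < criteria$brightness_threshold)
  low_saturation || frac > criteria$surface_fraction
}

#' Mark background patches in a grid
#'
#' Re-derives the tissue mask from the slide raster: patch `(i, j)` is
#' tissue iff [is_background()] is `FALSE` for its pixel block. Grid
#' geometry is never changed.
#'
#' @param grid `patch_grid` produced from `slide` by [tile_slide()].
#' @param slide the originating [slide_image()].
#' @param criteria a [background_criteria()].
#' @return The grid with an updated `tissue_mask`.
#' @export
filter_background <- function(grid, slide,
                              criteria = background_criteria()) {
  stopifnot(inherits(grid, "patch_grid"), inherits(slide, "slide_image"))
  p <- grid$patch_size_px
  if (grid$slide_id != slide$slide_id ||
      slide$height %/% p != grid$n_rows || slide$width %/% p != grid$n_cols)
    stop("patch grid does not match the slide it claims to tile")
  mask <- matrix(NA, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows))
    for (j in seq_len(grid$n_cols))
      mask[i, j] <- !is_background(get_patch(slide, grid, i, j), criteria)
  grid$tissue_mask <- mask
  grid
}

#' Write a patch-grid manifest as TSV
#'
#' Columns: `slide_id, row, col, x0, y0, is_tissue` with 0-based patch
#' coordinates and 0-based half-open pixel offsets (`x0` = column offset,
#' `y0` = row offset), stated in a `#`-comment header.
#'
#' @param grid a `patch_grid`.
#' @param path output TSV path.
#' @export
write_patch_manifest <- function(grid, path) {
  df <- manifest_frame(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# patch manifest: 0-based row/col; patch (row, col) covers pixel",
    sprintf("# rows [row*p, (row+1)*p) and cols [col*p, (col+1)*p), p = %d",
            grid$patch_size_px)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

manifest_frame <- function(grid) {
  p <- grid$patch_size_px
  rows <- rep(seq_len(grid$n_rows), times = grid$n_cols) - 1L
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows) - 1L
  data.frame(slide_id = grid$slide_id, row = rows, col = cols,
             x0 = cols * p, y0 = rows * p,
             is_tissue = as.integer(grid$tissue_mask))
}
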