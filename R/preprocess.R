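#' Resize a patch with bilinear interpolation
#'
#' Separable bilinear resampling with an align-corners convention: output
#' sample `k` (0-based) of `t` maps to source coordinate
#' `k * (s - 1) / (t - 1)`, so the four corner pixels are preserved exactly
#' and a constant patch stays constant. Used to map the 300-px tiles onto a
#' classifier's input side (299 px for Inception-style networks).
#'
#' @param patch_pixels RGB array (8-bit or real-valued).
#' @param target_side output side length in pixels.
#' @return A real-valued `target_side x target_side x 3` array (not
#'   rounded, so downstream normalization loses nothing to quantization).
#' @export
resize_patch <- function(patch_pixels, target_side) {
  check_raster_real(patch_pixels, "patch")
  stopifnot(target_side >= 1, target_side == floor(target_side))
  s_h <- dim(patch_pixels)[1L]; s_w <- dim(patch_pixels)[2L]
  coords <- function(t, s) {
    if (t == 1L) return((s - 1) / 2)
    if (s == 1L) return(rep(0, t))
    (0:(t - 1)) * (s - 1) / (t - 1)
  }
  ys <- coords(target_side, s_h); xs <- coords(target_side, s_w)
  y0 <- pmin(floor(ys), s_h - 1); x0 <- pmin(floor(xs), s_w - 1)
  y1 <- pmin(y0 + 1, s_h - 1);    x1 <- pmin(x0 + 1, s_w - 1)
  wy <- ys - y0; wx <- xs - x0
  w00 <- outer(1 - wy, 1 - wx); w01 <- outer(1 - wy, wx)
  w10 <- outer(wy, 1 - wx);     w11 <- outer(wy, wx)
  out <- array(0, c(target_side, target_side, 3L))
  for (ch in 1:3) {
    pl <- patch_pixels[, , ch]
    out[, , ch] <- w00 * pl[y0 + 1, x0 + 1, drop = FALSE] +
      w01 * pl[y0 + 1, x1 + 1, drop = FALSE] +
      w10 * pl[y1 + 1, x0 + 1, drop = FALSE] +
      w11 * pl[y1 + 1, x1 + 1, drop = FALSE]
  }
  out
}

#' Center and scale a patch to [-1, 1]
#'
#' Each pixel is centered by the image mean (a single scalar pooled over
#' channels by default, per-channel with `per_channel_mean = TRUE`), scaled
#' by `2/255` so the full 8-bit range maps into `[-1, 1]`, and clipped.
#' Centering first makes the result invariant (pre-clip) to adding a
#' constant to every pixel.
#'
#' @param patch_pixels RGB array with values on the `[0, 255]` scale.
#' @param per_channel_mean center each channel by its own mean.
#' @param provenance optional `(slide_id, row, col)` record carried along.
#' @return A `normalized_patch`: list with `values` (real array in
#'   `[-1, 1]`) and `provenance`.
#' @export
normalize_patch <- function(patch_pixels, per_channel_mean = FALSE,
                            provenance = NULL) {
  check_raster_real(patch_pixels, "patch")
  if (min(patch_pixels) < 0 || max(patch_pixels) > 255)
    stop("patch values must lie on the [0, 255] scale")
  centered <-
    if (per_channel_mean) {
      mu <- apply(patch_pixels, 3L, mean)
      sweep(patch_pixels, 3L, mu)
    } else {
      patch_pixels - mean(patch_pixels)
    }
  values <- clamp(centered * (2 / 255), -1, 1)
  structure(list(values = values, provenance = provenance),
            class = "normalized_patch")
}

#' Training-time augmentation configuration
#'
#' Random horizontal flip plus random adjustment of saturation, brightness,
#' contrast, and hue, each drawn uniformly within its configured range.
#' Identity values: saturation/contrast factor 1, brightness/hue delta 0.
#' Brightness deltas are fractions of the 8-bit range; hue deltas are
#' fractions of a full hue turn.
#'
#' @param flip allow random horizontal flips.
#' @param saturation_range,contrast_range multiplicative factor intervals.
#' @param brightness_range,hue_range additive delta intervals.
#' @param seed optional seed fixing the random stream.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(flip = TRUE,
                                saturation_range = c(0.8, 1.2),
                                brightness_range = c(-0.1, 0.1),
                                contrast_range = c(0.8, 1.2),
                                hue_range = c(-0.05, 0.05),
                                seed = NULL) {
  chk <- function(r, name) {
    if (!(is.numeric(r) && length(r) == 2L && all(is.finite(r)) &&
          r[1L] <= r[2L]))
      stop(name, " must be a finite interval c(lo, hi) with lo <= hi",
           call. = FALSE)
    r
  }
  structure(list(flip = isTRUE(flip),
                 saturation_range = chk(saturation_range, "saturation_range"),
                 brightness_range = chk(brightness_range, "brightness_range"),
                 contrast_range = chk(contrast_range, "contrast_range"),
                 hue_range = chk(hue_range, "hue_range"),
                 seed = seed),
            class = "augmentation_config")
}

#' Randomly augment a patch
#'
#' Applies, in order: horizontal flip (probability 1/2 when enabled),
#' saturation factor, hue rotation, brightness delta, contrast factor.
#' Every draw is uniform within its configured range; a draw equal to the
#' identity value leaves the raster untouched, so degenerate-identity
#' ranges give a bit-exact identity map. Deterministic given `cfg$seed`.
#'
#' @param patch_pixels 8-bit RGB array.
#' @param cfg an [augmentation_config()].
#' @return An 8-bit RGB array of the same shape.
#' @export
augment_patch <- function(patch_pixels, cfg = augmentation_config()) {
  check_raster8(patch_pixels, "patch")
  stopifnot(inherits(cfg, "augmentation_config"))
  with_seed(cfg$seed, {
    do_flip <- cfg$flip && runif(1) < 0.5
    sat <- runif(1, cfg$saturation_range[1L], cfg$saturation_range[2L])
    hue <- runif(1, cfg$hue_range[1L], cfg$hue_range[2L])
    bri <- runif(1, cfg$brightness_range[1L], cfg$brightness_range[2L])
    con <- runif(1, cfg$contrast_range[1L], cfg$contrast_range[2L])
    out <- patch_pixels
    if (do_flip) out <- out[, dim(out)[2L]:1L, , drop = FALSE]
    if (sat != 1 || hue != 0) {
      d <- dim(out)
      flat <- rbind(as.vector(out[, , 1L]), as.vector(out[, , 2L]),
                    as.vector(out[, , 3L]))
      hsv_m <- rgb2hsv(flat, maxColorValue = 255)
      hsv_m["s", ] <- clamp(hsv_m["s", ] * sat, 0, 1)
      hsv_m["h", ] <- (hsv_m["h", ] + hue) %% 1
      back <- col2rgb(hsv(hsv_m["h", ], hsv_m["s", ], hsv_m["v", ]))
      out <- array(0, d)
      out[, , 1L] <- back[1L, ]; out[, , 2L] <- back[2L, ]
      out[, , 3L] <- back[3L, ]
    }
    if (bri != 0) out <- out + bri * 255
    if (con != 1) out <- (out - mean(out)) * con + mean(out)
    out <- clamp(round(out), 0, 255)
    storage.mode(out) <- "integer"
    out
  })
}
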