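# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# 8-bit RGB raster: height x width x 3 array of whole numbers in [0, 255]
check_raster8 <- function(x, what = "raster") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop(what, " must be a height x width x 3 RGB array", call. = FALSE)
  if (!is.numeric(x) || anyNA(x))
    stop(what, " must be numeric with no missing values", call. = FALSE)
  rng <- range(x)
  if (rng[1L] < 0 || rng[2L] > 255 || any(x != floor(x)))
    stop(what, " must hold 8-bit values (whole numbers in [0, 255])",
         call. = FALSE)
  invisible(TRUE)
}

# relaxed check for real-valued rasters (e.g. bilinear-resized patches)
check_raster_real <- function(x, what = "raster") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop(what, " must be a height x width x 3 RGB array", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, " must be numeric and finite", call. = FALSE)
  invisible(TRUE)
}

check_connectivity <- function(connectivity) {
  if (!(length(connectivity) == 1L && connectivity %in% c(4, 8)))
    stop("connectivity must be 4 or 8", call. = FALSE)
  as.integer(connectivity)
}

check_probability <- function(x, name, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > 0 else x >= 0) && (if (open_hi) x < 1 else x <= 1)
  if (!ok) stop(name, " must be a single value in ",
                if (open_lo) "(" else "[", "0, 1",
                if (open_hi) ")" else "]", call. = FALSE)
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
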