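#' Simulated patch-classifier configuration
#'
#' Describes a patch classifier by its operating point rather than its
#' weights: `sensitivity` is the probability that a truly cancerous patch
#' scores at or above `threshold`, `specificity` the probability that a
#' truly normal patch scores below it. Scores are continuous on `[0, 1]`:
#' the side of the threshold is drawn Bernoulli at the configured rate, and
#' the value within the side follows a truncated power density with
#' concentration `score_dispersion` toward the class mode (1 for cancer,
#' 0 for normal). The operating point therefore holds exactly for any
#' dispersion, while dispersion shapes how peaked the score histogram is
#' (useful for ROC experiments). A patch-level operating point of roughly
#' 95% sensitivity / 99% specificity is the regime in which the cluster
#' rule controls patient-level error.
#'
#' @param sensitivity,specificity per-patch true-positive and true-negative
#'   rates, in `(0, 1]`.
#' @param threshold score binarization threshold, strictly inside `(0, 1)`.
#' @param score_dispersion concentration (> 0) of the within-side density.
#' @param seed optional seed carried to scoring functions.
#' @return A `simulated_classifier_config`.
#' @export
simulated_classifier_config <- function(sensitivity = 0.95,
                                        specificity = 0.99,
                                        threshold = 0.5,
                                        score_dispersion = 4,
                                        seed = NULL) {
  check_probability(sensitivity, "sensitivity", open_lo = TRUE)
  check_probability(specificity, "specificity", open_lo = TRUE)
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold < 1))
    stop("threshold must lie strictly inside (0, 1); a threshold at 0 or 1",
         " cannot separate the two score modes")
  stopifnot(is.numeric(score_dispersion), score_dispersion > 0)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 threshold = threshold, score_dispersion = score_dispersion,
                 seed = seed),
            class = "simulated_classifier_config")
}

# draw with density proportional to x^(d-1) (mode toward hi) on [lo, hi]
draw_toward_hi <- function(n, lo, hi, d) {
  u <- runif(n, lo^d, hi^d)
  u^(1 / d)
}

#' Draw simulated confidence scores
#'
#' Vectorized over `truth_label`. For a cancer patch the score lands in
#' `[threshold, 1]` with probability `sensitivity` (else in
#' `[0, threshold)`), with density rising toward 1; for a normal patch it
#' lands in `[0, threshold)` with probability `specificity` (else in
#' `[threshold, 1]`), with density rising toward 0. Deterministic given
#' `cfg$seed`.
#'
#' @param truth_label character vector of `"cancer"` / `"normal"`.
#' @param cfg a [simulated_classifier_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
simulated_score <- function(truth_label, cfg = simulated_classifier_config(),
                            seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulated_classifier_config"))
  if (!all(truth_label %in% c("cancer", "normal")))
    stop("truth_label values must be 'cancer' or 'normal'")
  n <- length(truth_label)
  with_seed(seed, {
    cancer <- truth_label == "cancer"
    p_correct <- ifelse(cancer, cfg$sensitivity, cfg$specificity)
    correct <- runif(n) < p_correct
    above <- cancer == correct  # TRUE: score in [threshold, 1]
    t <- cfg$threshold; d <- cfg$score_dispersion
    lo <- ifelse(above, t, 0); hi <- ifelse(above, 1, t)
    scores <- numeric(n)
    # cancer scores rise toward 1 within their side; normal scores rise
    # toward 0 (drawn as the mirror image)
    if (any(cancer))
      scores[cancer] <- draw_toward_hi(sum(cancer), lo[cancer], hi[cancer], d)
    if (any(!cancer))
      scores[!cancer] <- 1 - draw_toward_hi(sum(!cancer), 1 - hi[!cancer],
                                            1 - lo[!cancer], d)
    scores
  })
}

new_score_grid <- function(scores, slide_id = "slide", threshold = 0.5) {
  stopifnot(is.matrix(scores))
  present <- scores[!is.na(scores)]
  if (length(present) && (min(present) < 0 || max(present) > 1))
    stop("scores must lie in [0, 1]")
  structure(list(slide_id = slide_id, n_rows = nrow(scores),
                 n_cols = ncol(scores), scores = scores,
                 threshold = threshold),
            class = "score_grid")
}

#' Per-patch confidence-score grid
#'
#' Assigns one confidence score to every tissue patch of a grid;
#' non-tissue cells carry `NA`. `grid` may be a `patch_grid` (with `truth`
#' a matching character lattice of `"cancer"`/`"normal"`, `NA` allowed on
#' non-tissue cells) or a [simulate_truth()] result, whose own truth
#' lattice and tissue mask are used.
#'
#' @param grid a `patch_grid` or `simulated_slide`.
#' @param truth character lattice matching the grid dims (ignored for
#'   `simulated_slide` input).
#' @param cfg a [simulated_classifier_config()].
#' @param seed optional seed (default: the config's).
#' @return A `score_grid`.
#' @export
score_grid <- function(grid, truth = NULL,
                       cfg = simulated_classifier_config(),
                       seed = cfg$seed) {
  if (inherits(grid, "simulated_slide")) {
    truth <- grid$truth
    mask <- grid$tissue_mask
    slide_id <- grid$slide_id
    nr <- grid$n_rows; nc <- grid$n_cols
  } else if (inherits(grid, "patch_grid")) {
    if (is.null(truth)) stop("truth lattice required for a patch_grid")
    mask <- grid$tissue_mask
    slide_id <- grid$slide_id
    nr <- grid$n_rows; nc <- grid$n_cols
  } else stop("grid must be a patch_grid or simulated_slide")
  if (!(is.matrix(truth) && nrow(truth) == nr && ncol(truth) == nc))
    stop("truth lattice shape does not match the grid")
  tissue <- mask & !is.na(truth)
  scores <- matrix(NA_real_, nr, nc)
  scores[tissue] <- with_seed(seed,
                              simulated_score(truth[tissue], cfg, seed = NULL))
  new_score_grid(scores, slide_id, threshold = cfg$threshold)
}

#' Wrap external score matrices as a score grid
#'
#' Adapter for real classifiers: any model that produces one confidence in
#' `[0, 1]` per tissue patch (e.g. a CNN softmax output) plugs into the
#' aggregation stage through this constructor, with `NA` marking non-tissue
#' cells.
#'
#' @param scores numeric matrix of confidences (`NA` = non-tissue).
#' @param slide_id slide identifier.
#' @param threshold binarization threshold stored with the grid.
#' @return A `score_grid`.
#' @export
as_score_grid <- function(scores, slide_id = "slide", threshold = 0.5) {
  new_score_grid(scores, slide_id, threshold)
}

#' @export
print.score_grid <- function(x, ...) {
  cat(sprintf("<score_grid> %s: %d x %d, %d scored patches, threshold %.2f\n",
              x$slide_id, x$n_rows, x$n_cols, sum(!is.na(x$scores)),
              x$threshold))
  invisible(x)
}

#' Patch-classifier contract
#'
#' Any object with a `score(normalized_patch) -> confidence in [0, 1]`
#' function plus `name`, `input_side`, `version` metadata can drive the
#' pipeline; [score_slide()] handles tiling-side preprocessing. The
#' simulated classifier satisfies the same downstream contract at the grid
#' level via [score_grid()].
#'
#' @param score_fun function taking a [normalize_patch()] result and
#'   returning a single confidence in `[0, 1]`.
#' @param name classifier name.
#' @param input_side input side length in pixels the classifier expects.
#' @param version free-form version string.
#' @return A `patch_classifier`.
#' @export
patch_classifier <- function(score_fun, name, input_side = 299,
                             version = "1") {
  stopifnot(is.function(score_fun), input_side >= 1)
  structure(list(score = score_fun, name = name,
                 input_side = as.integer(input_side), version = version),
            class = "patch_classifier")
}

#' Constant-score stub classifier
#'
#' Scores every patch identically; used to exercise the classifier contract
#' without a trained model.
#'
#' @param value the constant confidence.
#' @param input_side input side length.
#' @return A [patch_classifier()].
#' @export
constant_classifier <- function(value = 0.5, input_side = 299) {
  check_probability(value, "value")
  patch_classifier(function(patch) value, name = "constant",
                   input_side = input_side, version = "1")
}

#' Score every tissue patch of a slide with a classifier
#'
#' For each tissue patch: extract, bilinear-resize to the classifier's
#' input side, normalize to `[-1, 1]`, and score.
#'
#' @param slide a [slide_image()].
#' @param grid its filtered `patch_grid`.
#' @param classifier a [patch_classifier()].
#' @param threshold binarization threshold stored on the result.
#' @return A `score_grid`.
#' @export
score_slide <- function(slide, grid, classifier, threshold = 0.5) {
  stopifnot(inherits(classifier, "patch_classifier"))
  scores <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      if (!grid$tissue_mask[i, j]) next
      patch <- get_patch(slide, grid, i, j)
      np <- normalize_patch(resize_patch(patch, classifier$input_side),
                            provenance = list(slide_id = grid$slide_id,
                                              row = i, col = j))
      s <- classifier$score(np)
      if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1)
        stop("classifier '", classifier$name,
             "' returned an invalid confidence for patch (", i, ", ", j, ")")
      scores[i, j] <- s
    }
  }
  new_score_grid(scores, grid$slide_id, threshold)
}

#' Write a score grid as TSV
#'
#' Columns `slide_id, row, col, score` (0-based coordinates, tissue cells
#' only).
#'
#' @param sg a `score_grid`.
#' @param path output TSV path.
#' @export
write_score_grid <- function(sg, path) {
  df <- scores_frame(sg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-patch confidence scores: 0-based row/col, tissue only",
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

scores_frame <- function(sg) {
  idx <- which(!is.na(sg$scores))
  data.frame(slide_id = sg$slide_id,
             row = (idx - 1L) %% sg$n_rows,
             col = (idx - 1L) %/% sg$n_rows,
             score = sprintf("%.10g", sg$scores[idx]))
}

#' Read a score grid from TSV
#'
#' @param path TSV written by [write_score_grid()].
#' @param n_rows,n_cols grid dimensions; inferred from the largest
#'   coordinates when omitted.
#' @param threshold binarization threshold stored on the result.
#' @return A `score_grid`.
#' @export
read_score_grid <- function(path, n_rows = NULL, n_cols = NULL,
                            threshold = 0.5) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  n_rows <- n_rows %||% (max(df$row) + 1L)
  n_cols <- n_cols %||% (max(df$col) + 1L)
  scores <- matrix(NA_real_, n_rows, n_cols)
  scores[cbind(df$row + 1L, df$col + 1L)] <- as.numeric(df$score)
  new_score_grid(scores, df$slide_id[1L] %||% "slide", threshold)
}
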