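#' Confusion counts and diagnostic rates
#'
#' Counts TP/FP/TN/FN of binary calls against binary truth and derives
#' accuracy `(TP + TN) / total`, sensitivity `TP / (TP + FN)`, and
#' specificity `TN / (TN + FP)`. A rate whose class is absent from the
#' truth is reported as `NA` (undefined), never as 0.
#'
#' @param calls,truth equal-length vectors of 0/1 (logicals accepted).
#' @return A `confusion_table`: `tp`, `fp`, `tn`, `fn`, `total`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion <- function(calls, truth) {
  calls <- as.integer(calls); truth <- as.integer(truth)
  if (length(calls) != length(truth) || length(calls) < 1L)
    stop("calls and truth must be nonempty vectors of equal length")
  if (!all(calls %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L)))
    stop("calls and truth must be binary (0/1)")
  tp <- sum(calls == 1L & truth == 1L)
  fp <- sum(calls == 1L & truth == 0L)
  tn <- sum(calls == 0L & truth == 0L)
  fn <- sum(calls == 0L & truth == 1L)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, total = length(calls),
    accuracy = (tp + tn) / length(calls),
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_),
    class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP %d FP %d TN %d FN %d\n", x$tp, x$fp,
              x$tn, x$fn))
  cat(sprintf("  accuracy %.4f, sensitivity %s, specificity %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "undefined",
                     sprintf("%.4f", x$sensitivity)),
              ifelse(is.na(x$specificity), "undefined",
                     sprintf("%.4f", x$specificity))))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sensitivity against false positive rate over all score thresholds, with
#' the trapezoidal AUC; for continuous-or-tied scores this equals the
#' Mann-Whitney statistic `P(score_pos > score_neg) + 0.5 P(tie)`. Both
#' classes must be present.
#'
#' @param scores numeric confidence scores.
#' @param truth binary labels (1 = positive class).
#' @return A `roc_curve`: `points` (data.frame `fpr`, `sensitivity`,
#'   monotone from (0, 0) to (1, 1)) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% c(0L, 1L)))
  if (length(unique(truth)) < 2L)
    stop("ROC requires both classes in the truth labels")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities,
                    sensitivity = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$sensitivity), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = as.numeric(r$auc),
                 n_pos = sum(truth == 1L), n_neg = sum(truth == 0L)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `K = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` and chance agreement `p_e` from the raters' marginals.
#' Symmetric in the raters. When both raters are constant and identical
#' (`p_e = 1`, forcing `p_o = 1`), `K` is defined as 1.
#'
#' @param rater_a,rater_b equal-length binary vectors.
#' @return An `agreement_result`: `kappa`, `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  a <- as.integer(rater_a); b <- as.integer(rater_b)
  if (length(a) != length(b) || length(a) < 1L)
    stop("raters must give nonempty vectors of equal length")
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L)))
    stop("ratings must be binary (0/1)")
  p_o <- mean(a == b)
  p_e <- mean(a == 1L) * mean(b == 1L) + mean(a == 0L) * mean(b == 0L)
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = length(a)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> kappa %.4f (p_o %.4f, p_e %.4f, n %d)\n",
              x$kappa, x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired values (e.g. per-dataset AUCs of two raters).
#' Zero differences are dropped, the exact signed-rank distribution is used
#' for up to `exact_max` nonzero untied differences, and the normal
#' approximation with continuity and tie correction otherwise. All
#' differences zero gives `p = 1` by convention (no evidence of any
#' shift). Swapping the two inputs leaves the p-value unchanged.
#'
#' @param values_a,values_b equal-length paired numeric vectors.
#' @param exact_max largest n for which the exact distribution is used.
#' @return A list: `p.value`, `statistic` (V, sum of positive-difference
#'   ranks), `n` (nonzero pairs), `exact`.
#' @export
paired_wilcoxon <- function(values_a, values_b, exact_max = 25) {
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) == length(values_b), length(values_a) >= 1L)
  d <- values_a - values_b
  if (all(d == 0))
    return(list(p.value = 1, statistic = NA_real_, n = 0L, exact = TRUE))
  nz <- d[d != 0]
  ties <- any(duplicated(abs(nz)))
  exact <- length(nz) <= exact_max && !ties
  ht <- suppressWarnings(
    wilcox.test(nz, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(p.value = unname(ht$p.value), statistic = unname(ht$statistic),
       n = length(nz), exact = exact)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Nonparametric bootstrap over the given per-dataset values (10,000
#' resamples by default), percentile interval, seeded.
#'
#' @param values numeric vector (one value per dataset).
#' @param level confidence level.
#' @param n_boot number of resamples.
#' @param seed optional seed.
#' @return A list: `mean`, `lower`, `upper`, `level`, `n_boot`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 10000,
                         seed = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1L, level > 0, level < 1)
  with_seed(seed, {
    n <- length(values)
    means <- vapply(seq_len(n_boot),
                    function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    alpha <- (1 - level) / 2
    qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
    list(mean = mean(values), lower = qs[1L], upper = qs[2L],
         level = level, n_boot = n_boot)
  })
}
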