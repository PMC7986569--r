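#' Rectangular lesion specification
#'
#' An axis-aligned block of cancer patches; tumours tend to gather
#' together, so contiguous blocks are the default lesion geometry.
#'
#' @param row,col 1-based coordinates of the top-left patch.
#' @param height,width extent in patches.
#' @return A `lesion_rect`.
#' @export
lesion_rect <- function(row, col, height, width) {
  stopifnot(row >= 1, col >= 1, height >= 1, width >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = c("lesion_rect", "lesion"))
}

#' Random-walk blob lesion specification
#'
#' Grows a connected blob of `n_cells` patches by repeatedly attaching a
#' random in-grid 4-neighbour of a random current member, starting from
#' `start` (random when `NULL`). Cell placement is drawn when the lesion is
#' planted by [simulate_truth()], under that call's random stream.
#'
#' @param n_cells number of patches in the blob.
#' @param start optional `c(row, col)` of the first cell.
#' @return A `lesion_blob`.
#' @export
lesion_blob <- function(n_cells, start = NULL) {
  stopifnot(n_cells >= 1)
  structure(list(n_cells = as.integer(n_cells), start = start),
            class = c("lesion_blob", "lesion"))
}

lesion_cells <- function(lesion, n_rows, n_cols) UseMethod("lesion_cells")

#' @export
lesion_cells.lesion_rect <- function(lesion, n_rows, n_cols) {
  if (lesion$row + lesion$height - 1L > n_rows ||
      lesion$col + lesion$width - 1L > n_cols)
    stop("lesion extends outside the grid")
  cells <- matrix(FALSE, n_rows, n_cols)
  cells[lesion$row:(lesion$row + lesion$height - 1L),
        lesion$col:(lesion$col + lesion$width - 1L)] <- TRUE
  cells
}

#' @export
lesion_cells.lesion_blob <- function(lesion, n_rows, n_cols) {
  if (lesion$n_cells > n_rows * n_cols)
    stop("lesion extends outside the grid")
  start <- lesion$start %||% c(sample.int(n_rows, 1L), sample.int(n_cols, 1L))
  if (start[1L] < 1L || start[1L] > n_rows || start[2L] < 1L ||
      start[2L] > n_cols)
    stop("lesion extends outside the grid")
  cells <- matrix(FALSE, n_rows, n_cols)
  cells[start[1L], start[2L]] <- TRUE
  members <- matrix(start, ncol = 2L)
  offsets <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  while (sum(cells) < lesion$n_cells) {
    seedcell <- members[sample.int(nrow(members), 1L), ]
    cand <- sweep(offsets, 2L, seedcell, `+`)
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= n_rows &
      cand[, 2L] >= 1L & cand[, 2L] <= n_cols
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[!cells[cand], , drop = FALSE]
    if (nrow(cand) == 0L) next
    add <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    cells[add] <- TRUE
    members <- rbind(members, add)
  }
  cells
}

#' Draw a random rectangular lesion
#'
#' Samples a lesion whose area fraction of the grid is uniform within
#' `area_fraction` (default 10-50%, the range spanning most clinical
#' slides) with a mildly random aspect ratio, placed uniformly inside the
#' grid.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param area_fraction interval of lesion area as a fraction of the grid.
#' @return A [lesion_rect()].
#' @export
sample_lesion <- function(n_rows, n_cols, area_fraction = c(0.1, 0.5)) {
  stopifnot(length(area_fraction) == 2L, area_fraction[1L] > 0,
            area_fraction[2L] <= 1, area_fraction[1L] <= area_fraction[2L])
  frac <- runif(1, area_fraction[1L], area_fraction[2L])
  area <- max(1, round(frac * n_rows * n_cols))
  aspect <- exp(runif(1, -0.7, 0.7))
  h <- clamp(round(sqrt(area * aspect)), 1, n_rows)
  w <- clamp(ceiling(area / h), 1, n_cols)
  lesion_rect(sample.int(n_rows - h + 1L, 1L),
              sample.int(n_cols - w + 1L, 1L), h, w)
}

#' Simulate a ground-truth slide lattice
#'
#' Builds the per-patch truth of one synthetic slide: a tissue mask (each
#' cell tissue independently with probability `tissue_fraction`) and
#' planted lesions whose cells, clipped to tissue, are labelled `"cancer"`;
#' remaining tissue is `"normal"` and non-tissue is `NA`. The slide label
#' is `"cancer"` iff at least one cancer cell exists. Deterministic given
#' `seed`.
#'
#' @param n_rows,n_cols lattice dimensions in patches.
#' @param lesions list of lesion specifications ([lesion_rect()] /
#'   [lesion_blob()]); empty for a normal slide.
#' @param tissue_fraction probability a cell is tissue, in (0, 1].
#' @param seed optional seed.
#' @param slide_id identifier.
#' @return A `simulated_slide` with fields `truth`, `tissue_mask`,
#'   `n_rows`, `n_cols`, `lesions`, `slide_label`, `tissue_fraction`,
#'   `seed`, `slide_id`.
#' @export
simulate_truth <- function(n_rows, n_cols, lesions = list(),
                           tissue_fraction = 1, seed = NULL,
                           slide_id = "sim") {
  stopifnot(n_rows >= 1, n_cols >= 1)
  check_probability(tissue_fraction, "tissue_fraction", open_lo = TRUE)
  if (inherits(lesions, "lesion")) lesions <- list(lesions)
  with_seed(seed, {
    tissue <- if (tissue_fraction < 1)
      matrix(runif(n_rows * n_cols) < tissue_fraction, n_rows, n_cols)
    else matrix(TRUE, n_rows, n_cols)
    cancer <- matrix(FALSE, n_rows, n_cols)
    for (L in lesions)
      cancer <- cancer | lesion_cells(L, n_rows, n_cols)
    cancer <- cancer & tissue
    truth <- matrix(NA_character_, n_rows, n_cols)
    truth[tissue] <- "normal"
    truth[cancer] <- "cancer"
    structure(list(truth = truth, tissue_mask = tissue,
                   n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                   lesions = lesions,
                   slide_label = if (any(cancer)) "cancer" else "non-cancer",
                   tissue_fraction = tissue_fraction, seed = seed,
                   slide_id = slide_id),
              class = "simulated_slide")
  })
}

#' @export
print.simulated_slide <- function(x, ...) {
  cat(sprintf(
    "<simulated_slide> %s: %d x %d patches, %d tissue, %d cancer (%s)\n",
    x$slide_id, x$n_rows, x$n_cols, sum(x$tissue_mask),
    sum(x$truth == "cancer", na.rm = TRUE), x$slide_label))
  invisible(x)
}

#' Convert a simulated slide to a patch grid
#'
#' @param sim a `simulated_slide`.
#' @param patch_size_px nominal patch side in pixels.
#' @return A `patch_grid` carrying the simulated tissue mask.
#' @export
as_patch_grid <- function(sim, patch_size_px = 300) {
  stopifnot(inherits(sim, "simulated_slide"))
  new_patch_grid(sim$slide_id, sim$n_rows, sim$n_cols, patch_size_px,
                 tissue_mask = sim$tissue_mask)
}

#' Render a simulated slide to an RGB raster
#'
#' Fixture generator so the tiling and background-filter paths can be
#' exercised end-to-end. Non-tissue cells are rendered as near-white
#' zero-saturation pixels (grey levels 235-255), which both background
#' clauses flag; tissue cells are rendered as a two-colour
#' haematoxylin/eosin-like checkerboard with per-pixel channel range 100
#' and dark luma, which neither clause flags. Round-tripping through
#' [tile_slide()] + [filter_background()] with default criteria therefore
#' recovers the tissue mask exactly. Cancer cells use a slightly darker
#' palette so heatmap demos have visible structure; the rendered pixels are
#' not meant to carry diagnostic signal.
#'
#' @param sim a `simulated_slide`.
#' @param patch_size_px pixels per patch side (small values keep fixtures
#'   light; the geometry is scale-free).
#' @param seed optional seed for the background grey jitter.
#' @return A [slide_image()].
#' @export
render_slide <- function(sim, patch_size_px = 300, seed = NULL) {
  stopifnot(inherits(sim, "simulated_slide"), patch_size_px >= 2)
  p <- as.integer(patch_size_px)
  H <- sim$n_rows * p; W <- sim$n_cols * p
  with_seed(seed, {
    grey <- sample(235:255, H * W, replace = TRUE)
    img <- array(0L, c(H, W, 3L))
    img[, , 1L] <- grey; img[, , 2L] <- grey; img[, , 3L] <- grey
    # pixel-level maps of cell type
    cell_cancer <- !is.na(sim$truth) & sim$truth == "cancer"
    one <- matrix(1L, p, p)
    tissue_px <- kronecker(sim$tissue_mask * 1L, one) == 1L
    cancer_px <- kronecker(cell_cancer * 1L, one) == 1L
    parity <- outer(seq_len(H), seq_len(W), function(i, j) (i + j) %% 2L)
    palette <- list(
      normal = list(a = c(180L, 80L, 160L), b = c(90L, 40L, 120L)),
      cancer = list(a = c(150L, 50L, 110L), b = c(70L, 20L, 90L)))
    for (ch in 1:3) {
      layer <- img[, , ch]
      sel <- tissue_px & !cancer_px
      layer[sel] <- ifelse(parity[sel] == 0L, palette$normal$a[ch],
                           palette$normal$b[ch])
      layer[cancer_px] <- ifelse(parity[cancer_px] == 0L,
                                 palette$cancer$a[ch], palette$cancer$b[ch])
      img[, , ch] <- layer
    }
    slide_image(img, slide_id = sim$slide_id, mpp = 0.5)
  })
}

#' Estimate slide-level operating characteristics by Monte Carlo
#'
#' Links the patch-level operating point to slide-level error for a set of
#' cluster sizes. Each replicate simulates one cancer slide (a lesion drawn
#' by `lesion_sampler`) and one normal slide, scores every tissue patch
#' with the simulated classifier, and applies the cluster rule at each
#' cluster size. Slide sensitivity is the fraction of cancer replicates
#' called positive; slide FPR the fraction of normal replicates called
#' positive. Standard errors are binomial. Deterministic given `seed`.
#'
#' @param n_rows,n_cols slide lattice dimensions (defaults 71 x 71, about
#'   5000 patches, the scale of a typical whole slide).
#' @param lesion_sampler zero-argument function returning a lesion spec for
#'   a cancer replicate; default: random rectangles covering 10-50% of the
#'   grid.
#' @param classifier_cfg a [simulated_classifier_config()].
#' @param cluster_sizes integer vector of cluster sizes to evaluate.
#' @param threshold binarization threshold.
#' @param connectivity 4 or 8.
#' @param tissue_fraction probability a cell is tissue.
#' @param n_reps replicates per class, >= 1.
#' @param seed optional seed.
#' @return An `operating_point_table` (a data.frame): `cluster_size`,
#'   `threshold`, `patch_sens`, `patch_spec`, `n_patches`,
#'   `slide_sensitivity`, `slide_FPR`, `se_sensitivity`, `se_FPR`,
#'   `n_reps`.
#' @export
estimate_operating_characteristics <- function(
    n_rows = 71, n_cols = 71,
    lesion_sampler = function() sample_lesion(n_rows, n_cols),
    classifier_cfg = simulated_classifier_config(),
    cluster_sizes = c(1, 2, 4, 8),
    threshold = classifier_cfg$threshold,
    connectivity = 4, tissue_fraction = 1,
    n_reps = 200, seed = NULL) {
  stopifnot(n_reps >= 1, length(cluster_sizes) >= 1, all(cluster_sizes >= 1))
  cluster_sizes <- as.integer(cluster_sizes)
  connectivity <- check_connectivity(connectivity)
  with_seed(seed, {
    pos_cancer <- pos_normal <- setNames(integer(length(cluster_sizes)),
                                         cluster_sizes)
    tp <- fn <- tn <- fp <- 0; tissue_total <- 0
    for (r in seq_len(n_reps)) {
      sims <- list(
        cancer = simulate_truth(n_rows, n_cols,
                                lesions = list(lesion_sampler()),
                                tissue_fraction = tissue_fraction),
        normal = simulate_truth(n_rows, n_cols,
                                tissue_fraction = tissue_fraction))
      for (cls in names(sims)) {
        sim <- sims[[cls]]
        sg <- score_grid(sim, cfg = classifier_cfg, seed = NULL)
        bin <- binarize(sg, threshold)
        truth_cancer <- !is.na(sim$truth) & sim$truth == "cancer"
        truth_normal <- !is.na(sim$truth) & sim$truth == "normal"
        tp <- tp + sum(bin & truth_cancer)
        fn <- fn + sum(!bin & truth_cancer)
        fp <- fp + sum(bin & truth_normal)
        tn <- tn + sum(!bin & truth_normal)
        tissue_total <- tissue_total + sum(sim$tissue_mask)
        sizes <- component_sizes(bin, connectivity)
        max_size <- if (length(sizes)) max(sizes) else 0L
        hit <- max_size >= cluster_sizes
        if (cls == "cancer") pos_cancer <- pos_cancer + hit
        else pos_normal <- pos_normal + hit
      }
    }
    sens <- pos_cancer / n_reps
    fpr <- pos_normal / n_reps
    out <- data.frame(
      cluster_size = cluster_sizes,
      threshold = threshold,
      patch_sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      patch_spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      n_patches = tissue_total / (2 * n_reps),
      slide_sensitivity = as.numeric(sens),
      slide_FPR = as.numeric(fpr),
      se_sensitivity = sqrt(sens * (1 - sens) / n_reps),
      se_FPR = sqrt(fpr * (1 - fpr) / n_reps),
      n_reps = n_reps)
    class(out) <- c("operating_point_table", "data.frame")
    out
  })
}

#' Patient-level error under the union rule
#'
#' Groups simulated slides into patients of `slides_per_patient` slides and
#' applies [diagnose_patient()]. Every slide of a cancer patient carries a
#' lesion; normal patients' slides carry none. Under independence the
#' patient FPR follows `1 - (1 - FPR_slide)^m`, which is why slide-level
#' false positives must be controlled before the union.
#'
#' @param slides_per_patient slides per simulated patient, >= 1.
#' @param n_rows,n_cols,lesion_sampler,classifier_cfg,threshold,connectivity,tissue_fraction
#'   as in [estimate_operating_characteristics()].
#' @param cluster_size single cluster size used for slide calls.
#' @param n_reps simulated patients per class.
#' @param seed optional seed.
#' @return A list: `patient_sensitivity`, `patient_FPR`,
#'   `slide_sensitivity`, `slide_FPR`, binomial `se_*`, plus the settings.
#' @export
patient_level_error <- function(
    slides_per_patient, n_rows = 71, n_cols = 71,
    lesion_sampler = function() sample_lesion(n_rows, n_cols),
    classifier_cfg = simulated_classifier_config(),
    cluster_size = 4, threshold = classifier_cfg$threshold,
    connectivity = 4, tissue_fraction = 1, n_reps = 200, seed = NULL) {
  stopifnot(slides_per_patient >= 1, n_reps >= 1)
  m <- as.integer(slides_per_patient)
  with_seed(seed, {
    pat_pos_cancer <- pat_pos_normal <- 0L
    slide_pos_cancer <- slide_pos_normal <- 0L
    slide_call <- function(sim) {
      sg <- score_grid(sim, cfg = classifier_cfg, seed = NULL)
      sizes <- component_sizes(binarize(sg, threshold), connectivity)
      as.integer(length(sizes) > 0L && max(sizes) >= cluster_size)
    }
    for (r in seq_len(n_reps)) {
      calls_c <- vapply(seq_len(m), function(i) slide_call(
        simulate_truth(n_rows, n_cols, lesions = list(lesion_sampler()),
                       tissue_fraction = tissue_fraction)), integer(1))
      calls_n <- vapply(seq_len(m), function(i) slide_call(
        simulate_truth(n_rows, n_cols, tissue_fraction = tissue_fraction)),
        integer(1))
      slide_pos_cancer <- slide_pos_cancer + sum(calls_c)
      slide_pos_normal <- slide_pos_normal + sum(calls_n)
      pat_pos_cancer <- pat_pos_cancer +
        diagnose_patient(calls_c, "sim-cancer")$call
      pat_pos_normal <- pat_pos_normal +
        diagnose_patient(calls_n, "sim-normal")$call
    }
    p_sens <- pat_pos_cancer / n_reps
    p_fpr <- pat_pos_normal / n_reps
    s_sens <- slide_pos_cancer / (n_reps * m)
    s_fpr <- slide_pos_normal / (n_reps * m)
    list(patient_sensitivity = p_sens, patient_FPR = p_fpr,
         slide_sensitivity = s_sens, slide_FPR = s_fpr,
         se_patient_sensitivity = sqrt(p_sens * (1 - p_sens) / n_reps),
         se_patient_FPR = sqrt(p_fpr * (1 - p_fpr) / n_reps),
         slides_per_patient = m, cluster_size = as.integer(cluster_size),
         n_reps = n_reps)
  })
}
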