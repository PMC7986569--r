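#' Binarize a score grid
#'
#' A tissue cell is positive iff its score is at least `threshold`;
#' non-tissue (`NA`) cells are never positive, so they break connectivity
#' in the cluster search. Raising the threshold can only remove positives.
#'
#' @param sg a `score_grid`.
#' @param threshold binarization threshold in `[0, 1]`; defaults to the
#'   threshold stored on the grid.
#' @return Logical matrix of positive calls.
#' @export
binarize <- function(sg, threshold = NULL) {
  stopifnot(inherits(sg, "score_grid"))
  threshold <- threshold %||% sg$threshold
  check_probability(threshold, "threshold")
  pos <- !is.na(sg$scores) & sg$scores >= threshold
  pos
}

#' Find topologically connected clusters of positive patches
#'
#' Maximal connected components of the positive cells of a binary lattice,
#' under 4-connectivity (edge-sharing neighbours; the default, and the
#' stricter choice — a 2 x 2 block of patches is 4-connected) or
#' 8-connectivity (corners too). Every positive cell belongs to exactly one
#' cluster.
#'
#' @param lattice logical (or 0/1) matrix; `NA` is treated as negative.
#' @param connectivity 4 or 8.
#' @return List of clusters, each a `patch_cluster` with `members` (a
#'   data.frame of 1-based `row`, `col`) and `size`, sorted by decreasing
#'   size.
#' @export
find_clusters <- function(lattice, connectivity = 4) {
  connectivity <- check_connectivity(connectivity)
  if (!is.matrix(lattice)) stop("lattice must be a matrix")
  pos <- if (is.logical(lattice)) lattice else lattice > 0
  pos[is.na(pos)] <- FALSE
  nr <- nrow(pos); nc <- ncol(pos)
  idx <- which(pos)
  if (length(idx) == 0L) return(list())
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  ea <- integer(0); eb <- integer(0)
  link <- function(from, offset) {
    to <- from + offset
    keep <- pos[to]
    ea <<- c(ea, from[keep]); eb <<- c(eb, to[keep])
    invisible(NULL)
  }
  link(idx[row < nr], 1L)        # down
  link(idx[col < nc], nr)        # right
  if (connectivity == 8L) {
    link(idx[row < nr & col < nc], nr + 1L)  # down-right
    link(idx[row > 1L & col < nc], nr - 1L)  # up-right
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ea), to = as.character(eb)),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  membership <- igraph::components(g)$membership
  groups <- split(as.integer(names(membership)), membership)
  clusters <- lapply(groups, function(ix) {
    ix <- sort(ix)
    structure(list(members = data.frame(row = (ix - 1L) %% nr + 1L,
                                        col = (ix - 1L) %/% nr + 1L),
                   size = length(ix)),
              class = "patch_cluster")
  })
  sizes <- vapply(clusters, function(cl) cl$size, integer(1))
  unname(clusters[order(sizes, decreasing = TRUE)])
}

#' @export
print.patch_cluster <- function(x, ...) {
  cat(sprintf("<patch_cluster> size %d at rows %d..%d, cols %d..%d\n",
              x$size, min(x$members$row), max(x$members$row),
              min(x$members$col), max(x$members$col)))
  invisible(x)
}

# component sizes only; hot path for the simulator
component_sizes <- function(lattice, connectivity = 4) {
  vapply(find_clusters(lattice, connectivity), function(cl) cl$size,
         integer(1))
}

#' Diagnose a slide by the positive-patch cluster rule
#'
#' The slide is called positive (`call = 1`) iff some maximal connected
#' component of positive patches reaches `cluster_size` patches. Requiring
#' a cluster rather than any single positive patch controls the false
#' positive rate accumulated over thousands of per-patch predictions, since
#' classifier errors scatter while tumour patches sit together. The default
#' `cluster_size = 4` balances sensitivity against the false positive rate;
#' `cluster_size = 2` trades specificity for screening-level sensitivity.
#'
#' @param sg a `score_grid`.
#' @param threshold binarization threshold (default: the grid's).
#' @param cluster_size minimum qualifying component size, >= 1.
#' @param connectivity 4 or 8 (see [find_clusters()]).
#' @return A `slide_diagnosis`: `slide_id`, `call` (1/0), `clusters` (the
#'   qualifying components), `cluster_size`, `connectivity`, `threshold`,
#'   `n_clusters`, `max_cluster_size` (over all components).
#' @export
diagnose_slide <- function(sg, threshold = NULL, cluster_size = 4,
                           connectivity = 4) {
  stopifnot(inherits(sg, "score_grid"),
            cluster_size >= 1, cluster_size == floor(cluster_size))
  threshold <- threshold %||% sg$threshold
  if (all(is.na(sg$scores))) {
    warning("score grid has no tissue patches; slide called negative")
    return(structure(list(slide_id = sg$slide_id, call = 0L,
                          clusters = list(),
                          cluster_size = as.integer(cluster_size),
                          connectivity = check_connectivity(connectivity),
                          threshold = threshold, n_clusters = 0L,
                          max_cluster_size = 0L),
                     class = "slide_diagnosis"))
  }
  all_clusters <- find_clusters(binarize(sg, threshold), connectivity)
  sizes <- vapply(all_clusters, function(cl) cl$size, integer(1))
  qualifying <- all_clusters[sizes >= cluster_size]
  structure(list(slide_id = sg$slide_id,
                 call = as.integer(length(qualifying) > 0L),
                 clusters = qualifying,
                 cluster_size = as.integer(cluster_size),
                 connectivity = check_connectivity(connectivity),
                 threshold = threshold,
                 n_clusters = length(qualifying),
                 max_cluster_size = if (length(sizes)) max(sizes) else 0L),
            class = "slide_diagnosis")
}

#' @export
print.slide_diagnosis <- function(x, ...) {
  cat(sprintf(
    "<slide_diagnosis> %s: call %d (k = %d, %d qualifying clusters, max size %d)\n",
    x$slide_id, x$call, x$cluster_size, x$n_clusters, x$max_cluster_size))
  invisible(x)
}

#' Diagnose a patient from slide calls (union rule)
#'
#' A patient with slides `S = {s_1, ..., s_l}` is diagnosed
#' `D(S) = D(s_1) | D(s_2) | ... | D(s_l)`: cancer as soon as any slide is
#' positive. Order-invariant.
#'
#' @param slide_calls nonempty list of `slide_diagnosis` objects, or a
#'   vector of 0/1 calls.
#' @param patient_id identifier.
#' @return A `patient_diagnosis` with `patient_id`, `slide_ids`,
#'   `slide_calls`, `call`.
#' @export
diagnose_patient <- function(slide_calls, patient_id = "patient") {
  if (length(slide_calls) == 0L)
    stop("a patient must have at least one slide")
  if (inherits(slide_calls, "slide_diagnosis"))
    slide_calls <- list(slide_calls)
  if (is.list(slide_calls)) {
    stopifnot(all(vapply(slide_calls, inherits, TRUE, "slide_diagnosis")))
    ids <- vapply(slide_calls, function(d) d$slide_id, character(1))
    calls <- vapply(slide_calls, function(d) d$call, integer(1))
  } else {
    calls <- as.integer(slide_calls)
    ids <- paste0("slide", seq_along(calls))
  }
  if (!all(calls %in% c(0L, 1L))) stop("slide calls must be 0 or 1")
  structure(list(patient_id = patient_id, slide_ids = ids,
                 slide_calls = calls, call = max(calls)),
            class = "patient_diagnosis")
}

#' @export
print.patient_diagnosis <- function(x, ...) {
  cat(sprintf("<patient_diagnosis> %s: call %d from %d slide(s)\n",
              x$patient_id, x$call, length(x$slide_calls)))
  invisible(x)
}

#' Write slide diagnoses as TSV
#'
#' Columns `slide_id, call, n_clusters, max_cluster_size`.
#'
#' @param diagnoses list of `slide_diagnosis` objects.
#' @param path output TSV path.
#' @export
write_slide_calls <- function(diagnoses, path) {
  df <- data.frame(
    slide_id = vapply(diagnoses, function(d) d$slide_id, character(1)),
    call = vapply(diagnoses, function(d) d$call, integer(1)),
    n_clusters = vapply(diagnoses, function(d) d$n_clusters, integer(1)),
    max_cluster_size = vapply(diagnoses, function(d) d$max_cluster_size,
                              integer(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write patient diagnoses as TSV
#'
#' Columns `patient_id, call, n_slides`.
#'
#' @param patients list of `patient_diagnosis` objects.
#' @param path output TSV path.
#' @export
write_patient_calls <- function(patients, path) {
  df <- data.frame(
    patient_id = vapply(patients, function(p) p$patient_id, character(1)),
    call = vapply(patients, function(p) p$call, integer(1)),
    n_slides = vapply(patients, function(p) length(p$slide_calls),
                      integer(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
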