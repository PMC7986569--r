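# fixture builders and independent oracles used across test files

# uniform-colour 8-bit patch
uniform_patch <- function(side, rgb) {
  arr <- array(0L, c(side, side, 3L))
  for (ch in 1:3) arr[, , ch] <- as.integer(rgb[ch])
  arr
}

# pixel-checkerboard of two colours (H&E-like when given stain colours)
checker_patch <- function(side, rgb_a, rgb_b) {
  parity <- outer(seq_len(side), seq_len(side), function(i, j) (i + j) %% 2L)
  arr <- array(0L, c(side, side, 3L))
  for (ch in 1:3)
    arr[, , ch] <- ifelse(parity == 0L, as.integer(rgb_a[ch]),
                          as.integer(rgb_b[ch]))
  arr
}

he_colors <- list(a = c(180, 80, 160), b = c(90, 40, 120))

stained_patch <- function(side) checker_patch(side, he_colors$a, he_colors$b)

# independent connected-components oracle: iterative flood fill
flood_fill_labels <- function(lat, connectivity = 4) {
  lat[is.na(lat)] <- FALSE
  nr <- nrow(lat); nc <- ncol(lat)
  offsets <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8)
    offsets <- c(offsets, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L),
                               c(1L, 1L)))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!lat[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0L) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offsets) {
        r <- cell[1L] + o[1L]; c2 <- cell[2L] + o[2L]
        if (r >= 1L && r <= nr && c2 >= 1L && c2 <= nc &&
            lat[r, c2] && lab[r, c2] == 0L) {
          lab[r, c2] <- cur
          stack[[length(stack) + 1L]] <- c(r, c2)
        }
      }
    }
  }
  lab
}

# canonical representation of a component partition: sorted list of sorted
# linear-index vectors
component_sets_from_labels <- function(lab) {
  idx <- which(lab > 0L)
  sets <- unname(split(idx, lab[idx]))
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, 0L, 1L))]
}

component_sets_from_clusters <- function(clusters, nr) {
  sets <- lapply(clusters, function(cl)
    sort((cl$members$col - 1L) * nr + cl$members$row))
  sets[order(vapply(sets, `[`, 0L, 1L))]
}

expect_same_components <- function(lattice, connectivity) {
  got <- component_sets_from_clusters(
    find_clusters(lattice, connectivity), nrow(lattice))
  want <- component_sets_from_labels(
    flood_fill_labels(lattice, connectivity))
  expect_identical(got, want)
}

# pairwise Mann-Whitney AUC oracle: P(pos > neg) + 0.5 P(tie)
mann_whitney_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# exact two-sided signed-rank p by enumeration of all sign patterns
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# all 512 3x3 binary lattices
all_3x3_lattices <- function() {
  lapply(0:511, function(code) {
    bits <- as.integer(intToBits(code)[1:9])
    matrix(bits == 1L, 3L, 3L)
  })
}
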