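# Independent oracles used across the suite. Each is a deliberately naive,
# separate implementation of the operation it checks.

# Globally optimal K-means inertia by exhaustive enumeration of assignments.
# The first point is fixed to cluster 1 (label symmetry); assignments with
# empty clusters are dominated by the optimum and need no special handling.
brute_force_kmeans_inertia <- function(X, K) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  n <- nrow(X)
  if (K == 1) {
    return(sum(sweep(X, 2, colMeans(X))^2))
  }
  m <- K^(n - 1)
  codes <- 0:(m - 1)
  A <- matrix(1L, nrow = m, ncol = n)
  for (j in 2:n) {
    A[, j] <- (codes %/% K^(j - 2)) %% K + 1L
  }
  sq <- rowSums(X^2)
  total <- rep(0, m)
  for (k in 1:K) {
    M <- A == k
    nk <- rowSums(M)
    ss <- as.vector(M %*% sq)
    cent_sq <- rep(0, m)
    for (d in seq_len(ncol(X))) {
      s <- as.vector(M %*% X[, d])
      cent_sq <- cent_sq + ifelse(nk > 0, s^2 / nk, 0)
    }
    total <- total + ss - cent_sq
  }
  min(total)
}

# Direct double-loop computation of the within-cluster sum of squares.
naive_inertia <- function(X, centroids, assignments) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(centroids)) centroids <- matrix(centroids, ncol = 1)
  total <- 0
  for (i in seq_len(nrow(X))) {
    for (d in seq_len(ncol(X))) {
      total <- total + (X[i, d] - centroids[assignments[i], d])^2
    }
  }
  total
}

# Connected-component labelling by scalar BFS flood fill.
bfs_label_components <- function(binary, connectivity = 8) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    moves <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  current <- 0L
  for (start in which(binary)) {
    if (lab[start] > 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0) {
      px <- queue[1]; queue <- queue[-1]
      r <- (px - 1L) %% h + 1L
      cc <- (px - 1L) %/% h + 1L
      for (mi in seq_len(nrow(moves))) {
        r2 <- r + moves[mi, 1]; c2 <- cc + moves[mi, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          nb <- (c2 - 1L) * h + r2
          if (binary[nb] && lab[nb] == 0L) {
            lab[nb] <- current
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

# Area filter on top of the BFS labelling (independent of the package path).
bfs_remove_small <- function(binary, min_area_fraction, connectivity = 8) {
  threshold <- ceiling(min_area_fraction * length(binary))
  lab <- bfs_label_components(binary, connectivity)
  out <- binary
  if (max(lab) == 0) return(out)
  areas <- tabulate(lab[lab > 0])
  for (k in seq_along(areas)) {
    if (areas[k] < threshold) out[lab == k] <- FALSE
  }
  out
}

bfs_fill_holes <- function(binary, min_area_fraction, connectivity = 8) {
  threshold <- ceiling(min_area_fraction * length(binary))
  lab <- bfs_label_components(!binary, connectivity)
  out <- binary
  if (max(lab) == 0) return(out)
  h <- nrow(binary); w <- ncol(binary)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  areas <- tabulate(lab[lab > 0])
  for (k in seq_along(areas)) {
    if (areas[k] < threshold && !(k %in% border)) out[lab == k] <- TRUE
  }
  out
}

# Direct CIE sRGB (D65) -> XYZ -> L*a*b*, written from the standard formulas.
reference_rgb_to_lab <- function(r, g, b) {
  lin <- function(u) ifelse(u <= 0.04045, u / 12.92,
                            ((u + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3, byrow = TRUE)
  xyz <- M %*% c(lin(r), lin(g), lin(b))
  white <- c(0.95047, 1.0, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / white[1]); fy <- f(xyz[2] / white[2])
  fz <- f(xyz[3] / white[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Small helpers ---------------------------------------------------------------

random_binary_raster <- function(h, w, p = 0.5) {
  matrix(runif(h * w) < p, h, w)
}

random_confusion <- function(max_count = 200) {
  as_confusion(matrix(sample.int(max_count, 25, replace = TRUE), 5, 5))
}

# A small, fast scene spec for module-level tests: the default 256 px world
# shrunk uniformly to half scale, preserving class area fractions (the
# full-size default set is exercised in the acceptance suite).
small_scene_spec <- function(seed = 0, ...) {
  defaults <- list(height = 128, width = 128,
                   n_bunches = 3, bunch_radius = c(5, 9),
                   n_leaves = 45, leaf_radius = c(3, 7),
                   n_branches = 7, branch_width = c(1, 2),
                   stem_width = c(4, 6), seed = seed)
  do.call(scene_spec, utils::modifyList(defaults, list(...)))
}
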