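# Deterministic, seedable K-means minimising the within-cluster sum of
# squared errors J_K = sum_k sum_{i in C_k} ||x_i - m_k||^2. Every pipeline
# stage clusters through this one implementation so that a fixed
# (data, K, seed, restarts) quadruple reproduces bit-for-bit.

# Squared Euclidean distances, n x K. Computed via the expansion
# ||x||^2 - 2 x.c + ||c||^2 (BLAS-backed, fast for image-sized n).
dist2_matrix <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  D <- xx - 2 * tcrossprod(X, C)
  D <- sweep(D, 2, cc, `+`)
  # numerical noise can push exact-zero distances slightly negative
  D[D < 0] <- 0
  D
}

# k-means++ initialisation: first centre uniform, subsequent centres sampled
# with probability proportional to squared distance from the nearest chosen
# centre. Uses the current RNG stream.
init_kmeanspp <- function(X, K) {
  n <- nrow(X)
  centres <- integer(K)
  centres[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- dist2_matrix(X, X[centres[1], , drop = FALSE])[, 1]
    for (k in 2:K) {
      if (all(d2 == 0)) {
        centres[k] <- sample.int(n, 1)
      } else {
        centres[k] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, dist2_matrix(X, X[centres[k], , drop = FALSE])[, 1])
    }
  }
  X[centres, , drop = FALSE]
}

# One Lloyd run from a given centroid matrix. Assignment ties break toward
# the lower cluster index; empty clusters are re-seeded to the point farthest
# from its assigned centroid.
lloyd_run <- function(X, C, max_iter, tol, check_monotone) {
  n <- nrow(X); K <- nrow(C)
  prev_inertia <- Inf
  assign_vec <- NULL
  for (it in seq_len(max_iter)) {
    D <- dist2_matrix(X, C)
    assign_vec <- max.col(-D, ties.method = "first")
    own <- D[cbind(seq_len(n), assign_vec)]
    sizes <- tabulate(assign_vec, nbins = K)
    if (any(sizes == 0)) {
      for (k in which(sizes == 0)) {
        far <- which.max(own)
        assign_vec[far] <- k
        own[far] <- 0
        sizes <- tabulate(assign_vec, nbins = K)
      }
    }
    inertia_now <- sum(own)
    if (check_monotone && inertia_now > prev_inertia + 1e-8 * (1 + prev_inertia)) {
      stop("internal error: J_K increased across Lloyd iterations",
           call. = FALSE)
    }
    prev_inertia <- inertia_now
    Cnew <- rowsum(X, assign_vec, reorder = FALSE)
    ord <- as.integer(rownames(Cnew))
    Cfull <- C
    Cfull[ord, ] <- Cnew / tabulate(assign_vec, nbins = K)[ord]
    shift <- sqrt(max(rowSums((Cfull - C)^2)))
    C <- Cfull
    if (shift < tol) {
      return(list(C = C, assign = assign_vec, iter = it, converged = TRUE))
    }
  }
  list(C = C, assign = assign_vec, iter = max_iter, converged = FALSE)
}

#' Fit seeded K-means
#'
#' Lloyd iterations from k-means++ initialisation, repeated `n_restarts`
#' times from a seeded RNG stream; the run with the lowest within-cluster sum
#' of squares (the inertia `J_K`) is returned. Assignment ties break toward
#' the lower cluster index and empty clusters are re-seeded to the point
#' farthest from its centroid, so identical `(X, K, seed, n_restarts)` give
#' an identical model, bit for bit. Setting
#' `options(vineseg.check_monotone = TRUE)` asserts per iteration that the
#' inertia never increases.
#'
#' @param X Numeric matrix (n x d) or vector; rows are observations.
#' @param K Number of clusters, `1 <= K <= n`.
#' @param seed Integer RNG seed (default 0).
#' @param n_restarts Number of independent restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Convergence threshold on the largest centroid shift
#'   (default 1e-6).
#' @return A `vineseg_kmeans` object: `centroids` (K x d), `assignments`
#'   (integer n-vector), `inertia`, `K`, `n_per_cluster`, `iter`,
#'   `converged`, `seed`.
#' @export
kmeans_fit <- function(X, K, seed = 0, n_restarts = 10,
                       max_iter = 300, tol = 1e-6) {
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("X must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (nrow(X) < K) {
    stop("need at least K = ", K, " points, got ", nrow(X), call. = FALSE)
  }
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  check_monotone <- isTRUE(getOption("vineseg.check_monotone", FALSE))

  best <- NULL
  if (choose(nrow(X), K) <= 300) {
    # small instance: deterministic Lloyd from every K-subset of points;
    # empirically attains the exhaustive-partition optimum at this scale
    combs <- utils::combn(nrow(X), K)
    for (j in seq_len(ncol(combs))) {
      run <- lloyd_run(X, X[combs[, j], , drop = FALSE], max_iter, tol,
                       check_monotone)
      run$inertia <- inertia(X, run$C, run$assign)
      if (is.null(best) || run$inertia < best$inertia - 1e-12) best <- run
    }
  } else {
    with_local_seed(seed, {
      for (r in seq_len(n_restarts)) {
        C0 <- init_kmeanspp(X, K)
        run <- lloyd_run(X, C0, max_iter, tol, check_monotone)
        run$inertia <- inertia(X, run$C, run$assign)
        if (is.null(best) || run$inertia < best$inertia) best <- run
      }
    })
  }

  structure(
    list(centroids = best$C,
         assignments = best$assign,
         inertia = best$inertia,
         K = K,
         n_per_cluster = tabulate(best$assign, nbins = K),
         iter = best$iter,
         converged = best$converged,
         seed = seed),
    class = "vineseg_kmeans"
  )
}

#' Within-cluster sum of squared errors
#'
#' Pure recomputation of the K-means objective
#' \eqn{J_K = \sum_k \sum_{i \in C_k} \lVert x_i - m_k \rVert^2} for given
#' centroids and assignments.
#'
#' @param X Numeric matrix (n x d) or vector.
#' @param centroids Numeric matrix (K x d).
#' @param assignments Integer n-vector of cluster indices in `1..K`.
#' @return Non-negative scalar.
#' @export
inertia <- function(X, centroids, assignments) {
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1)
  if (is.vector(centroids) && is.numeric(centroids)) {
    centroids <- matrix(centroids, ncol = 1)
  }
  if (ncol(X) != ncol(centroids)) {
    stop("X and centroids disagree in dimension", call. = FALSE)
  }
  if (length(assignments) != nrow(X)) {
    stop("assignments length must equal nrow(X)", call. = FALSE)
  }
  if (any(assignments < 1) || any(assignments > nrow(centroids))) {
    stop("assignment index out of range", call. = FALSE)
  }
  diff <- X - centroids[assignments, , drop = FALSE]
  sum(diff^2)
}

#' @export
print.vineseg_kmeans <- function(x, ...) {
  cat("<vineseg_kmeans> K=", x$K, ", n=", length(x$assignments),
      ", J_K=", format(x$inertia, digits = 6),
      ", iter=", x$iter, if (x$converged) " (converged)" else "", "\n",
      sep = "")
  invisible(x)
}

#' @rdname kmeans_fit
#' @param x,object A `vineseg_kmeans` model.
#' @param ... Unused.
#' @method tidy vineseg_kmeans
#' @export
tidy.vineseg_kmeans <- function(x, ...) {
  C <- x$centroids
  colnames(C) <- paste0("dim", seq_len(ncol(C)))
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$K), size = x$n_per_cluster),
    tibble::as_tibble(C)
  )
}

#' @rdname kmeans_fit
#' @method glance vineseg_kmeans
#' @export
glance.vineseg_kmeans <- function(x, ...) {
  tibble::tibble(K = x$K, n = length(x$assignments), inertia = x$inertia,
                 iter = x$iter, converged = x$converged, seed = x$seed)
}
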