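test_that("kmeans_fit recovers exact solutions on hand-checkable instances", {
  # one point per cluster: perfect fit
  m <- kmeans_fit(c(0, 10), 2)
  expect_equal(sort(m$centroids[, 1]), c(0, 10))
  expect_equal(m$inertia, 0)

  # K = 1: centroid is the mean, J = (0-2)^2 + (2-2)^2 + (4-2)^2 = 8
  m1 <- kmeans_fit(c(0, 2, 4), 1)
  expect_equal(m1$centroids[1, 1], 2)
  expect_equal(m1$inertia, 8)

  # two tight groups: global optimum {0,1,2} | {10,11,12}, J = 2 + 2
  m2 <- kmeans_fit(c(0, 1, 2, 10, 11, 12), 2)
  expect_equal(sort(m2$centroids[, 1]), c(1, 11))
  expect_equal(m2$inertia, 4)
  expect_equal(m2$inertia, brute_force_kmeans_inertia(c(0, 1, 2, 10, 11, 12), 2))
  expect_equal(sort(m2$n_per_cluster), c(3, 3))
})

test_that("kmeans_fit rejects invalid input", {
  expect_error(kmeans_fit(c(1, 2), 3), "at least K")
  expect_error(kmeans_fit(c(1, 2), 0), "K must be")
  expect_error(kmeans_fit(c(1, NA), 2), "non-finite")
  expect_error(kmeans_fit(c(1, Inf), 2), "non-finite")
})

test_that("inertia matches a brute-force double loop and flags bad indices", {
  expect_equal(inertia(matrix(c(1, 2), 2), matrix(c(1, 2), 2), c(1, 2)), 0)
  expect_equal(inertia(5, matrix(2), 1), 9)
  withr::with_seed(42, {
    X <- matrix(rnorm(40), ncol = 2)
    C <- matrix(rnorm(6), ncol = 2)
    a <- sample.int(3, 20, replace = TRUE)
    expect_equal(inertia(X, C, a), naive_inertia(X, C, a))
  })
  expect_error(inertia(matrix(1), matrix(1), 2), "out of range")
})

test_that("small instances attain the exhaustive-enumeration optimum", {
  withr::with_seed(7, {
    for (case in 1:25) {
      K <- sample(1:3, 1)
      d <- sample(1:2, 1)
      n <- sample(max(K, 4):9, 1)
      X <- matrix(rnorm(n * d), ncol = d)
      fit <- kmeans_fit(X, K, seed = case)
      expect_equal(fit$inertia, brute_force_kmeans_inertia(X, K),
                   tolerance = 1e-8)
    }
  })
})

test_that("inertia never increases across Lloyd iterations", {
  withr::with_options(list(vineseg.check_monotone = TRUE), {
    withr::with_seed(11, {
      for (case in 1:10) {
        X <- matrix(rnorm(60 * 2), ncol = 2)
        expect_no_error(kmeans_fit(X, 4, seed = case, n_restarts = 3))
      }
    })
  })
})

test_that("identical inputs reproduce the model bit for bit", {
  X <- matrix(withr::with_seed(1, rnorm(100)), ncol = 2)
  a <- kmeans_fit(X, 3, seed = 5, n_restarts = 4)
  b <- kmeans_fit(X, 3, seed = 5, n_restarts = 4)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$inertia, b$inertia)
  # and a different seed may start differently but the RNG stream is isolated
  expect_identical(kmeans_fit(X, 3, seed = 5)$inertia,
                   kmeans_fit(X, 3, seed = 5)$inertia)
})

test_that("permuting rows permutes assignments and preserves the optimum", {
  # well-separated data so every restart reaches the global optimum
  X <- matrix(withr::with_seed(2, c(rnorm(20, 0, .1), rnorm(20, 5, .1),
                                    rnorm(20, 10, .1))), ncol = 1)
  perm <- withr::with_seed(3, sample(nrow(X)))
  a <- kmeans_fit(X, 3, seed = 0)
  b <- kmeans_fit(X[perm, , drop = FALSE], 3, seed = 0)
  expect_equal(a$inertia, b$inertia, tolerance = 1e-12)
  # cluster labels may swap; the induced partitions must match
  relabel <- function(z) match(z, unique(z))
  expect_identical(relabel(b$assignments), relabel(a$assignments[perm]))
})

test_that("assignment ties break toward the lower cluster index", {
  # from centroids {0, 2} the point at 1 is exactly equidistant; the
  # contract sends it to cluster 1
  run <- vineseg:::lloyd_run(matrix(c(0, 1, 2), ncol = 1),
                             matrix(c(0, 2), ncol = 1),
                             max_iter = 1, tol = 1e-6,
                             check_monotone = FALSE)
  expect_identical(run$assign, c(1L, 1L, 2L))
})

test_that("empty clusters are re-seeded to the farthest point", {
  # both initial centroids sit on the left group; the right outlier must
  # be claimed by the starved cluster
  X <- matrix(c(0, 0.1, 0.2, 50), ncol = 1)
  run <- vineseg:::lloyd_run(X, matrix(c(0, 100), ncol = 1),
                             max_iter = 50, tol = 1e-9,
                             check_monotone = FALSE)
  expect_setequal(run$assign, c(1L, 2L))
  fit_inertia <- inertia(X, run$C, run$assign)
  expect_equal(fit_inertia, brute_force_kmeans_inertia(X, 2),
               tolerance = 1e-9)
})

test_that("stats::kmeans agrees on a well-separated instance", {
  X <- matrix(withr::with_seed(4, c(rnorm(30, 0, .2), rnorm(30, 8, .2))),
              ncol = 2)
  ours <- kmeans_fit(X, 2, seed = 0)
  ref <- stats::kmeans(X, 2, nstart = 10)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
})

test_that("tidy and glance expose the fitted model as tibbles", {
  m <- kmeans_fit(matrix(withr::with_seed(5, rnorm(40)), ncol = 2), 2)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("cluster", "size", "dim1", "dim2"))
  expect_equal(sum(td$size), 20)
  gl <- glance(m)
  expect_equal(gl$inertia, m$inertia)
  expect_true(gl$converged)
})
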