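make_clouds <- function(n_per = 20, centers = list(c(0, 0), c(20, 20)), sd = 0.1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(centers, function(mu) {
    cbind(rnorm(n_per, mu[1], sd), rnorm(n_per, mu[2], sd))
  }))
}

test_that("partition_entropy matches closed forms and the element-wise oracle", {
  crisp <- diag(3)[c(1, 2, 3, 1, 2), ]
  expect_equal(partition_entropy(crisp), 0)
  expect_equal(partition_entropy(matrix(0.25, 5, 4)), log(4))
  U <- random_U(17, 5, seed = 3)
  expect_equal(partition_entropy(U), oracle_partition_entropy(U), tolerance = 1e-12)
  expect_error(partition_entropy(matrix(0.4, 3, 2)), "invalid partition")
})

test_that("fcm_fit separates two tight far-apart clouds with near-crisp memberships", {
  X <- make_clouds()
  fit <- fcm_fit(X, fcm_config(c = 2, seed = 7))
  expect_true(fit$converged)
  own <- apply(fit$U, 1, max)
  expect_true(all(own >= 0.99))
  # memberships agree with an independent distance-ratio evaluation at
  # the fitted centers (the defining update rule, recomputed from scratch)
  d2 <- as.matrix(stats::dist(rbind(fit$V, X)))[-(1:2), 1:2]^2
  U_ref <- 1 / (1 + cbind(d2[, 1] / d2[, 2], d2[, 2] / d2[, 1]))
  expect_equal(fit$U, U_ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("fcm_fit memberships are row-stochastic and the objective never increases", {
  set.seed(9)
  X <- matrix(rnorm(60 * 3), ncol = 3)
  fit <- fcm_fit(X, fcm_config(c = 4, seed = 2))
  expect_true(all(abs(rowSums(fit$U) - 1) < 1e-9))
  expect_true(all(fit$U >= 0 & fit$U <= 1))
  expect_true(all(diff(fit$objective) <= 1e-9))
})

test_that("a point coinciding with a center gets crisp membership", {
  # two exact duplicates force a center onto the duplicated point
  X <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10.5, 10), c(10, 10.5))
  fit <- fcm_fit(X, fcm_config(c = 2, seed = 4, max_iter = 200))
  d2 <- as.matrix(stats::dist(rbind(fit$V, X)))[-(1:2), 1:2]^2
  if (any(d2 == 0)) {
    hit <- which(d2 == 0, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      expect_equal(fit$U[hit[r, 1], hit[r, 2]], 1)
    }
  }
  # the degenerate rule directly: a zero distance yields membership 1 there
  U <- fwrnet:::memberships_from_dist(rbind(c(0, 4), c(1, 1), c(0, 0)), alpha = 2)
  expect_equal(U[1, ], c(1, 0))
  expect_equal(U[3, ], c(0.5, 0.5))  # ties split equally
  expect_true(all(abs(rowSums(U) - 1) < 1e-12))
})

test_that("fcm_fit is bit-deterministic given the seed", {
  X <- make_clouds(seed = 5)
  f1 <- fcm_fit(X, fcm_config(c = 3, seed = 11))
  f2 <- fcm_fit(X, fcm_config(c = 3, seed = 11))
  expect_identical(f1$U, f2$U)
  expect_identical(f1$V, f2$V)
  expect_identical(f1$H, f2$H)
})

test_that("fcm_fit rejects degenerate inputs", {
  expect_error(fcm_fit(matrix(1:6, 3, 2), fcm_config(c = 3)), "insufficient data")
  X <- matrix(rnorm(20), 10, 2)
  X[3, 1] <- NaN
  expect_error(fcm_fit(X, fcm_config(c = 2)), "invalid input")
})

test_that("nearly crisp alpha reproduces nearest-center assignment", {
  X <- make_clouds(centers = list(c(0, 0), c(15, 0), c(0, 15)), seed = 6)
  fit <- fcm_fit(X, fcm_config(c = 3, alpha = 1.01, seed = 8))
  hard <- apply(fit$U, 1, which.max)
  d <- as.matrix(stats::dist(rbind(fit$V, X)))[-(1:3), 1:3]
  nearest <- apply(d, 1, which.min)
  expect_identical(unname(hard), unname(nearest))
})

test_that("permuting observations permutes memberships and preserves H", {
  X <- make_clouds(seed = 12)
  fit <- fcm_fit(X, fcm_config(c = 2, seed = 3, tol = 1e-12, max_iter = 500))
  perm <- sample(nrow(X))
  # restart from the permuted data; compare converged states up to relabeling
  fitp <- fcm_fit(X[perm, ], fcm_config(c = 2, seed = 3, tol = 1e-12, max_iter = 500))
  relabel <- if (sum((fit$V[1, ] - fitp$V[1, ])^2) < sum((fit$V[1, ] - fitp$V[2, ])^2)) 1:2 else 2:1
  expect_equal(fitp$U[order(perm), relabel], fit$U, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fitp$V[relabel, ], fit$V, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fitp$H, fit$H, tolerance = 1e-6)
})

test_that("fcm_fit agrees with an established independent implementation", {
  skip_if_not_installed("e1071")
  X <- make_clouds(seed = 15)
  fit <- fcm_fit(X, fcm_config(c = 2, seed = 7, tol = 1e-10, max_iter = 300))
  cm <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 300)
  ord <- if (sum((cm$centers[1, ] - fit$V[1, ])^2) < sum((cm$centers[1, ] - fit$V[2, ])^2)) 1:2 else 2:1
  expect_equal(fit$V, unname(cm$centers[ord, , drop = FALSE]), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$U, unname(cm$membership[, ord]), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("select_cluster_count recovers three well-separated Gaussians", {
  X <- make_clouds(n_per = 30, centers = list(c(0, 0), c(8, 8), c(16, 0)), sd = 0.2, seed = 42)
  best <- select_cluster_count(X, 2, 6, fcm_config(seed = 5))
  expect_identical(as.integer(best), 3L)
  scan <- attr(best, "scan")
  expect_identical(scan$c, 2:6)
  expect_identical(scan$c[which.min(scan$H)], 3L)
  expect_true(all(scan$H >= 0))
})

test_that("select_cluster_count handles single candidates and degenerate data", {
  X <- make_clouds(n_per = 15, seed = 2)
  best <- select_cluster_count(X, 4, 4, fcm_config(seed = 1))
  expect_identical(as.integer(best), 4L)
  # one diffuse cloud: returned c must equal the argmin of the logged scan
  set.seed(3)
  Y <- matrix(rnorm(80), ncol = 2)
  b2 <- select_cluster_count(Y, 2, 4, fcm_config(seed = 9))
  scan <- attr(b2, "scan")
  expect_identical(as.integer(b2), as.integer(scan$c[which.min(scan$H)]))
})

test_that("partition CSV pair round-trips U and records metadata", {
  X <- make_clouds(seed = 20)
  fit <- fcm_fit(X, fcm_config(c = 2, seed = 6))
  stem <- tempfile()
  write_partition_csv(fit, stem)
  U_back <- as.matrix(read.csv(paste0(stem, "_U.csv")))
  expect_equal(unname(U_back), unname(fit$U), tolerance = 1e-12)
  hdr <- readLines(paste0(stem, "_V.csv"), n = 1)
  expect_match(hdr, "H=")
  expect_match(hdr, "seed=6")
  unlink(paste0(stem, c("_U.csv", "_V.csv")))
})
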