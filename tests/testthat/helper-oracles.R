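# Independent brute-force oracles used across the suite. All are written
# as literal loops over the defining formulas, deliberately sharing no
# code with the package implementation.

# Unweighted local clustering by explicit neighbor-pair counting.
oracle_unweighted_cc <- function(A) {
  n <- nrow(A)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      s <- s + A[i, j] * A[j, h] * A[h, i]
    }
    Ci[i] <- s / (k * (k - 1))
  }
  mean(Ci)
}

# Weighted (geometric-mean) local clustering, triple loop.
oracle_weighted_cc <- function(W, tau = 0) {
  n <- nrow(W)
  A <- (W > tau) * 1
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      s <- s + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    Ci[i] <- s / (k * (k - 1))
  }
  mean(Ci)
}

# All-pairs shortest paths by Floyd-Warshall on transformed lengths.
oracle_floyd_warshall <- function(W, transform = "reciprocal", tau = 0) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > tau) {
      D[i, j] <- if (transform == "reciprocal") 1 / W[i, j] else 1 - W[i, j]
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Max-min fuzzy relation, triple loop.
oracle_fuzzy_relation <- function(U) {
  L <- nrow(U)
  R <- matrix(0, L, L)
  for (a in seq_len(L)) for (b in seq_len(L)) {
    best <- 0
    for (i in seq_len(ncol(U))) best <- max(best, min(U[a, i], U[b, i]))
    R[a, b] <- best
  }
  diag(R) <- 1
  R
}

# Element-wise partition entropy.
oracle_partition_entropy <- function(U) {
  s <- 0
  for (n in seq_len(nrow(U))) for (j in seq_len(ncol(U))) {
    if (U[n, j] > 0) s <- s + U[n, j] * log(U[n, j])
  }
  -s / nrow(U)
}

# Random row-stochastic membership matrix.
random_U <- function(L, c, seed) {
  set.seed(seed)
  U <- matrix(runif(L * c), L, c)
  U / rowSums(U)
}

# Tiny flat mcimage helper.
flat_image <- function(M, N, K = 3, value = 0.5) {
  mcimage(array(value, dim = c(M, N, K)))
}
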