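#' Fuzzy c-means configuration
#'
#' Bundles the clustering parameters used throughout the pipeline. The
#' defaults (`alpha = 2`, `max_iter = 100`, `tol = 1e-5`) are the widely
#' adopted settings for fuzzy c-means; `c = 20` is the pipeline default
#' cluster count for image tiles.
#'
#' @param c Number of clusters (`>= 2`).
#' @param alpha Fuzziness (weighting) exponent, `> 1`.
#' @param max_iter Maximum number of alternating update iterations.
#' @param tol Convergence tolerance on the Frobenius norm of the change in
#'   the membership matrix between successive iterations.
#' @param seed Integer seed for the random row-stochastic initialization.
#' @return A list of class `fcm_config`.
#' @export
fcm_config <- function(c = 20L, alpha = 2, max_iter = 100L, tol = 1e-5, seed = 1L) {
  stopifnot(c >= 2L, alpha > 1, max_iter >= 1L, tol > 0)
  structure(
    list(c = as.integer(c), alpha = alpha, max_iter = as.integer(max_iter),
         tol = tol, seed = as.integer(seed)),
    class = "fcm_config"
  )
}

# Squared Euclidean distances between rows of X (L x K) and rows of V (c x K).
sq_dist <- function(X, V) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(V))) +
    outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * tcrossprod(X, V)
  d2[d2 < 0] <- 0
  d2
}

# Membership update from squared distances; alpha > 1.
# Distances are normalized by the row minimum before the -1/(alpha-1)
# power so small alpha (nearly crisp) cannot overflow; rows with a zero
# distance get crisp membership on the coincident center(s), split
# equally among ties.
memberships_from_dist <- function(d2, alpha) {
  p <- 1 / (alpha - 1)
  rmin <- do.call(pmin, as.data.frame(d2))
  inv <- (d2 / rmin)^(-p)
  U <- inv / rowSums(inv)
  zero_rows <- which(rmin == 0)
  for (n in zero_rows) {
    hit <- d2[n, ] == 0
    U[n, ] <- 0
    U[n, hit] <- 1 / sum(hit)
  }
  U
}

#' Fit fuzzy c-means to a feature set
#'
#' Alternates the center update (fuzzy-weighted means) and the membership
#' update (inverse-distance-ratio rule with exponent `2/(alpha-1)`)
#' starting from a seeded random row-stochastic membership matrix, until
#' the Frobenius norm of the membership change drops below `tol` or
#' `max_iter` is reached. Points coinciding exactly with a center receive
#' crisp membership there (split equally over ties). The fuzzy objective
#' `J = sum_nj u_nj^alpha d^2(x_n, v_j)` is recorded per iteration and is
#' non-increasing.
#'
#' @param X A `feature_set` or a numeric `L x K` matrix of observations.
#' @param cfg An [fcm_config].
#' @return An object of class `fuzzy_partition`: `U` (`L x c` memberships,
#'   rows summing to 1), `V` (`c x K` centers), `H` (partition entropy),
#'   `n_iter`, `converged`, `objective` (per-iteration trace), and `cfg`.
#' @examples
#' set.seed(7)
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 10), 20))
#' fit <- fcm_fit(X, fcm_config(c = 2, seed = 3))
#' range(rowSums(fit$U))  # both 1
#' @export
fcm_fit <- function(X, cfg = fcm_config()) {
  if (inherits(X, "feature_set")) X <- X$vectors
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stop("invalid input: non-finite features", call. = FALSE)
  L <- nrow(X)
  if (L <= cfg$c) {
    stop("insufficient data: need more observations (", L, ") than clusters (", cfg$c, ")",
         call. = FALSE)
  }
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  U0 <- matrix(stats::runif(L * cfg$c), nrow = L)
  U <- U0 / rowSums(U0)
  objective <- numeric(0)
  converged <- FALSE
  t <- 0L
  repeat {
    t <- t + 1L
    Ua <- U^cfg$alpha
    V <- (t(Ua) %*% X) / colSums(Ua)
    d2 <- sq_dist(X, V)
    U_new <- memberships_from_dist(d2, cfg$alpha)
    objective <- c(objective, sum(U_new^cfg$alpha * d2))
    delta <- sqrt(sum((U_new - U)^2))
    U <- U_new
    if (delta < cfg$tol) { converged <- TRUE; break }
    if (t >= cfg$max_iter) break
  }
  structure(
    list(U = U, V = V, H = partition_entropy(U), n_iter = t,
         converged = converged, objective = objective, cfg = cfg),
    class = "fuzzy_partition"
  )
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> L = %d, c = %d, H = %.4f, %d iteration(s)%s\n",
              nrow(x$U), ncol(x$U), x$H, x$n_iter,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}

#' Partition entropy of a fuzzy membership matrix
#'
#' Bezdek's cluster-validity measure `H = -(1/L) sum_jn u_nj ln(u_nj)`
#' (with `0 ln 0 = 0`). `H` is 0 for a crisp partition and `ln(c)` for the
#' maximally fuzzy one; smaller is better when scanning cluster counts.
#'
#' @param U Row-stochastic `L x c` membership matrix (row sums within
#'   `1e-6` of 1).
#' @return Non-negative scalar.
#' @examples
#' partition_entropy(matrix(0.25, 3, 4))  # log(4)
#' @export
partition_entropy <- function(U) {
  U <- as.matrix(U)
  if (any(abs(rowSums(U) - 1) > 1e-6) || any(U < 0)) {
    stop("invalid partition: rows of U must be non-negative and sum to 1", call. = FALSE)
  }
  terms <- U * log(U)
  terms[U == 0] <- 0
  -sum(terms) / nrow(U)
}

#' Select a cluster count by minimum partition entropy
#'
#' Fits fuzzy c-means for each candidate `c` in `[c_min, c_max]` (same
#' seed and parameters throughout) and returns the `c` with the smallest
#' partition entropy, breaking ties toward the smaller count. The full
#' `(c, H)` scan is attached as attribute `"scan"`.
#'
#' @param X A `feature_set` or numeric matrix.
#' @param c_min,c_max Candidate range, `2 <= c_min <= c_max < L`.
#' @param cfg An [fcm_config]; its `c` field is overridden by the scan.
#' @return Integer optimal cluster count with attribute `scan`
#'   (a data frame of candidates and entropies).
#' @export
select_cluster_count <- function(X, c_min, c_max, cfg = fcm_config()) {
  Xm <- if (inherits(X, "feature_set")) X$vectors else as.matrix(X)
  stopifnot(c_min >= 2L, c_max >= c_min, c_max < nrow(Xm))
  cand <- seq.int(c_min, c_max)
  H <- vapply(cand, function(cc) {
    cfg_c <- cfg; cfg_c$c <- as.integer(cc)
    fcm_fit(Xm, cfg_c)$H
  }, numeric(1))
  best <- cand[which.min(H)]  # which.min takes the first minimum: ties go small
  structure(as.integer(best), scan = data.frame(c = cand, H = H))
}

#' Write a fuzzy partition to a CSV pair
#'
#' `<stem>_U.csv` holds the membership matrix; `<stem>_V.csv` holds the
#' centers with `H`, iteration count and configuration in comment-style
#' header lines.
#'
#' @param fit A `fuzzy_partition`.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_partition_csv <- function(fit, stem) {
  stopifnot(inherits(fit, "fuzzy_partition"))
  u_path <- paste0(stem, "_U.csv")
  v_path <- paste0(stem, "_V.csv")
  utils::write.csv(as.data.frame(fit$U), u_path, row.names = FALSE)
  hdr <- sprintf("# H=%.10g n_iter=%d converged=%s c=%d alpha=%g tol=%g seed=%d",
                 fit$H, fit$n_iter, fit$converged, fit$cfg$c, fit$cfg$alpha,
                 fit$cfg$tol, fit$cfg$seed)
  con <- file(v_path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(fit$V), con, row.names = FALSE)
  invisible(c(u_path, v_path))
}
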