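#' Max-min fuzzy relation between observations
#'
#' Routes similarity between two observations through the fuzzy clusters:
#' `R[a, b] = max_i min(U[a, i], U[b, i])`, the max-min composition of the
#' membership matrix with itself. Two points are strongly related exactly
#' when some cluster claims both with high membership — the recurrence of
#' a shared local texture state. The diagonal is set to 1 (reflexivity of
#' a similarity relation); the matrix is symmetric by construction.
#'
#' @param U Row-stochastic `L x c` membership matrix, `L >= 2`.
#' @return Symmetric `L x L` matrix with unit diagonal, entries in `[0, 1]`.
#' @examples
#' U <- rbind(c(1, 0), c(1, 0), c(0, 1))  # crisp: two clusters
#' fuzzy_relation(U)                      # block structure
#' @export
fuzzy_relation <- function(U) {
  U <- as.matrix(U)
  if (nrow(U) < 2L) stop("invalid partition: need at least 2 observations", call. = FALSE)
  if (any(abs(rowSums(U) - 1) > 1e-6) || any(U < 0) || any(U > 1)) {
    stop("invalid partition: U must be row-stochastic with entries in [0,1]", call. = FALSE)
  }
  R <- Reduce(pmax, lapply(seq_len(ncol(U)), function(i) outer(U[, i], U[, i], pmin)))
  diag(R) <- 1
  R
}

#' Adjacency matrix of the fuzzy weighted recurrence network
#'
#' Removes self-similarity from the fuzzy relation: `W = R - I`, leaving
#' the off-diagonal similarities untouched and a zero diagonal.
#'
#' @param R Symmetric relation matrix with unit diagonal, entries in `[0, 1]`.
#' @param node_coords Optional `L x 2` matrix of source-pixel coordinates.
#' @param build_params Optional named list of provenance (window `m`,
#'   cluster count, seed, stride, ...).
#' @return A `weighted_network`: `W` (symmetric, zero diagonal, `[0, 1]`),
#'   `node_coords`, `build_params`.
#' @export
adjacency_from_relation <- function(R, node_coords = NULL, build_params = list()) {
  R <- as.matrix(R)
  if (any(abs(diag(R) - 1) > 1e-12)) {
    stop("invalid relation: diagonal must be 1", call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-12) stop("invalid relation: must be symmetric", call. = FALSE)
  if (any(R < 0) || any(R > 1)) stop("invalid relation: entries must lie in [0,1]", call. = FALSE)
  W <- R
  diag(W) <- 0
  structure(
    list(W = W, node_coords = node_coords, build_params = build_params),
    class = "weighted_network"
  )
}

#' Construct a weighted network directly from a weight matrix
#'
#' Convenience constructor validating the `weighted_network` invariants.
#'
#' @param W Symmetric matrix, zero diagonal, entries in `[0, 1]`.
#' @inheritParams adjacency_from_relation
#' @return A `weighted_network`.
#' @export
weighted_network <- function(W, node_coords = NULL, build_params = list()) {
  W <- as.matrix(W)
  if (any(diag(W) != 0)) stop("invalid weights: diagonal must be 0", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-12) stop("invalid weights: W must be symmetric", call. = FALSE)
  if (any(W < 0) || any(W > 1)) stop("invalid weights: entries must lie in [0,1]", call. = FALSE)
  structure(
    list(W = W, node_coords = node_coords, build_params = build_params),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, mean off-diagonal weight %.4f\n",
              nrow(x$W), mean(x$W[upper.tri(x$W)])))
  invisible(x)
}

#' Build the fuzzy weighted recurrence network of a feature set
#'
#' Composition of [fcm_fit()], [fuzzy_relation()] and
#' [adjacency_from_relation()]: partitions the feature vectors into fuzzy
#' clusters and connects every pair of observations by their strongest
#' shared cluster membership.
#'
#' @param X A `feature_set` or numeric `L x K` matrix.
#' @param cfg An [fcm_config].
#' @return A `weighted_network` whose `build_params` record the
#'   clustering configuration and the source id; the fitted
#'   `fuzzy_partition` is attached as element `partition`.
#' @export
build_network <- function(X, cfg = fcm_config()) {
  coords <- if (inherits(X, "feature_set")) X$coords else NULL
  src <- if (inherits(X, "feature_set")) X$source_id else NA_character_
  fit <- fcm_fit(X, cfg)
  net <- adjacency_from_relation(
    fuzzy_relation(fit$U),
    node_coords = coords,
    build_params = list(c = cfg$c, alpha = cfg$alpha, max_iter = cfg$max_iter,
                        tol = cfg$tol, seed = cfg$seed, source_id = src,
                        H = fit$H, n_iter = fit$n_iter)
  )
  net$partition <- fit
  net
}

#' Write a weighted network as edge list and dense matrix CSVs
#'
#' @param net A `weighted_network`.
#' @param stem Output path stem; writes `<stem>_edges.csv`,
#'   `<stem>_matrix.csv` and `<stem>_provenance.json`.
#' @return The paths, invisibly.
#' @export
write_network_csv <- function(net, stem) {
  stopifnot(inherits(net, "weighted_network"))
  W <- net$W
  ut <- which(upper.tri(W), arr.ind = TRUE)
  edges <- data.frame(node_a = ut[, 1L], node_b = ut[, 2L], weight = W[ut])
  e_path <- paste0(stem, "_edges.csv")
  m_path <- paste0(stem, "_matrix.csv")
  p_path <- paste0(stem, "_provenance.json")
  utils::write.csv(edges, e_path, row.names = FALSE)
  utils::write.csv(as.data.frame(W), m_path, row.names = FALSE)
  jsonlite::write_json(net$build_params, p_path, auto_unbox = TRUE, digits = NA)
  invisible(c(e_path, m_path, p_path))
}
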