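#' Average unweighted clustering coefficient
#'
#' Mean over nodes of the triangle density around each node,
#' `C_i = sum_jk a_ij a_jk a_ki / (k_i (k_i - 1))` with `k_i` the degree.
#' Nodes of degree 0 or 1 have no possible triangle; by default they
#' contribute `C_i = 0` to the average, or are excluded entirely with
#' `exclude_low_degree = TRUE`.
#'
#' @param A Symmetric binary adjacency matrix with zero diagonal.
#' @param exclude_low_degree Drop degree-0/1 nodes from the average
#'   instead of counting them as 0.
#' @return Scalar in `[0, 1]`.
#' @examples
#' A <- matrix(1, 3, 3) - diag(3)
#' unweighted_clustering_coefficient(A)  # 1
#' @export
unweighted_clustering_coefficient <- function(A, exclude_low_degree = FALSE) {
  A <- as.matrix(A)
  if (max(abs(A - t(A))) > 0) stop("invalid adjacency: must be symmetric", call. = FALSE)
  if (!all(A %in% c(0, 1)) || any(diag(A) != 0)) {
    stop("invalid adjacency: must be binary with zero diagonal", call. = FALSE)
  }
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)  # 2 * triangles through each node
  Ci <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  if (exclude_low_degree) {
    keep <- k > 1
    if (!any(keep)) return(0)
    mean(Ci[keep])
  } else {
    mean(Ci)
  }
}

#' Average weighted clustering coefficient (geometric-mean form)
#'
#' Fagiolo's weighted extension: each triangle through node `i`
#' contributes the geometric mean of its three edge weights,
#' `C_i^w = sum_jk (w_ij w_ik w_jk)^{1/3} / (k_i (k_i - 1))`, where the
#' degree `k_i` counts neighbors with weight above the threshold `tau`.
#' With 0/1 weights this reduces exactly to the unweighted coefficient.
#'
#' @param net A `weighted_network`, or a symmetric weight matrix with zero
#'   diagonal and entries in `[0, 1]`.
#' @param tau Edge threshold: entries `<= tau` are treated as absent
#'   (default 0, keeping every positive weight).
#' @param normalize_by_max Divide weights by `max(W)` first (Fagiolo's
#'   original normalization; off by default since recurrence weights
#'   already lie in `[0, 1]`).
#' @param exclude_low_degree Drop degree-0/1 nodes from the average.
#' @return Scalar in `[0, 1]`.
#' @examples
#' W <- matrix(0.5, 3, 3); diag(W) <- 0
#' weighted_clustering_coefficient(W)  # 0.5
#' @export
weighted_clustering_coefficient <- function(net, tau = 0, normalize_by_max = FALSE,
                                            exclude_low_degree = FALSE) {
  W <- if (inherits(net, "weighted_network")) net$W else as.matrix(net)
  if (any(W < 0)) stop("invalid weight: negative entries", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-12) stop("invalid weight: W must be symmetric", call. = FALSE)
  stopifnot(tau >= 0)
  W <- W * (W > tau)
  diag(W) <- 0
  if (normalize_by_max && max(W) > 0) W <- W / max(W)
  k <- rowSums(W > 0)
  W3 <- W^(1 / 3)
  tri <- diag(W3 %*% W3 %*% W3)
  Ci <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  if (exclude_low_degree) {
    keep <- k > 1
    if (!any(keep)) return(0)
    mean(Ci[keep])
  } else {
    mean(Ci)
  }
}

# igraph over edges with w > tau, edge lengths from the chosen transform.
as_length_graph <- function(W, transform, tau) {
  ut <- which(upper.tri(W) & W > tau, arr.ind = TRUE)
  lengths <- switch(transform,
    reciprocal = 1 / W[ut],
    complement = 1 - W[ut],
    stop("unknown length transform: ", transform, call. = FALSE)
  )
  if (length(lengths) && any(lengths <= 0)) {
    stop("invalid transform: non-positive edge length produced", call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(ut, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(W) - igraph::vcount(g)))
  igraph::E(g)$weight <- lengths
  g
}

#' All-pairs shortest weighted path lengths
#'
#' Converts similarity weights to edge lengths (`1/w` by default, or
#' `1 - w`), drops edges with weight `<= tau`, and runs Dijkstra's
#' algorithm from every source. Unreachable pairs are `Inf`; the diagonal
#' is 0.
#'
#' @inheritParams weighted_clustering_coefficient
#' @param transform `"reciprocal"` (`length = 1/w`) or `"complement"`
#'   (`length = 1 - w`; invalid when any retained weight equals 1).
#' @return Symmetric `L x L` numeric distance matrix.
#' @export
shortest_path_lengths <- function(net, transform = "reciprocal", tau = 0) {
  W <- if (inherits(net, "weighted_network")) net$W else as.matrix(net)
  if (max(abs(W - t(W))) > 1e-12) stop("invalid weight: W must be symmetric", call. = FALSE)
  g <- as_length_graph(W, transform, tau)
  D <- igraph::distances(g, algorithm = "dijkstra")
  unname(D)
}

#' Characteristic path length
#'
#' Mean shortest weighted path length over all ordered node pairs,
#' `CP = sum_{i != j} d_ij / (N (N - 1))`. Requires the thresholded
#' network to be connected.
#'
#' @inheritParams shortest_path_lengths
#' @return Scalar `CP`.
#' @export
characteristic_path_length <- function(net, transform = "reciprocal", tau = 0) {
  D <- shortest_path_lengths(net, transform = transform, tau = tau)
  if (any(is.infinite(D))) {
    W <- if (inherits(net, "weighted_network")) net$W else as.matrix(net)
    g <- as_length_graph(W, transform, tau)
    ncomp <- igraph::count_components(g)
    stop("disconnected network: ", ncomp, " components after thresholding", call. = FALSE)
  }
  n <- nrow(D)
  sum(D) / (n * (n - 1))
}

#' Summary network metrics for one network
#'
#' Computes the average weighted clustering coefficient and the
#' characteristic path length with a shared edge threshold and length
#' transform, stamping both settings into the result so metrics computed
#' under different conventions are never mixed silently.
#'
#' @inheritParams shortest_path_lengths
#' @inheritParams weighted_clustering_coefficient
#' @return A one-row data frame: `n_nodes`, `CC`, `CP`, `tau`,
#'   `transform`.
#' @export
network_metrics <- function(net, tau = 0, transform = "reciprocal",
                            normalize_by_max = FALSE, exclude_low_degree = FALSE) {
  W <- if (inherits(net, "weighted_network")) net$W else as.matrix(net)
  data.frame(
    n_nodes = nrow(W),
    CC = weighted_clustering_coefficient(W, tau = tau, normalize_by_max = normalize_by_max,
                                         exclude_low_degree = exclude_low_degree),
    CP = characteristic_path_length(W, transform = transform, tau = tau),
    tau = tau,
    transform = transform,
    stringsAsFactors = FALSE
  )
}
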