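#' Frobenius norm of a local image window
#'
#' The scalar summary of a `(2m+1) x (2m+1)` pixel window: the square root
#' of the sum of squared entries. Being a function of the entry multiset it
#' is invariant under any permutation of the window, in particular under
#' right-angle rotations and flips.
#'
#' @param window Square numeric matrix with odd side length `>= 3`.
#' @param squared If `TRUE`, return the sum of squares without the radical.
#' @return Non-negative scalar.
#' @examples
#' frobenius_norm(matrix(1, 3, 3))  # 3
#' @export
frobenius_norm <- function(window, squared = FALSE) {
  if (!is.matrix(window) || nrow(window) != ncol(window)) {
    stop("invalid window: must be a square matrix", call. = FALSE)
  }
  n <- nrow(window)
  if (n < 3L || n %% 2L == 0L) {
    stop("invalid window: side must be odd and >= 3", call. = FALSE)
  }
  if (!all(is.finite(window))) stop("invalid window: non-finite entries", call. = FALSE)
  s <- sum(window^2)
  if (squared) s else sqrt(s)
}

# Sliding-window sum of squares over one channel via a zero-padded
# summed-area table; exact up to floating point, O(MN).
window_sq_sums <- function(channel, m) {
  M <- nrow(channel)
  N <- ncol(channel)
  S <- matrix(0, M + 1L, N + 1L)
  S[-1L, -1L] <- t(apply(apply(channel^2, 2L, cumsum), 1L, cumsum))
  w <- 2L * m + 1L
  ci <- (m + 1L):(M - m)  # valid window centers (rows)
  cj <- (m + 1L):(N - m)
  # window over rows (i-m)..(i+m): S entries offset by the padding row/col
  S[ci + m + 1L, cj + m + 1L, drop = FALSE] -
    S[ci - m, cj + m + 1L, drop = FALSE] -
    S[ci + m + 1L, cj - m, drop = FALSE] +
    S[ci - m, cj - m, drop = FALSE]
}

#' Extract window-based Frobenius-norm feature vectors
#'
#' Slides a `(2m+1) x (2m+1)` window over every pixel whose window fits
#' entirely inside the image (centers needing out-of-bounds pixels are
#' skipped) and records, per retained center, the Frobenius norm of the
#' window in each channel. With stride 1 this yields
#' `L = (M - 2m)(N - 2m)` feature vectors of length `K`; `node_stride > 1`
#' keeps every `stride`-th valid center along each axis, thinning the node
#' set of the downstream network.
#'
#' @param image An [mcimage].
#' @param m Window half-width (window side `2m + 1`).
#' @param node_stride Subsampling step over valid centers (`>= 1`).
#' @param squared Use the squared norm (no radical) instead.
#' @param source_id Identifier stamped on the output (e.g. a tile id).
#' @return An object of class `feature_set`: `vectors` (`L x K` matrix),
#'   `coords` (`L x 2` 0-based center positions, row-major order),
#'   `source_id`.
#' @examples
#' img <- mcimage(array(1, dim = c(10, 12, 3)))
#' fs <- extract_features(img, m = 3)
#' nrow(fs$vectors)  # (10-6)*(12-6) = 24
#' @export
extract_features <- function(image, m = 3L, node_stride = 1L,
                             squared = FALSE, source_id = NA_character_) {
  stopifnot(inherits(image, "mcimage"), m >= 1L, node_stride >= 1L)
  m <- as.integer(m)
  node_stride <- as.integer(node_stride)
  d <- dim(image$pixels)
  M <- d[1L]; N <- d[2L]; K <- d[3L]
  w <- 2L * m + 1L
  if (M < w || N < w) {
    stop("empty feature set: image (", M, " x ", N, ") smaller than window ", w, " x ", w,
         call. = FALSE)
  }
  ri <- as.integer(seq(1L, M - 2L * m, by = node_stride))  # offsets into the valid-center grid
  rj <- as.integer(seq(1L, N - 2L * m, by = node_stride))
  L <- length(ri) * length(rj)
  vectors <- matrix(0, nrow = L, ncol = K)
  for (k in seq_len(K)) {
    sq <- window_sq_sums(image$pixels[, , k], m)
    vals <- sq[ri, rj, drop = FALSE]
    vectors[, k] <- as.vector(t(vals))  # row-major over centers
  }
  vectors[vectors < 0] <- 0  # guard tiny negative fp residue before sqrt
  if (!squared) vectors <- sqrt(vectors)
  centers_i <- rep(ri + m - 1L, each = length(rj))  # 0-based center rows
  centers_j <- rep(rj + m - 1L, times = length(ri))
  structure(
    list(
      vectors = `colnames<-`(vectors, image$channel_names),
      coords = cbind(i = centers_i, j = centers_j),
      source_id = source_id
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d vectors x %d channel(s), source: %s\n",
              nrow(x$vectors), ncol(x$vectors), x$source_id))
  invisible(x)
}

#' Write a feature set to CSV
#'
#' Columns: `tile_id`, `i`, `j`, then one `norm_<channel>` per channel.
#'
#' @param fs A `feature_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- data.frame(
    tile_id = fs$source_id,
    i = fs$coords[, "i"],
    j = fs$coords[, "j"]
  )
  norms <- as.data.frame(fs$vectors)
  names(norms) <- paste0("norm_", seq_len(ncol(norms)))
  utils::write.csv(cbind(df, norms), path, row.names = FALSE)
  invisible(path)
}
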