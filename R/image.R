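#' Multi-channel image container
#'
#' Wraps an `M x N x K` array of non-negative intensities together with
#' channel labels and the bit depth of the source file. Intensities are
#' stored on the unit scale `[0, 1]` regardless of source bit depth, so
#' downstream thresholds (e.g. background luminance) are depth-independent.
#'
#' @param pixels Numeric array `M x N x K` (a plain `M x N` matrix is
#'   promoted to `K = 1`). All entries must be finite and `>= 0`.
#' @param channel_names Character vector of length `K`; defaults to
#'   `c("R","G","B")` for `K = 3`, `"gray"` for `K = 1`, else `ch1..chK`.
#' @param bit_depth Integer bit depth of the source data (informational).
#' @return An object of class `mcimage` with elements `pixels`,
#'   `channel_names` and `bit_depth`.
#' @examples
#' img <- mcimage(array(runif(20 * 30 * 3), dim = c(20, 30, 3)))
#' dim(img$pixels)
#' @export
mcimage <- function(pixels, channel_names = NULL, bit_depth = 8L) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be an M x N x K array or an M x N matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("image intensities must be finite and non-negative", call. = FALSE)
  }
  K <- dim(pixels)[3L]
  if (is.null(channel_names)) {
    channel_names <- if (K == 3L) c("R", "G", "B") else if (K == 1L) "gray" else paste0("ch", seq_len(K))
  }
  if (length(channel_names) != K) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  structure(
    list(pixels = pixels, channel_names = channel_names, bit_depth = as.integer(bit_depth)),
    class = "mcimage"
  )
}

#' @export
print.mcimage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<mcimage> %d x %d, %d channel(s) [%s], %d-bit source\n",
    d[1L], d[2L], d[3L], paste(x$channel_names, collapse = ","), x$bit_depth
  ))
  invisible(x)
}

#' @export
dim.mcimage <- function(x) dim(x$pixels)

#' Read a PNG or TIFF tile as a multi-channel image
#'
#' Reads 8- or 16-bit grayscale/RGB rasters. An alpha channel, if present,
#' is dropped. Intensities are returned on `[0, 1]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An [mcimage].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    bits <- 8L  # png::readPNG rescales 16-bit to [0,1]; depth kept nominal
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, convert = FALSE)
    bits <- 8L
  } else {
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)", call. = FALSE)
  }
  if (length(dim(px)) == 3L && dim(px)[3L] %in% c(2L, 4L)) {
    px <- px[, , seq_len(dim(px)[3L] - 1L), drop = FALSE]  # drop alpha
  }
  mcimage(px, bit_depth = bits)
}

#' Write a multi-channel image to PNG or TIFF
#'
#' @param image An [mcimage] with intensities in `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "mcimage"))
  px <- pmin(pmax(image$pixels, 0), 1)
  if (dim(px)[3L] == 1L) px <- px[, , 1L]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, where = path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Split an image into non-overlapping square tiles
#'
#' Tiles are emitted in row-major order (left to right, then top to bottom).
#' Trailing rows/columns that do not fill a complete tile are dropped.
#' Each tile is also classified as background or tissue via
#' [is_background()] so callers can exclude empty slide regions.
#'
#' @param image An [mcimage].
#' @param tile_size Tile side length in pixels.
#' @param white_luminance_frac,max_background_frac Background-call
#'   thresholds passed to [is_background()].
#' @return A list of class `tileset` with `tiles` (list of [mcimage]),
#'   `kept_flags` (logical; `TRUE` = tissue, retained), `tile_size`, and
#'   `origins` (0-based row/col offset of each tile).
#' @examples
#' img <- mcimage(array(0.5, dim = c(300, 300, 3)))
#' length(tile_image(img, 150)$tiles)  # 4
#' @export
tile_image <- function(image, tile_size,
                       white_luminance_frac = 0.9,
                       max_background_frac = 0.5) {
  stopifnot(inherits(image, "mcimage"), tile_size >= 1)
  d <- dim(image$pixels)
  n_rows <- d[1L] %/% tile_size
  n_cols <- d[2L] %/% tile_size
  if (n_rows == 0L || n_cols == 0L) {
    warning("tile_size larger than image; returning empty tile set", call. = FALSE)
    return(structure(
      list(tiles = list(), kept_flags = logical(0), tile_size = as.integer(tile_size),
           origins = matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("row", "col")))),
      class = "tileset"
    ))
  }
  tiles <- vector("list", n_rows * n_cols)
  origins <- matrix(0L, nrow = n_rows * n_cols, ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  idx <- 0L
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      idx <- idx + 1L
      i0 <- (r - 1L) * tile_size
      j0 <- (cc - 1L) * tile_size
      tiles[[idx]] <- mcimage(
        image$pixels[(i0 + 1L):(i0 + tile_size), (j0 + 1L):(j0 + tile_size), , drop = FALSE],
        channel_names = image$channel_names, bit_depth = image$bit_depth
      )
      origins[idx, ] <- c(i0, j0)
    }
  }
  kept <- !vapply(tiles, is_background, logical(1),
                  white_luminance_frac = white_luminance_frac,
                  max_background_frac = max_background_frac)
  structure(
    list(tiles = tiles, kept_flags = kept, tile_size = as.integer(tile_size), origins = origins),
    class = "tileset"
  )
}

#' Classify a tile as slide background
#'
#' A pixel counts as background when its mean channel intensity exceeds
#' `white_luminance_frac` of full scale (1.0 on the unit intensity scale);
#' the tile is background when the fraction of such near-white pixels
#' exceeds `max_background_frac`. Both comparisons are strict.
#'
#' @param tile An [mcimage] with 1 or 3 channels.
#' @param white_luminance_frac Luminance cutoff as a fraction of full scale.
#' @param max_background_frac Maximum tolerated fraction of near-white pixels.
#' @return `TRUE` if the tile is background, else `FALSE`.
#' @export
is_background <- function(tile, white_luminance_frac = 0.9, max_background_frac = 0.5) {
  stopifnot(inherits(tile, "mcimage"))
  K <- dim(tile$pixels)[3L]
  if (!K %in% c(1L, 3L)) stop("background call expects 1 or 3 channels", call. = FALSE)
  lum <- if (K == 1L) tile$pixels[, , 1L] else (tile$pixels[, , 1L] + tile$pixels[, , 2L] + tile$pixels[, , 3L]) / 3
  mean(lum > white_luminance_frac) > max_background_frac
}
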