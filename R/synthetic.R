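#' Parameters of the synthetic two-stain texture generator
#'
#' Describes an immunohistochemistry-like tile: a brown positive stain
#' (DAB) over a blue counter-stain (hematoxylin), laid out as spatially
#' correlated blobs. The spatial field is seeded white noise smoothed with
#' a Gaussian kernel of standard deviation `blob_scale` pixels and
#' thresholded at the `1 - dab_fraction` quantile, so the realized brown
#' fraction matches `dab_fraction` up to pixel rounding and `blob_scale`
#' sets the correlation length of the stain pattern.
#'
#' @param image_size Side length of the square tile in pixels.
#' @param dab_fraction Target fraction of brown-stain pixels, in `[0, 1]`.
#' @param blob_scale Correlation length of the stain blobs in pixels (>= 1).
#' @param dab_rgb,hematoxylin_rgb Mean stain colors in unit RGB.
#' @param noise_sd Per-channel Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A list of class `stain_params`.
#' @export
stain_params <- function(image_size = 150L, dab_fraction = 0.3, blob_scale = 8,
                         dab_rgb = c(0.57, 0.39, 0.23),
                         hematoxylin_rgb = c(0.26, 0.33, 0.61),
                         noise_sd = 0.03, seed = 1L) {
  stopifnot(
    image_size >= 8L, dab_fraction >= 0, dab_fraction <= 1, blob_scale >= 1,
    length(dab_rgb) == 3L, length(hematoxylin_rgb) == 3L,
    all(dab_rgb >= 0 & dab_rgb <= 1), all(hematoxylin_rgb >= 0 & hematoxylin_rgb <= 1),
    noise_sd >= 0
  )
  structure(
    list(image_size = as.integer(image_size), dab_fraction = dab_fraction,
         blob_scale = blob_scale, dab_rgb = dab_rgb,
         hematoxylin_rgb = hematoxylin_rgb, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "stain_params"
  )
}

#' Generate a synthetic IHC-like image
#'
#' Builds the smoothed-noise stain field described by [stain_params()],
#' colors DAB pixels brown and hematoxylin pixels blue, adds seeded
#' Gaussian noise and clips to `[0, 1]`. The realized brown fraction is
#' exact up to pixel rounding (`< 1/image_size^2` plus quantile ties).
#'
#' @param params A [stain_params()] list.
#' @return An [mcimage] of size `image_size x image_size x 3` with
#'   attribute `dab_mask` (logical matrix of brown pixels).
#' @examples
#' img <- generate_ihc_image(stain_params(image_size = 32, seed = 9))
#' mean(attr(img, "dab_mask"))
#' @export
generate_ihc_image <- function(params = stain_params()) {
  stopifnot(inherits(params, "stain_params"))
  n <- params$image_size
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()), add = TRUE)
  set.seed(params$seed)
  field <- matrix(stats::rnorm(n * n), n, n)
  # cap the kernel radius so blob_scale up to ~image_size stays usable
  radius <- min(2L * ceiling(3 * params$blob_scale) + 1L, n - (1L - n %% 2L))
  if (radius %% 2L == 0L) radius <- radius - 1L
  field <- EBImage::gblur(field, sigma = params$blob_scale, radius = radius,
                          boundary = "replicate")
  if (params$dab_fraction <= 0) {
    mask <- matrix(FALSE, n, n)
  } else if (params$dab_fraction >= 1) {
    mask <- matrix(TRUE, n, n)
  } else {
    cut <- stats::quantile(field, probs = 1 - params$dab_fraction, type = 1L)
    mask <- field > cut
  }
  px <- array(0, dim = c(n, n, 3L))
  for (k in 1:3) {
    base <- ifelse(mask, params$dab_rgb[k], params$hematoxylin_rgb[k])
    px[, , k] <- pmin(pmax(base + stats::rnorm(n * n, sd = params$noise_sd), 0), 1)
  }
  img <- mcimage(px, bit_depth = 8L)
  attr(img, "dab_mask") <- mask
  img
}

#' Parameters of the synthetic cohort generator
#'
#' Describes a two-arm cohort used to test whether the imaging pipeline
#' can recover a planted association between stain-texture change and
#' survival. Each patient has a biopsy tile (fixed blob scale) and a
#' tumor tile whose blob scale is multiplied by a patient-specific
#' heterogeneity ratio; in the responder arm survival increases linearly
#' with that ratio, in the non-responder (null) arm survival is drawn
#' independently of it.
#'
#' @param n_patients Cohort size (>= 4).
#' @param responder_fraction Fraction assigned to the responder arm.
#' @param effect_size Survival months gained per unit increase of the
#'   heterogeneity ratio above 1 (responders only).
#' @param survival_noise_sd SD of the additive survival noise in months.
#' @param baseline_survival Mean survival at ratio 1, in months.
#' @param ratio_range Range the heterogeneity ratios are drawn from.
#' @param image_size Side length of each generated tile.
#' @param base_blob_scale Biopsy correlation length in pixels.
#' @param dab_fraction Brown-stain fraction for all tiles.
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 28L, responder_fraction = 0.5,
                          effect_size = 120, survival_noise_sd = 10,
                          baseline_survival = 100, ratio_range = c(0.5, 2),
                          image_size = 64L, base_blob_scale = 4,
                          dab_fraction = 0.3, seed = 1L) {
  stopifnot(n_patients >= 4L, responder_fraction >= 0, responder_fraction <= 1,
            effect_size >= 0, survival_noise_sd >= 0, baseline_survival > 0,
            length(ratio_range) == 2L, ratio_range[1] > 0,
            ratio_range[2] >= ratio_range[1])
  structure(
    list(n_patients = as.integer(n_patients), responder_fraction = responder_fraction,
         effect_size = effect_size, survival_noise_sd = survival_noise_sd,
         baseline_survival = baseline_survival, ratio_range = ratio_range,
         image_size = as.integer(image_size), base_blob_scale = base_blob_scale,
         dab_fraction = dab_fraction, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Generate a synthetic two-arm imaging cohort
#'
#' For each patient, draws a heterogeneity ratio `r` uniformly from
#' `ratio_range`, renders a biopsy tile at `base_blob_scale` and a tumor
#' tile at `base_blob_scale * r`, and assigns survival months:
#' responders get `baseline + effect_size * (r - 1) + noise`, the null
#' arm gets `baseline + noise` independent of `r`. Ground-truth ratios
#' are returned for parameter-recovery tests.
#'
#' @param params A [cohort_params()] list.
#' @return A list with `cohort` (data frame: `patient_id`, `arm`,
#'   `true_ratio`, `survival_months`) and `images` (named list per
#'   patient with `biopsy` and `tumor` [mcimage]s).
#' @export
generate_synthetic_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()), add = TRUE)
  set.seed(params$seed)
  n <- params$n_patients
  n_resp <- round(params$responder_fraction * n)
  arm <- c(rep("responder", n_resp), rep("null", n - n_resp))
  ratio <- stats::runif(n, params$ratio_range[1], params$ratio_range[2])
  noise <- stats::rnorm(n, sd = params$survival_noise_sd)
  survival <- ifelse(
    arm == "responder",
    params$baseline_survival + params$effect_size * (ratio - 1) + noise,
    params$baseline_survival + noise
  )
  survival <- pmax(survival, 1)
  image_seeds <- sample.int(.Machine$integer.max, 2L * n)
  images <- vector("list", n)
  names(images) <- paste0("P", seq_len(n))
  for (p in seq_len(n)) {
    biopsy <- generate_ihc_image(stain_params(
      image_size = params$image_size, dab_fraction = params$dab_fraction,
      blob_scale = params$base_blob_scale, seed = image_seeds[2L * p - 1L]
    ))
    tumor <- generate_ihc_image(stain_params(
      image_size = params$image_size, dab_fraction = params$dab_fraction,
      blob_scale = params$base_blob_scale * ratio[p], seed = image_seeds[2L * p]
    ))
    images[[p]] <- list(biopsy = biopsy, tumor = tumor)
  }
  list(
    cohort = data.frame(
      patient_id = names(images), arm = arm, true_ratio = ratio,
      survival_months = survival, stringsAsFactors = FALSE
    ),
    images = images
  )
}

#' Generate random weighted graph fixtures
#'
#' Seeded random symmetric weight matrices with zero diagonal and weights
#' in `[0, 1]`: each unordered pair carries an edge with probability
#' `density`, with uniform weight. Optionally a random spanning path is
#' added so the graph is guaranteed connected.
#'
#' @param n_nodes Number of nodes (<= 20 by design; these are oracle-sized).
#' @param density Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_graphs Number of fixtures to generate.
#' @param ensure_connected Add a random spanning path of positive weights.
#' @return A list of `weighted_network` objects.
#' @export
generate_fixture_graphs <- function(n_nodes = 10L, density = 0.5, seed = 1L,
                                    n_graphs = 1L, ensure_connected = FALSE) {
  stopifnot(n_nodes >= 2L, n_nodes <= 20L, density >= 0, density <= 1, n_graphs >= 1L)
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_graphs), function(g) {
    W <- matrix(0, n_nodes, n_nodes)
    ut <- upper.tri(W)
    present <- stats::runif(sum(ut)) < density
    w <- stats::runif(sum(ut))
    W[ut] <- present * w
    W <- W + t(W)
    if (ensure_connected) {
      ord <- sample.int(n_nodes)
      for (i in seq_len(n_nodes - 1L)) {
        a <- ord[i]; b <- ord[i + 1L]
        if (W[a, b] == 0) {
          wt <- stats::runif(1, 0.05, 1)
          W[a, b] <- wt; W[b, a] <- wt
        }
      }
    }
    weighted_network(W, build_params = list(seed = seed, density = density, index = g))
  })
}
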