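#' Pipeline run configuration
#'
#' One object holding every tunable of the image-to-metrics pipeline.
#' Defaults are the standard analysis settings: window half-width
#' `m = 3` (7 x 7 windows), 150 x 150 tiles, `c = 20` fuzzy clusters
#' with `alpha = 2`, at most 100 iterations and tolerance `1e-5`, node
#' stride 4, no edge threshold, reciprocal length transform, and
#' predictive ratio bands `[0.97, 1.05]` (clustering-coefficient ratio)
#' and `[0.99, 1.10]` (path-length ratio).
#'
#' @param m Window half-width.
#' @param node_stride Node subsampling stride over valid window centers.
#' @param tile_size Tile side length in pixels.
#' @param white_luminance_frac,max_background_frac Background-exclusion
#'   thresholds (see [is_background()]).
#' @param c,alpha,max_iter,tol Fuzzy c-means settings (see [fcm_config()]).
#' @param tau Edge threshold for network metrics.
#' @param transform Weight-to-length map for shortest paths.
#' @param cc_ratio_range,cp_ratio_range Predictive ratio bands.
#' @param survival_range_cc,survival_range_cp Predicted survival bands in
#'   months for the two ratio rules.
#' @param seed Integer seed used for every stochastic step.
#' @return A list of class `fwrn_config`.
#' @export
fwrn_config <- function(m = 3L, node_stride = 4L, tile_size = 150L,
                        white_luminance_frac = 0.9, max_background_frac = 0.5,
                        c = 20L, alpha = 2, max_iter = 100L, tol = 1e-5,
                        tau = 0, transform = "reciprocal",
                        cc_ratio_range = c(0.97, 1.05),
                        cp_ratio_range = c(0.99, 1.10),
                        survival_range_cc = c(101, 288),
                        survival_range_cp = c(126, 288),
                        seed = 1L) {
  cfg <- list(
    m = as.integer(m), node_stride = as.integer(node_stride),
    tile_size = as.integer(tile_size),
    white_luminance_frac = white_luminance_frac,
    max_background_frac = max_background_frac,
    c = as.integer(c), alpha = alpha, max_iter = as.integer(max_iter), tol = tol,
    tau = tau, transform = transform,
    cc_ratio_range = cc_ratio_range, cp_ratio_range = cp_ratio_range,
    survival_range_cc = survival_range_cc, survival_range_cp = survival_range_cp,
    seed = as.integer(seed)
  )
  class(cfg) <- "fwrn_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg An `fwrn_config` (or plain named list with the same fields).
#' @return `cfg`, invisibly; errors describe the offending field.
#' @export
validate_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  check(cfg$m >= 1L, "m must be >= 1")
  check(cfg$node_stride >= 1L, "node_stride must be >= 1")
  check(cfg$tile_size >= 2L * cfg$m + 1L, "tile_size must cover the window (>= 2m+1)")
  check(cfg$white_luminance_frac > 0 && cfg$white_luminance_frac <= 1,
        "white_luminance_frac must be in (0,1]")
  check(cfg$max_background_frac >= 0 && cfg$max_background_frac <= 1,
        "max_background_frac must be in [0,1]")
  check(cfg$c >= 2L, "c must be >= 2")
  check(cfg$alpha > 1, "alpha must be > 1")
  check(cfg$max_iter >= 1L, "max_iter must be >= 1")
  check(cfg$tol > 0, "tol must be positive")
  check(cfg$tau >= 0, "tau must be >= 0")
  check(cfg$transform %in% c("reciprocal", "complement"), "unknown length transform")
  check(diff(cfg$cc_ratio_range) >= 0, "cc_ratio_range must be ordered")
  check(diff(cfg$cp_ratio_range) >= 0, "cp_ratio_range must be ordered")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of `fwrn_config` fields and merges it over the
#' defaults; explicit `overrides` (e.g. parsed command-line flags) take
#' precedence over the file, which takes precedence over the defaults.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list of fields overriding the file.
#' @return An `fwrn_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(fwrn_config)))
    if (length(unknown)) {
      stop("invalid config: unknown field(s) ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  vals[names(overrides)] <- overrides
  do.call(fwrn_config, vals)
}

#' Short content hash of a configuration
#'
#' Used to stamp output files so results from different configurations
#' are never conflated.
#'
#' @param cfg An `fwrn_config`.
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(cfg)[order(names(unclass(cfg)))], tf, version = 2L)
  unname(tools::md5sum(tf))
}

#' Per-tile network metrics of one image
#'
#' The full single-image pipeline: tile the image, drop background tiles,
#' and for each kept tile extract windowed Frobenius-norm features, build
#' the fuzzy weighted recurrence network and compute its metrics.
#'
#' @param image An [mcimage] or a path readable by [read_image()].
#' @param cfg An [fwrn_config()].
#' @param image_id Identifier stamped on the output rows.
#' @return Data frame with one row per kept tile: `image_id`, `tile_id`,
#'   `n_nodes`, `CC`, `CP`, `tau`, `transform`, plus `n_tiles_total` and
#'   `n_tiles_kept` as attributes. Zero kept tiles yields a zero-row
#'   frame with a warning.
#' @export
image_metrics <- function(image, cfg = fwrn_config(), image_id = NULL) {
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  ts <- tile_image(image, cfg$tile_size,
                   white_luminance_frac = cfg$white_luminance_frac,
                   max_background_frac = cfg$max_background_frac)
  kept <- which(ts$kept_flags)
  empty <- data.frame(image_id = character(0), tile_id = integer(0),
                      n_nodes = integer(0), CC = numeric(0), CP = numeric(0),
                      tau = numeric(0), transform = character(0),
                      stringsAsFactors = FALSE)
  if (!length(kept)) {
    warning("no kept tiles for image ", image_id, call. = FALSE)
    attr(empty, "n_tiles_total") <- length(ts$tiles)
    attr(empty, "n_tiles_kept") <- 0L
    return(empty)
  }
  fcm <- fcm_config(c = cfg$c, alpha = cfg$alpha, max_iter = cfg$max_iter,
                    tol = cfg$tol, seed = cfg$seed)
  rows <- lapply(kept, function(t_idx) {
    fs <- extract_features(ts$tiles[[t_idx]], m = cfg$m, node_stride = cfg$node_stride,
                           source_id = sprintf("%s_tile%03d", image_id, t_idx))
    net <- build_network(fs, fcm)
    met <- network_metrics(net, tau = cfg$tau, transform = cfg$transform)
    cbind(data.frame(image_id = image_id, tile_id = t_idx, stringsAsFactors = FALSE), met)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tiles_total") <- length(ts$tiles)
  attr(out, "n_tiles_kept") <- length(kept)
  out
}

#' Specimen summaries for an in-memory imaging cohort
#'
#' Runs [image_metrics()] on the biopsy and tumor image of every patient
#' and averages the tile metrics into per-specimen summaries. Tiles from
#' multiple images of the same (patient, specimen) pool into one mean.
#'
#' @param images Named list (one element per patient) of lists with
#'   `biopsy` and `tumor` entries, each an [mcimage] or a list of them.
#' @param cfg An [fwrn_config()].
#' @return Data frame of specimen summaries (two rows per patient).
#' @export
specimen_metrics_from_images <- function(images, cfg = fwrn_config()) {
  rows <- lapply(names(images), function(pid) {
    per_type <- lapply(c(biopsy = "biopsy", tumor = "tumor"), function(tp) {
      imgs <- images[[pid]][[tp]]
      if (inherits(imgs, "mcimage")) imgs <- list(imgs)
      tiles <- do.call(rbind, lapply(seq_along(imgs), function(i) {
        image_metrics(imgs[[i]], cfg, image_id = sprintf("%s_%s_%d", pid, tp, i))
      }))
      aggregate_specimen(tiles, pid, if (tp == "tumor") "primary_tumor" else "biopsy")
    })
    do.call(rbind, per_type)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full cohort report from specimen summaries
#'
#' Joins per-patient tumor/biopsy ratios with the cohort table, computes
#' the ratio-survival Pearson correlation and sign-test probability in
#' each survival group, and evaluates the predictive ratio bands.
#'
#' @param specimens Specimen summaries (see [aggregate_specimen()]).
#' @param cohort Cohort data frame with `patient_id`, `survival_months`
#'   and a grouping column.
#' @param cfg An [fwrn_config()].
#' @param group_col Name of the grouping column in `cohort` (default
#'   `"group"`; a synthetic cohort uses `"arm"`).
#' @return A list: `ratios`, `associations` (one row per group x ratio
#'   type), `probabilities` (the two ratio-band rules), `scatter`
#'   (per-patient ratios with survival and group, for plotting).
#' @export
cohort_report <- function(specimens, cohort, cfg = fwrn_config(), group_col = "group") {
  ratios <- tumor_biopsy_ratios(specimens)
  merged <- merge(ratios, cohort, by = "patient_id")
  assoc <- do.call(rbind, lapply(split(merged, merged[[group_col]]), function(gdf) {
    do.call(rbind, lapply(c("cc_ratio", "cp_ratio"), function(fld) {
      a <- subgroup_association(gdf[[fld]], gdf$survival_months)
      data.frame(group = as.character(gdf[[group_col]][1L]), ratio = fld,
                 R = a$R, p_sign = a$p_sign, n = a$n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(assoc) <- NULL
  # an empty ratio band is reported as not-evaluable, not a hard stop
  band_or_na <- function(field, rng, srng) {
    tryCatch(survival_range_probability(ratios, cohort, field, rng, srng),
             error = function(e) list(k = 0L, n = 0L, probability = NA_real_))
  }
  prob_cc <- band_or_na("cc_ratio", cfg$cc_ratio_range, cfg$survival_range_cc)
  prob_cp <- band_or_na("cp_ratio", cfg$cp_ratio_range, cfg$survival_range_cp)
  probabilities <- data.frame(
    ratio = c("cc_ratio", "cp_ratio"),
    ratio_lo = c(cfg$cc_ratio_range[1], cfg$cp_ratio_range[1]),
    ratio_hi = c(cfg$cc_ratio_range[2], cfg$cp_ratio_range[2]),
    survival_lo = c(cfg$survival_range_cc[1], cfg$survival_range_cp[1]),
    survival_hi = c(cfg$survival_range_cc[2], cfg$survival_range_cp[2]),
    k = c(prob_cc$k, prob_cp$k), n = c(prob_cc$n, prob_cp$n),
    probability = c(prob_cc$probability, prob_cp$probability),
    stringsAsFactors = FALSE
  )
  scatter <- merged[, c("patient_id", "cc_ratio", "cp_ratio", "survival_months", group_col)]
  list(ratios = ratios, associations = assoc, probabilities = probabilities,
       scatter = scatter)
}

# CSV with a comment provenance header line.
write_provenanced_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fwrnet %s config_hash=%s seed=%d",
                     as.character(utils::packageVersion("fwrnet")),
                     config_hash(cfg), cfg$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Command-line style metrics run over image files
#'
#' Computes per-tile metrics for each image path and writes one CSV with
#' a provenance header (package version, configuration hash, seed).
#' Unreadable files are reported and skipped; the run continues.
#'
#' @param paths Character vector of image paths.
#' @param out_csv Output CSV path.
#' @param cfg An [fwrn_config()].
#' @return The combined metrics data frame, invisibly, with attribute
#'   `n_errors`.
#' @export
cmd_metrics <- function(paths, out_csv, cfg = fwrn_config()) {
  n_errors <- 0L
  rows <- lapply(paths, function(p) {
    tryCatch(image_metrics(p, cfg), error = function(e) {
      message("error processing ", p, ": ", conditionMessage(e))
      n_errors <<- n_errors + 1L
      NULL
    })
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  write_provenanced_csv(out, out_csv, cfg)
  attr(out, "n_errors") <- n_errors
  invisible(out)
}

#' Command-line style cohort run from a specimen manifest
#'
#' Reads a manifest CSV (`path`, `patient_id`, `specimen_type` with
#' values `biopsy`/`primary_tumor`), computes specimen summaries from the
#' referenced images, joins the cohort table and writes the ratio,
#' association, probability and scatter CSVs into `out_dir`.
#'
#' @param manifest_csv Manifest CSV path.
#' @param cohort_csv Cohort CSV path (`NULL` for the packaged cohort).
#' @param out_dir Output directory (created if missing).
#' @param cfg An [fwrn_config()].
#' @param group_col Grouping column for the association step.
#' @return The [cohort_report()] list, invisibly.
#' @export
cmd_cohort <- function(manifest_csv, cohort_csv = NULL, out_dir = ".",
                       cfg = fwrn_config(), group_col = "group") {
  manifest <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "patient_id", "specimen_type") %in% names(manifest)))
  cohort <- load_cohort_table(cohort_csv)
  images <- lapply(split(manifest, manifest$patient_id), function(mdf) {
    list(
      biopsy = lapply(mdf$path[mdf$specimen_type == "biopsy"], read_image),
      tumor = lapply(mdf$path[mdf$specimen_type == "primary_tumor"], read_image)
    )
  })
  paired <- vapply(images, function(x) length(x$biopsy) > 0 && length(x$tumor) > 0, logical(1))
  if (any(!paired)) {
    warning("skipping unpaired patient(s): ", paste(names(images)[!paired], collapse = ", "),
            call. = FALSE)
    images <- images[paired]
  }
  specimens <- specimen_metrics_from_images(images, cfg)
  report <- cohort_report(specimens, cohort, cfg, group_col = group_col)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_provenanced_csv(specimens, file.path(out_dir, "specimens.csv"), cfg)
  write_provenanced_csv(report$ratios, file.path(out_dir, "ratios.csv"), cfg)
  write_provenanced_csv(report$associations, file.path(out_dir, "associations.csv"), cfg)
  write_provenanced_csv(report$probabilities, file.path(out_dir, "probabilities.csv"), cfg)
  write_provenanced_csv(report$scatter, file.path(out_dir, "scatter.csv"), cfg)
  invisible(report)
}
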