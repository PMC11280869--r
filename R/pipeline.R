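## End-to-end orchestration: configuration, per-spot feature extraction,
## and the full stack -> matrix -> maps -> features pipeline with artifact
## output. The pipeline reports feature separations between annotated
## classes; it never infers malignancy itself.

#' Pipeline configuration
#'
#' All tunable settings of the analysis, with validated defaults. The
#' configuration round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param input Path to an intensity stack (16-page TIFF or directory of
#'   `I_XY.tif`), or `NULL` when the stack is passed in memory.
#' @param background_threshold Foreground threshold as a fraction of the
#'   99th-percentile m11 (see [normalize_m11()]).
#' @param delta_cutoff Retardance below which theta is undefined (radians).
#' @param histogram_bins,high_gray_threshold Histogram settings
#'   (see [histogram_summary()]).
#' @param glcm_levels,glcm_distance,glcm_angles,glcm_symmetric GLCM
#'   settings (see [glcm()]).
#' @param tamura_max_k,tamura_contrast_exponent,tamura_bins,tamura_distance,
#'   tamura_edge_threshold Tamura settings.
#' @param median_filter Apply a 3x3 median filter to the element images.
#' @param roi `"auto"` (disc detection on m11) or a data.frame of spots
#'   (`row`, `col`, `radius`, optional `class`).
#' @param spot_radius_range Optional accepted fitted-radius range for auto
#'   detection.
#' @param output_dir Where [run_pipeline()] writes its artifacts.
#' @param seed Seed recorded with the run.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(input = NULL,
                            background_threshold = 0.05,
                            delta_cutoff = 0.01,
                            histogram_bins = 64,
                            high_gray_threshold = 0.8,
                            glcm_levels = 16,
                            glcm_distance = 1,
                            glcm_angles = c(0, 45, 90, 135),
                            glcm_symmetric = TRUE,
                            tamura_max_k = 5,
                            tamura_contrast_exponent = 1 / 4,
                            tamura_bins = 16,
                            tamura_distance = 4,
                            tamura_edge_threshold = 0.1,
                            median_filter = FALSE,
                            roi = "auto",
                            spot_radius_range = NULL,
                            output_dir = "muellertma-out",
                            seed = 1) {
  stopifnot(background_threshold > 0, background_threshold < 1,
            delta_cutoff >= 0, delta_cutoff < pi,
            histogram_bins >= 2,
            high_gray_threshold >= 0, high_gray_threshold <= 1,
            glcm_levels >= 2, glcm_distance >= 1,
            all(glcm_angles >= 0), all(glcm_angles < 360),
            tamura_max_k >= 1, tamura_max_k <= 8,
            tamura_bins >= 2, tamura_distance >= 1,
            tamura_edge_threshold > 0, tamura_edge_threshold <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$roi <- if (is.data.frame(x$roi)) as.list(x$roi) else x$roi
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.list(x$roi)) x$roi <- as.data.frame(x$roi)
  args <- x[names(x) %in% names(formals(pipeline_config))]
  do.call(pipeline_config, args)
}

.feature_row <- function(gray, config) {
  hs <- histogram_summary(gray, config$histogram_bins,
                          config$high_gray_threshold)
  st <- distribution_stats(gray)
  gf <- glcm_features(glcm(gray, Ng = config$glcm_levels,
                           distance = config$glcm_distance,
                           angles = config$glcm_angles,
                           symmetric = config$glcm_symmetric))
  coarse <- tryCatch(tamura_coarseness(gray, config$tamura_max_k),
                     error = function(e) NA_real_)
  data.frame(
    gray_median = median(gray$pixels[gray$mask]),
    high_gray_fraction = hs$high_gray_fraction,
    kurtosis = st$kurtosis, skewness = st$skewness,
    glcm_contrast = gf$contrast, glcm_energy = gf$energy,
    glcm_homogeneity = gf$homogeneity, glcm_correlation = gf$correlation,
    tamura_coarseness = coarse,
    tamura_contrast = tamura_contrast(gray, config$tamura_contrast_exponent),
    tamura_line_likeness = suppressWarnings(
      tamura_line_likeness(gray, config$tamura_bins, config$tamura_distance,
                           config$tamura_edge_threshold))
  )
}

#' Per-spot feature extraction from decomposition maps
#'
#' For every spot ROI, crops the bounding box of its disc, renders the
#' delta and theta maps as fixed-range grayscale images, and computes the
#' full feature vector (median gray level, high-gray fraction, kurtosis,
#' skewness, four GLCM
#' features, three Tamura features) for each of the two parameter images.
#'
#' @param maps A `decomposition_maps` object.
#' @param spots data.frame with `spot_id`, `row`, `col`, `radius` and
#'   optionally `class`.
#' @param config A [pipeline_config()].
#' @return data.frame, one row per spot x parameter image (`param` column
#'   `"delta"` or `"theta"`).
#' @export
extract_spot_features <- function(maps, spots, config = pipeline_config()) {
  shape <- dim(maps$delta)
  out <- list()
  for (k in seq_len(nrow(spots))) {
    sp <- spots[k, ]
    mask <- spot_mask(shape, sp$row, sp$col, sp$radius) & maps$valid
    r0 <- max(1, floor(sp$row - sp$radius)); r1 <- min(shape[1], ceiling(sp$row + sp$radius))
    c0 <- max(1, floor(sp$col - sp$radius)); c1 <- min(shape[2], ceiling(sp$col + sp$radius))
    sub_mask <- mask[r0:r1, c0:c1]
    for (param in c("delta", "theta")) {
      m <- maps[[param]][r0:r1, c0:c1]
      pm <- sub_mask & is.finite(m)
      if (!any(pm)) next
      gray <- to_grayscale(m, kind = param, mask = pm)
      row <- .feature_row(gray, config)
      row <- cbind(data.frame(spot_id = sp$spot_id,
                              class = if ("class" %in% names(sp))
                                as.character(sp$class) else "unknown",
                              param = param), row)
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Per-class medians and class-difference signs of a feature table
#'
#' @param features Output of [extract_spot_features()].
#' @return Nested list: per parameter image, per feature, the per-class
#'   medians and the sign of the `normal - cancer` difference (when both
#'   classes are present).
#' @export
summarize_features <- function(features) {
  feat_cols <- setdiff(names(features), c("spot_id", "class", "param"))
  out <- list()
  for (param in unique(features$param)) {
    sub <- features[features$param == param, ]
    per_feat <- list()
    for (f in feat_cols) {
      med <- tapply(sub[[f]], sub$class, median, na.rm = TRUE)
      entry <- list(median = as.list(med))
      if (all(c("normal", "cancer") %in% names(med))) {
        dif <- med[["normal"]] - med[["cancer"]]
        entry$normal_minus_cancer <- dif
        entry$sign <- sign(dif)
      }
      per_feat[[f]] <- entry
    }
    out[[param]] <- per_feat
  }
  out
}

#' Run the full analysis pipeline
#'
#' Reads (or takes) a 16-image stack, reconstructs and normalizes the
#' Mueller image, decomposes it per pixel, detects or accepts spot ROIs,
#' extracts per-spot texture features, and writes all artifacts to
#' `config$output_dir`: the element images and mask
#' (`mueller_elements.tif`), the parameter maps (`maps.tif` + JSON
#' sidecar), the feature table (`features.csv`), the run summary
#' (`summary.json`, containing the per-class medians and difference signs
#' for every feature) and a structured log (`log.txt`). Deterministic
#' given the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param stack Optional in-memory `intensity_stack` (otherwise
#'   `config$input` is read).
#' @param spot_classes Optional class annotation for the ROIs: a named
#'   vector or data.frame keyed by `spot_id`, or a data.frame with `row`,
#'   `col`, `class` columns (each detected spot takes the class of the
#'   nearest annotated center).
#' @return Invisibly, list with `features`, `summary`, `maps`, `spots` and
#'   `paths`.
#' @export
run_pipeline <- function(config, stack = NULL, spot_classes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  logs <- character()
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    logs <<- c(logs, msg)
  }
  log_line("MuellerTMA pipeline, seed = ", config$seed)
  if (is.null(stack)) {
    if (is.null(config$input)) stop("no input stack given")
    stack <- read_stack(config$input)
    log_line("read stack from ", config$input)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  mi <- mm_reconstruct(stack)
  if (isTRUE(config$median_filter)) mi <- median_filter_elements(mi)
  m11_raw <- mi$elements[, , 1, 1]
  mi <- normalize_m11(mi, config$background_threshold)
  log_line("reconstructed; foreground pixels: ", sum(mi$mask))

  maps <- decompose_image(mi, delta_cutoff = config$delta_cutoff)
  log_line("decomposed; valid pixels: ", sum(maps$valid),
           "; clamped acos arguments: ", maps$n_clamped,
           "; undefined-theta fraction: ",
           round(mean(is.na(maps$theta[maps$valid])), 4))

  if (identical(config$roi, "auto")) {
    spots <- detect_spots(m11_raw, radius_range = config$spot_radius_range)
    rej <- attr(spots, "rejected")
    if (!is.null(rej) && nrow(rej))
      log_line("rejected ", nrow(rej), " non-circular component(s)")
  } else {
    spots <- config$roi
    if (!"spot_id" %in% names(spots)) spots$spot_id <- seq_len(nrow(spots))
  }
  if (!is.null(spot_classes)) {
    if (is.data.frame(spot_classes) &&
        all(c("row", "col") %in% names(spot_classes))) {
      ## annotation by position: assign each detected spot the class of
      ## the nearest annotated center
      idx <- vapply(seq_len(nrow(spots)), function(k)
        which.min((spot_classes$row - spots$row[k])^2 +
                    (spot_classes$col - spots$col[k])^2), integer(1))
      spots$class <- as.character(spot_classes$class[idx])
    } else if (is.data.frame(spot_classes)) {
      cls <- setNames(as.character(spot_classes$class),
                      spot_classes$spot_id)
      spots$class <- unname(cls[as.character(spots$spot_id)])
    } else {
      cls <- setNames(as.character(spot_classes), names(spot_classes))
      spots$class <- unname(cls[as.character(spots$spot_id)])
    }
  }
  log_line("spots: ", nrow(spots))

  features <- extract_spot_features(maps, spots, config)
  if (is.null(features) || nrow(features) == 0)
    stop("empty ROI: no features could be extracted")
  summary <- list(
    seed = config$seed,
    n_spots = nrow(spots),
    n_feature_rows = nrow(features),
    undefined_theta_fraction = mean(is.na(maps$theta[maps$valid])),
    n_clamped = maps$n_clamped,
    class_summary = summarize_features(features)
  )

  paths <- list(
    elements = file.path(config$output_dir, "mueller_elements.tif"),
    maps = file.path(config$output_dir, "maps.tif"),
    features = file.path(config$output_dir, "features.csv"),
    summary = file.path(config$output_dir, "summary.json"),
    config = file.path(config$output_dir, "config.yaml"),
    log = file.path(config$output_dir, "log.txt")
  )
  write_mueller_image(mi, paths$elements)
  write_maps(maps, paths$maps)
  write.csv(features, paths$features, row.names = FALSE)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config(config, paths$config)
  log_line("done in ", round(as.numeric(Sys.time()) - as.numeric(t0), 2),
           " s")
  writeLines(logs, paths$log)
  invisible(list(features = features, summary = summary, maps = maps,
                 spots = spots, paths = paths))
}
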