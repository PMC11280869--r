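## Forward model of the 16-state acquisition: the polarization state
## generator prepares state X in {H, P, V, R}, the light crosses the sample
## (Mueller matrix M), the analyzer selects state Y, and the camera records
## I_XY = 0.5 * a_Y . (M p_X), where p_X is the generator Stokes vector and
## a_Y the analyzer state. The 1/2 is the ideal-analyzer transmission
## factor; it makes the element-recovery sums return 2 * m_ij, which the
## m11 normalization removes downstream.

#' Detector intensity for one (generator, analyzer) state pair
#'
#' @param m 4x4 sample Mueller matrix.
#' @param generator,analyzer State labels in `{"H","P","V","R"}`.
#' @return Scalar intensity `0.5 * a . (m p)`; non-negative for a physical
#'   sample.
#' @export
#' @examples
#' simulate_intensity(diag(4), "H", "H")  # 1
#' simulate_intensity(diag(4), "H", "V")  # 0 (crossed polarizers)
#' simulate_intensity(diag(4), "H", "P")  # 0.5
simulate_intensity <- function(m, generator, analyzer) {
  p <- stokes_state(generator)
  a <- stokes_state(analyzer)
  0.5 * as.numeric(a %*% m %*% p)
}

#' Detector noise specification
#'
#' Additive Gaussian read noise (`gaussian_sd`, intensity units) and/or
#' Poisson shot noise: with `poisson_scale = s` (expected counts per unit
#' intensity), each pixel becomes `rpois(1, s * I) / s`. Intensities are
#' clipped at 0 after noise.
#'
#' @param gaussian_sd Read-noise standard deviation (0 disables).
#' @param poisson_scale Counts per unit intensity (`NULL` disables).
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(gaussian_sd = 0, poisson_scale = NULL) {
  stopifnot(gaussian_sd >= 0, is.null(poisson_scale) || poisson_scale > 0)
  structure(list(gaussian_sd = gaussian_sd, poisson_scale = poisson_scale),
            class = "noise_spec")
}

.apply_noise <- function(img, noise) {
  if (!is.null(noise$poisson_scale)) {
    s <- noise$poisson_scale
    img[] <- rpois(length(img), pmax(0, img) * s) / s
  }
  if (noise$gaussian_sd > 0) {
    img <- img + rnorm(length(img), sd = noise$gaussian_sd)
  }
  pmax(img, 0)
}

.new_stack <- function(images) {
  stopifnot(identical(names(images), state_pairs()))
  structure(list(images = images, shape = dim(images[[1]])),
            class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  cat("Intensity stack: 16 images (", paste(x$shape, collapse = " x "),
      "), range [", format(min(vapply(x$images, min, 0)), digits = 4), ", ",
      format(max(vapply(x$images, max, 0)), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Simulate the full 16-image acquisition
#'
#' Produces one image per (generator, analyzer) pair, in canonical order
#' `HH, HP, HV, HR, PH, ..., RR`. The sample is either a single Mueller
#' matrix (uniform field) or a per-pixel [mueller_image]. The noiseless
#' simulation is deterministic; with a `noise_spec` and a `seed` it is
#' exactly reproducible.
#'
#' @param m 4x4 Mueller matrix or a `mueller_image`.
#' @param shape `c(height, width)`; required (and checked) for a uniform
#'   field, must match the image for a per-pixel field.
#' @param noise A [noise_spec()] or `NULL` for noiseless.
#' @param seed Integer seed used when `noise` is given.
#' @return An `intensity_stack`: list with `$images` (named list of 16
#'   matrices) and `$shape`.
#' @export
simulate_stack <- function(m, shape = NULL, noise = NULL, seed = NULL) {
  pairs <- state_pairs()
  if (inherits(m, "mueller_image")) {
    if (!is.null(shape) && !identical(as.integer(shape), dim(m$elements)[1:2]))
      stop("`shape` does not match the Mueller image dimensions")
    shape <- dim(m$elements)[1:2]
    el <- m$elements
    images <- lapply(pairs, function(pair) {
      p <- stokes_state(substr(pair, 1, 1))
      a <- stokes_state(substr(pair, 2, 2))
      img <- matrix(0, shape[1], shape[2])
      for (i in 1:4) for (j in 1:4) {
        w <- a[i] * p[j]
        if (w != 0) img <- img + w * el[, , i, j]
      }
      0.5 * img
    })
  } else {
    stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
    if (is.null(shape)) stop("`shape` is required for a uniform sample")
    shape <- as.integer(shape)
    images <- lapply(pairs, function(pair) {
      matrix(simulate_intensity(m, substr(pair, 1, 1), substr(pair, 2, 2)),
             shape[1], shape[2])
    })
  }
  names(images) <- pairs
  if (!is.null(noise)) {
    if (!is.null(seed)) set.seed(seed)
    images <- lapply(images, .apply_noise, noise = noise)
  }
  .new_stack(images)
}

## float32 TIFF helpers: the tiff package stores values in [0, 1], so pages
## are affinely rescaled and the (offset, scale) encoding recorded in the
## sidecar JSON; readers invert it.
.float_encoding <- function(pages) {
  v <- range(unlist(lapply(pages, range), use.names = FALSE))
  list(offset = v[1], scale = if (v[2] > v[1]) v[2] - v[1] else 1)
}

.encode_pages <- function(pages, enc) {
  lapply(pages, function(p) (p - enc$offset) / enc$scale)
}

.decode_page <- function(img, enc) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * enc$scale + enc$offset
}

#' Write an intensity stack to TIFF
#'
#' Either one 16-page float32 TIFF (pages in canonical order `HH, HP, ...,
#' RR`) or 16 single-page files `I_XY.tif`. A sidecar JSON records the page
#' order and value scale.
#'
#' @param stack An `intensity_stack`.
#' @param path Output file (multi-page layout) or directory (file-per-state
#'   layout).
#' @param layout `"multi"` or `"files"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, layout = c("multi", "files")) {
  layout <- match.arg(layout)
  enc <- .float_encoding(stack$images)
  scaled <- .encode_pages(stack$images, enc)
  if (layout == "multi") {
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(
      list(layout = "multi", page_order = state_pairs(),
           sample_format = "float32",
           offset = enc$offset, scale = enc$scale),
      paste0(sub("\\.tiff?$", "", path), ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (pair in state_pairs()) {
      tiff::writeTIFF(scaled[[pair]],
                      file.path(path, sprintf("I_%s.tif", pair)),
                      bits.per.sample = 32L, reduce = FALSE)
    }
    jsonlite::write_json(
      list(layout = "files", files = sprintf("I_%s.tif", state_pairs()),
           sample_format = "float32",
           offset = enc$offset, scale = enc$scale),
      file.path(path, "stack.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an intensity stack written by [write_stack()]
#'
#' @param path Multi-page TIFF file or directory of `I_XY.tif` files.
#' @return An `intensity_stack`.
#' @export
read_stack <- function(path) {
  pairs <- state_pairs()
  read_enc <- function(sidecar) {
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      list(offset = meta$offset %||% 0, scale = meta$scale %||% 1)
    } else list(offset = 0, scale = 1)
  }
  if (dir.exists(path)) {
    enc <- read_enc(file.path(path, "stack.json"))
    files <- file.path(path, sprintf("I_%s.tif", pairs))
    missing <- pairs[!file.exists(files)]
    if (length(missing))
      stop("missing state-pair images: ", paste(missing, collapse = ", "))
    images <- lapply(files, function(f)
      .decode_page(tiff::readTIFF(f, as.is = FALSE), enc))
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    enc <- read_enc(paste0(sub("\\.tiff?$", "", path), ".json"))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (length(pages) != 16)
      stop("expected a 16-page TIFF, found ", length(pages), " pages")
    images <- lapply(pages, .decode_page, enc = enc)
  }
  names(images) <- pairs
  .new_stack(images)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
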