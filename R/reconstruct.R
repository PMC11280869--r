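## Mueller-matrix reconstruction from the 16 state-pair intensities.
##
## With I_XY = 0.5 * a_Y . (M p_X) each element m_ij is a fixed linear
## combination of intensities, and every combination below evaluates to
## exactly 2 * m_ij. The published element table for this protocol carries
## sign typos in three rows (the trailing IHH/IHV/IVH/IVV terms of m33 and
## m34, and the IVR and trailing terms of m44); the combinations used here
## are the minimal sign corrections that satisfy the forward/reconstruct
## round-trip identity, which is enforced by the test suite on random
## physical samples.

## coefficient table: element label -> named numeric vector over state pairs
.mm_coefficients <- local({
  co <- function(...) {
    v <- c(...)
    out <- setNames(numeric(16), state_pairs())
    out[names(v)] <- v
    out
  }
  msum <- co(HH = 1, HV = 1, VH = 1, VV = 1)      # = 2 m11
  mrow <- co(HH = 1, HV = -1, VH = 1, VV = -1)    # = 2 m21
  mcol <- co(HH = 1, HV = 1, VH = -1, VV = -1)    # = 2 m12
  list(
    m11 = msum,
    m12 = mcol,
    m13 = co(PH = 2, PV = 2) - msum,
    m14 = co(RH = 2, RV = 2) - msum,
    m21 = mrow,
    m22 = co(HH = 1, HV = -1, VH = -1, VV = 1),
    m23 = co(PH = 2, PV = -2) - mrow,
    m24 = co(RH = 2, RV = -2) - mrow,
    m31 = co(HP = 2, VP = 2) - msum,
    m32 = co(HP = 2, VP = -2) - mcol,
    m33 = co(PP = 4, PH = -2, PV = -2, HP = -2, VP = -2) + msum,
    m34 = co(RP = 4, RH = -2, RV = -2, HP = -2, VP = -2) + msum,
    m41 = co(HR = 2, VR = 2) - msum,
    m42 = co(HR = 2, VR = -2) - mcol,
    m43 = co(PR = 4, PH = -2, PV = -2, HR = -2, VR = -2) + msum,
    m44 = co(RR = 4, RH = -2, RV = -2, HR = -2, VR = -2) + msum
  )
})

#' Element-recovery formulas used by the reconstruction
#'
#' Returns, for each Mueller element `m_ij`, the coefficients of the linear
#' combination of the 16 state-pair intensities that recovers `2 * m_ij`
#' under the forward model.
#'
#' @return Named list of 16 numeric vectors (one per element, row-major
#'   `m11 ... m44`), each named by state pair.
#' @export
mm_element_formulas <- function() .mm_coefficients

.new_mueller_image <- function(elements, normalized = FALSE, mask = NULL) {
  structure(list(elements = elements, normalized = normalized, mask = mask),
            class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x$elements)
  cat("Mueller image ", d[1], " x ", d[2],
      if (x$normalized) " (m11-normalized)" else " (unnormalized)", "\n",
      sep = "")
  if (!is.null(x$mask))
    cat("  foreground: ", sum(x$mask), " / ", length(x$mask), " pixels\n",
        sep = "")
  invisible(x)
}

#' Per-pixel Mueller matrix of a uniform or assembled field
#'
#' Low-level constructor: `elements` is a `height x width x 4 x 4` array
#' with `elements[, , i, j]` the image of element `m_ij`.
#'
#' @param elements 4-D numeric array.
#' @param normalized Whether m11 is 1 on the foreground.
#' @param mask Optional logical foreground matrix.
#' @return A `mueller_image`.
#' @export
mueller_image <- function(elements, normalized = FALSE, mask = NULL) {
  stopifnot(is.array(elements), length(dim(elements)) == 4,
            all(dim(elements)[3:4] == c(4, 4)))
  if (!is.null(mask))
    stopifnot(identical(dim(mask), dim(elements)[1:2]))
  .new_mueller_image(elements, normalized, mask)
}

#' Extract the 4x4 Mueller matrix at one pixel
#'
#' @param mi A `mueller_image`.
#' @param row,col Pixel indices.
#' @return 4x4 matrix.
#' @export
pixel_matrix <- function(mi, row, col) {
  matrix(mi$elements[row, col, , ], 4, 4)
}

#' Reconstruct the per-pixel Mueller matrix from an intensity stack
#'
#' Applies the element-recovery linear combinations (see
#' [mm_element_formulas()]) to the 16 images. Under the package's forward
#' model the result equals `2 * M` exactly in the noiseless case; the
#' global factor is removed by [normalize_m11()].
#'
#' @param stack An `intensity_stack` (all 16 state pairs present).
#' @return An unnormalized `mueller_image`.
#' @export
mm_reconstruct <- function(stack) {
  stopifnot(inherits(stack, "intensity_stack"))
  missing <- setdiff(state_pairs(), names(stack$images))
  if (length(missing))
    stop("missing state-pair images: ", paste(missing, collapse = ", "))
  shape <- stack$shape
  el <- array(0, c(shape[1], shape[2], 4, 4))
  for (i in 1:4) for (j in 1:4) {
    co <- .mm_coefficients[[paste0("m", i, j)]]
    img <- matrix(0, shape[1], shape[2])
    for (pair in names(co)[co != 0]) {
      img <- img + co[[pair]] * stack$images[[pair]]
    }
    el[, , i, j] <- img
  }
  .new_mueller_image(el, normalized = FALSE)
}

#' Normalize a Mueller image by its m11 element and mask the background
#'
#' Foreground pixels are those whose m11 exceeds `background_threshold`
#' times the 99th percentile of m11; every element there is divided by the
#' pixel's m11. Background pixels are set to `NA` and excluded from all
#' downstream statistics.
#'
#' @param mi Unnormalized `mueller_image`.
#' @param background_threshold Fraction of the 99th-percentile m11 (default
#'   0.05) below which a pixel is background.
#' @return A normalized `mueller_image` with a logical `$mask`.
#' @export
normalize_m11 <- function(mi, background_threshold = 0.05) {
  stopifnot(inherits(mi, "mueller_image"), !mi$normalized)
  m11 <- mi$elements[, , 1, 1]
  thr <- background_threshold * quantile(m11, 0.99, names = FALSE)
  mask <- is.finite(m11) & (m11 > thr)
  if (!any(mask)) stop("no foreground pixels: image is all background")
  el <- mi$elements
  denom <- ifelse(mask, m11, NA_real_)
  for (i in 1:4) for (j in 1:4) el[, , i, j] <- el[, , i, j] / denom
  .new_mueller_image(el, normalized = TRUE, mask = mask)
}

#' Optional 3x3 median filter on every element image
#'
#' Off by default in the pipeline; intended for noisy acquisitions.
#' Border pixels keep their original values.
#'
#' @param mi A `mueller_image`.
#' @return Filtered `mueller_image` of the same kind.
#' @export
median_filter_elements <- function(mi) {
  el <- mi$elements
  h <- dim(el)[1]; w <- dim(el)[2]
  if (h < 3 || w < 3) return(mi)
  for (i in 1:4) for (j in 1:4) {
    x <- el[, , i, j]
    ## 9 shifted copies of the interior, median across the third axis
    shifts <- expand.grid(dr = -1:1, dc = -1:1)
    arr <- array(NA_real_, c(h - 2, w - 2, 9))
    for (k in seq_len(9)) {
      dr <- shifts$dr[k]; dc <- shifts$dc[k]
      arr[, , k] <- x[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc)]
    }
    med <- apply(arr, c(1, 2), median)
    x[2:(h - 1), 2:(w - 1)] <- med
    el[, , i, j] <- x
  }
  .new_mueller_image(el, mi$normalized, mi$mask)
}

#' Write the element images of a Mueller image as a multi-page TIFF
#'
#' Pages are in row-major element order `m11, m12, ..., m44`; the
#' foreground mask (if any) is written alongside as `<path>_mask.tif`.
#' `NA` background values are written as 0; a sidecar JSON records the
#' float encoding (offset/scale) and page order.
#'
#' @param mi A `mueller_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mueller_image <- function(mi, path) {
  pages <- list()
  labels <- character()
  for (i in 1:4) for (j in 1:4) {
    img <- mi$elements[, , i, j]
    img[!is.finite(img)] <- 0
    pages[[length(pages) + 1]] <- img
    labels <- c(labels, paste0("m", i, j))
  }
  enc <- .float_encoding(pages)
  tiff::writeTIFF(.encode_pages(pages, enc), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pages = labels, normalized = mi$normalized,
         offset = enc$offset, scale = enc$scale),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  if (!is.null(mi$mask)) {
    tiff::writeTIFF(matrix(as.numeric(mi$mask), nrow(mi$mask)),
                    sub("\\.tiff?$", "_mask.tif", path),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}
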