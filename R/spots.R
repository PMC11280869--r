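## Automatic TMA spot detection on the m11 (total transmittance) image.
## Tissue cores absorb, so spots are darker than the open background;
## thresholding followed by connected-component labeling and a circularity
## check recovers the circular regions of interest.

#' Detect circular TMA spots in an m11 image
#'
#' Pixels below `(1 - drop_fraction)` times the background level (the
#' 99th-percentile m11) are foreground; connected components are labeled
#' (EBImage), and each component is fitted with a disc from its centroid
#' and area. Components whose shape deviates from a disc beyond
#' `circularity_min`, or whose radius falls outside `radius_range` (when
#' given), are reported in the `rejected` attribute rather than silently
#' dropped. Circularity is measured as the ratio of the area-equivalent
#' radius to the maximum radial extent of the component: 1 for a disc,
#' about 0.71 for two fused discs.
#'
#' @param m11 Numeric matrix (the m11 element image).
#' @param drop_fraction Minimum fractional drop below the background level
#'   for a pixel to be foreground (default 0.05; tissue cores transmit
#'   10-25% less than the open substrate, while detector noise on m11 stays
#'   well below this at realistic SNR).
#' @param min_area Minimum component area in pixels (default 50).
#' @param circularity_min Minimum circularity (default 0.8).
#' @param radius_range Optional `c(min, max)` fitted-radius bounds.
#' @return data.frame with columns `spot_id`, `row`, `col`, `radius`,
#'   `area`, `circularity`; attribute `"rejected"` holds the same columns
#'   for failed components, attribute `"labels"` the label matrix.
#' @export
detect_spots <- function(m11, drop_fraction = 0.05, min_area = 50,
                         circularity_min = 0.8, radius_range = NULL) {
  bg <- quantile(m11, 0.99, names = FALSE)
  if (!is.finite(bg) || bg <= 0) stop("m11 image has no usable background")
  bw <- m11 < (1 - drop_fraction) * bg
  if (!any(bw)) stop("no spots detected; provide manual ROI masks")
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- EBImage::imageData(lab)
  n <- max(labm)
  if (n == 0) stop("no spots detected; provide manual ROI masks")
  rows <- matrix(seq_len(nrow(m11)), nrow(m11), ncol(m11))
  cols <- matrix(seq_len(ncol(m11)), nrow(m11), ncol(m11), byrow = TRUE)
  rec <- lapply(seq_len(n), function(k) {
    px <- labm == k
    area <- sum(px)
    ctr <- c(mean(rows[px]), mean(cols[px]))
    radius <- sqrt(area / pi)
    rmax <- sqrt(max((rows[px] - ctr[1])^2 + (cols[px] - ctr[2])^2))
    circ <- min(1, radius / max(rmax, 1))
    data.frame(spot_id = k, row = ctr[1], col = ctr[2], radius = radius,
               area = area, circularity = circ)
  })
  rec <- do.call(rbind, rec)
  ok <- rec$area >= min_area & rec$circularity >= circularity_min
  if (!is.null(radius_range))
    ok <- ok & rec$radius >= radius_range[1] & rec$radius <= radius_range[2]
  accepted <- rec[ok, , drop = FALSE]
  if (nrow(accepted) == 0)
    stop("no circular spots detected; provide manual ROI masks")
  accepted$spot_id <- seq_len(nrow(accepted))
  rejected <- rec[!ok, , drop = FALSE]
  structure(accepted, rejected = rejected, labels = labm)
}

#' Logical mask of one detected (or known) circular spot
#'
#' @param shape `c(height, width)`.
#' @param row,col Center.
#' @param radius Radius in pixels.
#' @return Logical matrix.
#' @export
spot_mask <- function(shape, row, col, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - row)^2 + (c - col)^2 <= radius^2
}
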