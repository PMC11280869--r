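## Texture analyzers for the delta / theta parameter maps: grayscale
## rendering over a fixed physical range, histogram summaries, raw
## distribution moments, and gray-level co-occurrence (GLCM) features.
## Quantization is always over the fixed [0, 1] grayscale range (never
## per-image min/max) so that features are comparable across spots and
## classes.

#' Render a parameter map as a grayscale image on a fixed physical range
#'
#' Linear scaling by the parameter's full physical range: delta maps
#' `[0, pi] -> [0, 1]`, theta maps `[0, pi) -> [0, 1)`. Values outside the
#' range (possible only through numerical noise) are clipped and counted.
#'
#' @param map Numeric matrix (radians); `NA` allowed outside the mask.
#' @param kind `"delta"` or `"theta"`.
#' @param mask Logical foreground matrix; defaults to finite pixels of
#'   `map`.
#' @return Object of class `grayscale_image`: list with `pixels` (matrix in
#'   `[0, 1]`, `NA` on background), `mask`, `kind`, `range` and
#'   `n_clipped`.
#' @export
to_grayscale <- function(map, kind = c("delta", "theta"), mask = NULL) {
  kind <- match.arg(kind)
  if (is.null(mask)) mask <- is.finite(map)
  mask <- mask & is.finite(map)
  if (!any(mask)) stop("empty foreground: no finite pixels to scale")
  rng <- c(0, pi)
  g <- (map - rng[1]) / (rng[2] - rng[1])
  n_clipped <- sum(g[mask] < 0 | g[mask] > 1, na.rm = TRUE)
  g <- pmin(pmax(g, 0), 1)
  g[!mask] <- NA_real_
  structure(list(pixels = g, mask = mask, kind = kind, range = rng,
                 n_clipped = n_clipped),
            class = "grayscale_image")
}

.gray_values <- function(g) {
  stopifnot(inherits(g, "grayscale_image"))
  g$pixels[g$mask]
}

#' Peak-normalized histogram and high-gray fraction of a grayscale image
#'
#' Bin counts over `[0, 1]` are divided by the maximum bin count
#' (peak normalization, so the tallest bin is 1). The high-gray fraction is
#' the fraction of foreground pixels with gray value above `high_threshold`
#' (default 0.8, the "high grayscale region" of the class comparison).
#'
#' @param g A `grayscale_image`.
#' @param bins Number of equal-width bins (>= 2).
#' @param high_threshold Gray level above which a pixel counts as
#'   high-gray.
#' @return List with `breaks`, `counts`, `normalized` (peak-normalized
#'   counts) and `high_gray_fraction`.
#' @export
histogram_summary <- function(g, bins = 64, high_threshold = 0.8) {
  stopifnot(bins >= 2)
  x <- .gray_values(g)
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(bins, findInterval(x, breaks, rightmost.closed = TRUE))
  idx <- pmax(1L, idx)
  counts <- tabulate(idx, nbins = bins)
  list(breaks = breaks, counts = counts,
       normalized = counts / max(counts),
       high_gray_fraction = mean(x > high_threshold))
}

#' Kurtosis and skewness of a grayscale image (raw population moments)
#'
#' `kurtosis = mean(z^4)` and `skewness = mean(z^3)` with
#' `z = (x - mean) / s` and `s` the population (1/n) standard deviation.
#' Note the kurtosis is the raw fourth standardized moment, with no `-3`
#' excess correction: a normal population gives kurtosis 3.
#'
#' @param g A `grayscale_image`, or a numeric vector of values.
#' @return List with `kurtosis` and `skewness` (`NA` with a warning for a
#'   constant image).
#' @export
distribution_stats <- function(g) {
  x <- if (inherits(g, "grayscale_image")) .gray_values(g) else
    g[is.finite(g)]
  if (length(x) < 2) stop("need at least 2 foreground pixels")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    warning("constant image: kurtosis/skewness undefined")
    return(list(kurtosis = NA_real_, skewness = NA_real_))
  }
  z <- (x - mean(x)) / s
  list(kurtosis = mean(z^4), skewness = mean(z^3))
}

.offset_rc <- function(distance, angle_deg) {
  a <- angle_deg * pi / 180
  c(dr = -round(distance * sin(a)), dc = round(distance * cos(a)))
}

## pair counts of quantized levels q (1..Ng, NA = background) at offset
.glcm_count <- function(q, Ng, dr, dc) {
  h <- nrow(q); w <- ncol(q)
  r0 <- max(1, 1 - dr); r1 <- min(h, h - dr)
  c0 <- max(1, 1 - dc); c1 <- min(w, w - dc)
  if (r0 > r1 || c0 > c1) return(matrix(0, Ng, Ng))
  a <- q[r0:r1, c0:c1]
  b <- q[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(matrix(0, Ng, Ng))
  matrix(tabulate((a[keep] - 1) * Ng + b[keep], nbins = Ng * Ng),
         Ng, Ng, byrow = TRUE)
}

#' Gray-level co-occurrence matrix of a grayscale image
#'
#' The foreground is quantized to `Ng` levels over the fixed `[0, 1]`
#' range; pixel pairs at each spatial offset are counted (pairs touching
#' the background are dropped, not zero-filled), each offset's matrix is
#' normalized to sum 1, and the matrices are averaged over offsets.
#'
#' @param g A `grayscale_image`.
#' @param Ng Number of quantization levels (default 16).
#' @param distance Offset distance in pixels (default 1).
#' @param angles Offset angles in degrees (default `c(0, 45, 90, 135)`).
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @return Object of class `glcm`: `Ng x Ng` matrix summing to 1, with
#'   attributes `Ng`, `distance`, `angles`, `symmetric`.
#' @export
glcm <- function(g, Ng = 16, distance = 1, angles = c(0, 45, 90, 135),
                 symmetric = TRUE) {
  stopifnot(Ng >= 2, distance >= 1)
  x <- g$pixels
  q <- matrix(NA_integer_, nrow(x), ncol(x))
  fg <- g$mask & is.finite(x)
  q[fg] <- pmin(Ng, floor(x[fg] * Ng) + 1L)
  mats <- lapply(angles, function(a) {
    off <- .offset_rc(distance, a)
    p <- .glcm_count(q, Ng, off["dr"], off["dc"])
    if (symmetric) p <- p + t(p)
    tot <- sum(p)
    if (tot == 0) stop("no valid pixel pairs at angle ", a, " degrees")
    p / tot
  })
  p <- Reduce(`+`, mats) / length(mats)
  structure(p, class = c("glcm", "matrix"),
            Ng = Ng, distance = distance, angles = angles,
            symmetric = symmetric)
}

#' Haralick-type features of a normalized co-occurrence matrix
#'
#' For a normalized GLCM `P` with level indices `i, j`:
#' contrast `= sum (i - j)^2 P(i, j)` (equivalently the weighted sum over
#' level differences `n = |i - j|`), energy `= sum P^2`, homogeneity
#' `= sum P / (1 + (i - j)^2)`, correlation
#' `= (sum i j P - mu_x mu_y) / (sigma_x sigma_y)` with the moments taken
#' from the marginal distributions.
#'
#' @param p A `glcm` (or any normalized co-occurrence matrix).
#' @return List with `contrast`, `energy`, `homogeneity`, `correlation`
#'   (`NA` correlation for a constant image, where a marginal sd is 0).
#' @export
glcm_features <- function(p) {
  p <- unclass(p)
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  contrast <- sum((i - j)^2 * p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + (i - j)^2))
  px <- rowSums(p); py <- colSums(p)
  lev <- seq_len(Ng)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum(lev^2 * px) - mux^2)
  sy <- sqrt(sum(lev^2 * py) - muy^2)
  correlation <- if (sx <= 0 || sy <= 0) NA_real_ else
    (sum(i * j * p) - mux * muy) / (sx * sy)
  list(contrast = contrast, energy = energy, homogeneity = homogeneity,
       correlation = correlation)
}
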