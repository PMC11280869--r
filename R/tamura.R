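## Tamura texture features: coarseness, contrast and line-likeness.
## All three operate on a grayscale_image; windows or pixel pairs that
## touch the background are dropped rather than zero-filled.

## summed-area table with a leading zero row/column; window sums in O(1)
.sat <- function(x) {
  x[is.na(x)] <- 0
  s <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed cumsum
  s <- t(s)
  rbind(0, cbind(0, s))
}

## mean over the 2^k x 2^k window anchored at (x - half .. x + half - 1);
## NA wherever the window leaves the image or touches background
.window_mean <- function(sat_x, sat_n, half, h, w) {
  A <- matrix(NA_real_, h, w)
  if (h - half + 1 < half + 1 || w - half + 1 < half + 1) return(A)
  rows <- (half + 1):(h - half + 1)
  cols <- (half + 1):(w - half + 1)
  r0 <- rows - half; r1 <- rows + half - 1
  c0 <- cols - half; c1 <- cols + half - 1
  ## row indices vary down the grid, column indices across: submatrix
  ## indexing evaluates all (r, c) combinations at once
  ws <- function(s)
    s[r1 + 1, c1 + 1] - s[r0, c1 + 1] - s[r1 + 1, c0] + s[r0, c0]
  total <- ws(sat_x)
  count <- ws(sat_n)
  full <- (2 * half)^2
  vals <- ifelse(count == full, total / full, NA_real_)
  A[rows, cols] <- vals
  A
}

## shift a matrix by (dr, dc), filling with NA
.shift <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(NA_real_, h, w)
  r_src <- max(1, 1 + dr):min(h, h + dr)
  c_src <- max(1, 1 + dc):min(w, w + dc)
  out[r_src - dr, c_src - dc] <- x[r_src, c_src]
  out
}

#' Tamura coarseness
#'
#' For each pixel, local averages over `2^k x 2^k` windows (`k = 1 ..
#' max_k`) are compared between opposite neighborhoods in the horizontal
#' and vertical directions; the best scale `S_best = 2^k` is the one
#' maximizing the absolute average difference, and coarseness is the mean
#' of `S_best` over pixels where at least one scale is valid. Windows that
#' leave the image or touch masked background are dropped.
#'
#' @param g A `grayscale_image`, at least 64 x 64 pixels.
#' @param max_k Largest scale exponent (default 5, windows up to 32 x 32).
#' @return Scalar coarseness (in pixels).
#' @export
tamura_coarseness <- function(g, max_k = 5) {
  x <- g$pixels
  h <- nrow(x); w <- ncol(x)
  if (h < 64 || w < 64)
    stop("coarseness requires an image of at least 64 x 64 pixels")
  fg <- g$mask & is.finite(x)
  xf <- ifelse(fg, x, 0)
  sat_x <- .sat(xf)
  sat_n <- .sat(matrix(as.numeric(fg), h, w))
  best_e <- matrix(-Inf, h, w)
  best_s <- matrix(NA_real_, h, w)
  for (k in seq_len(max_k)) {
    half <- 2^(k - 1)
    A <- .window_mean(sat_x, sat_n, half, h, w)
    Eh <- abs(.shift(A, 0, half) - .shift(A, 0, -half))
    Ev <- abs(.shift(A, half, 0) - .shift(A, -half, 0))
    E <- pmax(Eh, Ev)
    upd <- !is.na(E) & (E > best_e)
    best_e[upd] <- E[upd]
    best_s[upd] <- 2^k
  }
  keep <- fg & !is.na(best_s)
  if (!any(keep)) stop("no pixels with a valid coarseness window")
  mean(best_s[keep])
}

#' Tamura contrast
#'
#' `sigma / alpha4^(1/4)` with `sigma` the population standard deviation of
#' the foreground intensities and `alpha4` their kurtosis (fourth
#' standardized moment). A constant image has contrast 0 by convention.
#'
#' @param g A `grayscale_image`.
#' @param exponent Exponent applied to `alpha4` (default `1/4`, the
#'   original Tamura normalization).
#' @return Scalar contrast.
#' @export
tamura_contrast <- function(g, exponent = 1 / 4) {
  x <- .gray_values(g)
  sigma <- sqrt(mean((x - mean(x))^2))
  if (sigma == 0) return(0)
  alpha4 <- mean(((x - mean(x)) / sigma)^4)
  sigma / alpha4^exponent
}

## Sobel gradients; NA at borders and wherever the 3x3 support touches
## background
.sobel <- function(x, fg) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gh <- matrix(NA_real_, nrow(x), ncol(x))
  gv <- matrix(NA_real_, nrow(x), ncol(x))
  acc_h <- 0; acc_v <- 0; ok <- 1
  for (dr in -1:1) for (dc in -1:1) {
    s <- .shift(x, dr, dc)
    m <- .shift(matrix(as.numeric(fg), nrow(x)), dr, dc)
    wgt_h <- kx[dr + 2, dc + 2]   # kernel column = horizontal change
    wgt_v <- kx[dc + 2, dr + 2]
    s0 <- ifelse(is.na(s), 0, s)
    acc_h <- acc_h + wgt_h * s0
    acc_v <- acc_v + wgt_v * s0
    ok <- ok * ifelse(is.na(m), 0, m)
  }
  valid <- ok == 1 & fg
  gh[valid] <- acc_h[valid]
  gv[valid] <- acc_v[valid]
  list(gh = gh, gv = gv)
}

#' Tamura line-likeness
#'
#' Edge pixels are those whose Sobel gradient magnitude exceeds
#' `edge_threshold` times the maximum magnitude. Each edge pixel's
#' direction (mod pi) is quantized to `n_bins`; for every edge pixel, the
#' pixel at distance `d` along its local edge direction is looked up, and
#' co-occurring direction bins `(i, j)` are accumulated into a direction
#' co-occurrence matrix `P`. Line-likeness is
#' `sum P(i, j) cos((i - j) 2 pi / n) / sum P(i, j)`: straight oriented
#' structures concentrate mass near the diagonal and score high.
#'
#' @param g A `grayscale_image`.
#' @param n_bins Number of direction bins (default 16).
#' @param d Co-occurrence distance in pixels (default 4).
#' @param edge_threshold Fraction of the maximum gradient magnitude
#'   (default 0.1) above which a pixel is an edge pixel.
#' @return Scalar in `[-1, 1]`, or `NA` if there are no edge pixels.
#' @export
tamura_line_likeness <- function(g, n_bins = 16, d = 4,
                                 edge_threshold = 0.1) {
  x <- g$pixels
  fg <- g$mask & is.finite(x)
  gr <- .sobel(x, fg)
  mag <- (abs(gr$gh) + abs(gr$gv)) / 2
  if (all(is.na(mag)) || max(mag, na.rm = TRUE) == 0) {
    warning("no edge pixels: line-likeness undefined")
    return(NA_real_)
  }
  thr <- edge_threshold * max(mag, na.rm = TRUE)
  edge <- !is.na(mag) & mag >= thr
  if (!any(edge)) {
    warning("no edge pixels: line-likeness undefined")
    return(NA_real_)
  }
  ## edge direction = gradient direction rotated by pi/2, taken mod pi
  phi <- (atan2(gr$gv, gr$gh) + pi / 2) %% pi
  bin <- matrix(NA_integer_, nrow(x), ncol(x))
  bin[edge] <- pmin(n_bins, floor(phi[edge] / pi * n_bins) + 1L)
  P <- matrix(0, n_bins, n_bins)
  idx <- which(edge, arr.ind = TRUE)
  ## neighbor along the local edge direction (row axis points down)
  ang <- phi[edge]
  nr <- idx[, 1] - round(d * sin(ang))
  nc <- idx[, 2] + round(d * cos(ang))
  ok <- nr >= 1 & nr <= nrow(x) & nc >= 1 & nc <= ncol(x)
  if (any(ok)) {
    i <- bin[edge][ok]
    jj <- bin[cbind(nr[ok], nc[ok])]
    keep <- !is.na(jj)
    if (any(keep)) {
      tab <- tabulate((i[keep] - 1) * n_bins + jj[keep],
                      nbins = n_bins * n_bins)
      P <- matrix(tab, n_bins, n_bins, byrow = TRUE)
    }
  }
  if (sum(P) == 0) {
    warning("no co-occurring edge pairs: line-likeness undefined")
    return(NA_real_)
  }
  i <- matrix(seq_len(n_bins), n_bins, n_bins)
  sum(P * cos((i - t(i)) * 2 * pi / n_bins)) / sum(P)
}
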