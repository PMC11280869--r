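## Forward polar decomposition M = M_Delta %*% M_R %*% M_D of a normalized
## Mueller matrix (Lu & Chipman), followed by extraction of the two
## headline tissue parameters: the linear phase retardance delta and the
## equivalent-waveplate fast-axis azimuth theta.
##
## Algorithm per pixel:
##   1. Diattenuator: D vector = (m12, m13, m14); M_D from the Lu-Chipman
##      closed form; M' = M %*% solve(M_D).
##   2. Depolarizer: with G = m' m'^T (m' the 3x3 block of M') and
##      eigenvalues l1 >= l2 >= l3 of G,
##      m_Delta = +/- [G + (sqrt(l1 l2)+sqrt(l2 l3)+sqrt(l3 l1)) I]^-1
##                    [(sqrt(l1)+sqrt(l2)+sqrt(l3)) G + sqrt(l1 l2 l3) I],
##      sign = sign(det m'); polarizance column from M'.
##   3. Retarder: M_R = solve(M_Delta) %*% M'.
## Retarder scalars:
##   total retardance  R     = acos(tr(M_R)/2 - 1)
##   linear retardance delta = acos(sqrt((mR22+mR33)^2+(mR32-mR23)^2) - 1)
##   optical rotation  psi   = 0.5 atan2(mR23 - mR32, mR22 + mR33)
##   fast-axis azimuth theta = 0.5 atan2(r2, r1), r_i the Levi-Civita
##      contraction of the 3x3 block of the linear factor M_LR =
##      M_R %*% solve(M_CR(psi)), divided by 2 sin(delta).
## The delta formula uses the DIFFERENCE of the off-diagonal retarder
## elements; this is what makes delta independent of any circular
## component, and it is pinned by the construct-and-recover tests.

.clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Diattenuation of a normalized Mueller matrix
#'
#' `D = sqrt(m12^2 + m13^2 + m14^2) / m11`, clamped to `[0, 1]`.
#'
#' @param m 4x4 Mueller matrix.
#' @return Scalar in `[0, 1]`.
#' @export
diattenuation <- function(m) {
  min(1, sqrt(sum((m[1, 2:4] / m[1, 1])^2)))
}

#' Depolarization index of a depolarizer factor
#'
#' `1 - mean(abs(diag))` of the 3x3 block: 0 for a non-depolarizing
#' element, 1 for the ideal depolarizer.
#'
#' @param m_delta 4x4 depolarizer Mueller matrix.
#' @return Scalar in `[0, 1]`.
#' @export
depolarization_index <- function(m_delta) {
  min(1, max(0, 1 - mean(abs(diag(m_delta)[2:4]))))
}

#' Total retardance of a retarder factor
#'
#' `R = acos(tr(M_R) / 2 - 1)`, in `[0, pi]`.
#'
#' @param m_R 4x4 pure-retarder Mueller matrix.
#' @return Scalar in radians.
#' @export
total_retardance <- function(m_R) {
  acos(.clamp1(sum(diag(m_R)) / 2 - 1))
}

#' Linear retardance of a retarder factor
#'
#' `delta = acos(sqrt((mR22 + mR33)^2 + (mR32 - mR23)^2) - 1)`, in
#' `[0, pi]`; the arccos argument is clamped to `[-1, 1]`. Any circular
#' (optical-rotation) component of the retarder does not contribute.
#'
#' @param m_R 4x4 pure-retarder Mueller matrix (linear, circular or mixed).
#' @return Scalar in radians.
#' @export
linear_retardance <- function(m_R) {
  acos(.clamp1(sqrt((m_R[2, 2] + m_R[3, 3])^2 +
                    (m_R[3, 2] - m_R[2, 3])^2) - 1))
}

#' Split a retarder into linear and circular factors
#'
#' The optical-rotation angle is `psi = 0.5 * atan2(mR23 - mR32,
#' mR22 + mR33)`; the circular factor is `circular_retarder(psi)` and the
#' linear factor is `M_LR = M_R %*% solve(M_CR)`, so `M_LR %*% M_CR = M_R`.
#'
#' @param m_R 4x4 pure-retarder Mueller matrix.
#' @return List with `M_LR`, `M_CR`, and `psi` (radians).
#' @export
split_circular <- function(m_R) {
  psi <- 0.5 * atan2(m_R[2, 3] - m_R[3, 2], m_R[2, 2] + m_R[3, 3])
  M_CR <- circular_retarder(psi)
  M_LR <- m_R %*% solve(M_CR)
  list(M_LR = M_LR, M_CR = M_CR, psi = psi)
}

#' Fast-axis azimuth of a linear retarder factor
#'
#' Assembles the retardance axis vector by the Levi-Civita contraction
#' `r_i = (1 / (2 sin delta)) * sum_jk eps_ijk mLR(j, k)` over the 3x3
#' block of the linear retarder, and returns
#' `theta = 0.5 * atan2(r2, r1)`, wrapped to `[0, pi)`. Below
#' `delta_cutoff` the division by `sin(delta)` is unstable and the azimuth
#' is undefined (`NA`).
#'
#' @param m_LR 4x4 linear-retarder Mueller matrix (or its 3x3 block).
#' @param delta Linear retardance in radians.
#' @param delta_cutoff Retardance below which theta is reported `NA`
#'   (default 0.01 rad).
#' @return Azimuth in radians in `[0, pi)`, or `NA`.
#' @export
fast_axis_azimuth <- function(m_LR, delta, delta_cutoff = 0.01) {
  if (!is.finite(delta) || delta <= delta_cutoff) return(NA_real_)
  b <- if (all(dim(m_LR) == c(4, 4))) m_LR[2:4, 2:4] else m_LR
  s <- 2 * sin(delta)
  r1 <- (b[2, 3] - b[3, 2]) / s
  r2 <- (b[3, 1] - b[1, 3]) / s
  th <- 0.5 * atan2(r2, r1)
  if (th < 0) th <- th + pi
  th
}

#' Lu-Chipman polar decomposition of a single Mueller matrix
#'
#' Factors `m` (normalized so `m11 = 1`) as
#' `M_Delta %*% M_R %*% M_D` and extracts the scalar polarization
#' parameters. The retarder is further split into linear and circular
#' factors to obtain the linear retardance `delta` and its fast-axis
#' azimuth `theta`.
#'
#' @param m 4x4 Mueller matrix, approximately physical. If `m[1,1] != 1`
#'   the matrix is normalized first.
#' @param delta_cutoff Passed to [fast_axis_azimuth()].
#' @return List with factors `M_D`, `M_Delta`, `M_R`, `M_LR`, `M_CR` and
#'   scalars `D`, `Delta`, `R`, `delta`, `theta`, `psi`, plus a logical
#'   `ok` flag (FALSE for near-singular cases, with `reason`).
#' @export
#' @examples
#' M <- pure_depolarizer(0.95, 0.95, 0.9) %*%
#'   linear_retarder(0.3, 0.7) %*% linear_diattenuator(0.1, 0.2)
#' f <- lc_decompose(M / M[1, 1])
#' c(delta = f$delta, theta = f$theta, D = f$D, Delta = f$Delta)
lc_decompose <- function(m, delta_cutoff = 0.01) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  if (!is.finite(m[1, 1]) || m[1, 1] <= 0)
    return(list(ok = FALSE, reason = "nonpositive or nonfinite m11"))
  m <- m / m[1, 1]
  Dv <- m[1, 2:4]
  D <- sqrt(sum(Dv^2))
  if (D >= 1 - 1e-9)
    return(list(ok = FALSE, reason = "ideal polarizer: M_D not invertible",
                D = min(1, D)))
  if (D < 1e-14) {
    M_D <- diag(4)
    Mp <- m
  } else {
    dhat <- Dv / D
    a <- sqrt(1 - D^2)
    mD <- a * diag(3) + (1 - a) * tcrossprod(dhat)
    M_D <- rbind(c(1, Dv), cbind(Dv, mD))
    Mp <- m %*% solve(M_D)
  }
  mp <- Mp[2:4, 2:4]
  G <- mp %*% t(mp)
  ev <- sort(pmax(0, eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
  A <- G + (sqrt(l1 * l2) + sqrt(l2 * l3) + sqrt(l3 * l1)) * diag(3)
  B <- (sqrt(l1) + sqrt(l2) + sqrt(l3)) * G + sqrt(l1 * l2 * l3) * diag(3)
  detmp <- det(mp)
  if (abs(det(A)) < 1e-300)
    return(list(ok = FALSE, reason = "singular depolarizer block",
                D = D, M_D = M_D))
  m_delta <- (if (detmp < 0) -1 else 1) * solve(A, B)
  M_Delta <- rbind(c(1, 0, 0, 0), cbind(Mp[2:4, 1], m_delta))
  if (abs(det(M_Delta)) < 1e-12)
    return(list(ok = FALSE, reason = "near-singular depolarizer factor",
                D = D, M_D = M_D, M_Delta = M_Delta))
  M_R <- solve(M_Delta) %*% Mp
  delta <- linear_retardance(M_R)
  sp <- split_circular(M_R)
  list(
    ok = TRUE,
    M_D = M_D, M_Delta = M_Delta, M_R = M_R,
    M_LR = sp$M_LR, M_CR = sp$M_CR,
    D = D,
    Delta = depolarization_index(M_Delta),
    R = total_retardance(M_R),
    delta = delta,
    theta = fast_axis_azimuth(sp$M_LR, delta, delta_cutoff),
    psi = sp$psi
  )
}

#' Per-pixel polar decomposition of a Mueller image
#'
#' Applies the Lu-Chipman decomposition at every foreground pixel (compiled
#' kernel) and returns the parameter maps. Pixels where the decomposition
#' fails (non-invertible diattenuator, singular depolarizer block) are
#' flagged in the quality mask and excluded; isolated bad pixels never
#' abort the image.
#'
#' @param mi A normalized `mueller_image` (see [normalize_m11()]).
#' @param mask Optional logical foreground matrix; defaults to `mi$mask`
#'   (or all pixels).
#' @param delta_cutoff Linear retardance below which theta is undefined
#'   (default 0.01 rad).
#' @return Object of class `decomposition_maps`: list of matrices `delta`,
#'   `theta`, `R`, `Delta`, `D` (NA outside the valid foreground), the
#'   logical `valid` quality mask, `n_clamped` (count of arccos arguments
#'   clamped into `[-1, 1]`), and `delta_cutoff`.
#' @export
decompose_image <- function(mi, mask = NULL, delta_cutoff = 0.01) {
  stopifnot(inherits(mi, "mueller_image"))
  if (!mi$normalized)
    stop("decompose_image() expects an m11-normalized Mueller image")
  if (is.null(mask)) mask <- mi$mask
  if (is.null(mask)) mask <- matrix(TRUE, dim(mi$elements)[1],
                                    dim(mi$elements)[2])
  res <- decompose_image_cpp(mi$elements, mask, delta_cutoff)
  structure(list(
    delta = res$delta, theta = res$theta, R = res$R,
    Delta = res$Delta, D = res$D,
    psi = res$psi,
    valid = res$valid & mask,
    n_clamped = res$n_clamped,
    delta_cutoff = delta_cutoff
  ), class = "decomposition_maps")
}

#' @export
print.decomposition_maps <- function(x, ...) {
  cat("Decomposition maps (", nrow(x$delta), " x ", ncol(x$delta), ")\n",
      sep = "")
  cat("  valid pixels: ", sum(x$valid), "; clamped acos args: ",
      x$n_clamped, "\n", sep = "")
  for (nm in c("delta", "theta", "Delta", "D")) {
    v <- x[[nm]][x$valid]
    v <- v[is.finite(v)]
    if (length(v))
      cat(sprintf("  %-6s median %.4f  range [%.4f, %.4f]\n", nm,
                  median(v), min(v), max(v)))
  }
  invisible(x)
}

#' Write decomposition maps as a multi-page float32 TIFF
#'
#' Pages: delta, theta, R, Delta, D, followed by the quality mask; a
#' sidecar JSON records units and the theta cutoff. `NA` values are
#' written as 0 (the mask page identifies them).
#'
#' @param maps A `decomposition_maps` object.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_maps <- function(maps, path) {
  pages <- lapply(c("delta", "theta", "R", "Delta", "D"), function(nm) {
    img <- maps[[nm]]
    img[!is.finite(img)] <- 0
    img
  })
  pages[[6]] <- matrix(as.numeric(maps$valid), nrow(maps$valid))
  enc <- .float_encoding(pages)
  tiff::writeTIFF(.encode_pages(pages, enc), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pages = c("delta", "theta", "R", "Delta", "D", "valid"),
         units = list(delta = "radians", theta = "radians", R = "radians",
                      Delta = "dimensionless", D = "dimensionless"),
         offset = enc$offset, scale = enc$scale,
         delta_cutoff = maps$delta_cutoff,
         n_clamped = maps$n_clamped),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
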