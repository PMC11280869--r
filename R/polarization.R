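## Polarization algebra: Stokes vectors, canonical Mueller matrices and a
## physicality check. Everything downstream (forward model, reconstruction,
## decomposition, phantom generator) is built on these primitives.
##
## Conventions:
##  * Stokes vector (s0, s1, s2, s3): s0 total intensity, s1/s2 linear at
##    0/90 and +/-45 degrees, s3 right-circular.
##  * Angles in radians. Fast-axis / transmission-axis azimuths are
##    directors, defined modulo pi.
##  * Mueller matrices are plain 4x4 numeric matrices (class "mueller" is a
##    thin tag used for printing only); they are stored unnormalized, and
##    normalization by m11 is an explicit operation in the reconstruction
##    module.

#' Stokes vector of a canonical polarization state
#'
#' The acquisition protocol uses four states: H (linear horizontal, 0
#' degrees), P (linear diagonal, 45 degrees), V (linear vertical, 90
#' degrees) and R (right-handed circular), all at unit intensity.
#'
#' @param label One of `"H"`, `"P"`, `"V"`, `"R"`.
#' @return Numeric length-4 Stokes vector.
#' @export
#' @examples
#' stokes_state("H")   # c(1, 1, 0, 0)
#' stokes_state("R")   # c(1, 0, 0, 1)
stokes_state <- function(label) {
  switch(match.arg(label, .states),
    H = c(1,  1, 0, 0),
    P = c(1,  0, 1, 0),
    V = c(1, -1, 0, 0),
    R = c(1,  0, 0, 1)
  )
}

.mueller <- function(m) structure(m, class = c("mueller", class(m)))

#' @export
print.mueller <- function(x, digits = 4, ...) {
  cat("Mueller matrix (m11 =", format(x[1, 1], digits = digits), ")\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Mueller matrix of a linear retarder
#'
#' Standard Lu-Chipman convention: for fast-axis azimuth `theta` and
#' retardance `delta`, the (2,4) element is `-sin(2 theta) sin(delta)` and
#' the (4,2) element is `+sin(2 theta) sin(delta)`. Same-axis retardances
#' compose additively: `linear_retarder(t, d1) %*% linear_retarder(t, d2)`
#' equals `linear_retarder(t, d1 + d2)`.
#'
#' @param theta Fast-axis azimuth in radians (interpreted modulo pi).
#' @param delta Retardance in radians, in `[0, pi]`.
#' @return 4x4 Mueller matrix.
#' @export
#' @examples
#' linear_retarder(0, pi)        # half-wave plate at 0: diag(1, 1, -1, -1)
#' linear_retarder(pi / 4, pi / 2)  # quarter-wave plate at 45 degrees
linear_retarder <- function(theta, delta) {
  C <- cos(2 * theta); S <- sin(2 * theta)
  cd <- cos(delta); sd <- sin(delta)
  .mueller(matrix(c(
    1, 0, 0, 0,
    0, C^2 + S^2 * cd, S * C * (1 - cd), -S * sd,
    0, S * C * (1 - cd), S^2 + C^2 * cd,  C * sd,
    0, S * sd, -C * sd, cd
  ), 4, 4, byrow = TRUE))
}

#' Mueller matrix of a circular retarder (optical rotation)
#'
#' Rotates the linear-polarization plane by `psi`; acts on the (s1, s2)
#' block as a rotation by `2 psi` and leaves s3 unchanged.
#'
#' @param psi Optical rotation angle in radians.
#' @return 4x4 Mueller matrix.
#' @export
circular_retarder <- function(psi) {
  c2 <- cos(2 * psi); s2 <- sin(2 * psi)
  .mueller(matrix(c(
    1, 0, 0, 0,
    0, c2, s2, 0,
    0, -s2, c2, 0,
    0, 0, 0, 1
  ), 4, 4, byrow = TRUE))
}

#' Mueller matrix of a rotation of the laboratory frame
#'
#' Conjugating a sample matrix `M` by `mm_rotation(alpha)`,
#' `mm_rotation(alpha) %*% M %*% mm_rotation(-alpha)`, expresses the same
#' sample in a frame rotated by `alpha`; a retarder's fast-axis azimuth
#' shifts by `alpha` (mod pi) under this operation.
#'
#' @param alpha Rotation angle in radians.
#' @return 4x4 Mueller matrix.
#' @export
mm_rotation <- function(alpha) circular_retarder(-alpha)

#' Mueller matrix of a linear diattenuator (partial polarizer)
#'
#' Built from the diattenuation vector `D = d (cos 2 theta, sin 2 theta, 0)`
#' in the Lu-Chipman form, scaled so the maximum transmittance (along the
#' transmission axis) is 1: `m11 = 1 / (1 + d)`. `d = 0` gives the identity;
#' `d = 1` gives the ideal (rank-deficient) polarizer, e.g.
#' `0.5 * rbind(c(1,1,0,0), c(1,1,0,0), 0, 0)` at `theta = 0`.
#'
#' @param theta Transmission-axis azimuth in radians.
#' @param d Diattenuation in `[0, 1]`.
#' @return 4x4 Mueller matrix with first row `(1, d cos2t, d sin2t, 0) * m11`.
#' @export
linear_diattenuator <- function(theta, d) {
  if (d < 0 || d > 1) stop("diattenuation `d` must be in [0, 1]")
  m11 <- 1 / (1 + d)
  if (d == 0) return(.mueller(diag(4)))
  Dv <- d * c(cos(2 * theta), sin(2 * theta), 0)
  dhat <- Dv / d
  a <- sqrt(pmax(0, 1 - d^2))
  mD <- a * diag(3) + (1 - a) * tcrossprod(dhat)
  out <- m11 * rbind(c(1, Dv), cbind(Dv, mD))
  dimnames(out) <- NULL
  .mueller(out)
}

#' Mueller matrix of a pure (diagonal) depolarizer
#'
#' `diag(1, a, b, c)` with principal depolarization factors in `[0, 1]`.
#' Its depolarization index in the polar-decomposition sense is
#' `1 - (a + b + c) / 3`.
#'
#' @param a,b,c Depolarization factors along s1, s2, s3.
#' @return 4x4 Mueller matrix.
#' @export
#' @examples
#' pure_depolarizer(0.9, 0.8, 0.7)  # depolarization 0.2
pure_depolarizer <- function(a, b, c) {
  stopifnot(all(c(a, b, c) >= 0), all(c(a, b, c) <= 1))
  .mueller(diag(c(1, a, b, c)))
}

## Deterministic latitude/longitude grid of unit vectors on the Poincare
## sphere (poles included once).
.poincare_grid <- function(n_lat = 9, n_lon = 16) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  g <- expand.grid(lat = lat, lon = lon)
  u <- cbind(cos(g$lat) * cos(g$lon), cos(g$lat) * sin(g$lon), sin(g$lat))
  unique(round(u, 12))
}

#' Check whether a Mueller matrix maps physical light to physical light
#'
#' Applies `m` to every fully polarized Stokes vector on a deterministic
#' latitude/longitude grid of the Poincare sphere and requires the output to
#' have non-negative intensity (`s0 >= -tol`) and degree of polarization at
#' most `1 + tol`. This is a necessary (grid-sampled) transmission
#' condition, not a full positive-semidefiniteness test.
#'
#' @param m 4x4 Mueller matrix.
#' @param tol Numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_physical(diag(4))             # TRUE
#' is_physical(diag(c(1, 2, 0, 0))) # FALSE: overpolarizes H input
is_physical <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  u <- .poincare_grid()
  S <- cbind(1, u)            # rows are input Stokes vectors, DOP = 1
  out <- S %*% t(m)           # rows are output Stokes vectors
  s0 <- out[, 1]
  if (any(s0 < -tol)) return(FALSE)
  p <- sqrt(rowSums(out[, 2:4, drop = FALSE]^2))
  ## dark outputs: polarized part must vanish too
  dark <- s0 <= tol
  if (any(p[dark] > tol)) return(FALSE)
  all(p[!dark] / s0[!dark] <= 1 + tol)
}
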