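## Synthetic tissue-microarray phantom generator.
##
## A phantom is a field of non-overlapping circular spots (emulating 1.5 mm
## TMA cores at a configured pixel pitch) on an optically empty background.
## Each spot belongs to a class ("normal" or "cancer") with class-dependent
## polarization structure:
##   * linear retardance delta: Gaussian around the class mean, spatially
##     smoothed at a fiber-texture correlation length (normal tissue keeps
##     birefringent collagen, so delta_normal > delta_cancer);
##   * fast-axis azimuth theta: wrapped-normal on the doubled angle 2*theta
##     around a per-spot mean axis, with concentration set by the order
##     parameter kappa in [0, 1] (1 = perfectly aligned axes, 0 = uniform);
##   * small depolarization and diattenuation, plus an overall spot
##     transmittance < 1 (tissue absorbs) that makes spots visible in m11.
## The per-pixel sample matrix is assembled as
## tau * M_Delta %*% M_R(delta, theta) %*% M_D and pushed through the
## forward model to produce the 16-image stack.

#' Specification of a synthetic TMA phantom
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param spot_centers Two-column matrix of `(row, col)` centers.
#' @param spot_radius Spot radius in pixels (all spots equal; the default
#'   40 px corresponds to a scaled-down 1.5 mm core; at the full-scale 2
#'   micron pixel pitch a core is about 375 px in radius).
#' @param spot_classes Character vector (one per spot) of class labels,
#'   each a name of `class_params`.
#' @param class_params Named list of per-class parameter lists with fields
#'   `delta_mean`, `delta_sd` (radians), `kappa` (axis order parameter in
#'   `[0, 1]`), `depol_range`, `diatten_range`, `transmittance_range`
#'   (each length-2), and `corr_length` (pixels).
#' @param noise A [noise_spec()] or `NULL`.
#' @param seed Integer seed; the whole phantom is deterministic given the
#'   spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape, spot_centers, spot_radius = 40,
                         spot_classes,
                         class_params = default_class_params(),
                         noise = NULL, seed = 1) {
  spot_centers <- as.matrix(spot_centers)
  stopifnot(ncol(spot_centers) == 2,
            length(spot_classes) == nrow(spot_centers),
            all(spot_classes %in% names(class_params)))
  for (cp in class_params) {
    stopifnot(cp$delta_mean >= 0, cp$delta_mean <= pi,
              cp$delta_sd >= 0, cp$kappa >= 0, cp$kappa <= 1,
              all(cp$depol_range >= 0), all(cp$depol_range <= 1),
              all(cp$diatten_range >= 0), all(cp$diatten_range < 1),
              all(cp$transmittance_range > 0),
              all(cp$transmittance_range <= 1))
  }
  ## spots must not overlap (and must fit in the image)
  n <- nrow(spot_centers)
  if (n > 1) {
    dd <- as.matrix(dist(spot_centers))
    diag(dd) <- Inf
    if (any(dd < 2 * spot_radius))
      stop("overlapping spots: minimum center distance is below 2 * radius")
  }
  if (any(spot_centers[, 1] < spot_radius + 1 |
          spot_centers[, 1] > image_shape[1] - spot_radius |
          spot_centers[, 2] < spot_radius + 1 |
          spot_centers[, 2] > image_shape[2] - spot_radius))
    stop("spots must lie fully inside the image")
  structure(list(image_shape = as.integer(image_shape),
                 spot_centers = spot_centers, spot_radius = spot_radius,
                 spot_classes = spot_classes, class_params = class_params,
                 noise = noise, seed = seed),
            class = "phantom_spec")
}

#' Default per-class phantom parameters
#'
#' Normal tissue: high retardance (`delta_mean = 0.5` rad) from intact
#' birefringent collagen, with a fiber-scale texture correlation length of
#' 5 px; cancer: degraded and destroyed collagen, `delta_mean = 0.1` rad
#' and a short 1.5 px correlation length (fine-grained, spatially
#' decorrelated texture). Axis order `kappa` defaults to 0.9 (normal) vs
#' 0.3 (cancer); the direction of the order contrast is a free choice,
#' only the delta direction is treated as fixed. Depolarization is kept
#' small (<= 0.05), as expected for 4-micron transmissive sections.
#'
#' @return Named list with `normal` and `cancer` parameter lists.
#' @export
default_class_params <- function() {
  list(
    normal = list(delta_mean = 0.5, delta_sd = 0.05, kappa = 0.9,
                  depol_range = c(0.01, 0.05),
                  diatten_range = c(0.01, 0.05),
                  transmittance_range = c(0.75, 0.9),
                  corr_length = 5),
    cancer = list(delta_mean = 0.1, delta_sd = 0.05, kappa = 0.3,
                  depol_range = c(0.01, 0.05),
                  diatten_range = c(0.01, 0.05),
                  transmittance_range = c(0.75, 0.9),
                  corr_length = 1.5)
  )
}

#' Regular grid of spot centers
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch Center-to-center distance in pixels.
#' @param margin Distance from the image border to the first center.
#' @return Two-column matrix of `(row, col)` centers.
#' @export
tma_grid_centers <- function(n_rows, n_cols, pitch, margin = pitch / 2 + 1) {
  as.matrix(expand.grid(
    row = margin + (seq_len(n_rows) - 1) * pitch,
    col = margin + (seq_len(n_cols) - 1) * pitch
  ))
}

## Gaussian smoothing by separable convolution (reflection padding),
## used to give the delta field a fiber-like correlation length.
.gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(m) {
    h <- nrow(m)
    pad <- rbind(m[half:1, , drop = FALSE], m,
                 m[h:(h - half + 1), , drop = FALSE])
    out <- matrix(0, h, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * pad[(i):(i + h - 1), ,
                                                    drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(x))))
}

.runif_range <- function(n, range) runif(n, range[1], range[2])

#' Generate the ground-truth parameter maps of a phantom
#'
#' @param spec A [phantom_spec()].
#' @return List of matrices `delta`, `theta`, `Delta`, `D`, `d_axis`
#'   (diattenuation axis), `tau` (transmittance), integer `spot_id`
#'   (0 = background) and character `class_map` entries per spot
#'   (`$spot_table`: data.frame spot_id, class, plus the per-spot draws).
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  delta <- matrix(0, h, w); theta <- matrix(0, h, w)
  Delta <- matrix(0, h, w); D <- matrix(0, h, w)
  d_axis <- matrix(0, h, w); tau <- matrix(1, h, w)
  spot_id <- matrix(0L, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  n <- nrow(spec$spot_centers)
  tab <- data.frame(spot_id = seq_len(n), class = spec$spot_classes,
                    theta0 = NA_real_, Delta = NA_real_, D = NA_real_,
                    d_axis = NA_real_, tau = NA_real_)
  for (s in seq_len(n)) {
    cp <- spec$class_params[[spec$spot_classes[s]]]
    ctr <- spec$spot_centers[s, ]
    inside <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= spec$spot_radius^2
    npx <- sum(inside)
    ## delta: smoothed Gaussian field rescaled to the class mean/sd
    f <- matrix(rnorm(h * w), h, w)
    f <- .gauss_smooth(f, cp$corr_length)
    f <- (f - mean(f[inside])) / max(sd(f[inside]), 1e-12)
    dfield <- cp$delta_mean + cp$delta_sd * f
    delta[inside] <- pmin(pi, pmax(0, dfield[inside]))
    ## theta: wrapped normal on 2*theta with concentration rho = kappa
    theta0 <- runif(1, 0, pi)
    if (cp$kappa >= 1) {
      th <- rep(theta0, npx)
    } else if (cp$kappa <= 0) {
      th <- runif(npx, 0, pi)
    } else {
      sd2 <- sqrt(-2 * log(cp$kappa))   # wrapped-normal sd on 2*theta
      th <- (theta0 + 0.5 * rnorm(npx, sd = sd2)) %% pi
    }
    theta[inside] <- th
    ## per-spot constants
    tab$theta0[s] <- theta0
    tab$Delta[s] <- Delta[inside] <- .runif_range(1, cp$depol_range)
    tab$D[s] <- D[inside] <- .runif_range(1, cp$diatten_range)
    tab$d_axis[s] <- d_axis[inside] <- runif(1, 0, pi)
    tab$tau[s] <- tau[inside] <- .runif_range(1, cp$transmittance_range)
    spot_id[inside] <- s
  }
  list(delta = delta, theta = theta, Delta = Delta, D = D,
       d_axis = d_axis, tau = tau, spot_id = spot_id, spot_table = tab,
       spec = spec)
}

#' Assemble the per-pixel Mueller matrix field of a phantom
#'
#' `tau * M_Delta %*% M_R(delta, theta) %*% M_D` at every pixel
#' (depolarizer isotropic with index `Delta`, linear retarder, linear
#' diattenuator along `d_axis`). Background pixels are identity optics.
#'
#' @param truth Output of [generate_ground_truth()].
#' @return A `mueller_image` (unnormalized).
#' @export
truth_mueller_image <- function(truth) {
  h <- nrow(truth$delta); w <- ncol(truth$delta)
  el <- array(0, c(h, w, 4, 4))
  ## start from identity everywhere
  for (i in 1:4) el[, , i, i] <- 1
  idx <- which(truth$spot_id > 0)
  for (p in idx) {
    r <- ((p - 1) %% h) + 1
    c <- ((p - 1) %/% h) + 1
    u <- 1 - truth$Delta[p]
    M <- truth$tau[p] *
      pure_depolarizer(u, u, u) %*%
      linear_retarder(truth$theta[p], truth$delta[p]) %*%
      linear_diattenuator(truth$d_axis[p], truth$D[p])
    el[r, c, , ] <- M
  }
  mueller_image(el)
}

#' Forward-simulate the 16-image stack of a phantom
#'
#' @param truth Output of [generate_ground_truth()].
#' @param noise Overrides the spec's noise (use `NULL` for noiseless).
#' @param seed Overrides the spec's seed for the noise draw.
#' @return An `intensity_stack`.
#' @export
render_stack <- function(truth, noise = truth$spec$noise,
                         seed = truth$spec$seed) {
  mi <- truth_mueller_image(truth)
  simulate_stack(mi, noise = noise, seed = seed)
}

#' Gaussian read-noise level corresponding to a target SNR
#'
#' `sigma = rms(intensities) * 10^(-snr_db / 20)` over the 16 noiseless
#' images.
#'
#' @param stack Noiseless `intensity_stack`.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return A [noise_spec()] with the matching `gaussian_sd`.
#' @export
snr_noise <- function(stack, snr_db) {
  v <- unlist(lapply(stack$images, as.vector), use.names = FALSE)
  rms <- sqrt(mean(v^2))
  noise_spec(gaussian_sd = rms * 10^(-snr_db / 20))
}
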