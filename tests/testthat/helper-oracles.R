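# Shared fixtures and independent oracles, all generated in code.

# random physical Mueller matrix: depolarizer . retarder . (optional
# circular) . diattenuator with parameters drawn inside the physical range
random_physical_mm <- function(with_circular = FALSE) {
  th <- runif(1, 0, pi)
  de <- runif(1, 0.05, pi - 0.05)
  tha <- runif(1, 0, pi)
  d <- runif(1, 0, 0.6)
  ab <- runif(3, 0.6, 1)
  M <- pure_depolarizer(ab[1], ab[2], ab[3]) %*% linear_retarder(th, de)
  psi <- 0
  if (with_circular) {
    psi <- runif(1, -0.6, 0.6)
    M <- M %*% circular_retarder(psi)
  }
  M <- M %*% linear_diattenuator(tha, d)
  list(M = M, theta = th, delta = de, d = d, d_axis = tha,
       depol = 1 - mean(ab), psi = psi)
}

# distance between two director angles (defined modulo pi)
axis_distance <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# naive double-loop GLCM feature oracle, straight from the definitions
naive_glcm_features <- function(p) {
  Ng <- nrow(p)
  contrast <- 0; energy <- 0; homogeneity <- 0; sij <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    energy <- energy + p[i, j]^2
    homogeneity <- homogeneity + p[i, j] / (1 + (i - j)^2)
    sij <- sij + i * j * p[i, j]
  }
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum(seq_len(Ng)^2 * px) - mux^2)
  sy <- sqrt(sum(seq_len(Ng)^2 * py) - muy^2)
  list(contrast = contrast, energy = energy, homogeneity = homogeneity,
       correlation = (sij - mux * muy) / (sx * sy))
}

# grayscale_image wrapper around a plain matrix in [0, 1]
as_gray <- function(x, mask = NULL) {
  to_grayscale(x * pi, kind = "delta", mask = mask)
}

# small two-class phantom used by several files
small_phantom_spec <- function(seed = 11, noise = NULL) {
  phantom_spec(
    image_shape = c(120, 220),
    spot_centers = rbind(c(60, 60), c(60, 160)),
    spot_radius = 40,
    spot_classes = c("normal", "cancer"),
    noise = noise, seed = seed
  )
}
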