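# Shared fixtures and independent oracles used across the test files.

# Monte-Carlo irradiance oracle: cosine-weighted hemisphere sampling around
# the normal, independent of the quadrature path. With stratified = TRUE
# the unit square is jittered on a regular grid, which shrinks the
# integration error well below the plain-MC standard error.
mc_irradiance <- function(sky, n, n_samples = 1e5, seed = 1,
                          stratified = FALSE) {
  fr <- countershade:::orthonormal_frame(n)
  set.seed(seed)
  if (stratified) {
    m <- floor(sqrt(n_samples))
    g <- (seq_len(m) - 1) / m
    u1 <- rep(g, each = m) + stats::runif(m * m) / m
    u2 <- rep(g, times = m) + stats::runif(m * m) / m
  } else {
    u1 <- stats::runif(n_samples)
    u2 <- stats::runif(n_samples)
  }
  st <- sqrt(u1)
  ct <- sqrt(1 - u1)
  ph <- 2 * pi * u2
  d <- ct %o% n + (st * cos(ph)) %o% fr$t1 + (st * sin(ph)) %o% fr$t2
  L <- environment_radiance(sky, d)
  sun <- sky$sun_irradiance * max(0, sum(n * sky$sun_direction))
  list(value = sun + pi * mean(L),
       se = pi * stats::sd(L) / sqrt(length(L)))
}

# An isotropic environment of radiance L0 from every direction: uniform
# sky, no sun, perfectly reflective ground (which then also returns L0).
isotropic_sky <- function(L0 = 1) {
  sky_model(sky_type = "uniform", zenith_radiance = L0, sun_irradiance = 0,
            ground_albedo = 1)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Area-weighted mean normal of a face subset.
mean_normal <- function(mesh, sel) {
  v <- colSums(mesh$normals[sel, , drop = FALSE] * mesh$areas[sel])
  v / sqrt(sum(v^2))
}

# Dihedral opened by a fold (degrees): how far the two lateral half-sheet
# mean normals have turned apart relative to the unfolded leaf. Measured on
# front-sheet faces only (identified on the flat reference) because the rim
# of the closed thin mesh, and the sheet's own curvature, would contaminate
# absolute normal directions.
fold_dihedral <- function(leaf, flat_leaf, min_nx = 0.95) {
  sheet <- flat_leaf$normals[, 1] > min_nx
  top <- flat_leaf$centroids[, 3] > 0
  ang <- function(a, b) acos(min(max(sum(a * b), -1), 1)) * 180 / pi
  ang(mean_normal(leaf, sheet & top), mean_normal(flat_leaf, sheet & top)) +
    ang(mean_normal(leaf, sheet & !top), mean_normal(flat_leaf, sheet & !top))
}

# Coarse-but-adequate quadrature for tests that exercise structure rather
# than radiometric accuracy.
quad_fast <- function() hemisphere_quadrature(16, 8)
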