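#' CIE general-sky coefficient presets
#'
#' Gradation and indicatrix coefficients (a, b, c, d, e) of the CIE general
#' sky. The \code{"clear"} preset is the standard clear-sky set (low
#' turbidity), \code{"overcast"} the standard overcast set, and
#' \code{"uniform"} an isotropic sky useful for analytic checks.
#'
#' @param type one of \code{"clear"}, \code{"overcast"}, \code{"uniform"}.
#' @return named numeric vector \code{c(a, b, c, d, e)}.
#' @export
cie_sky_coefficients <- function(type = c("clear", "overcast", "uniform")) {
  type <- match.arg(type)
  switch(type,
         clear    = c(a = -1,  b = -0.32, c = 10, d = -3, e = 0.45),
         overcast = c(a =  4,  b = -0.70, c = 0,  d = -1, e = 0),
         uniform  = c(a =  0,  b = -1,    c = 0,  d = -1, e = 0))
}

#' Directional light field: sun, CIE sky dome and diffuse ground
#'
#' A scene light field made of three parts: a delta ("sun") beam of given
#' irradiance at normal incidence, a continuous sky dome following the CIE
#' general-sky two-factor formula scaled to a zenith radiance, and a
#' constant-radiance ground term coupling single-bounce reflection of the
#' total horizontal irradiance off a Lambertian ground of given albedo.
#'
#' All radiometric quantities are in arbitrary linear units; every quantity
#' consumed downstream is a ratio. When \code{sun_irradiance} is omitted it
#' is set so that the direct horizontal irradiance is
#' \code{sun_diffuse_ratio} times the diffuse (sky) horizontal irradiance, a
#' typical clear-sky split.
#'
#' @param sun_azimuth sun azimuth in degrees, clockwise from north
#'   (default 270: due west, above and behind a viewer facing east).
#' @param sun_altitude sun altitude in degrees above the horizon (0--90).
#' @param sky_type preset name passed to [cie_sky_coefficients()]; ignored
#'   when \code{sky_coefficients} is supplied.
#' @param sky_coefficients optional named vector \code{c(a, b, c, d, e)}.
#' @param zenith_radiance radiance of the sky at the zenith (>= 0).
#' @param sun_irradiance irradiance of the direct beam at normal incidence;
#'   \code{NULL} (default) derives it from \code{sun_diffuse_ratio}.
#' @param sun_diffuse_ratio target ratio of direct to diffuse horizontal
#'   irradiance used when \code{sun_irradiance} is \code{NULL}.
#' @param ground_albedo Lambertian ground albedo in [0, 1].
#' @return an object of class \code{sky_model}.
#' @examples
#' sky <- sky_model()                      # sunny default
#' sky_radiance(sky, direction_from_angles(0, 90))  # zenith radiance
#' @export
sky_model <- function(sun_azimuth = 270, sun_altitude = 45,
                      sky_type = "clear", sky_coefficients = NULL,
                      zenith_radiance = 1, sun_irradiance = NULL,
                      sun_diffuse_ratio = 5, ground_albedo = 0.3) {
  if (sun_altitude < 0 || sun_altitude > 90)
    stop("sun_altitude must lie in [0, 90] degrees")
  if (sun_azimuth < 0 || sun_azimuth > 360)
    stop("sun_azimuth must lie in [0, 360] degrees")
  if (zenith_radiance < 0) stop("zenith_radiance must be >= 0")
  if (ground_albedo < 0 || ground_albedo > 1)
    stop("ground_albedo must lie in [0, 1]")
  if (is.null(sky_coefficients)) {
    sky_coefficients <- cie_sky_coefficients(sky_type)
  } else {
    if (!all(c("a", "b", "c", "d", "e") %in% names(sky_coefficients)))
      stop("sky_coefficients must name a, b, c, d, e")
    sky_type <- "custom"
  }
  sky <- structure(list(
    sun_azimuth      = sun_azimuth,
    sun_altitude     = sun_altitude,
    sun_direction    = drop(direction_from_angles(sun_azimuth, sun_altitude)),
    sky_type         = sky_type,
    sky_coefficients = sky_coefficients[c("a", "b", "c", "d", "e")],
    zenith_radiance  = zenith_radiance,
    sun_irradiance   = 0,
    ground_albedo    = ground_albedo
  ), class = "sky_model")
  if (is.null(sun_irradiance)) {
    if (sun_diffuse_ratio < 0) stop("sun_diffuse_ratio must be >= 0")
    ed <- sky_cosine_integral(sky, c(0, 0, 1), default_quadrature())
    s  <- sin(sun_altitude * pi / 180)
    sun_irradiance <- if (s > 0) sun_diffuse_ratio * ed / s else 0
  }
  if (sun_irradiance < 0) stop("sun_irradiance must be >= 0")
  sky$sun_irradiance <- sun_irradiance
  sky
}

#' @export
print.sky_model <- function(x, ...) {
  cat("Light field (sky_model)\n")
  cat(sprintf("  sun: azimuth %g deg, altitude %g deg, irradiance %.4g\n",
              x$sun_azimuth, x$sun_altitude, x$sun_irradiance))
  cat(sprintf("  sky: %s (a=%g b=%g c=%g d=%g e=%g), zenith radiance %.4g\n",
              x$sky_type, x$sky_coefficients["a"], x$sky_coefficients["b"],
              x$sky_coefficients["c"], x$sky_coefficients["d"],
              x$sky_coefficients["e"], x$zenith_radiance))
  cat(sprintf("  ground albedo: %g\n", x$ground_albedo))
  invisible(x)
}

#' Hemispherical quadrature rule
#'
#' Product rule used for cosine-weighted integrals over a hemisphere:
#' Gauss--Legendre nodes in elevation crossed with uniformly spaced azimuth
#' nodes. The azimuthal arc is split analytically at the horizon when sky
#' and ground contributions differ, so the integrand seen by the rule is
#' smooth.
#'
#' @param n_elev number of Gauss--Legendre elevation nodes (>= 8).
#' @param n_az number of azimuth nodes per elevation ring (>= 4).
#' @return a quadrature specification list.
#' @export
hemisphere_quadrature <- function(n_elev = 64, n_az = 32) {
  if (n_elev < 8 || n_az < 4)
    stop("quadrature resolution below the accepted minimum (8 x 4)")
  gl <- pracma::gaussLegendre(n_elev, 0, pi / 2)
  list(n_elev = n_elev, n_az = n_az,
       psi = gl$x, w = gl$w, cp = cos(gl$x), sp = sin(gl$x))
}

default_quadrature <- function() {
  hemisphere_quadrature(64, 32)
}

# CIE general-sky relative radiance, unchecked and vectorized over rows of
# the direction matrix d (assumed above the horizon).
cie_relative_radiance <- function(sky, d) {
  k <- sky$sky_coefficients
  cz <- pmin(pmax(d[, 3], 0), 1)
  gradation <- 1 + k[["a"]] * exp(k[["b"]] / cz)       # exp(-Inf) = 0 at horizon
  cchi <- pmin(pmax(d %*% sky$sun_direction, -1), 1)
  chi <- acos(cchi)
  indicatrix <- 1 + k[["c"]] * (exp(k[["d"]] * chi) - exp(k[["d"]] * pi / 2)) +
    k[["e"]] * cchi^2
  zs <- pi / 2 - sky$sun_altitude * pi / 180
  norm <- (1 + k[["a"]] * exp(k[["b"]])) *
    (1 + k[["c"]] * (exp(k[["d"]] * zs) - exp(k[["d"]] * pi / 2)) +
       k[["e"]] * cos(zs)^2)
  drop(gradation * indicatrix / norm)
}

#' Diffuse sky radiance in a direction above the horizon
#'
#' Evaluates the CIE general-sky formula (gradation times scattering
#' indicatrix, normalized so that the zenith value equals
#' \code{zenith_radiance}). The direct solar beam is excluded; it is a
#' separate delta term handled by [irradiance()].
#'
#' @param sky a [sky_model()].
#' @param direction unit 3-vector or n x 3 matrix of unit rows; all rows
#'   must be strictly above the horizon.
#' @return radiance value(s), same length as the number of directions.
#' @export
sky_radiance <- function(sky, direction) {
  d <- as_direction_matrix(direction)
  if (any(d[, 3] <= 0))
    stop("sky_radiance is defined above the horizon only; ",
         "use environment_radiance for full-sphere queries")
  sky$zenith_radiance * cie_relative_radiance(sky, d)
}

# Constant ground radiance: single bounce of the total horizontal
# irradiance (sun + sky; an up-facing patch sees no ground, so one pass
# closes the coupling).
ground_radiance <- function(sky, quad = default_quadrature()) {
  if (sky$ground_albedo == 0) return(0)
  e_sun <- sky$sun_irradiance * max(0, sin(sky$sun_altitude * pi / 180))
  e_sky <- sky_cosine_integral(sky, c(0, 0, 1), quad)
  sky$ground_albedo * (e_sun + e_sky) / pi
}

#' Radiance of the full environment sphere
#'
#' Above the horizon this is the diffuse sky ([sky_radiance()]); below it is
#' the constant ground radiance, ground albedo times the total horizontal
#' irradiance over pi.
#'
#' @inheritParams sky_radiance
#' @param quad quadrature rule used to resolve the ground coupling.
#' @return radiance value(s).
#' @export
environment_radiance <- function(sky, direction, quad = default_quadrature()) {
  d <- as_direction_matrix(direction)
  out <- numeric(nrow(d))
  up <- d[, 3] > 0
  if (any(up)) out[up] <- sky_radiance(sky, d[up, , drop = FALSE])
  if (any(!up)) out[!up] <- ground_radiance(sky, quad)
  out
}

# Cosine-weighted integral of the *sky dome only* over the hemisphere above
# unit normal n: int L_sky(w) max(0, n.w) dw. Each elevation ring around n
# is clipped analytically to the part above the world horizon, so the
# quadrature never straddles the sky/ground discontinuity.
sky_cosine_integral <- function(sky, n, quad) {
  if (sky$zenith_radiance == 0) return(0)
  fr <- orthonormal_frame(n)
  t1 <- fr$t1; t2 <- fr$t2
  r <- sqrt(max(0, 1 - n[3]^2))
  phi0 <- atan2(t2[3], t1[3])          # ring azimuth of maximal world z
  A <- quad$cp * n[3]
  B <- quad$sp * r
  c0 <- ifelse(B > 1e-14, -A / B, ifelse(A > 0, -1, 1))
  theta_m <- acos(pmin(pmax(c0, -1), 1))  # half-width of the sky arc
  keep <- theta_m > 1e-12
  if (!any(keep)) return(0)
  cp <- quad$cp[keep]; sp <- quad$sp[keep]
  w  <- quad$w[keep];  tm <- theta_m[keep]
  n_az <- quad$n_az
  # midpoint azimuth nodes on the sky arc of each ring
  frac <- (seq_len(n_az) - 0.5) / n_az          # in (0, 1)
  theta <- outer(2 * frac - 1, tm)              # n_az x n_ring, in (-tm, tm)
  phi <- phi0 + theta
  cpm <- matrix(cp, n_az, length(cp), byrow = TRUE)
  spm <- matrix(sp, n_az, length(sp), byrow = TRUE)
  dx <- cpm * n[1] + spm * (cos(phi) * t1[1] + sin(phi) * t2[1])
  dy <- cpm * n[2] + spm * (cos(phi) * t1[2] + sin(phi) * t2[2])
  dz <- cpm * n[3] + spm * (cos(phi) * t1[3] + sin(phi) * t2[3])
  L <- cie_relative_radiance(sky, cbind(c(dx), c(dy), c(dz)))
  ring <- colSums(matrix(L, n_az)) * (2 * tm / n_az)
  sky$zenith_radiance * sum(w * cp * sp * ring)
}

#' Irradiance on an oriented Lambertian patch
#'
#' Total irradiance on a patch of unit normal \code{normal}: the direct beam
#' (cosine-weighted, clamped at grazing), the diffuse sky integrated over
#' the visible part of the dome by the product quadrature rule, and the
#' ground term, whose cosine-weighted solid angle has the closed form
#' \code{pi * (1 - nz) / 2}. No occlusion: bodies are assumed convex and
#' cast no shadows on one another, matching a scene arranged to avoid
#' shadow cues.
#'
#' @param sky a [sky_model()].
#' @param normal unit 3-vector or n x 3 matrix of unit patch normals.
#' @param quad a [hemisphere_quadrature()] rule.
#' @return irradiance value(s) (>= 0), one per normal.
#' @examples
#' sky <- sky_model()
#' irradiance(sky, c(0, 0, 1))   # horizontal, up-facing patch
#' @export
irradiance <- function(sky, normal, quad = default_quadrature()) {
  n <- as_direction_matrix(normal, what = "normal")
  lg <- ground_radiance(sky, quad)
  e_sun <- sky$sun_irradiance * pmax(0, drop(n %*% sky$sun_direction))
  e_sky <- vapply(seq_len(nrow(n)),
                  function(i) sky_cosine_integral(sky, n[i, ], quad),
                  numeric(1))
  e_ground <- lg * pi * (1 - n[, 3]) / 2
  unname(e_sun + e_sky + e_ground)
}

#' Read or write a light-field configuration
#'
#' Plain-text (YAML) round trip for a [sky_model()], recording the sun
#' position and irradiance, the sky coefficients, the zenith radiance and
#' the ground albedo.
#'
#' @param sky a \code{sky_model}.
#' @param path file path.
#' @return \code{read_sky_config} returns a \code{sky_model};
#'   \code{write_sky_config} returns \code{path} invisibly.
#' @export
write_sky_config <- function(sky, path) {
  stopifnot(inherits(sky, "sky_model"))
  yaml::write_yaml(list(
    sun_azimuth = sky$sun_azimuth, sun_altitude = sky$sun_altitude,
    sun_irradiance = sky$sun_irradiance, sky_type = sky$sky_type,
    sky_coefficients = as.list(sky$sky_coefficients),
    zenith_radiance = sky$zenith_radiance,
    ground_albedo = sky$ground_albedo), path)
  invisible(path)
}

#' @rdname write_sky_config
#' @export
read_sky_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sky_model(sun_azimuth = cfg$sun_azimuth, sun_altitude = cfg$sun_altitude,
            sky_coefficients = unlist(cfg$sky_coefficients),
            zenith_radiance = cfg$zenith_radiance,
            sun_irradiance = cfg$sun_irradiance,
            ground_albedo = cfg$ground_albedo)
}
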