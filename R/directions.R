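#' Unit directions in the world frame
#'
#' The world frame is right-handed with \code{z} pointing up. Azimuth is
#' measured clockwise from +y ("north") when seen from above, so azimuth 90
#' degrees is +x ("east"). Elevation is measured from the horizon, positive
#' upwards.
#'
#' @param azimuth azimuth in degrees (0--360, clockwise from north).
#' @param elevation elevation in degrees (-90--90, 0 at the horizon).
#' @return a numeric matrix with one unit row vector (x, y, z) per input
#'   angle pair.
#' @examples
#' direction_from_angles(270, 45)  # the default sun direction
#' @export
direction_from_angles <- function(azimuth, elevation) {
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  cbind(x = sin(az) * cos(el), y = cos(az) * cos(el), z = sin(el))
}

# Coerce a length-3 vector or n x 3 matrix to an n x 3 matrix of unit rows.
# Non-unit rows are an error: directions and normals must arrive normalized.
as_direction_matrix <- function(direction, tol = 1e-8, what = "direction") {
  if (is.null(dim(direction))) {
    if (length(direction) != 3L)
      stop(what, " must be a 3-vector or an n x 3 matrix")
    direction <- matrix(direction, nrow = 1L)
  }
  direction <- as.matrix(direction)
  if (ncol(direction) != 3L)
    stop(what, " must have 3 columns (x, y, z)")
  nrm <- sqrt(rowSums(direction^2))
  if (any(abs(nrm - 1) > tol))
    stop("non-unit ", what, ": |norm - 1| up to ",
         format(max(abs(nrm - 1))), " exceeds tolerance ", format(tol))
  direction
}

# An orthonormal frame (tangent, bitangent) completing the unit vector n.
orthonormal_frame <- function(n) {
  a <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- a - sum(a * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so seeded helpers do not disturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
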