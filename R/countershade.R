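# Optimal countershading: invert the irradiance pattern of a body in its
# reference orientation so that every surface element returns the radiance
# of a horizontal leaf, then quantify how the apparent shading (max - min
# outgoing radiance) grows as the body departs from that orientation.

#' Radiance of a horizontal, upward-facing leaf patch
#'
#' The Lambertian radiance of an up-facing horizontal patch with the leaf
#' albedo: \code{albedo * irradiance(up) / pi}. This is the constant
#' radiance the optimally countershaded body matches in its reference
#' orientation, and the radiance of the backdrop and ground plane in the
#' search stimuli.
#'
#' @param sky a [sky_model()].
#' @param leaf_albedo Lambertian albedo of the leaves, in (0, 1].
#' @param quad quadrature rule.
#' @return a radiance scalar.
#' @export
leaf_reference_radiance <- function(sky, leaf_albedo = 0.5,
                                    quad = default_quadrature()) {
  if (leaf_albedo <= 0 || leaf_albedo > 1)
    stop("leaf_albedo must lie in (0, 1]")
  leaf_albedo * irradiance(sky, c(0, 0, 1), quad) / pi
}

#' Optimal countershading reflectance for the reference orientation
#'
#' Per-face albedo inverting the irradiance pattern:
#' \code{albedo = pi * rad_hor_leaf / irradiance(face normal)}. A body
#' painted this way and lit in the reference orientation returns the same
#' radiance \code{rad_hor_leaf} from every face — zero apparent shading.
#' Faces turned far from the light may demand albedo > 1 (not physically
#' realisable as a reflectance); by default the map is left unclamped with
#' a warning, which keeps the flatness identity exact. With
#' \code{clamp = TRUE} such faces are clipped to 1 and the flatness breaks
#' on the darkest faces.
#'
#' @param mesh a \code{tri_mesh} in the reference orientation.
#' @param sky a [sky_model()].
#' @param rad_hor_leaf target radiance, usually [leaf_reference_radiance()].
#' @param quad quadrature rule.
#' @param clamp clip albedo at 1?
#' @param tol faces with irradiance below \code{tol * max(irradiance)} are
#'   an error (they would need unbounded albedo).
#' @return a \code{reflectance_map}: list with per-face \code{albedo} and
#'   the \code{clamped} flag.
#' @export
optimal_reflectance <- function(mesh, sky, rad_hor_leaf,
                                quad = default_quadrature(),
                                clamp = FALSE, tol = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (rad_hor_leaf <= 0) stop("rad_hor_leaf must be > 0")
  irr <- irradiance(sky, mesh$normals, quad)
  bad <- which(irr <= tol * max(irr))
  if (length(bad))
    stop("face(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " receive (near-)zero irradiance; optimal albedo would be unbounded")
  albedo <- pi * rad_hor_leaf / irr
  if (clamp) {
    albedo <- pmin(albedo, 1)
  } else if (any(albedo > 1)) {
    warning(sum(albedo > 1), " face(s) demand albedo > 1; ",
            "map left unclamped (flatness preserved)")
  }
  structure(list(albedo = albedo, clamped = clamp), class = "reflectance_map")
}

#' Render a reflectance-mapped body at an orientation
#'
#' Rotates the body (the reflectance pattern travels with its faces),
#' recomputes each face's irradiance under the light field, and returns the
#' Lambertian outgoing radiance \code{albedo * irradiance / pi} together
#' with a viewer-visibility flag from the back-face test.
#'
#' @param mesh a \code{tri_mesh} in the reference orientation.
#' @param refl a \code{reflectance_map} aligned to \code{mesh}'s faces, or
#'   a single albedo recycled to all faces (uniform body).
#' @param sky a [sky_model()].
#' @param orient an [orientation()].
#' @param view_direction unit vector from viewer into the scene
#'   (default +x, the viewer facing azimuth 90).
#' @param quad quadrature rule.
#' @return a \code{rendered_view}: per-face \code{radiance}, logical
#'   \code{visible}, the \code{orientation} and the rotated mesh.
#' @export
render_view <- function(mesh, refl, sky, orient = orientation(),
                        view_direction = c(1, 0, 0),
                        quad = default_quadrature()) {
  stopifnot(inherits(mesh, "tri_mesh"))
  albedo <- if (inherits(refl, "reflectance_map")) refl$albedo else
    as.numeric(refl)
  if (length(albedo) == 1L) albedo <- rep(albedo, nrow(mesh$faces))
  if (length(albedo) != nrow(mesh$faces))
    stop("reflectance map has ", length(albedo),
         " entries but the mesh has ", nrow(mesh$faces), " faces")
  if (any(albedo < 0)) stop("albedo must be >= 0")
  rot <- rotate_mesh(mesh, orient)
  irr <- irradiance(sky, rot$normals, quad)
  vd <- as_direction_matrix(view_direction)[1, ]
  structure(list(
    radiance = albedo * irr / pi,
    visible = drop(rot$normals %*% vd) < 0,
    orientation = orient,
    mesh = rot
  ), class = "rendered_view")
}

#' @export
print.rendered_view <- function(x, ...) {
  cat(sprintf(
    "Rendered view (pitch %g, roll %g, yaw %g): %d faces, %d visible\n",
    x$orientation$pitch, x$orientation$roll, x$orientation$yaw,
    length(x$radiance), sum(x$visible)))
  cat(sprintf("  radiance range [%.4g, %.4g]\n",
              min(x$radiance), max(x$radiance)))
  invisible(x)
}

#' Apparent shading of a rendered body
#'
#' The difference between the maximum and the minimum of the per-face
#' outgoing radiance — the conspicuousness proxy. By default only
#' viewer-visible faces enter (the observer sees one side of the body);
#' \code{visible_only = FALSE} uses all faces.
#'
#' @param view a \code{rendered_view}.
#' @param visible_only restrict to viewer-visible faces?
#' @return a non-negative scalar in radiance units.
#' @export
apparent_shading <- function(view, visible_only = TRUE) {
  stopifnot(inherits(view, "rendered_view"))
  r <- if (visible_only) view$radiance[view$visible] else view$radiance
  if (!length(r)) stop("no faces selected")
  max(r) - min(r)
}

#' Apparent-shading curves over orientation departures
#'
#' Renders the countershaded body at each departure level along each axis
#' (pitch, roll, yaw; the other two angles held at 0), computes the
#' apparent shading, and normalizes all values by one shared factor so the
#' global maximum is exactly 1.
#'
#' @param mesh a \code{tri_mesh} in the reference orientation.
#' @param refl the body's \code{reflectance_map} (the optimal map for the
#'   reference orientation, for the standard curves).
#' @param sky a [sky_model()].
#' @param axes subset of \code{c("pitch", "roll", "yaw")}.
#' @param levels departure angles in degrees.
#' @param visible_only passed to [apparent_shading()].
#' @param quad quadrature rule.
#' @return a data frame of class \code{shading_curve} with columns
#'   \code{axis}, \code{angle}, \code{raw}, \code{normalized}.
#' @examples
#' \donttest{
#' sky <- sky_model()
#' mesh <- make_ellipsoid(subdivision = 2)
#' refl <- optimal_reflectance(mesh, sky, leaf_reference_radiance(sky))
#' shading_curves(mesh, refl, sky, quad = hemisphere_quadrature(16, 8))
#' }
#' @export
shading_curves <- function(mesh, refl, sky,
                           axes = c("pitch", "roll", "yaw"),
                           levels = c(0, 15, 30, 45, 90),
                           visible_only = TRUE,
                           quad = default_quadrature()) {
  axes <- match.arg(axes, several.ok = TRUE)
  grid <- expand.grid(axis = axes, angle = levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$raw <- vapply(seq_len(nrow(grid)), function(i) {
    args <- list(pitch = 0, roll = 0, yaw = 0)
    args[[grid$axis[i]]] <- grid$angle[i]
    ori <- do.call(orientation, args)
    apparent_shading(render_view(mesh, refl, sky, ori, quad = quad),
                     visible_only = visible_only)
  }, numeric(1))
  top <- max(grid$raw)
  if (top <= 0) stop("all shading values are zero: degenerate light field")
  grid$normalized <- grid$raw / top
  grid <- grid[order(match(grid$axis, axes), grid$angle), ]
  rownames(grid) <- NULL
  class(grid) <- c("shading_curve", "data.frame")
  grid
}

#' Look up normalized shading by level for one axis
#'
#' Convenience accessor turning a [shading_curves()] table into the named
#' vector (level -> normalized shading) consumed by [simulate_trials()].
#'
#' @param curves a \code{shading_curve} data frame.
#' @param axis one of \code{"pitch"}, \code{"roll"}, \code{"yaw"}.
#' @return named numeric vector of normalized shading values.
#' @export
shading_lookup <- function(curves, axis = c("pitch", "roll", "yaw")) {
  axis <- match.arg(axis)
  sub <- curves[curves$axis == axis, ]
  stats::setNames(sub$normalized, sub$angle)
}
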