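# Triangle-mesh bodies: the ellipsoidal target ("caterpillar") and the
# flattened, folded leaf distractors, plus rigid pitch/roll/yaw posing.
#
# Frame convention: meshes are built in world coordinates at the reference
# pose (pitch = roll = yaw = 0). The body long axis (semi_axes[1]) lies
# along world y (fronto-parallel to a viewer looking along +x, azimuth 90),
# the depth axis (semi_axes[2]) along world x, and the vertical axis
# (semi_axes[3]) along world z.

new_tri_mesh <- function(vertices, faces) {
  mesh <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  update_face_geometry(mesh)
}

update_face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))
  if (any(len <= 0)) stop("degenerate face with zero area")
  mesh$normals <- cr / len
  mesh$areas <- len / 2
  mesh$centroids <- (p1 + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces, total area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$areas)))
  invisible(x)
}

# Unit icosphere: icosahedron subdivided `subdivision` times, vertices
# projected to the unit sphere. Outward winding.
unit_icosphere <- function(subdivision) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivision)) {
    mids <- new.env()
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- mids[[key]]
      if (is.null(idx)) {
        m <- (verts[i, ] + verts[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        idx <- nrow(verts)
        mids[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  # enforce outward winding (convex body centred at the origin)
  for (k in seq_len(nrow(f))) {
    p1 <- v[f[k, 1], ]; p2 <- v[f[k, 2], ]; p3 <- v[f[k, 3], ]
    nrm <- pracma::cross(p2 - p1, p3 - p1)
    if (sum(nrm * (p1 + p2 + p3)) < 0) f[k, ] <- f[k, c(1L, 3L, 2L)]
  }
  list(vertices = v, faces = f)
}

#' Ellipsoidal target mesh
#'
#' Icosphere-subdivision triangle mesh scaled to an ellipsoid. The default
#' semi-axes (60, 20, 20) mm give the 120 mm long, 40 mm wide target body;
#' the long semi-axis lies along world y at the reference pose.
#'
#' @param semi_axes positive semi-axis lengths in mm: long, depth, vertical.
#' @param subdivision icosphere subdivision level (>= 1); the mesh has
#'   \code{20 * 4^subdivision} faces.
#' @return a \code{tri_mesh} with per-face unit outward normals, areas (mm^2)
#'   and centroids.
#' @examples
#' mesh <- make_ellipsoid()          # 1280 faces at subdivision 3
#' sum(mesh$areas)                   # total surface area, mm^2
#' @export
make_ellipsoid <- function(semi_axes = c(60, 20, 20), subdivision = 3) {
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (subdivision < 1) stop("subdivision must be >= 1")
  ico <- unit_icosphere(subdivision)
  v <- cbind(ico$vertices[, 1] * semi_axes[2],   # depth  -> world x
             ico$vertices[, 2] * semi_axes[1],   # long   -> world y
             ico$vertices[, 3] * semi_axes[3])   # height -> world z
  mesh <- new_tri_mesh(v, ico$faces)
  mesh$semi_axes <- semi_axes
  mesh
}

#' Leaf distractor mesh
#'
#' Starts from the target ellipsoid, flattens the depth semi-axis by
#' \code{flatten_ratio}, folds the two lateral halves about the long axis,
#' and rescales the vertical extent so the projected outline on the viewing
#' plane matches the unfolded ellipse (distractors and target share the
#' same 2D screen shape).
#'
#' The fold turns the sheet about the long axis so that the surface
#' tangents at the two lateral extremes form a total dihedral of
#' \code{fold_angle}. In the default smooth mode ("curved along the long
#' axis") the cross-section is bent onto a circular arc: the tangent turns
#' linearly with the lateral offset, reaching \code{fold_angle / 2} at each
#' extreme. In \code{crease} mode each half is rotated rigidly by
#' \code{fold_angle / 2}, a sharp fold with the same extreme dihedral.
#'
#' @inheritParams make_ellipsoid
#' @param flatten_ratio scale of the depth semi-axis, in (0, 1].
#' @param fold_angle fold dihedral in degrees, in [0, 90).
#' @param crease logical; sharp fold instead of smooth curvature.
#' @return a \code{tri_mesh}.
#' @export
make_leaf <- function(semi_axes = c(60, 20, 20), flatten_ratio = 0.1,
                      fold_angle = 20, subdivision = 3, crease = FALSE) {
  if (flatten_ratio <= 0 || flatten_ratio > 1)
    stop("flatten_ratio must lie in (0, 1]")
  if (fold_angle < 0 || fold_angle >= 90)
    stop("fold_angle must lie in [0, 90) degrees")
  mesh <- make_ellipsoid(semi_axes, subdivision)
  v <- mesh$vertices
  v[, 1] <- v[, 1] * flatten_ratio
  if (fold_angle > 0) {
    zmax <- max(abs(v[, 3]))
    if (crease) {
      beta <- sign(v[, 3]) * (fold_angle / 2) * pi / 180
      x <- v[, 1] * cos(beta) + v[, 3] * sin(beta)
      z <- -v[, 1] * sin(beta) + v[, 3] * cos(beta)
    } else {
      # circular-arc bend: tangent turns linearly with lateral offset,
      # by fold_angle / 2 at each extreme (curvature c rad/mm)
      cc <- (fold_angle / 2) * pi / 180 / zmax
      alpha <- cc * v[, 3]
      x <- (1 - cos(alpha)) / cc + v[, 1] * cos(alpha)
      z <- sin(alpha) / cc - v[, 1] * sin(alpha)
    }
    v[, 1] <- x
    v[, 3] <- z
    # restore the projected outline: rescale the vertical extent
    v[, 3] <- v[, 3] * zmax / max(abs(v[, 3]))
  }
  mesh$vertices <- v
  mesh <- update_face_geometry(mesh)
  mesh$semi_axes <- semi_axes
  mesh
}

#' Body orientation as pitch, roll and yaw
#'
#' Pitch tilts the long axis vertically (positive nose-up, -90 to 90 deg),
#' roll spins the body about its long axis (-180 to 180 deg), and yaw
#' rotates it about the world vertical (-180 to 180 deg). The reference
#' orientation is (0, 0, 0): body horizontal, long axis fronto-parallel.
#'
#' @param pitch,roll,yaw angles in degrees.
#' @return an \code{orientation} object.
#' @export
orientation <- function(pitch = 0, roll = 0, yaw = 0) {
  if (pitch < -90 || pitch > 90) stop("pitch must lie in [-90, 90] degrees")
  if (roll <= -180 || roll > 180) stop("roll must lie in (-180, 180] degrees")
  if (yaw <= -180 || yaw > 180) stop("yaw must lie in (-180, 180] degrees")
  structure(list(pitch = pitch, roll = roll, yaw = yaw), class = "orientation")
}

#' @export
print.orientation <- function(x, ...) {
  cat(sprintf("Orientation: pitch %g, roll %g, yaw %g (degrees)\n",
              x$pitch, x$roll, x$yaw))
  invisible(x)
}

# Wrap an arbitrary (pitch, roll, yaw) triple into the canonical ranges,
# using the equivalence (p, r, y) ~ (180 - p, r + 180, y + 180). Needed for
# leaf pitch drawn uniformly on [-180, 180].
wrap_orientation <- function(pitch, roll, yaw) {
  wrap180 <- function(a) {
    a <- (a + 180) %% 360 - 180
    ifelse(a == -180, 180, a)
  }
  pitch <- wrap180(pitch)
  flip <- abs(pitch) > 90
  pitch <- ifelse(flip, sign(pitch) * 180 - pitch, pitch)
  roll <- wrap180(ifelse(flip, roll + 180, roll))
  yaw <- wrap180(ifelse(flip, yaw + 180, yaw))
  orientation(pitch, roll, yaw)
}

rotation_matrix <- function(orientation) {
  p <- orientation$pitch * pi / 180
  r <- orientation$roll * pi / 180
  y <- orientation$yaw * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  ry <- rbind(c(cos(r), 0, sin(r)), c(0, 1, 0), c(-sin(r), 0, cos(r)))
  rz <- rbind(c(cos(y), -sin(y), 0), c(sin(y), cos(y), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rigid rotation of a mesh to a pose
#'
#' Rotates the mesh about its centroid. Rotations compose intrinsically in
#' the order roll (about the body long axis), then pitch (about the body
#' lateral axis), then yaw (about the world vertical); since every
#' experimental condition varies a single angle from the reference pose,
#' the order matters only for combined poses. Normals and areas are
#' recomputed.
#'
#' @param mesh a \code{tri_mesh}.
#' @param orient an [orientation()].
#' @return the rotated \code{tri_mesh}.
#' @export
rotate_mesh <- function(mesh, orient) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(orient, "orientation"))
  R <- rotation_matrix(orient)
  ctr <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2, ctr)
  mesh$vertices <- v %*% t(R) + matrix(ctr, nrow(v), 3, byrow = TRUE)
  update_face_geometry(mesh)
}

#' Mesh file export and import (ASCII OBJ / PLY)
#'
#' Plain-text OBJ or PLY, 1 unit = 1 mm, z up.
#'
#' @param mesh a \code{tri_mesh}.
#' @param path file path.
#' @return the path (write) or a \code{tri_mesh} (read).
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tri_mesh export, units mm, z up", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  new_tri_mesh(v, f)
}

#' @rdname write_obj
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment tri_mesh export, units mm, z up",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
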