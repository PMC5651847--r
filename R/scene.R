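# Visual-search stimuli: one countershaded (or uniform) target among 20 or
# 40 leaf distractors on a fronto-parallel stimulus plane, rendered with a
# flat-shaded orthographic rasterizer and tone-mapped for display.

#' Sample a visual-search scene
#'
#' Draws item positions i.i.d. uniformly on the square stimulus plane and
#' keeps the whole draw only when every pairwise centre distance is at
#' least \code{separation} leaf lengths (whole-scene rejection; per-item
#' resampling would bias the spatial distribution). Leaf orientations are
#' drawn as roll ~ Normal(0, 50 deg), yaw ~ Normal(0, 10 deg), pitch ~
#' Uniform(-180, 180) wrapped into the canonical pitch range, and leaf fold
#' angles as Normal(20, 20) deg truncated to [0, 90). The target is the
#' reference orientation with \code{target_angle} applied on
#' \code{target_axis}.
#'
#' @param seed integer seed (the scene is fully reproducible from it).
#' @param n_distractors 20 or 40 leaves.
#' @param target_axis departure axis: \code{"pitch"}, \code{"roll"} or
#'   \code{"yaw"}.
#' @param target_angle departure angle in degrees.
#' @param condition target coloration: \code{"countershaded"} (the optimal
#'   map for the reference orientation) or \code{"uniform"}.
#' @param plane_side side of the square stimulus plane in mm. The default
#'   (30 item lengths) keeps whole-scene rejection tractable at 41 items
#'   with the 1.3-length separation.
#' @param item_length leaf/target long-axis length in mm.
#' @param separation minimum pairwise centre distance in leaf lengths.
#' @param max_attempts whole-scene rejection budget.
#' @return a \code{scene_spec}: item data frame (role, position, pose,
#'   fold angle) plus the scene parameters.
#' @export
sample_scene <- function(seed, n_distractors = 20,
                         target_axis = c("pitch", "roll", "yaw"),
                         target_angle = 0,
                         condition = c("countershaded", "uniform"),
                         plane_side = 3600, item_length = 120,
                         separation = 1.3, max_attempts = 1e4) {
  target_axis <- match.arg(target_axis)
  condition <- match.arg(condition)
  if (!n_distractors %in% c(20L, 40L))
    stop("n_distractors must be 20 or 40")
  n_items <- n_distractors + 1L
  min_dist <- separation * item_length
  with_seed(seed, {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      px <- stats::runif(n_items, 0, plane_side)
      py <- stats::runif(n_items, 0, plane_side)
      if (n_items < 2 || min(stats::dist(cbind(px, py))) >= min_dist) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("whole-scene rejection budget (", max_attempts, " attempts) ",
           "exhausted; use a larger plane_side or fewer items")
    roll <- stats::rnorm(n_distractors, 0, 50)
    yaw <- stats::rnorm(n_distractors, 0, 10)
    pitch <- stats::runif(n_distractors, -180, 180)
    fold <- stats::rnorm(n_distractors, 20, 20)
    while (any(bad <- fold < 0 | fold >= 90))
      fold[bad] <- stats::rnorm(sum(bad), 20, 20)
    leaf_pose <- Map(wrap_orientation, pitch, roll, yaw)
    tgt <- list(pitch = 0, roll = 0, yaw = 0)
    tgt[[target_axis]] <- target_angle
    items <- data.frame(
      role = c("target", rep("leaf", n_distractors)),
      x = px - plane_side / 2,       # centred plane coordinates (mm)
      y = py - plane_side / 2,
      pitch = c(tgt$pitch, vapply(leaf_pose, `[[`, numeric(1), "pitch")),
      roll = c(tgt$roll, vapply(leaf_pose, `[[`, numeric(1), "roll")),
      yaw = c(tgt$yaw, vapply(leaf_pose, `[[`, numeric(1), "yaw")),
      fold_angle = c(NA_real_, fold),
      stringsAsFactors = FALSE)
    structure(list(items = items, n_distractors = n_distractors,
                   target_axis = target_axis, target_angle = target_angle,
                   condition = condition, plane_side = plane_side,
                   item_length = item_length, separation = separation,
                   seed = seed),
              class = "scene_spec")
  })
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "Scene (seed %d): %s target (%s %g deg) + %d leaves on %g mm plane\n",
    x$seed, x$condition, x$target_axis, x$target_angle, x$n_distractors,
    x$plane_side))
  invisible(x)
}

# Rasterize triangles onto an existing z-buffered image. img and zbuf are
# res x res matrices; row 1 = top of the image (+z), columns run along +y.
# depth = world x (smaller is nearer the viewer at -x looking along +x).
rasterize_mesh <- function(img, zbuf, mesh, radiance, plane_side, res) {
  px_of <- function(y) (y + plane_side / 2) / plane_side * res + 0.5
  v <- mesh$vertices
  cx <- px_of(v[, 2])            # image column from world y
  cy <- res + 1 - px_of(v[, 3])  # image row from world z (top = +z)
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    x1 <- cx[f[1]]; x2 <- cx[f[2]]; x3 <- cx[f[3]]
    y1 <- cy[f[1]]; y2 <- cy[f[2]]; y3 <- cy[f[3]]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    if (abs(det) < 1e-12) next
    lo_c <- max(1L, floor(min(x1, x2, x3)))
    hi_c <- min(res, ceiling(max(x1, x2, x3)))
    lo_r <- max(1L, floor(min(y1, y2, y3)))
    hi_r <- min(res, ceiling(max(y1, y2, y3)))
    if (lo_c > hi_c || lo_r > hi_r) next
    cc <- lo_c:hi_c
    rr <- lo_r:hi_r
    pc <- rep(cc, each = length(rr))
    pr <- rep(rr, length(cc))
    w2 <- ((pc - x1) * (y3 - y1) - (x3 - x1) * (pr - y1)) / det
    w3 <- ((x2 - x1) * (pr - y1) - (pc - x1) * (y2 - y1)) / det
    w1 <- 1 - w2 - w3
    inside <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(inside)) next
    depth <- w1 * v[f[1], 1] + w2 * v[f[2], 1] + w3 * v[f[3], 1]
    idx <- pr + (pc - 1L) * res
    idx <- idx[inside]
    depth <- depth[inside]
    closer <- depth < zbuf[idx]
    idx <- idx[closer]
    zbuf[idx] <- depth[closer]
    img[idx] <- radiance[k]
  }
  list(img = img, zbuf = zbuf)
}

#' Render a scene to a linear-radiance raster
#'
#' Flat-shaded, depth-buffered orthographic rasterization of the scene: one
#' radiance per face (\code{albedo * irradiance / pi}), no cast shadows or
#' inter-reflections, viewer looking along +x. Background (backdrop and
#' ground plane) is filled with the horizontal-leaf radiance.
#'
#' @param scene a [sample_scene()] result.
#' @param sky a [sky_model()].
#' @param resolution raster side in pixels.
#' @param leaf_albedo albedo of leaves, backdrop and the uniform target.
#' @param target_subdivision,leaf_subdivision mesh resolutions.
#' @param quad quadrature rule (scene rendering tolerates a coarser rule
#'   than the shading statistics; radiances enter only as an image).
#' @return an \code{image_raster}: \code{values} matrix (linear radiance),
#'   \code{pixel_size_mm}, and \code{linear = TRUE}.
#' @export
render_scene <- function(scene, sky, resolution = 256, leaf_albedo = 0.5,
                         target_subdivision = 3, leaf_subdivision = 2,
                         quad = hemisphere_quadrature(32, 16)) {
  stopifnot(inherits(scene, "scene_spec"))
  # 120 mm long, 40 mm wide at the default item_length
  semi <- c(scene$item_length / 2, scene$item_length / 6,
            scene$item_length / 6)
  rhl <- leaf_reference_radiance(sky, leaf_albedo, quad)
  target <- make_ellipsoid(semi, target_subdivision)
  target_refl <- if (scene$condition == "countershaded") {
    suppressWarnings(optimal_reflectance(target, sky, rhl, quad))
  } else {
    structure(list(albedo = rep(leaf_albedo, nrow(target$faces)),
                   clamped = TRUE), class = "reflectance_map")
  }
  img <- matrix(rhl, resolution, resolution)
  zbuf <- matrix(Inf, resolution, resolution)
  for (i in seq_len(nrow(scene$items))) {
    it <- scene$items[i, ]
    if (it$role == "target") {
      mesh <- target
      albedo <- target_refl$albedo
    } else {
      mesh <- make_leaf(semi, fold_angle = it$fold_angle,
                        subdivision = leaf_subdivision)
      albedo <- rep(leaf_albedo, nrow(mesh$faces))
    }
    mesh <- rotate_mesh(mesh, orientation(it$pitch, it$roll, it$yaw))
    irr <- irradiance(sky, mesh$normals, quad)
    radiance <- albedo * irr / pi
    mesh$vertices[, 2] <- mesh$vertices[, 2] + it$x
    mesh$vertices[, 3] <- mesh$vertices[, 3] + it$y
    out <- rasterize_mesh(img, zbuf, mesh, radiance,
                          scene$plane_side, resolution)
    img <- out$img
    zbuf <- out$zbuf
  }
  structure(list(values = img,
                 covered = is.finite(zbuf),   # pixels hit by any item
                 pixel_size_mm = scene$plane_side / resolution,
                 linear = TRUE),
            class = "image_raster")
}

#' @export
print.image_raster <- function(x, ...) {
  cat(sprintf("Image raster %d x %d (%s), values in [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values),
              if (x$linear) "linear radiance" else "display",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Tone-map a linear raster for display
#'
#' Rescales so the 99th-percentile pixel maps to 1, then clips values above
#' 1 — the high-dynamic-range to display mapping used for the stimuli.
#'
#' @param raster a linear \code{image_raster}.
#' @return an \code{image_raster} with display values in [0, 1].
#' @export
tone_map <- function(raster) {
  stopifnot(inherits(raster, "image_raster"))
  if (!raster$linear) stop("raster is already tone-mapped")
  if (all(raster$values == 0)) stop("all-zero raster cannot be tone-mapped")
  q99 <- stats::quantile(raster$values, 0.99, names = FALSE)
  raster$values <- pmin(raster$values / q99, 1)
  raster$linear <- FALSE
  raster
}

#' Write a raster image
#'
#' Display rasters go to PNG (8 or 16 bit); linear rasters to 32-bit float
#' TIFF.
#'
#' @param raster an \code{image_raster}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "image_raster"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (raster$linear)
      stop("tone_map() the raster before writing PNG")
    png::writePNG(raster$values, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(pmin(raster$values / max(raster$values), 1),
                    path, bits.per.sample = 32L)
  } else stop("unsupported image format: use .png or .tif(f)")
  invisible(path)
}

#' Balanced trial design
#'
#' 200 trials per participant session: each departure level appears equally
#' often, and within each level the two distractor set sizes are balanced
#' (40 trials per level, 20 per level-by-set-size cell at the defaults).
#' Trial order is shuffled by the seed; each trial carries its own scene
#' seed.
#'
#' @param seed integer seed.
#' @param levels departure levels in degrees.
#' @param set_sizes distractor counts.
#' @param n_trials total trials; must be divisible by
#'   \code{length(levels) * length(set_sizes)}.
#' @return a \code{trial_design} data frame: \code{trial}, \code{level},
#'   \code{n_distractors}, \code{scene_seed}.
#' @export
make_design <- function(seed, levels = c(0, 15, 30, 45, 90),
                        set_sizes = c(20, 40), n_trials = 200) {
  n_cells <- length(levels) * length(set_sizes)
  if (n_trials %% n_cells != 0)
    stop("n_trials (", n_trials, ") is not divisible by the ",
         n_cells, " level x set-size cells")
  reps <- n_trials / n_cells
  grid <- expand.grid(level = levels, n_distractors = set_sizes,
                      KEEP.OUT.ATTRS = FALSE)
  design <- grid[rep(seq_len(nrow(grid)), reps), ]
  with_seed(seed, {
    design <- design[sample.int(nrow(design)), ]
    design$scene_seed <- sample.int(.Machine$integer.max - 1L, n_trials)
  })
  design$trial <- seq_len(n_trials)
  rownames(design) <- NULL
  design <- design[, c("trial", "level", "n_distractors", "scene_seed")]
  class(design) <- c("trial_design", "data.frame")
  design
}
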