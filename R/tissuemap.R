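#' Voxel tissue-label map
#'
#' Rasterises the phantom's analytic solids into a 3D label grid
#' (background, muscle, cortical, cancellous) around one pedicle corridor —
#' the region a drilling trajectory and its sideways-looking photoacoustic
#' scans traverse. Voxel centres sit at `origin + (index - 1) * spacing`.
#'
#' @param phantom a [make_spine_phantom()] result.
#' @param level_id level to centre the map on (e.g. "L3").
#' @param side "R" or "L" pedicle.
#' @param spacing isotropic voxel spacing in mm.
#' @param bounds optional 2x3 matrix (min row, max row) of world-coordinate
#'   bounds in mm; a corridor-covering default is derived from the geometry.
#' @param transform optional [rigid_transform()] repositioning the phantom in
#'   world coordinates before rasterisation.
#' @return An object of class `tissue_map`: list with integer `labels` array,
#'   `spacing`, `origin`, `level_id`, `side`.
#' @export
make_tissue_map <- function(phantom, level_id, side = "R", spacing = 0.1,
                            bounds = NULL, transform = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  lv <- phantom_level(phantom, level_id)
  g <- lv$geom
  sx <- if (side == "R") 1 else -1
  if (is.null(bounds)) {
    bounds <- rbind(c(sx * g$xp - 5.5, -g$block_depth - 1.5, g$z0 - 5.5),
                    c(sx * g$xp + 5.5, 22, g$z0 + 5.5))
    if (side == "L") bounds[, 1] <- sort(bounds[, 1])
    if (!is.null(transform)) {
      corners <- as.matrix(expand.grid(bounds[, 1], bounds[, 2], bounds[, 3]))
      moved <- rt_apply(transform, corners)
      bounds <- rbind(apply(moved, 2, min), apply(moved, 2, max))
    }
  }
  ax <- lapply(1:3, function(j) seq(bounds[1, j], bounds[2, j], by = spacing))
  dims <- vapply(ax, length, 1L)
  centers <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  if (!is.null(transform)) {
    centers <- rt_apply(rt_invert(transform), centers)
  }
  lab <- label_points(phantom, centers)
  structure(list(labels = array(as.integer(lab), dim = dims),
                 spacing = spacing,
                 origin = bounds[1, ],
                 level_id = level_id, side = side,
                 transform = transform),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat("tissue_map:", paste(dim(x$labels), collapse = "x"), "voxels @",
      x$spacing, "mm,", x$level_id, x$side, "\n")
  invisible(x)
}

#' Label lookup in a tissue map
#'
#' Nearest-voxel lookup; points outside the grid return background (0).
#'
#' @param map a [make_tissue_map()] result.
#' @param points Nx3 matrix of world points in mm.
#' @return Integer label codes.
#' @export
map_label_at <- function(map, points) {
  p <- as_points(points)
  idx <- sweep(p, 2, map$origin)
  idx <- round(idx / map$spacing) + 1
  d <- dim(map$labels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(tissue_labels[["background"]], nrow(p))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    out[ok] <- map$labels[lin]
  }
  out
}

#' Cast a ray through a tissue map
#'
#' Samples labels at fixed steps along a ray; used as the elementary
#' operation behind the photoacoustic endoscopy simulator and as a
#' line-to-label intersection oracle.
#'
#' @param map a [make_tissue_map()] result.
#' @param origin length-3 world start point in mm.
#' @param direction length-3 direction (normalised internally).
#' @param max_range range to march in mm.
#' @param step sampling step in mm.
#' @return data.frame with `r` (range, mm) and `label` (integer codes).
#' @export
map_raycast <- function(map, origin, direction, max_range, step = 0.05) {
  dirn <- direction / sqrt(sum(direction^2))
  r <- seq(step, max_range, by = step)
  pts <- outer(r, dirn) + matrix(origin, length(r), 3, byrow = TRUE)
  data.frame(r = r, label = map_label_at(map, pts))
}

orthonormal_plane_basis <- function(direction) {
  d <- direction / sqrt(sum(direction^2))
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
          d[1] * a[2] - d[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Drill trajectory through a pedicle
#'
#' Constructs the three canonical screw-implantation paths through a given
#' level's pedicle: the correct path (CP) runs down the pedicle axis and
#' keeps more than the 1.44 mm safe distance to cortical bone; the lateral
#' misplacement path (LMP) is offset and tilted laterally so it grazes the
#' lateral cortical wall inside the pedicle before recovering into the
#' vertebral body; the medial misplacement path (MMP) is tilted medially and
#' breaches the medial cortical wall into the spinal canal. Trajectories
#' start on the posterior bone surface; photoacoustic endoscopy frames are
#' taken every `frame_interval_s` seconds (default 30).
#'
#' @param kind one of "CP", "LMP", "MMP".
#' @param phantom a `spine_phantom`.
#' @param level_id target level id.
#' @param side "R" or "L" pedicle.
#' @return An object of class `drill_trajectory` with `kind`, `level_id`,
#'   `entry_point` (mm), `direction` (unit vector), `speed` (mm/s),
#'   `frame_interval_s`.
#' @export
make_trajectory <- function(kind, phantom, level_id, side = "R") {
  if (!kind %in% c("CP", "LMP", "MMP")) {
    stop("kind must be one of CP, LMP, MMP")
  }
  lv <- phantom_level(phantom, level_id)
  g <- lv$geom
  sx <- if (side == "R") 1 else -1
  y0 <- -g$block_depth
  deg <- pi / 180
  if (kind == "CP") {
    entry <- c(sx * g$xp, y0, g$z0)
    dir <- c(0, 1, 0)
    speed <- 0.12
  } else if (kind == "LMP") {
    entry <- c(sx * (g$xp + 0.55), y0, g$z0)
    dir <- c(sx * sin(1.5 * deg), cos(1.5 * deg), 0)
    speed <- 0.12
  } else {
    entry <- c(sx * g$xp, y0, g$z0)
    dir <- c(-sx * sin(5 * deg), cos(5 * deg), 0)
    speed <- 0.09
  }
  structure(list(kind = kind, level_id = level_id, side = side,
                 entry_point = entry, direction = dir / sqrt(sum(dir^2)),
                 speed = speed, frame_interval_s = 30),
            class = "drill_trajectory")
}

#' @export
print.drill_trajectory <- function(x, ...) {
  cat(sprintf("drill_trajectory %s on %s (%s pedicle), %.2f mm/s\n",
              x$kind, x$level_id, x$side, x$speed))
  invisible(x)
}

#' Drill tip position at a given time
#'
#' @param trajectory a [make_trajectory()] result.
#' @param t_s time since entry in seconds (vectorised).
#' @return Nx3 matrix of tip positions in mm.
#' @export
trajectory_tip <- function(trajectory, t_s) {
  outer(t_s * trajectory$speed, trajectory$direction) +
    matrix(trajectory$entry_point, length(t_s), 3, byrow = TRUE)
}

#' Geometric zone ground truth at a drill tip
#'
#' Reference labelling used to score the photoacoustic zone classifier: the
#' truth is what an ideal sideways-looking sensor could know. If the tip is
#' in cancellous bone, rays are cast in the plane perpendicular to the drill
#' axis against the analytic phantom; the minimum radius at which cancellous
#' gives way to cortical bone is the interface distance. Below
#' `warning_threshold` the frame is `warning`, otherwise `safe`. A tip inside
#' cortical bone is `warning` (distance 0); a tip outside bone is
#' `dangerous` (signal loss).
#'
#' @param phantom a `spine_phantom`.
#' @param tip length-3 tip position in mm.
#' @param direction drill axis direction.
#' @param depth_range sensing range in mm.
#' @param warning_threshold safe distance in mm (default 1.44).
#' @param n_rays,step angular and radial sampling of the sensing plane.
#' @return List with `zone` ("safe", "warning" or "dangerous") and
#'   `min_interface_mm` (Inf when no cortical interface is in range).
#' @export
zone_truth <- function(phantom, tip, direction, depth_range = 3,
                       warning_threshold = 1.44, n_rays = 120, step = 0.02) {
  lab0 <- label_points(phantom, matrix(tip, 1, 3))
  if (lab0 == tissue_labels[["cortical"]]) {
    return(list(zone = "warning", min_interface_mm = 0))
  }
  if (lab0 != tissue_labels[["cancellous"]]) {
    return(list(zone = "dangerous", min_interface_mm = Inf))
  }
  b <- orthonormal_plane_basis(direction)
  theta <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  radii <- seq(step, depth_range, by = step)
  dirs <- outer(cos(theta), b$e1) + outer(sin(theta), b$e2)
  pts <- kronecker(dirs, matrix(radii, ncol = 1)) +
    matrix(tip, n_rays * length(radii), 3, byrow = TRUE)
  lab <- matrix(label_points(phantom, pts), nrow = length(radii))
  dmin <- Inf
  for (j in seq_len(n_rays)) {
    change <- which(lab[, j] != tissue_labels[["cancellous"]])
    if (length(change) > 0L && lab[change[1], j] == tissue_labels[["cortical"]]) {
      dmin <- min(dmin, radii[change[1]])
    }
  }
  list(zone = if (dmin < warning_threshold) "warning" else "safe",
       min_interface_mm = dmin)
}
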