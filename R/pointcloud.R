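#' Labelled 3D point cloud
#'
#' Container for bone-surface points in mm, optionally carrying a per-point
#' spine-level label (e.g. "L3").
#'
#' @param points Nx3 numeric matrix of coordinates in mm.
#' @param level optional character/factor vector of per-point level labels.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, level = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an Nx3 matrix")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (!is.null(level) && length(level) != nrow(points)) {
    stop("level labels must match the number of points")
  }
  structure(list(points = points, level = level), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$points), "points")
  if (!is.null(x$level)) {
    cat(" | levels:", paste(unique(x$level), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# Coerce point_cloud / matrix / vector to an Nx3 coordinate matrix.
as_points <- function(x) {
  if (inherits(x, "point_cloud")) return(x$points)
  if (is.null(dim(x))) return(matrix(x, ncol = 3))
  as.matrix(x)
}

# Subset a point cloud by logical or integer index, keeping labels aligned.
pc_subset <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$level)) cloud$level[idx])
}

#' Transform a point cloud rigidly
#'
#' @param cloud a [point_cloud()].
#' @param tf a [rigid_transform()].
#' @return The transformed [point_cloud()].
#' @export
pc_transform <- function(cloud, tf) {
  point_cloud(rt_apply(tf, cloud$points), cloud$level)
}
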