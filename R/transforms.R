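#' Rigid 3D transform
#'
#' A proper rigid transform (rotation + translation) mapping points, applied
#' as rotate-then-translate: `y = R x + t`. All coordinates are in mm in a
#' right-handed frame.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
#' @examples
#' tf <- rigid_transform(rot_axis_angle(c(0, 0, 1), 30), c(5, 2, 1))
#' rt_apply(tf, matrix(c(1, 0, 0), 1, 3))
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' Rotation matrix from axis and angle
#'
#' @param axis numeric length-3 rotation axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param points Nx3 numeric matrix (or length-3 vector) of points in mm.
#' @return Nx3 matrix of transformed points.
#' @export
rt_apply <- function(tf, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points %*% t(tf$R), 2, tf$t, "+")
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform applying `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
rt_invert <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Rotation angle of a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @return Angle of the rotation component in degrees, in `[0, 180]`.
#' @export
rt_angle_deg <- function(tf) {
  R <- tf$R
  # atan2 of the skew part is numerically stable for angles near 0 and 180,
  # where acos of the trace loses precision
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(v^2)) / 2
  c_ <- (sum(diag(R)) - 1) / 2
  atan2(s, c_) * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation", sprintf("%.3f deg", rt_angle_deg(x)),
      "| translation", sprintf("(%.3f, %.3f, %.3f) mm", x$t[1], x$t[2], x$t[3]),
      "\n")
  invisible(x)
}

#' Rotation, translation and target registration error between transforms
#'
#' Measures how far an estimated rigid transform is from a reference one.
#' The rotation error is the angle of `estimate o truth^-1`; the translation
#' error is the norm of its translation part; the target registration error
#' (TRE) is the RMS displacement of the evaluation points under the two
#' transforms.
#'
#' @param estimate,truth [rigid_transform()] objects.
#' @param eval_points Nx3 matrix of evaluation points in mm (or a
#'   `point_cloud`).
#' @return List with `rotation_deg`, `translation_mm`, `tre_mm`.
#' @export
transform_error <- function(estimate, truth, eval_points) {
  pts <- as_points(eval_points)
  delta <- rt_compose(estimate, rt_invert(truth))
  d <- rt_apply(estimate, pts) - rt_apply(truth, pts)
  list(rotation_deg = rt_angle_deg(delta),
       translation_mm = sqrt(sum(delta$t^2)),
       tre_mm = sqrt(mean(rowSums(d^2))))
}
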