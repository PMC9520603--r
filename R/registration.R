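#' @name registration
#' @title Hierarchical US-to-CT point cloud registration
#' @description
#' Coarse-to-fine rigid alignment of ultrasound bone-surface point clouds to
#' per-level vertebra models: a PCA-based coarse alignment of principal axes
#' and centroids, refined by point-to-point iterative closest point (ICP)
#' run over several crop radii around the target level, keeping the radius
#' with the smallest mean-squared-error (MSE) loss.
NULL

# Mean squared nearest-neighbour distance from src to dst (mm^2, per point).
nn_mse <- function(src, dst) {
  mean(nn_search(src, dst)$d2)
}

# Least-squares rigid fit mapping src onto paired dst points (Kabsch).
kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Coarse alignment by principal component analysis
#'
#' Aligns the centroids and principal axes of two clouds. The four proper
#' rotations compatible with the axis correspondence (sign ambiguity) are
#' scored by symmetric nearest-neighbour MSE and the best is returned.
#' Near-isotropic clouds (largest/smallest eigenvalue ratio below 1.1 in
#' either cloud) set an `ambiguous` attribute on the result.
#'
#' @param src,dst [point_cloud()]s (or Nx3 matrices) with at least 3
#'   non-collinear points.
#' @return A [rigid_transform()] mapping `src` onto `dst`, with logical
#'   attribute `ambiguous`.
#' @export
pca_coarse_align <- function(src, dst) {
  s <- as_points(src); d <- as_points(dst)
  if (nrow(s) < 3L || nrow(d) < 3L) stop("need at least 3 points per cloud")
  cs <- colMeans(s); cd <- colMeans(d)
  es <- eigen(stats::cov(s), symmetric = TRUE)
  ed <- eigen(stats::cov(d), symmetric = TRUE)
  if (es$values[2] < 1e-9 * es$values[1] || ed$values[2] < 1e-9 * ed$values[1]) {
    stop("degenerate geometry: point cloud is (near-)collinear")
  }
  ambiguous <- es$values[1] / es$values[3] < 1.1 || ed$values[1] / ed$values[3] < 1.1
  Vs <- es$vectors; Vd <- ed$vectors
  if (det(Vs) < 0) Vs[, 3] <- -Vs[, 3]
  if (det(Vd) < 0) Vd[, 3] <- -Vd[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL; best_score <- Inf
  for (sg in signs) {
    R <- Vd %*% diag(sg) %*% t(Vs)
    tf <- rigid_transform(R, cd - as.numeric(R %*% cs))
    fwd <- rt_apply(tf, s)
    score <- nn_mse(fwd, d) + nn_mse(d, fwd)
    if (score < best_score) { best_score <- score; best <- tf }
  }
  attr(best, "ambiguous") <- ambiguous
  best
}

#' Point-to-point iterative closest point
#'
#' Alternates nearest-neighbour correspondence with a least-squares rigid
#' update until the per-point MSE change falls below `tol` or `max_iter` is
#' reached. The reported MSE always corresponds to the returned transform,
#' and the per-iteration MSE sequence is non-increasing.
#'
#' @param src,dst [point_cloud()]s or Nx3 matrices.
#' @param init initial [rigid_transform()] (identity by default).
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the MSE change, mm^2.
#' @param gate optional correspondence distance gate in mm (off by default);
#'   when no correspondence passes the gate the result carries
#'   `status = "failed"`.
#' @param trim fraction of correspondences kept per iteration (best-ranked
#'   by distance); 1 disables trimming. Trimming makes the fit robust to
#'   outlier detections and partial overlap, and the reported MSE is then
#'   the trimmed mean.
#' @return A `registration_result`: list with `transform`, `mse` (mm^2),
#'   `iterations`, `mse_history`, `status`.
#' @export
icp <- function(src, dst, init = rigid_transform(), max_iter = 100,
                tol = 1e-6, gate = Inf, trim = 1) {
  s <- as_points(src); d <- as_points(dst)
  if (nrow(s) == 0L || nrow(d) == 0L) stop("point clouds must be non-empty")
  tf <- init
  history <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    moved <- rt_apply(tf, s)
    nn <- nn_search(moved, d)
    keep <- nn$d2 <= gate^2
    if (trim < 1 && sum(keep) > 10L) {
      cut <- stats::quantile(nn$d2[keep], trim, names = FALSE)
      keep <- keep & nn$d2 <= cut
    }
    if (!any(keep)) {
      return(structure(list(transform = tf, mse = NA_real_, iterations = iter,
                            mse_history = history, status = "failed"),
                       class = "registration_result"))
    }
    mse <- mean(nn$d2[keep])
    history <- c(history, mse)
    if (mse < tol || (iter > 1L && history[iter - 1L] - mse < tol) ||
        iter >= max_iter) {
      status <- if (iter >= max_iter && mse >= tol) "max_iter" else "converged"
      return(structure(list(transform = tf, mse = mse, iterations = iter,
                            mse_history = history, status = status),
                       class = "registration_result"))
    }
    tf <- kabsch(s[keep, , drop = FALSE], d[nn$idx[keep], , drop = FALSE])
  }
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: mse %.4g mm^2 after %d iterations (%s)",
              x$mse, x$iterations, x$status))
  if (!is.null(x$radius)) cat(sprintf(", radius %g mm", x$radius))
  cat("\n")
  invisible(x)
}

#' Radius-selective ICP against one spine level
#'
#' Crops the ultrasound cloud to candidate radii around the target level
#' centre (after applying the coarse initialisation), runs ICP against the
#' level model for each radius, and keeps the radius with the smallest MSE.
#' Radii capturing fewer than 10 points are skipped and flagged.
#'
#' @param us_cloud ultrasound bone-surface [point_cloud()].
#' @param level_model per-level model [point_cloud()].
#' @param level_center length-3 centre of the target level in model
#'   coordinates, mm.
#' @param radii positive, sorted candidate crop radii in mm.
#' @param init initial [rigid_transform()] (typically [pca_coarse_align()]).
#' @param ... further arguments to [icp()].
#' @return A `registration_result` as from [icp()], with `radius`,
#'   `per_radius_mse` (named numeric, NA for skipped radii) and
#'   `skipped_radii` fields added.
#' @export
radius_select_icp <- function(us_cloud, level_model, level_center,
                              radii = c(15, 25, 35, 50),
                              init = rigid_transform(), ...) {
  if (length(radii) == 0L || any(radii <= 0) || is.unsorted(radii)) {
    stop("radii must be a non-empty, positive, sorted vector")
  }
  s <- as_points(us_cloud)
  d <- as_points(level_model)
  coarse <- rt_apply(init, s)
  dist_c <- sqrt(rowSums(sweep(coarse, 2, level_center)^2))
  per_radius <- stats::setNames(rep(NA_real_, length(radii)), radii)
  results <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    sel <- dist_c <= radii[i]
    if (sum(sel) < 10L) next
    res <- icp(s[sel, , drop = FALSE], d, init = init, ...)
    if (res$status == "failed") next
    per_radius[i] <- res$mse
    results[[i]] <- res
  }
  if (all(is.na(per_radius))) {
    stop("insufficient points: every candidate radius captured fewer than 10 points")
  }
  best <- which.min(per_radius)
  out <- results[[best]]
  out$radius <- radii[best]
  out$per_radius_mse <- per_radius
  out$skipped_radii <- radii[is.na(per_radius)]
  out
}
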