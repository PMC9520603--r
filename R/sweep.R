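#' Simulate a freehand sweep of tracked frames
#'
#' Moves a downward-looking probe (image depth axis along world +y) across
#' the phantom's posterior surface along z, producing one tracked frame per
#' stop. Optionally the phantom is rigidly repositioned first (emulating
#' intra-operative patient motion) while the recorded poses stay in the
#' original tracker frame — exactly the situation US/CT registration has to
#' resolve.
#'
#' @param phantom a `spine_phantom`.
#' @param n_frames number of frames in the sweep.
#' @param z_range length-2 range of sweep positions in mm; defaults to the
#'   phantom's axial extent.
#' @param standoff_mm probe standoff above the most posterior surface.
#' @param n_rows,n_cols,pixel_spacing frame geometry.
#' @param seed RNG seed (advanced per frame).
#' @param motion optional [rigid_transform()] applied to the anatomy.
#' @param ... further arguments to [simulate_us_frame()].
#' @return List of [tracked_frame()]s; each carries attributes
#'   `surface_depth_mm` (per-column truth) and `nearest_level` (the level id
#'   whose axial centre is closest to the frame).
#' @export
simulate_us_sweep <- function(phantom, n_frames = 36, z_range = NULL,
                              standoff_mm = 4, n_rows = 96, n_cols = 96,
                              pixel_spacing = 0.5, seed = 1, motion = NULL,
                              ...) {
  zs <- vapply(phantom$levels, function(lv) lv$geom$z0, numeric(1))
  zext <- max(vapply(phantom$levels, function(lv) lv$geom$body_semi[3],
                     numeric(1)))
  if (is.null(z_range)) z_range <- c(min(zs) - zext, max(zs) + zext)
  depth_min <- -max(vapply(phantom$levels, function(lv) lv$geom$block_depth,
                           numeric(1)))
  y0 <- depth_min - standoff_mm
  x0 <- -(n_cols - 1) * pixel_spacing / 2
  ids <- vapply(phantom$levels, `[[`, "", "level_id")
  zpos <- seq(z_range[1], z_range[2], length.out = n_frames)
  lapply(seq_len(n_frames), function(i) {
    pose <- rigid_transform(diag(3), c(x0, y0, zpos[i]))
    sim_pose <- if (is.null(motion)) pose else rt_compose(rt_invert(motion), pose)
    fr <- simulate_us_frame(phantom, sim_pose, n_rows = n_rows,
                            n_cols = n_cols, pixel_spacing = pixel_spacing,
                            seed = derive_seed(seed, i), timestamp = i, ...)
    fr$pose <- pose
    attr(fr, "nearest_level") <- ids[which.min(abs(zpos[i] - zs))]
    fr
  })
}

#' Posterior-visible subset of a model point cloud
#'
#' Keeps the points an ultrasound probe scanning from the posterior aspect
#' (looking along +y) could actually insonate: within each lateral/axial
#' bin, only points close to the shallowest (most posterior) point survive.
#' Matching the visibility of the ultrasound cloud before PCA-based coarse
#' alignment keeps the principal frames of the two clouds comparable.
#'
#' @param cloud a [point_cloud()].
#' @param bin_mm lateral/axial bin size in mm.
#' @param tol_mm depth tolerance above the shallowest point per bin.
#' @return The filtered [point_cloud()].
#' @export
posterior_visible <- function(cloud, bin_mm = 2, tol_mm = 1.5) {
  p <- cloud$points
  key <- paste(round(p[, 1] / bin_mm), round(p[, 3] / bin_mm))
  ymin <- stats::ave(p[, 2], key, FUN = min)
  pc_subset(cloud, p[, 2] <= ymin + tol_mm)
}

#' True surface mask of a simulated frame
#'
#' Rasterises the simulator's per-column ground-truth surface depth into a
#' pixel mask (for detector training and evaluation).
#'
#' @param frame a frame from [simulate_us_frame()] / [simulate_us_sweep()].
#' @return Logical mask matching the frame image.
#' @export
true_surface_mask <- function(frame) {
  depth <- attr(frame, "surface_depth_mm")
  if (is.null(depth)) stop("frame carries no simulator ground truth")
  mask <- matrix(FALSE, nrow(frame$image), ncol(frame$image))
  rows <- round(depth / frame$pixel_spacing) + 1
  ok <- is.finite(rows) & rows >= 1 & rows <= nrow(mask)
  mask[cbind(rows[ok], which(ok))] <- TRUE
  mask
}
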