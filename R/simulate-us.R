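#' Tracked 2D ultrasound frame
#'
#' @param image numeric matrix of intensities in `[0, 1]`; rows run along
#'   depth, columns along the lateral direction.
#' @param pose [rigid_transform()] mapping image-plane coordinates (mm, pixel
#'   `[1, 1]` at the origin, z = 0) into the world frame.
#' @param pixel_spacing pixel size in mm.
#' @param timestamp acquisition time in seconds.
#' @return An object of class `tracked_frame`.
#' @export
tracked_frame <- function(image, pose, pixel_spacing, timestamp = 0) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop("frame image must be non-empty")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(image = image, pose = pose, pixel_spacing = pixel_spacing,
                 timestamp = timestamp), class = "tracked_frame")
}

# Pixel (row, col) centre in image-plane mm coordinates.
frame_pixel_coords <- function(frame, rows, cols) {
  s <- frame$pixel_spacing
  cbind((cols - 1) * s, (rows - 1) * s, 0)
}

# First intersection of a world ray with the union of phantom outer solids.
# Returns the ray parameter in mm, or Inf. Analytic: quadratics for the
# ellipsoidal body and cylindrical pedicles, slabs for the blocks.
phantom_first_hit <- function(phantom, origin, direction, max_range = 200) {
  d <- direction / sqrt(sum(direction^2))
  best <- Inf
  ray_ellipsoid <- function(center, semi) {
    o <- (origin - center) / semi
    dd <- d / semi
    a <- sum(dd^2); b <- 2 * sum(o * dd); cc <- sum(o^2) - 1
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(Inf)
    t1 <- (-b - sqrt(disc)) / (2 * a)
    if (t1 >= 0) t1 else Inf
  }
  ray_cylinder_y <- function(cx, cz, r, y0, y1) {
    # lateral wall
    a <- d[1]^2 + d[3]^2
    hits <- c()
    if (a > 1e-12) {
      ox <- origin[1] - cx; oz <- origin[3] - cz
      b <- 2 * (ox * d[1] + oz * d[3]); cc <- ox^2 + oz^2 - r^2
      disc <- b^2 - 4 * a * cc
      if (disc >= 0) {
        for (tt in (-b + c(-1, 1) * sqrt(disc)) / (2 * a)) {
          y <- origin[2] + tt * d[2]
          if (tt >= 0 && y >= y0 && y <= y1) hits <- c(hits, tt)
        }
      }
    }
    # end caps
    if (abs(d[2]) > 1e-12) {
      for (yc in c(y0, y1)) {
        tt <- (yc - origin[2]) / d[2]
        if (tt >= 0) {
          x <- origin[1] + tt * d[1]; z <- origin[3] + tt * d[3]
          if ((x - cx)^2 + (z - cz)^2 <= r^2) hits <- c(hits, tt)
        }
      }
    }
    if (length(hits) == 0L) Inf else min(hits)
  }
  ray_box <- function(lo, hi) {
    t0 <- 0; t1 <- Inf
    for (j in 1:3) {
      if (abs(d[j]) < 1e-12) {
        if (origin[j] < lo[j] || origin[j] > hi[j]) return(Inf)
      } else {
        ta <- (lo[j] - origin[j]) / d[j]; tb <- (hi[j] - origin[j]) / d[j]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
      }
    }
    if (t0 <= t1 && t0 >= 0) t0 else Inf
  }
  for (lv in phantom$levels) {
    g <- lv$geom
    z0 <- g$z0
    best <- min(best,
      ray_ellipsoid(g$body_center + c(0, 0, z0), g$body_semi),
      ray_cylinder_y(g$xp, z0, g$r_out, 0, g$ped_len),
      ray_cylinder_y(-g$xp, z0, g$r_out, 0, g$ped_len),
      ray_box(c(g$xp - g$block_half[1], -g$block_depth, z0 - g$block_half[2]),
              c(g$xp + g$block_half[1], 0, z0 + g$block_half[2])),
      ray_box(c(-g$xp - g$block_half[1], -g$block_depth, z0 - g$block_half[2]),
              c(-g$xp + g$block_half[1], 0, z0 + g$block_half[2])))
  }
  if (best > max_range) Inf else best
}

#' Simulate a tracked ultrasound frame of the phantom
#'
#' Minimal B-mode model of spinal sonography, where only the bone surface is
#' visible: each scanline (column) casts a ray into the phantom; the first
#' bone-surface crossing produces a bright ridge, everything beyond it is
#' acoustically shadowed (near-zero with an additive noise floor), and soft
#' tissue above carries multiplicative Rayleigh speckle. A probe that does
#' not face the phantom yields a frame of pure speckle.
#'
#' @param phantom a `spine_phantom`.
#' @param probe_pose [rigid_transform()] mapping image coordinates to world;
#'   the image depth axis is the pose's local +y.
#' @param n_rows,n_cols image size in pixels.
#' @param pixel_spacing pixel size in mm.
#' @param seed RNG seed for speckle and noise.
#' @param speckle_scale Rayleigh scale of the soft-tissue speckle.
#' @param noise_floor additive noise level in the shadow region.
#' @param timestamp acquisition time in seconds.
#' @return A [tracked_frame()]; the true surface depth per column (mm,
#'   `Inf` where no bone is hit) is attached as attribute `surface_depth_mm`.
#' @export
simulate_us_frame <- function(phantom, probe_pose, n_rows = 96, n_cols = 96,
                              pixel_spacing = 0.5, seed = 1,
                              speckle_scale = 0.05, noise_floor = 0.005,
                              timestamp = 0) {
  if (n_rows < 1 || n_cols < 1) stop("image size must be positive")
  depth_dir <- as.numeric(probe_pose$R %*% c(0, 1, 0))
  hits <- vapply(seq_len(n_cols), function(cc) {
    o <- rt_apply(probe_pose, c((cc - 1) * pixel_spacing, 0, 0))[1, ]
    phantom_first_hit(phantom, o, depth_dir,
                      max_range = n_rows * pixel_spacing)
  }, numeric(1))
  img <- with_seed(seed, matrix(rrayleigh(n_rows * n_cols, speckle_scale),
                                n_rows, n_cols))
  rows <- seq_len(n_rows)
  for (cc in seq_len(n_cols)) {
    if (!is.finite(hits[cc])) next
    hit_row <- hits[cc] / pixel_spacing + 1
    ridge <- exp(-(rows - hit_row)^2 / (2 * 1.0^2))
    shadow <- rows > hit_row + 1.5
    col <- img[, cc]
    col[shadow] <- 0
    img[, cc] <- pmin(1, col + ridge)
  }
  img <- img + with_seed(derive_seed(seed, 2),
                         matrix(abs(stats::rnorm(n_rows * n_cols, 0, noise_floor)),
                                n_rows, n_cols) * (img == 0))
  fr <- tracked_frame(pmin(img, 1), probe_pose, pixel_spacing, timestamp)
  attr(fr, "surface_depth_mm") <- hits
  fr
}
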