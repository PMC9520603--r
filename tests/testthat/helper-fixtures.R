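# Shared fixtures, built once per test run and cached across files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

test_phantom <- function() {
  fixture("phantom3", function() make_spine_phantom(3, seed = 7))
}

test_map <- function(level_id) {
  fixture(paste0("map_", level_id),
          function() make_tissue_map(test_phantom(), level_id))
}

# Tissue map built directly from a label function over a small box; for
# controlled PAE-scan scenarios independent of the spine geometry.
box_map <- function(labeller, half = 4, spacing = 0.1) {
  ax <- seq(-half, half, by = spacing)
  centers <- as.matrix(expand.grid(ax, ax, ax))
  lab <- labeller(centers)
  structure(list(labels = array(as.integer(lab), rep(length(ax), 3)),
                 spacing = spacing, origin = rep(-half, 3),
                 level_id = "synthetic", side = "R", transform = NULL),
            class = "tissue_map")
}

label_code <- function(name) {
  c(background = 0L, muscle = 1L, cortical = 2L, cancellous = 3L)[[name]]
}

# Straight-down probe pose at a lateral/axial position (image depth = +y).
probe_pose_at <- function(x0, y0, z0) {
  rigid_transform(diag(3), c(x0, y0, z0))
}

# Synthetic polar PAE image with a cancellous background signature in all
# sectors and optional cortical echoes at given distances per sector.
synthetic_pae <- function(n_angles = 32, n_depths = 60, depth_step = 0.05,
                          cancellous = TRUE, cortical_at = rep(NA, 8),
                          noise_sd = 0.02, seed = 1) {
  sig <- pa_defaults()
  radii <- seq_len(n_depths) * depth_step
  k_c <- sig$cancellous$fc_hz / sig$sound_speed_mm_s
  k_k <- sig$cortical$fc_hz / sig$sound_speed_mm_s
  per <- n_angles / length(cortical_at)
  set.seed(seed)
  polar <- matrix(rnorm(n_angles * n_depths, 0, noise_sd), n_angles, n_depths)
  for (i in seq_len(n_angles)) {
    if (cancellous) {
      p <- sig$cancellous
      polar[i, ] <- polar[i, ] +
        p$amp * exp(-(radii - p$r0_mm)^2 / (2 * p$sigma_mm^2)) *
        sin(2 * pi * k_c * radii)
    }
    ri <- cortical_at[ceiling(i / per)]
    if (!is.na(ri)) {
      p <- sig$cortical
      polar[i, ] <- polar[i, ] +
        p$amp * exp(-(radii - ri)^2 / (2 * p$sigma_mm^2)) *
        sin(2 * pi * k_k * (radii - ri))
    }
  }
  pae_image(polar, depth_step)
}
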