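test_that("classical detection finds the surface on noiseless frames", {
  ph <- test_phantom()
  fr <- simulate_us_frame(ph, probe_pose_at(-20, -16, 0), seed = 2,
                          speckle_scale = 0, noise_floor = 0)
  depth <- attr(fr, "surface_depth_mm")
  mask <- classical_detect(fr)
  pred <- mask_depths(mask)
  bone <- which(is.finite(depth))
  truth_rows <- round(depth[bone] / fr$pixel_spacing + 1)
  hit <- !is.na(pred[bone]) & abs(pred[bone] - truth_rows) <= 1
  expect_gte(mean(hit), 0.95)
})

test_that("speckle-only frames produce almost no detections", {
  ph <- test_phantom()
  pose <- rigid_transform(rot_axis_angle(c(1, 0, 0), 180), c(0, -40, 0))
  fr <- simulate_us_frame(ph, pose, seed = 6)
  expect_lt(mean(colSums(classical_detect(fr)) > 0), 0.05)
  expect_identical(classical_detect(matrix(0, 8, 8)), matrix(FALSE, 8, 8))
})

test_that("extracted point clouds lie on the phantom surface", {
  ph <- test_phantom()
  frames <- simulate_us_sweep(ph, n_frames = 12,
                              z_range = c(-8, 8), seed = 4,
                              speckle_scale = 0, noise_floor = 0)
  cloud <- extract_point_cloud(frames, "classical")
  dense <- make_spine_phantom(3, params = list(n_surface_points = 12000),
                              seed = 7)
  d <- sqrt(nn_search(cloud$points, phantom_cloud(dense)$points)$d2)
  expect_gte(mean(d <= 1.0), 0.9)
  expect_error(extract_point_cloud(frames, "classical", min_points = 1e6),
               "insufficient")
})

test_that("rigidly moving all poses moves the extracted cloud identically", {
  ph <- test_phantom()
  frames <- simulate_us_sweep(ph, n_frames = 6, z_range = c(-5, 5), seed = 5,
                              speckle_scale = 0, noise_floor = 0)
  tf <- rigid_transform(rot_axis_angle(c(0, 1, 2), 20), c(5, -3, 8))
  moved <- lapply(frames, function(fr) {
    fr$pose <- rt_compose(tf, fr$pose)
    fr
  })
  c0 <- extract_point_cloud(frames, "classical")
  c1 <- extract_point_cloud(moved, "classical")
  expect_equal(c1$points, rt_apply(tf, c0$points), tolerance = 1e-9)
})

test_that("point clouds can also be pulled from a compounded volume", {
  ph <- test_phantom()
  frames <- simulate_us_sweep(ph, n_frames = 10, z_range = c(-6, 6), seed = 6,
                              speckle_scale = 0, noise_floor = 0)
  vol <- compound_volume(frames, spacing = 1)
  cloud <- extract_point_cloud(vol, min_points = 20)
  expect_gt(nrow(cloud$points), 20)
})
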