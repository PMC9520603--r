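test_that("ultrasound scanlines place the ridge at the first bone crossing", {
  ph <- test_phantom()
  pose <- probe_pose_at(-20, -16, 0)
  fr <- simulate_us_frame(ph, pose, n_rows = 96, n_cols = 96,
                          pixel_spacing = 0.5, seed = 4)
  depth <- attr(fr, "surface_depth_mm")
  # independent oracle: dense marching over the analytic labels per ray
  cols <- seq(5, 95, by = 10)
  for (cc in cols) {
    o <- rt_apply(pose, c((cc - 1) * 0.5, 0, 0))[1, ]
    steps <- seq(0.01, 48, by = 0.01)
    pts <- cbind(o[1], o[2] + steps, o[3])
    lab <- label_points(ph, pts)
    hit <- which(lab >= label_code("cortical"))
    truth <- if (length(hit) == 0L) Inf else steps[hit[1]]
    if (is.finite(truth)) {
      expect_equal(depth[cc], truth, tolerance = 0.02)
      expect_lt(abs(which.max(fr$image[, cc]) - (truth / 0.5 + 1)), 1.5)
    } else {
      expect_false(is.finite(depth[cc]))
    }
  }
})

test_that("acoustic shadow suppresses everything beyond the surface", {
  ph <- test_phantom()
  fr <- simulate_us_frame(ph, probe_pose_at(-20, -16, 0), seed = 9)
  depth <- attr(fr, "surface_depth_mm")
  for (cc in which(is.finite(depth))[1:20]) {
    hr <- depth[cc] / fr$pixel_spacing + 1
    shadow <- fr$image[seq_len(96) > hr + 2.5, cc]
    if (length(shadow) > 5) {
      expect_lt(mean(shadow), 0.1 * max(fr$image[, cc]))
    }
  }
})

test_that("a probe facing away yields pure speckle, not an error", {
  ph <- test_phantom()
  pose <- rigid_transform(rot_axis_angle(c(1, 0, 0), 180), c(0, -30, 0))
  fr <- simulate_us_frame(ph, pose, seed = 2)
  expect_true(all(is.infinite(attr(fr, "surface_depth_mm"))))
  expect_lt(mean(classical_detect(fr)), 0.05)
})

test_that("PA signal amplitudes and spectra follow the tissue orderings", {
  amps <- sapply(1:16, function(s) {
    c(max(abs(simulate_pa_signal("cancellous", seed = s)$samples)),
      max(abs(simulate_pa_signal("cortical", seed = s)$samples)))
  })
  expect_gt(mean(amps[1, ]), mean(amps[2, ]))
  cen <- fft_profile(simulate_pa_signal("cancellous", seed = 1))$spectral_centroid
  cor <- fft_profile(simulate_pa_signal("cortical", seed = 1))$spectral_centroid
  expect_gt(cor, cen)
})

test_that("PA signal is exactly linear in fluence and zero at zero fluence", {
  s0 <- simulate_pa_signal("cancellous", pulse_params(fluence_mj_per_cm2 = 0),
                           seed = 3)
  expect_true(all(s0$samples == 0))
  s16 <- simulate_pa_signal("cancellous", pulse_params(fluence_mj_per_cm2 = 16),
                            seed = 3)
  s32 <- simulate_pa_signal("cancellous", pulse_params(fluence_mj_per_cm2 = 32),
                            seed = 3)
  expect_equal(s32$samples, 2 * s16$samples, tolerance = 1e-12)
  expect_error(simulate_pa_signal("cancellous", sampling_rate = 0), "positive")
  expect_error(simulate_pa_signal("skin"), "tissue")
})

test_that("PAE scans reflect the first tissue interfaces per ray", {
  canc <- label_code("cancellous")
  cort <- label_code("cortical")
  bg <- label_code("background")
  # surrounded by cancellous: every angle carries the signature, and the
  # sector amplitudes stay within a factor of 2
  m_all <- box_map(function(p) rep(canc, nrow(p)))
  pose <- rigid_transform(diag(3), c(0, 0, 0))
  img <- simulate_pae_scan(m_all, pose, n_angles = 32, seed = 5)
  peaks <- apply(abs(img$polar), 1, max)
  expect_gt(min(peaks), 0.5)
  expect_lt(max(peaks) / min(peaks), 2)
  expect_equal(classify_zone(img)$label, "safe")

  # planar cortical wall 1 mm to the +x side: cortical signature only in
  # sectors whose rays face the wall (ray-cast oracle against the grid)
  m_wall <- box_map(function(p) {
    ifelse(p[, 1] >= 1 & p[, 1] <= 1.6, cort, canc)
  })
  img_w <- simulate_pae_scan(m_wall, pose, n_angles = 32, seed = 6)
  bands <- padrill:::signature_bands()
  cort_peak <- sapply(seq_len(32), function(i) {
    max(padrill:::band_envelope(img_w$polar[i, ], img_w$depth_step,
                                bands$cortical[1], bands$cortical[2]))
  })
  theta <- (seq_len(32) - 1) * 2 * pi / 32
  b <- padrill:::orthonormal_plane_basis(c(0, 1, 0))
  facing <- sapply(seq_len(32), function(i) {
    dir <- cos(theta[i]) * b$e1 + sin(theta[i]) * b$e2
    rc <- map_raycast(m_wall, c(0, 0, 0), dir, max_range = 3, step = 0.02)
    any(rc$label == cort)
  })
  expect_true(all(cort_peak[facing] > 0.3))
  expect_true(all(cort_peak[!facing] < 0.2))

  # tip in background: all sectors at the noise floor
  m_bg <- box_map(function(p) rep(bg, nrow(p)))
  img_b <- simulate_pae_scan(m_bg, pose, n_angles = 32, seed = 7)
  expect_lt(max(abs(img_b$polar)), 0.15)
  expect_equal(classify_zone(img_b)$label, "dangerous")

  # determinism and domain errors
  img2 <- simulate_pae_scan(m_all, pose, n_angles = 32, seed = 5)
  expect_identical(img$polar, img2$polar)
  far <- rigid_transform(diag(3), c(50, 0, 0))
  expect_error(simulate_pae_scan(m_all, far), "outside")
  expect_error(simulate_pae_scan(m_all, pose, n_angles = 4), "at least 8")
})
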