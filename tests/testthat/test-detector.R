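# One detector trained on the parametric dataset, shared across blocks.
trained_detector <- function() {
  fixture("detector_and_data", function() {
    ds <- make_detector_dataset(64, n_levels = 3, size = 64, seed = 5)
    train_idx <- 1:48
    det <- train_two_loss_detector(
      list(frames = ds$frames[train_idx], masks = ds$masks[train_idx],
           levels = ds$levels[train_idx]),
      detector_config(seed = 2))
    list(det = det, ds = ds, held_out = 49:64)
  })
}

test_that("sigma schedule anneals monotonically through scheduled values", {
  fit <- trained_detector()
  h <- fit$det$history
  expect_true(all(diff(h$sigma) <= 0))
  expect_true(all(h$sigma %in% fit$det$config$sigma_schedule))
  expect_equal(h$sigma[1], 8)
  expect_equal(h$sigma[nrow(h)], 2)
  expect_lt(h$loss_heat[nrow(h)], h$loss_heat[1])
})

test_that("held-out surface recall and level accuracy meet their floors", {
  fit <- trained_detector()
  rec <- vapply(fit$held_out, function(i) {
    surface_recall(detect_surface(fit$det, fit$ds$frames[[i]]),
                   fit$ds$depth_px[i, ], tol_px = 2)
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
  acc <- mean(vapply(fit$held_out, function(i) {
    predict_level(fit$det, fit$ds$frames[[i]]) == fit$ds$levels[i]
  }, logical(1)))
  expect_gte(acc, 0.8)
})

test_that("configuration and dataset preconditions are enforced", {
  expect_error(detector_config(sigma_schedule = c(2, 4)), "decreasing")
  expect_error(detector_config(threshold = 1.2), "threshold")
  ds <- make_detector_dataset(8, n_levels = 1, size = 32, seed = 1)
  expect_error(train_two_loss_detector(ds, detector_config(sigma_schedule = c(4, 2))),
               "one level")
})

test_that("a sweep-trained detector labels extracted points by level", {
  ph2 <- make_spine_phantom(2, seed = 11)
  frames <- simulate_us_sweep(ph2, n_frames = 80, z_range = c(-8, 36),
                              n_rows = 64, n_cols = 64, pixel_spacing = 0.75,
                              seed = 3, speckle_scale = 0, noise_floor = 0)
  # frames grazing the inter-vertebral gap carry almost no surface and no
  # usable level cue; a curated training set keeps frames over bone
  frames <- frames[vapply(frames, function(fr) {
    sum(true_surface_mask(fr)) > 20
  }, logical(1))]
  levels <- vapply(frames, function(fr) attr(fr, "nearest_level"), "")
  masks <- lapply(frames, true_surface_mask)
  train_idx <- seq(1, length(frames), by = 2)
  det <- train_two_loss_detector(
    list(frames = lapply(frames[train_idx], `[[`, "image"),
         masks = masks[train_idx], levels = levels[train_idx]),
    detector_config(level_count = 2, epochs = 500, hidden = 64, seed = 4))
  held <- frames[-train_idx]
  cloud <- extract_point_cloud(held, detector = det, min_points = 30)
  truth <- unlist(lapply(held, function(fr) {
    mask <- detect_surface(det, fr$image)
    rep(attr(fr, "nearest_level"), sum(mask))
  }))
  expect_gte(mean(cloud$level == truth), 0.8)
})
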