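test_that("phantom generation is deterministic and validates parameters", {
  a <- make_spine_phantom(3, seed = 7)
  b <- make_spine_phantom(3, seed = 7)
  expect_identical(a$levels[[2]]$surface_points, b$levels[[2]]$surface_points)
  ids <- vapply(a$levels, `[[`, "", "level_id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(vapply(a$levels, function(lv) nrow(lv$surface_points),
                         1L) >= 500))
  expect_error(make_spine_phantom(0), "positive")
  expect_error(make_spine_phantom(2, params = list(pedicle_width = -1)),
               "positive")
  expect_error(make_spine_phantom(2, params = list(cortical_thickness = 2)),
               "pedicle width")
  expect_error(make_spine_phantom(2, params = list(nonsense = 1)), "unknown")
})

test_that("sampled pedicle cross-section width matches the 3.5 mm minimum", {
  ph <- test_phantom()
  for (lv in ph$levels) {
    pr <- lv$surface_points[lv$component == "pedicle_R", , drop = FALSE]
    axis_xz <- c(lv$geom$xp, lv$geom$z0)
    radius <- sqrt((pr[, 1] - axis_xz[1])^2 + (pr[, 3] - axis_xz[2])^2)
    expect_equal(2 * min(radius), 3.5, tolerance = 0.1 / 3.5)
    expect_equal(2 * max(radius), 3.5, tolerance = 0.1 / 3.5)
  }
})

test_that("trajectory contracts hold against the voxel label map", {
  ph <- test_phantom()
  cp <- make_trajectory("CP", ph, "L3")
  mmp <- make_trajectory("MMP", ph, "L5")
  lmp <- make_trajectory("LMP", ph, "L4")

  # CP clearance: distance from the trajectory line to every cortical voxel
  # centre inside the pedicle stays at or above the 1.44 mm safe distance
  tm <- test_map("L3")
  idx <- which(tm$labels == label_code("cortical"), arr.ind = TRUE)
  centers <- sweep((idx - 1) * tm$spacing, 2, tm$origin, "+")
  in_ped <- centers[, 2] >= 0 & centers[, 2] <= ph$levels[[1]]$geom$ped_len
  rel <- sweep(centers[in_ped, , drop = FALSE], 2, cp$entry_point)
  proj <- rel - outer(as.numeric(rel %*% cp$direction), cp$direction)
  expect_gte(min(sqrt(rowSums(proj^2))), 1.44)

  # MMP crosses the medial cortical wall: the ray along the trajectory
  # traverses cortical voxels for a positive length
  tm5 <- test_map("L5")
  rc <- map_raycast(tm5, mmp$entry_point, mmp$direction, max_range = 25,
                    step = 0.02)
  crossing_mm <- sum(rc$label == label_code("cortical")) * 0.02
  expect_gt(crossing_mm, 0)
  # ... and reaches background (the spinal canal) afterwards
  first_cort <- which(rc$label == label_code("cortical"))[1]
  expect_true(any(rc$label[first_cort:nrow(rc)] == label_code("background")))

  # LMP entry is laterally offset from the pedicle axis
  expect_gt(abs(lmp$entry_point[1]) - abs(cp$entry_point[1]), 0)
  expect_error(make_trajectory("XX", ph, "L3"), "kind")
  expect_error(make_trajectory("CP", ph, "L9"), "unknown level")
})

test_that("bone voxel volume is conserved under rigid repositioning", {
  ph <- make_spine_phantom(1, seed = 3)
  tf <- rigid_transform(rot_axis_angle(c(0.3, 1, 0.2), 25), c(4, -7, 2))
  # bounds must cover the whole vertebra in both maps, otherwise the box
  # would clip different anatomy before and after the motion
  b0 <- rbind(c(-25, -12, -13), c(25, 40, 13))
  corners <- as.matrix(expand.grid(b0[, 1], b0[, 2], b0[, 3]))
  moved <- rt_apply(tf, corners)
  b1 <- rbind(apply(moved, 2, min), apply(moved, 2, max))
  m0 <- make_tissue_map(ph, "L3", spacing = 0.25, bounds = b0)
  m1 <- make_tissue_map(ph, "L3", spacing = 0.25, bounds = b1, transform = tf)
  bone <- function(m) sum(m$labels == label_code("cortical") |
                            m$labels == label_code("cancellous"))
  expect_equal(bone(m1) / bone(m0), 1, tolerance = 0.01)
})

test_that("analytic labels nest correctly (cancellous enclosed by cortical)", {
  ph <- test_phantom()
  g <- ph$levels[[1]]$geom
  # radial probes across the pedicle: cancellous core, cortical shell,
  # background outside
  r <- c(0, 1.0, 1.6, 1.9)
  pts <- cbind(g$xp + r, 6, g$z0)
  lab <- label_points(ph, pts)
  expect_equal(unname(lab), c(3L, 3L, 2L, 0L))
})
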