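anisotropic_cloud <- function(n = 300, seed = 1) {
  set.seed(seed)
  cbind(rnorm(n, sd = 9), rnorm(n, sd = 4), rnorm(n, sd = 1.5))
}

test_that("PCA coarse alignment recovers constructed rigid motions", {
  src <- anisotropic_cloud()
  expect_equal(rt_angle_deg(pca_coarse_align(src, src)), 0, tolerance = 1e-7)

  tf <- rigid_transform(rot_axis_angle(c(0, 0, 1), 30), c(5, 2, 1))
  dst <- rt_apply(tf, src)
  est <- pca_coarse_align(src, dst)
  expect_lt(rt_angle_deg(rt_compose(est, rt_invert(tf))), 1e-6)
  expect_lt(max(abs(est$t - tf$t)), 1e-6)
  expect_false(attr(est, "ambiguous"))
})

test_that("degenerate and near-isotropic clouds are flagged", {
  line <- cbind(seq(0, 10, length.out = 50), 0, 0) +
    matrix(rnorm(150, sd = 1e-9), ncol = 3)
  expect_error(pca_coarse_align(line, line), "degenerate")
  set.seed(2)
  u <- matrix(rnorm(9000), ncol = 3)
  shell <- 10 * u / sqrt(rowSums(u^2))
  expect_true(attr(pca_coarse_align(shell, shell), "ambiguous"))
})

test_that("ICP is exact on identical clouds and recovers perturbations", {
  cloud <- test_phantom()$levels[[1]]$surface_points
  res0 <- icp(cloud, cloud)
  expect_equal(res0$mse, 0)
  expect_equal(res0$iterations, 1L)

  tf <- rigid_transform(rot_axis_angle(c(1, 1, 0), 5), c(1.2, -1, 1))
  moved <- rt_apply(tf, cloud)
  init <- pca_coarse_align(moved, cloud)
  res <- icp(moved, cloud, init = init)
  err <- transform_error(res$transform, rt_invert(tf), cloud)
  expect_lt(err$rotation_deg, 1)
  expect_lt(err$translation_mm, 0.5)
  expect_true(all(diff(res$mse_history) <= 1e-12))
})

test_that("reported ICP MSE equals the brute-force nearest-neighbour MSE", {
  set.seed(9)
  for (k in 1:3) {
    src <- matrix(rnorm(3 * 150, sd = 5), ncol = 3)
    dst <- matrix(rnorm(3 * 200, sd = 5), ncol = 3)
    res <- icp(src, dst, max_iter = 20)
    moved <- rt_apply(res$transform, src)
    d2 <- apply(moved, 1, function(p) {
      min(colSums((t(dst) - p)^2))
    })
    expect_equal(res$mse, mean(d2), tolerance = 1e-9)
  }
})

test_that("radius selection reduces to plain ICP for one covering radius", {
  ph <- test_phantom()
  cloud <- phantom_cloud(ph, "L3")
  tf <- rigid_transform(rot_axis_angle(c(0, 1, 0), 4), c(1, 0.5, -1))
  us <- pc_transform(cloud, tf)
  init <- pca_coarse_align(us, cloud)
  ctr <- ph$levels[[1]]$body_center
  plain <- icp(us, cloud, init = init)
  sel <- radius_select_icp(us, cloud, ctr, radii = 500, init = init)
  expect_equal(sel$mse, plain$mse, tolerance = 1e-12)
  expect_equal(sel$transform$R, plain$transform$R, tolerance = 1e-12)
  expect_equal(sel$radius, 500)
  expect_equal(sum(!is.na(sel$per_radius_mse)), 1L)
  expect_error(radius_select_icp(us, cloud, ctr, radii = 1, init = init),
               "insufficient")
  expect_error(radius_select_icp(us, cloud, ctr, radii = c(5, 3)), "sorted")
})

test_that("registration degrades gracefully with point noise", {
  ph <- make_spine_phantom(1, params = list(n_surface_points = 700), seed = 5)
  model <- phantom_cloud(ph, "L3")
  ctr <- ph$levels[[1]]$body_center
  med_tre <- vapply(c(0, 0.2, 0.5, 1.0), function(sigma) {
    tre <- vapply(1:12, function(s) {
      set.seed(1000 + s)
      tf <- rigid_transform(rot_axis_angle(rnorm(3), runif(1, 0, 8)),
                            rnorm(3) * 2)
      us <- rt_apply(tf, model$points) +
        matrix(rnorm(length(model$points), sd = sigma), ncol = 3)
      init <- pca_coarse_align(us, model)
      res <- icp(us, model, init = init, max_iter = 50)
      transform_error(res$transform, rt_invert(tf), model$points)$tre_mm
    }, numeric(1))
    median(tre)
  }, numeric(1))
  expect_true(all(diff(med_tre) >= -1e-6))
})
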