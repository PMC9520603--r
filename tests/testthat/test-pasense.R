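test_that("fft_profile locates tones and conserves energy (Parseval)", {
  fs <- 50e6
  t <- (0:511) / fs
  s5 <- pa_signal(sin(2 * pi * 5e6 * t), fs)
  expect_lt(abs(fft_profile(s5)$dominant_freq - 5e6), fs / 512 + 1)
  mix <- pa_signal(sin(2 * pi * 2e6 * t) + 2 * sin(2 * pi * 8e6 * t), fs)
  expect_lt(abs(fft_profile(mix)$dominant_freq - 8e6), fs / 512 + 1)
  expect_error(fft_profile(pa_signal(rnorm(8), fs)), "too short")

  # Parseval against a brute-force DFT on 64 samples
  set.seed(3)
  x <- rnorm(64)
  n <- 64
  Xb <- vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
  expect_equal(sum(x^2), sum(Mod(Xb)^2) / n, tolerance = 1e-6)
  expect_equal(sum(Mod(stats::fft(x))^2), sum(Mod(Xb)^2), tolerance = 1e-6)
})

test_that("tissue comparison reports the printed orderings and ties", {
  a <- simulate_pa_signal("cancellous", seed = 2)
  b <- simulate_pa_signal("cortical", seed = 2)
  rep16 <- sapply(1:16, function(s) {
    cmp <- compare_tissue_signatures(simulate_pa_signal("cancellous", seed = s),
                                     simulate_pa_signal("cortical", seed = s))
    c(cmp$amplitude_order, cmp$centroid_order)
  })
  expect_gte(mean(rep16[1, ] == "cancellous"), 0.75)
  expect_true(all(rep16[2, ] == "cortical"))
  same <- compare_tissue_signatures(a, a)
  expect_equal(same$amplitude_order, "tie")
  expect_equal(same$centroid_order, "tie")
})

test_that("scan conversion maps polar content to the right places", {
  img <- pae_image(matrix(0.7, 16, 40), depth_step = 0.05)
  cart <- scan_convert(img, pixel_mm = 0.04)
  nz <- cart != 0
  expect_true(all(cart[nz] == 0.7))
  r_max <- 40 * 0.05
  expect_equal(sum(nz) * 0.04^2, pi * r_max^2, tolerance = 0.05)

  # single bright A-line shows up as a ray at its angle
  one <- matrix(0, 16, 40)
  one[5, ] <- 1
  cart1 <- scan_convert(pae_image(one, 0.05), pixel_mm = 0.04)
  hit <- which(cart1 > 0.5, arr.ind = TRUE)
  ctr <- (dim(cart1)[1] + 1) / 2
  ang <- atan2(hit[, 2] - ctr, hit[, 1] - ctr) %% (2 * pi)
  target <- (5 - 1) * 2 * pi / 16
  expect_true(all(pmin(abs(ang - target),
                       2 * pi - abs(ang - target)) < 2 * pi / 16))

  # smooth images survive a polar -> cartesian -> polar round trip
  smooth <- outer(sin(seq(0, 2 * pi, length.out = 32)),
                  seq(1, 0.2, length.out = 50)) + 1
  pim <- pae_image(smooth, 0.05)
  cart2 <- scan_convert(pim, pixel_mm = 0.03)
  back <- matrix(NA_real_, 32, 50)
  for (i in 1:32) for (j in 1:50) {
    th <- (i - 1) * 2 * pi / 32
    r <- j * 0.05
    ci <- round(r * cos(th) / 0.03) + (dim(cart2)[1] + 1) / 2
    cj <- round(r * sin(th) / 0.03) + (dim(cart2)[1] + 1) / 2
    back[i, j] <- cart2[ci, cj]
  }
  expect_gt(stats::cor(as.numeric(smooth), as.numeric(back)), 0.95)
})

test_that("gCNR behaves at its analytic anchors", {
  # identical distributions: OVL ~ 1
  set.seed(11)
  x <- rnorm(2e4, 0.5, 0.1)
  g_same <- gcnr(x, 1:1e4, 1e4 + 1:1e4)
  expect_lt(g_same$gcnr, 0.05)
  # fully separated ROIs: exactly 1
  g_sep <- gcnr(c(rep(1, 100), rep(0, 100)), 1:100, 101:200)
  expect_identical(g_sep$gcnr, 1)
  # internal consistency
  expect_equal(g_same$gcnr, 1 - g_same$ovl, tolerance = 1e-12)
  dx <- diff(g_same$bin_edges)
  expect_equal(sum(g_same$pdf_in * dx), 1, tolerance = 1e-9)
  expect_equal(sum(g_same$pdf_out * dx), 1, tolerance = 1e-9)
  expect_error(gcnr(x, 1:100, 50:149), "disjoint")
  expect_error(gcnr(x, 1:10, 11:100), "at least 50")
})

test_that("gCNR matches a quadrature oracle for two normals", {
  set.seed(21)
  n <- 1e5
  vals <- c(rnorm(n, 0.6, 0.2), rnorm(n, 0.4, 0.2))
  est <- gcnr(vals, 1:n, n + 1:n)$gcnr
  ovl <- stats::integrate(function(x) {
    pmin(stats::dnorm(x, 0.6, 0.2), stats::dnorm(x, 0.4, 0.2))
  }, -2, 3)$value
  expect_equal(est, 1 - ovl, tolerance = 0.02)
  # monotone in separation
  gs <- vapply(c(0.4, 0.5, 0.6, 0.8), function(mu) {
    set.seed(30 + round(100 * mu))
    v <- c(rnorm(2e4, mu, 0.2), rnorm(2e4, 0.4, 0.2))
    gcnr(v, 1:2e4, 2e4 + 1:2e4)$gcnr
  }, numeric(1))
  expect_true(all(diff(gs) >= -0.02))
})

test_that("gCNR with rank-preserving bins ignores monotone remapping", {
  set.seed(31)
  v <- c(rnorm(2e4, 0.6, 0.15), rnorm(2e4, 0.35, 0.15))
  g0 <- gcnr(v, 1:2e4, 2e4 + 1:2e4, bin_method = "quantile")$gcnr
  g1 <- gcnr(exp(2 * v), 1:2e4, 2e4 + 1:2e4, bin_method = "quantile")$gcnr
  expect_equal(g0, g1, tolerance = 0.02)
})

test_that("interface distance estimation tracks the wall", {
  canc <- label_code("cancellous")
  cort <- label_code("cortical")
  m_wall <- box_map(function(p) ifelse(p[, 1] >= 1 & p[, 1] <= 1.6,
                                       cort, canc))
  pose0 <- rigid_transform(diag(3), c(0, 0, 0))
  img <- simulate_pae_scan(m_wall, pose0, n_angles = 32, seed = 3)
  d_by_sector <- vapply(1:8, function(s) {
    estimate_interface_distance(img, s)
  }, numeric(1))
  expect_equal(min(d_by_sector, na.rm = TRUE), 1.0, tolerance = 0.3)

  # pure cancellous surroundings: no interface anywhere
  m_all <- box_map(function(p) rep(canc, nrow(p)))
  img_c <- simulate_pae_scan(m_all, pose0, n_angles = 32, seed = 4)
  expect_true(all(is.na(vapply(1:8, function(s) {
    estimate_interface_distance(img_c, s)
  }, numeric(1)))))

  # estimates shrink monotonically as the tip advances toward the wall
  d_seq <- vapply(c(2.0, 1.4, 0.8), function(x0) {
    im <- simulate_pae_scan(m_wall, rigid_transform(diag(3), c(1 - x0, 0, 0)),
                            n_angles = 32, seed = 5)
    min(vapply(1:8, function(s) estimate_interface_distance(im, s),
               numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(d_seq) < 0))
  expect_error(estimate_interface_distance(img, 9), "out of range")
})

test_that("zone classification follows the sector evidence", {
  safe_img <- synthetic_pae(cortical_at = rep(NA, 8), seed = 1)
  expect_equal(classify_zone(safe_img)$label, "safe")

  warn_img <- synthetic_pae(cortical_at = c(1.0, 1.0, rep(NA, 6)), seed = 2)
  zw <- classify_zone(warn_img)
  expect_equal(zw$label, "warning")
  expect_equal(zw$sector_flags[1:2], c("interface", "interface"))
  expect_lt(zw$min_interface_distance, 1.44)

  noise_img <- synthetic_pae(cancellous = FALSE, cortical_at = rep(NA, 8),
                             seed = 3)
  expect_equal(classify_zone(noise_img)$label, "dangerous")

  # a far interface (beyond the safe distance) must not trigger a warning
  far_img <- synthetic_pae(cortical_at = c(2.2, rep(NA, 7)), seed = 4)
  expect_equal(classify_zone(far_img)$label, "safe")
  expect_error(classify_zone(safe_img, n_sectors = 5), "divide")
})

test_that("zone classification is rotation-equivariant", {
  img <- synthetic_pae(cortical_at = c(1.0, rep(NA, 7)), seed = 6)
  z0 <- classify_zone(img)
  k <- 3 # rotate by 3 sectors = 12 rows
  rot <- pae_image(img$polar[c(13:32, 1:12), ], img$depth_step)
  z1 <- classify_zone(rot)
  expect_equal(z1$label, z0$label)
  # shifting the rows down by k sectors means new sector i shows what old
  # sector i + k showed
  expect_equal(z1$sector_flags, z0$sector_flags[(seq_len(8) + k - 1) %% 8 + 1])
})

test_that("timeline segmentation and trajectory classes are consistent", {
  safe_img <- synthetic_pae(seed = 7)
  cl <- classify_timeline(list(safe_img, safe_img, safe_img))
  expect_true(all(cl$phase == "in-bone"))
  expect_equal(classify_trajectory(cl), "correct")
  expect_error(classify_timeline(list(safe_img)), "at least 2")

  noise_img <- synthetic_pae(cancellous = FALSE, seed = 8)
  warn_img <- synthetic_pae(cortical_at = c(0.9, rep(NA, 7)), seed = 9)
  cl2 <- classify_timeline(list(noise_img, safe_img, warn_img, noise_img))
  expect_equal(cl2$phase, c("initial", "in-bone", "in-bone", "exited"))
  expect_equal(classify_trajectory(cl2), "medial-breach")
  cl3 <- classify_timeline(list(safe_img, warn_img, safe_img))
  expect_equal(classify_trajectory(cl3), "lateral-graze")
})

test_that("simulated drilling timelines match the geometric ground truth", {
  ph <- test_phantom()
  lv <- c(CP = "L3", LMP = "L4", MMP = "L5")
  for (kind in names(lv)) {
    tr <- make_trajectory(kind, ph, lv[[kind]])
    tl <- simulate_pae_timeline(ph, tr, test_map(lv[[kind]]), seed = 31,
                                n_angles = 16)
    cl <- classify_timeline(tl$images)
    expect_gte(mean(cl$zones == tl$truth$zone), 0.85)
    expected <- c(CP = "correct", LMP = "lateral-graze",
                  MMP = "medial-breach")[[kind]]
    expect_equal(classify_trajectory(cl), expected)
  }
})

test_that("fluence checking applies the ANSI limit", {
  r <- check_fluence(16)
  expect_true(r$ok)
  expect_equal(r$margin, 14)
  expect_true(check_fluence(30)$ok)
  expect_equal(check_fluence(30)$margin, 0)
  expect_false(check_fluence(31)$ok)
  expect_error(check_fluence(-1), "non-negative")
})
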