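#' Laser pulse parameters
#'
#' Excitation settings for photoacoustic simulation: a Q-switched 532 nm,
#' 7 ns, 10 Hz source at 16 mJ/cm2 sample fluence by default.
#'
#' @param wavelength_nm excitation wavelength in nm.
#' @param pulse_width_ns pulse width in ns.
#' @param rep_rate_hz repetition rate in Hz.
#' @param fluence_mj_per_cm2 fluence at the sample in mJ/cm2 (may be 0 for a
#'   noise-free null signal; must not be negative).
#' @return An object of class `pulse_params`.
#' @export
pulse_params <- function(wavelength_nm = 532, pulse_width_ns = 7,
                         rep_rate_hz = 10, fluence_mj_per_cm2 = 16) {
  if (wavelength_nm <= 0 || pulse_width_ns <= 0 || rep_rate_hz <= 0 ||
      fluence_mj_per_cm2 < 0) {
    stop("pulse parameters must be positive (fluence may be zero)")
  }
  structure(list(wavelength_nm = wavelength_nm, pulse_width_ns = pulse_width_ns,
                 rep_rate_hz = rep_rate_hz,
                 fluence_mj_per_cm2 = fluence_mj_per_cm2),
            class = "pulse_params")
}

#' Photoacoustic tissue signature defaults
#'
#' Free parameters of the simulator, chosen to reproduce the qualitative
#' orderings observed ex vivo: cancellous bone yields a slightly stronger
#' peak amplitude at a lower centre frequency, cortical bone a weaker but
#' higher-frequency response. Depth conversion assumes a fixed 1540 m/s
#' speed of sound.
#'
#' @return Named list of signature parameters (`fc_hz` centre frequency,
#'   `amp` relative amplitude, `sigma_mm`/`sigma_us` envelope widths), plus
#'   `sound_speed_mm_s`, `noise_sd` and the reference fluence.
#' @export
pa_defaults <- function() {
  list(
    cancellous = list(fc_hz = 2e6, amp = 1.0, sigma_mm = 0.45, sigma_us = 0.40,
                      r0_mm = 0.6),
    cortical = list(fc_hz = 6e6, amp = 0.8, sigma_mm = 0.12, sigma_us = 0.25),
    sound_speed_mm_s = 1.54e6,
    noise_sd = 0.02,
    fluence_ref = 16
  )
}

#' 1D photoacoustic signal
#'
#' @param samples numeric amplitude sequence.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param tissue optional tissue tag.
#' @return An object of class `pa_signal`.
#' @export
pa_signal <- function(samples, sampling_rate, tissue = NULL) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 tissue = tissue), class = "pa_signal")
}

#' Simulate a single-element photoacoustic signal
#'
#' Produces a damped-oscillation burst plus receiver noise for a tissue
#' class. Amplitude scales exactly linearly with fluence (including the
#' noise term, so zero fluence yields an all-zero trace) and with the
#' packaged absorption spectrum evaluated at the excitation wavelength,
#' relative to 532 nm.
#'
#' @param tissue "cortical" or "cancellous".
#' @param pulse a [pulse_params()].
#' @param seed RNG seed for the noise draw.
#' @param sampling_rate sampling rate in Hz.
#' @param n_samples trace length.
#' @param sig signature parameter list, see [pa_defaults()].
#' @return A [pa_signal()].
#' @export
#' @examples
#' s <- simulate_pa_signal("cancellous", seed = 1)
#' max(abs(s$samples))
simulate_pa_signal <- function(tissue, pulse = pulse_params(), seed = 1,
                               sampling_rate = 50e6, n_samples = 512,
                               sig = pa_defaults()) {
  if (!tissue %in% c("cortical", "cancellous")) {
    stop("tissue must be 'cortical' or 'cancellous'")
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  p <- sig[[tissue]]
  t_us <- (seq_len(n_samples) - 1) / sampling_rate * 1e6
  t0 <- 2
  gain <- pulse$fluence_mj_per_cm2 / sig$fluence_ref
  wl_gain <- if (pulse$wavelength_nm == 532) 1 else {
    spec <- cancellous_absorption_spectrum(sort(c(532, pulse$wavelength_nm)))
    spec$absorbance[match(pulse$wavelength_nm, spec$wavelength_nm)] /
      spec$absorbance[match(532, spec$wavelength_nm)]
  }
  burst <- p$amp * exp(-(t_us - t0)^2 / (2 * p$sigma_us^2)) *
    sin(2 * pi * p$fc_hz * (t_us - t0) * 1e-6)
  noise <- with_seed(seed, stats::rnorm(n_samples, 0, sig$noise_sd))
  pa_signal(gain * wl_gain * (burst + noise), sampling_rate, tissue)
}

#' Polar photoacoustic endoscopy image
#'
#' @param polar numeric matrix, `n_angles` rows by `n_depths` columns of RF
#'   amplitude sampled radially outward from the drill axis.
#' @param depth_step radial sample spacing in mm.
#' @param acquisition_time_s time stamp of the scan in seconds.
#' @return An object of class `pae_image` with `angle_step_rad` derived from
#'   the row count.
#' @export
pae_image <- function(polar, depth_step, acquisition_time_s = 0) {
  polar <- as.matrix(polar)
  if (nrow(polar) < 8L) stop("a PAE image needs at least 8 angles")
  if (depth_step <= 0) stop("depth_step must be positive")
  structure(list(polar = polar, angle_step_rad = 2 * pi / nrow(polar),
                 depth_step = depth_step,
                 acquisition_time_s = acquisition_time_s),
            class = "pae_image")
}

#' @export
print.pae_image <- function(x, ...) {
  cat(sprintf("pae_image: %d angles x %d depths (%.2f mm range) at t=%gs\n",
              nrow(x$polar), ncol(x$polar), ncol(x$polar) * x$depth_step,
              x$acquisition_time_s))
  invisible(x)
}

#' Simulate a sideways-looking photoacoustic endoscopy scan
#'
#' For each rotation angle an A-scan is generated from the first tissue
#' interfaces along the radial ray cast through the tissue-label map: rays
#' starting in cancellous bone carry the near-range cancellous signature;
#' the first cortical interface within range adds the high-frequency
#' cortical signature centred at the interface radius; rays through muscle
#' or background stay at the noise floor.
#'
#' @param tissue_map a [make_tissue_map()] result.
#' @param drill_pose [rigid_transform()]; the tip sits at its translation
#'   and the drill axis is its local +y.
#' @param n_angles number of A-scans per revolution (>= 8).
#' @param depth_range radial sensing range in mm.
#' @param pulse a [pulse_params()].
#' @param seed RNG seed.
#' @param depth_step radial sampling in mm.
#' @param sig signature parameters, see [pa_defaults()].
#' @param acquisition_time_s time stamp carried by the image.
#' @return A [pae_image()].
#' @export
simulate_pae_scan <- function(tissue_map, drill_pose, n_angles = 32,
                              depth_range = 3, pulse = pulse_params(),
                              seed = 1, depth_step = 0.05,
                              sig = pa_defaults(), acquisition_time_s = 0) {
  if (n_angles < 8) stop("n_angles must be at least 8")
  tip <- drill_pose$t
  d <- dim(tissue_map$labels)
  rel <- (tip - tissue_map$origin) / tissue_map$spacing
  if (any(rel < -0.5) || any(rel > d - 0.5)) {
    stop("drill tip lies outside the tissue map")
  }
  axis <- as.numeric(drill_pose$R %*% c(0, 1, 0))
  b <- orthonormal_plane_basis(axis)
  radii <- seq(depth_step, depth_range, by = depth_step)
  nr <- length(radii)
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  gain <- pulse$fluence_mj_per_cm2 / sig$fluence_ref
  k_canc <- sig$cancellous$fc_hz / sig$sound_speed_mm_s  # cycles per mm
  k_cort <- sig$cortical$fc_hz / sig$sound_speed_mm_s
  polar <- with_seed(seed,
                     matrix(stats::rnorm(n_angles * nr, 0, sig$noise_sd),
                            n_angles, nr))
  canc <- tissue_labels[["cancellous"]]
  cort <- tissue_labels[["cortical"]]
  for (i in seq_len(n_angles)) {
    dir <- cos(theta[i]) * b$e1 + sin(theta[i]) * b$e2
    pts <- outer(radii, dir) + matrix(tip, nr, 3, byrow = TRUE)
    lab <- map_label_at(tissue_map, pts)
    a <- polar[i, ]
    # rays starting outside bone have no acoustic contact: noise floor only
    if (lab[1] == canc || lab[1] == cort) {
      if (lab[1] == canc) {
        p <- sig$cancellous
        a <- a + p$amp * exp(-(radii - p$r0_mm)^2 / (2 * p$sigma_mm^2)) *
          sin(2 * pi * k_canc * radii)
      }
      hit <- which(lab == cort)
      lost <- which(lab != canc & lab != cort)
      if (length(hit) > 0L &&
          (length(lost) == 0L || hit[1] < lost[1])) {
        ri <- radii[hit[1]]
        p <- sig$cortical
        a <- a + p$amp * exp(-(radii - ri)^2 / (2 * p$sigma_mm^2)) *
          sin(2 * pi * k_cort * (radii - ri))
      }
    }
    polar[i, ] <- a
  }
  pae_image(gain * polar, depth_step, acquisition_time_s)
}

#' Simulate a drilling timeline of PAE scans with ground truth
#'
#' Advances the drill tip along a trajectory, acquiring one PAE scan per
#' frame interval, and records the geometric zone ground truth for each
#' frame (see [zone_truth()]).
#'
#' @param phantom a `spine_phantom`.
#' @param trajectory a [make_trajectory()] result.
#' @param tissue_map optional pre-built [make_tissue_map()]; built on demand.
#' @param n_frames number of frames.
#' @param pulse a [pulse_params()].
#' @param seed RNG seed (advanced per frame).
#' @param jitter_mm axial entry offset applied to the whole timeline,
#'   emulating run-to-run variation in drilling start (mm along the path).
#' @param n_angles,depth_range,depth_step scan geometry, see
#'   [simulate_pae_scan()].
#' @return List with `images` (list of [pae_image()]), `truth` (data.frame
#'   of time, tip position, zone and interface distance) and `trajectory`.
#' @export
simulate_pae_timeline <- function(phantom, trajectory, tissue_map = NULL,
                                  n_frames = 8, pulse = pulse_params(),
                                  seed = 1, jitter_mm = 0, n_angles = 32,
                                  depth_range = 3, depth_step = 0.05) {
  if (is.null(tissue_map)) {
    tissue_map <- make_tissue_map(phantom, trajectory$level_id,
                                  trajectory$side)
  }
  times <- trajectory$frame_interval_s * seq_len(n_frames)
  tips <- trajectory_tip(trajectory, times + jitter_mm / trajectory$speed)
  axis <- trajectory$direction
  pose_R <- drill_pose_rotation(axis)
  images <- vector("list", n_frames)
  truth <- data.frame(time_s = times, x = tips[, 1], y = tips[, 2],
                      z = tips[, 3], zone = NA_character_,
                      min_interface_mm = NA_real_)
  for (k in seq_len(n_frames)) {
    pose <- rigid_transform(pose_R, tips[k, ])
    images[[k]] <- simulate_pae_scan(tissue_map, pose, n_angles = n_angles,
                                     depth_range = depth_range, pulse = pulse,
                                     seed = derive_seed(seed, k),
                                     depth_step = depth_step,
                                     acquisition_time_s = times[k])
    zt <- zone_truth(phantom, tips[k, ], axis, depth_range = depth_range)
    truth$zone[k] <- zt$zone
    truth$min_interface_mm[k] <- zt$min_interface_mm
  }
  list(images = images, truth = truth, trajectory = trajectory)
}

# Rotation whose local +y is the drill axis (world frame, det +1).
drill_pose_rotation <- function(axis) {
  d <- axis / sqrt(sum(axis^2))
  b <- orthonormal_plane_basis(d)
  cbind(b$e2, d, b$e1)
}
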