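#' @name pasense
#' @title Photoacoustic signal characterization and in-situ zone sensing
#' @description
#' Characterizes photoacoustic signals in time and frequency, scores image
#' quality with the generalized contrast-to-noise ratio (gCNR), estimates
#' the radial distance to the cortical interface from sideways-looking
#' endoscopy scans, and classifies each drilling frame into safe, warning
#' or dangerous zones against the 1.44 mm safe-distance rule.
NULL

#' One-sided spectrum profile of a PA signal
#'
#' @param signal a [pa_signal()] with at least 16 samples.
#' @return An object of class `spectrum_profile`: `frequencies` (Hz),
#'   `magnitudes`, `dominant_freq` (argmax magnitude excluding DC),
#'   `spectral_centroid` (magnitude-weighted mean frequency) and
#'   `peak_amplitude` (time-domain absolute peak).
#' @export
fft_profile <- function(signal) {
  x <- signal$samples
  n <- length(x)
  if (n < 16L) stop("signal too short: need at least 16 samples")
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1L)
  freq <- (half - 1) * signal$sampling_rate / n
  mag <- Mod(X[half])
  nz <- half[-1]
  dominant <- freq[-1][which.max(mag[-1])]
  centroid <- sum(freq[-1] * mag[-1]) / sum(mag[-1])
  structure(list(frequencies = freq, magnitudes = mag,
                 dominant_freq = dominant, spectral_centroid = centroid,
                 peak_amplitude = max(abs(x))),
            class = "spectrum_profile")
}

#' Compare two tissue PA signatures
#'
#' Reports which signal carries the larger time-domain amplitude peak and
#' the larger spectral centroid; equal values are reported as ties.
#'
#' @param sig_a,sig_b [pa_signal()]s; their `tissue` tags (or "a"/"b") name
#'   the winners.
#' @return List with `amplitude_order` and `centroid_order` (winning tag or
#'   "tie") plus the underlying numbers.
#' @export
compare_tissue_signatures <- function(sig_a, sig_b) {
  na <- sig_a$tissue %||% "a"
  nb <- sig_b$tissue %||% "b"
  pa <- fft_profile(sig_a); pb <- fft_profile(sig_b)
  pick <- function(va, vb) {
    if (va > vb) na else if (vb > va) nb else "tie"
  }
  list(amplitude_order = pick(pa$peak_amplitude, pb$peak_amplitude),
       centroid_order = pick(pa$spectral_centroid, pb$spectral_centroid),
       peak_amplitude = stats::setNames(c(pa$peak_amplitude, pb$peak_amplitude),
                                        c(na, nb)),
       spectral_centroid = stats::setNames(
         c(pa$spectral_centroid, pb$spectral_centroid), c(na, nb)))
}

#' Scan-convert a polar PAE image to cartesian
#'
#' Nearest-neighbour polar-to-cartesian resampling centred on the drill
#' axis. Pixels beyond the maximum depth (or inside the first radial
#' sample) are zero.
#'
#' @param image a [pae_image()].
#' @param pixel_mm cartesian pixel size in mm.
#' @return Numeric matrix (square, centred on the axis) with attribute
#'   `pixel_mm`.
#' @export
scan_convert <- function(image, pixel_mm = 0.05) {
  n_ang <- nrow(image$polar); n_dep <- ncol(image$polar)
  r_max <- n_dep * image$depth_step
  half <- ceiling(r_max / pixel_mm)
  ax <- (-half:half) * pixel_mm
  xy <- expand.grid(x = ax, y = ax)
  r <- sqrt(xy$x^2 + xy$y^2)
  th <- atan2(xy$y, xy$x) %% (2 * pi)
  ri <- round(r / image$depth_step)
  ai <- (round(th / image$angle_step_rad) %% n_ang) + 1
  ok <- ri >= 1 & ri <= n_dep
  out <- numeric(nrow(xy))
  out[ok] <- image$polar[cbind(ai[ok], ri[ok])]
  m <- matrix(out, length(ax), length(ax))
  attr(m, "pixel_mm") <- pixel_mm
  m
}

#' Generalized contrast-to-noise ratio
#'
#' Estimates the overlap (OVL) of the intensity probability density
#' functions inside and outside a target and returns `gCNR = 1 - OVL`. The
#' PDFs are histograms on shared bin edges spanning the pooled range; OVL is
#' the summed bin-wise minimum, which reduces to the single
#' optimal-threshold form when the PDFs cross once and also handles
#' multi-crossing PDFs. The reported threshold is the edge of the first
#' crossing bin.
#'
#' @param image numeric matrix (or vector) of pixel intensities.
#' @param roi_in,roi_out disjoint ROIs of at least 50 pixels each: logical
#'   masks or index vectors into `image`.
#' @param n_bins number of shared histogram bins.
#' @param bin_method `"equal"` for equal-width bins over the pooled range,
#'   `"quantile"` for rank-preserving shared bins (invariant to monotone
#'   intensity remapping).
#' @return An object of class `gcnr_result`: `gcnr`, `ovl`, `threshold`,
#'   `pdf_in`, `pdf_out` (densities), `bin_edges`.
#' @export
#' @examples
#' img <- matrix(c(rnorm(100, 0.8, 0.05), rnorm(100, 0.2, 0.05)), 10)
#' gcnr(img, 1:100, 101:200)$gcnr
gcnr <- function(image, roi_in, roi_out, n_bins = 64,
                 bin_method = c("equal", "quantile")) {
  bin_method <- match.arg(bin_method)
  vals <- as.numeric(image)
  sel <- function(roi) {
    if (is.logical(roi)) which(as.vector(roi)) else as.integer(roi)
  }
  i_in <- sel(roi_in); i_out <- sel(roi_out)
  if (length(i_in) < 50L || length(i_out) < 50L) {
    stop("each ROI needs at least 50 pixels")
  }
  if (length(intersect(i_in, i_out)) > 0L) stop("ROIs must be disjoint")
  x_in <- vals[i_in]; x_out <- vals[i_out]
  pooled <- c(x_in, x_out)
  if (bin_method == "equal") {
    rng <- range(pooled)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  } else {
    edges <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1L),
                                    names = FALSE, type = 8))
    if (length(edges) < 2L) edges <- c(edges[1] - 0.5, edges[1] + 0.5)
  }
  count <- function(x) {
    h <- graphics::hist(pmin(pmax(x, edges[1]), edges[length(edges)]),
                        breaks = edges, plot = FALSE)
    h$counts
  }
  m_in <- count(x_in) / length(x_in)
  m_out <- count(x_out) / length(x_out)
  dx <- diff(edges)
  ovl <- sum(pmin(m_in, m_out))
  sgn <- sign(m_in - m_out)
  cross <- which(diff(sgn[sgn != 0]) != 0)
  nz <- which(sgn != 0)
  threshold <- if (length(cross) > 0L) edges[nz[cross[1] + 1L]] else NA_real_
  structure(list(gcnr = 1 - ovl, ovl = ovl, threshold = threshold,
                 pdf_in = m_in / dx, pdf_out = m_out / dx, bin_edges = edges),
            class = "gcnr_result")
}

#' @export
print.gcnr_result <- function(x, ...) {
  cat(sprintf("gcnr_result: gCNR %.3f (OVL %.3f)\n", x$gcnr, x$ovl))
  invisible(x)
}

# Band-limited envelope of one radial A-scan via spectral masking: keep the
# positive-frequency band, double it, inverse transform, take the modulus
# (analytic-signal envelope).
band_envelope <- function(a, depth_step, f_lo, f_hi) {
  n <- length(a)
  fs <- 1 / depth_step              # samples per mm
  freq <- (seq_len(n) - 1) / n * fs # cycles per mm
  X <- stats::fft(a)
  keep <- freq >= f_lo & freq <= f_hi & freq <= fs / 2
  Y <- complex(real = rep(0, n))
  Y[keep] <- 2 * X[keep]
  Mod(stats::fft(Y, inverse = TRUE) / n)
}

# Spatial-frequency bands (cycles/mm) for the two bone signatures.
signature_bands <- function(sig = pa_defaults()) {
  k_c <- sig$cancellous$fc_hz / sig$sound_speed_mm_s
  k_k <- sig$cortical$fc_hz / sig$sound_speed_mm_s
  list(cancellous = c(0.55, 1.6) * k_c, cortical = c(0.75, 1.25) * k_k)
}

#' Estimate the radial distance to the cortical interface
#'
#' Band-passes each A-scan of a sector at the cortical centre frequency and
#' locates the envelope peak; the sector estimate is the smallest peak
#' radius across its A-scans (the closest wall point seen by the sector).
#' Sub-sample precision comes from parabolic interpolation around the peak.
#'
#' @param image a [pae_image()].
#' @param sector sector index in `1..n_sectors`.
#' @param n_sectors number of angular sectors (must divide the angle count).
#' @param noise_gate minimum envelope peak treated as a real echo.
#' @param sig signature parameters, see [pa_defaults()].
#' @return Distance in mm, or `NA` when no cortical echo exceeds the gate.
#' @export
estimate_interface_distance <- function(image, sector, n_sectors = 8,
                                        noise_gate = 0.25,
                                        sig = pa_defaults()) {
  n_ang <- nrow(image$polar)
  if (n_ang %% n_sectors != 0L) stop("n_sectors must divide the angle count")
  if (sector < 1 || sector > n_sectors) stop("sector out of range")
  per <- n_ang / n_sectors
  rows <- ((sector - 1) * per + 1):(sector * per)
  band <- signature_bands(sig)$cortical
  best <- NA_real_
  radii <- seq_len(ncol(image$polar)) * image$depth_step
  for (i in rows) {
    env <- band_envelope(image$polar[i, ], image$depth_step, band[1], band[2])
    j <- which.max(env)
    if (env[j] < noise_gate) next
    r <- radii[j]
    if (j > 1L && j < length(env)) {
      den <- env[j - 1] - 2 * env[j] + env[j + 1]
      if (den < 0) r <- r + 0.5 * (env[j - 1] - env[j + 1]) / den * image$depth_step
    }
    if (is.na(best) || r < best) best <- r
  }
  best
}

#' Classify a PAE frame into safe, warning or dangerous
#'
#' Splits the scan into angular sectors and flags each as `cancellous`
#' (low-frequency bone signature present), `interface` (cortical echo
#' closer than the warning threshold) or `none` (below the noise gate).
#' The frame is `dangerous` when at least 80% of sectors carry no signal
#' (signal loss outside bone), `warning` when any sector sees the cortical
#' interface inside the safe distance, and `safe` otherwise.
#'
#' @param image a [pae_image()].
#' @param n_sectors number of angular sectors (default 8).
#' @param warning_threshold safe distance in mm (default 1.44).
#' @param noise_gate envelope threshold separating signal from noise.
#' @param sig signature parameters, see [pa_defaults()].
#' @return An object of class `zone_status`: `label`, `sector_flags`,
#'   `min_interface_distance` (NA when no interface is seen),
#'   `warning_threshold`.
#' @export
classify_zone <- function(image, n_sectors = 8, warning_threshold = 1.44,
                          noise_gate = 0.25, sig = pa_defaults()) {
  n_ang <- nrow(image$polar)
  if (n_ang %% n_sectors != 0L) stop("n_sectors must divide the angle count")
  bands <- signature_bands(sig)
  per <- n_ang / n_sectors
  flags <- character(n_sectors)
  dmin <- NA_real_
  for (s in seq_len(n_sectors)) {
    rows <- ((s - 1) * per + 1):(s * per)
    canc_peak <- 0
    for (i in rows) {
      env <- band_envelope(image$polar[i, ], image$depth_step,
                           bands$cancellous[1], bands$cancellous[2])
      canc_peak <- max(canc_peak, max(env))
    }
    d <- estimate_interface_distance(image, s, n_sectors, noise_gate, sig)
    if (!is.na(d) && (is.na(dmin) || d < dmin)) dmin <- d
    flags[s] <- if (!is.na(d) && d < warning_threshold) {
      "interface"
    } else if (canc_peak >= noise_gate) {
      "cancellous"
    } else {
      "none"
    }
  }
  label <- if (mean(flags == "none") >= 0.8) {
    "dangerous"
  } else if (any(flags == "interface")) {
    "warning"
  } else {
    "safe"
  }
  structure(list(label = label, sector_flags = flags,
                 min_interface_distance = dmin,
                 warning_threshold = warning_threshold),
            class = "zone_status")
}

#' @export
print.zone_status <- function(x, ...) {
  cat(sprintf("zone_status: %s (min interface %.2f mm)\n", x$label,
              ifelse(is.na(x$min_interface_distance), Inf,
                     x$min_interface_distance)))
  invisible(x)
}

#' Classify a drilling timeline of PAE frames
#'
#' Applies [classify_zone()] per frame and segments the timeline into
#' phases: `initial` is the leading run of signal-loss (dangerous) frames
#' before the probe reaches bone, `exited` the trailing run after it leaves,
#' and `in-bone` everything between.
#'
#' @param images list of [pae_image()]s (at least 2).
#' @param ... arguments forwarded to [classify_zone()].
#' @return List with `status` (list of `zone_status`), `zones` (character),
#'   `phase` (character) per frame.
#' @export
classify_timeline <- function(images, ...) {
  if (length(images) < 2L) stop("need at least 2 frames")
  status <- lapply(images, classify_zone, ...)
  zones <- vapply(status, `[[`, "", "label")
  n <- length(zones)
  phase <- rep("in-bone", n)
  nd <- which(zones != "dangerous")
  if (length(nd) == 0L) {
    phase[] <- "exited"
  } else {
    if (nd[1] > 1L) phase[seq_len(nd[1] - 1L)] <- "initial"
    if (nd[length(nd)] < n) phase[(nd[length(nd)] + 1L):n] <- "exited"
  }
  list(status = status, zones = zones, phase = phase)
}

#' Trajectory-level interpretation of a zone sequence
#'
#' Reduces a per-frame zone sequence to the three canonical drilling
#' outcomes: `"correct"` (no breach warning at any point), `"lateral-graze"`
#' (warning followed by recovery to safe drilling) and `"medial-breach"`
#' (warning followed by signal loss, i.e. cortical penetration).
#'
#' @param zones character vector of per-frame labels, or the result of
#'   [classify_timeline()].
#' @return One of `"correct"`, `"lateral-graze"`, `"medial-breach"`.
#' @export
classify_trajectory <- function(zones) {
  if (is.list(zones)) zones <- zones$zones
  w <- which(zones == "warning")
  if (length(w) == 0L) return("correct")
  after <- zones[seq.int(max(w) + 1L, length.out = length(zones) - max(w))]
  if (length(after) > 0L && all(after == "dangerous")) return("medial-breach")
  "lateral-graze"
}

#' Laser fluence safety check
#'
#' Compares a sample fluence against the ANSI skin exposure limit.
#'
#' @param fluence fluence at the sample in mJ/cm2 (>= 0).
#' @param limit safety limit in mJ/cm2 (default 30, the ANSI standard).
#' @return List with `ok` (fluence within the limit) and `margin`
#'   (`limit - fluence`, mJ/cm2).
#' @export
check_fluence <- function(fluence, limit = 30) {
  if (fluence < 0) stop("fluence must be non-negative")
  list(ok = fluence <= limit, margin = limit - fluence)
}
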