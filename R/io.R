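#' @name io
#' @title Readers and writers for the toolkit's artifact types
#' @description
#' Point clouds travel as ASCII PLY (x, y, z and an optional integer level
#' with a label dictionary in a header comment); volumes as NIfTI with a
#' JSON geometry sidecar; tracked frames as 8-bit PNG plus a CSV pose table
#' (12 row-major entries of the 3x4 point-mapping transform); signals and
#' spectra as two-column CSV; polar PAE images as 32-bit float TIFF with a
#' JSON sidecar; run configurations as YAML. Floating-point round-trips are
#' exact except PNG images, which quantize to 1/255 on first write.
NULL

#' Write a point cloud to ASCII PLY
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  n <- nrow(cloud$points)
  has_level <- !is.null(cloud$level)
  dict <- if (has_level) sort(unique(cloud$level))
  header <- c(
    "ply", "format ascii 1.0",
    if (has_level) paste0("comment levels ", paste(dict, collapse = ",")),
    paste("element vertex", n),
    "property double x", "property double y", "property double z",
    if (has_level) "property int level",
    "end_header")
  body <- apply(format(cloud$points, digits = 17, trim = TRUE,
                       scientific = FALSE), 1, paste, collapse = " ")
  if (has_level) body <- paste(body, match(cloud$level, dict) - 1L)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a point cloud from ASCII PLY
#'
#' @param path input file written by [write_ply()] (or any ASCII PLY with
#'   x, y, z leading vertex properties).
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != "ply") {
    stop("format error: not an ASCII PLY file")
  }
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("format error: PLY header not terminated")
  header <- lines[seq_len(endh)]
  nline <- grep("^element vertex ", header, value = TRUE)
  if (length(nline) != 1L) stop("format error: missing vertex element")
  n <- as.integer(sub("^element vertex ", "", nline))
  dict <- NULL
  cl <- grep("^comment levels ", header, value = TRUE)
  if (length(cl) == 1L) dict <- strsplit(sub("^comment levels ", "", cl), ",")[[1]]
  body <- lines[seq.int(endh + 1L, length.out = length(lines) - endh)]
  body <- body[nzchar(body)]
  if (length(body) < n) {
    stop(sprintf("format error: truncated PLY, expected %d vertices got %d (line %d)",
                 n, length(body), length(lines)))
  }
  fields <- do.call(rbind, strsplit(trimws(body[seq_len(n)]), "\\s+"))
  pts <- matrix(as.numeric(fields[, 1:3]), ncol = 3)
  lvl <- if (!is.null(dict) && ncol(fields) >= 4L) {
    dict[as.integer(fields[, 4]) + 1L]
  }
  point_cloud(pts, lvl)
}

#' Write a compounded ultrasound volume
#'
#' Voxel values go to NIfTI (empty voxels as NaN), hit counts to a second
#' NIfTI, and spacing/origin to a JSON sidecar.
#'
#' @param vol a [us_volume()].
#' @param path base path; `.nii.gz`, `_hits.nii.gz` and `.json` files are
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_us_volume <- function(vol, path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  RNifti::writeNifti(RNifti::asNifti(vol$voxels, pixdim = rep(vol$spacing, 3)),
                     paste0(base, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(vol$hit_count + 0,
                                     pixdim = rep(vol$spacing, 3)),
                     paste0(base, "_hits.nii.gz"))
  jsonlite::write_json(list(spacing = vol$spacing, origin = vol$origin),
                       paste0(base, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a compounded ultrasound volume
#'
#' @param path base path as given to [write_us_volume()].
#' @return A [us_volume()].
#' @export
read_us_volume <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  vox <- RNifti::readNifti(paste0(base, ".nii.gz"))
  hits <- RNifti::readNifti(paste0(base, "_hits.nii.gz"))
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  vx <- array(as.numeric(vox), dim = dim(vox))
  vx[is.nan(vx)] <- NA_real_
  us_volume(vx, meta$spacing, meta$origin,
            array(as.integer(round(as.numeric(hits))), dim = dim(hits)))
}

#' Write tracked frames as PNG images plus a CSV pose table
#'
#' The pose table stores one row per frame: `frame_id`, the 12 row-major
#' entries of the 3x4 point-mapping transform (`r11..r33`, `t1..t3`
#' interleaved as rows `r11 r12 r13 t1 ...`), `pixel_spacing` and
#' `timestamp`. PNG is 8-bit: intensities quantize to 1/255.
#'
#' @param frames list of [tracked_frame()]s.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return The pose CSV path, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    png::writePNG(pmin(pmax(fr$image, 0), 1),
                  file.path(dir, sprintf("%s_%04d.png", prefix, i)))
    M <- cbind(fr$pose$R, fr$pose$t)
    data.frame(frame_id = i, t(as.vector(t(M))),
               pixel_spacing = fr$pixel_spacing, timestamp = fr$timestamp)
  })
  tab <- do.call(rbind, rows)
  names(tab)[2:13] <- paste0("m", rep(1:3, each = 4), rep(1:4, 3))
  csv <- file.path(dir, paste0(prefix, "_poses.csv"))
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}

#' Read tracked frames written by [write_frames()]
#'
#' @param dir directory holding the PNGs and pose CSV.
#' @param prefix file-name prefix used when writing.
#' @return List of [tracked_frame()]s.
#' @export
read_frames <- function(dir, prefix = "frame") {
  tab <- utils::read.csv(file.path(dir, paste0(prefix, "_poses.csv")))
  lapply(seq_len(nrow(tab)), function(i) {
    img <- png::readPNG(file.path(dir, sprintf("%s_%04d.png", prefix,
                                               tab$frame_id[i])))
    M <- matrix(as.numeric(tab[i, 2:13]), 3, 4, byrow = TRUE)
    tracked_frame(img, rigid_transform(M[, 1:3], M[, 4]),
                  tab$pixel_spacing[i], tab$timestamp[i])
  })
}

#' Write a PA signal as CSV
#'
#' @param signal a [pa_signal()].
#' @param path output CSV with columns `t_s`, `amplitude`.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  t_s <- (seq_along(signal$samples) - 1) / signal$sampling_rate
  utils::write.csv(data.frame(t_s = t_s, amplitude = signal$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a PA signal from CSV
#'
#' @param path CSV written by [write_signal_csv()].
#' @param tissue optional tissue tag to attach.
#' @return A [pa_signal()].
#' @export
read_signal_csv <- function(path, tissue = NULL) {
  tab <- utils::read.csv(path)
  if (!all(c("t_s", "amplitude") %in% names(tab)) || nrow(tab) < 2L) {
    stop("format error: expected columns t_s, amplitude")
  }
  pa_signal(tab$amplitude, 1 / diff(tab$t_s[1:2]), tissue)
}

#' Write a spectrum model as CSV
#'
#' @param spectrum a `spectrum_model`.
#' @param path output CSV with columns `wavelength_nm`, `absorbance`.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength_nm,
                              absorbance = spectrum$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a polar PAE image as float TIFF with a JSON sidecar
#'
#' @param image a [pae_image()].
#' @param path output TIFF path; a `.json` sidecar carries the geometry.
#' @return `path`, invisibly.
#' @export
write_pae_tiff <- function(image, path) {
  # RF amplitudes are signed; TIFF stores [0, 1] floats, so rescale and keep
  # the affine coefficients in the sidecar (round-trip exact to float32).
  lo <- min(image$polar); hi <- max(image$polar)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image$polar - lo) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(depth_step = image$depth_step,
                            acquisition_time_s = image$acquisition_time_s,
                            offset = lo, scale = scale),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a polar PAE image written by [write_pae_tiff()]
#'
#' @param path TIFF path.
#' @return A [pae_image()].
#' @export
read_pae_tiff <- function(path) {
  polar <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pae_image(polar * meta$scale + meta$offset, meta$depth_step,
            meta$acquisition_time_s)
}

run_config_blocks <- c("seed", "phantom", "sweep", "detector", "registration",
                       "pae", "output_dir")

#' Read and validate a run configuration
#'
#' @param path YAML file with blocks among `seed`, `phantom`, `sweep`,
#'   `detector`, `registration`, `pae`, `output_dir`; unknown keys are
#'   rejected.
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_blocks)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config named list / `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), run_config_blocks)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Save a trained detector as JSON
#'
#' Weights, configuration and training history in one JSON checkpoint.
#'
#' @param detector a [train_two_loss_detector()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_detector <- function(detector, path) {
  payload <- list(
    par = lapply(detector$par, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    config = unclass(detector$config),
    levels_seen = detector$levels_seen,
    n_rows = detector$n_rows,
    history = detector$history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a detector checkpoint written by [write_detector()]
#'
#' @param path JSON checkpoint path.
#' @return A `two_loss_detector`.
#' @export
read_detector <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(payload$par, function(p) {
    dm <- as.integer(unlist(p$dim))
    dat <- as.numeric(unlist(p$data))
    if (length(dm) == 2L) matrix(dat, dm[1], dm[2]) else dat
  })
  structure(list(par = par,
                 config = do.call(detector_config, payload$config),
                 levels_seen = payload$levels_seen,
                 n_rows = payload$n_rows,
                 history = payload$history),
            class = "two_loss_detector")
}
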