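#' Compounded 3D ultrasound volume
#'
#' @param voxels 3D numeric array; voxels never touched by a frame are `NA`
#'   (marked empty, not zero-valued).
#' @param spacing isotropic voxel spacing in mm.
#' @param origin world coordinate of the centre of voxel `[1, 1, 1]`, mm.
#' @param hit_count integer array of contributing-pixel counts per voxel.
#' @return An object of class `us_volume`.
#' @export
us_volume <- function(voxels, spacing, origin, hit_count) {
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 hit_count = hit_count), class = "us_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  cat("us_volume:", paste(dim(x$voxels), collapse = "x"), "voxels @",
      x$spacing, "mm,", sum(x$hit_count > 0), "occupied\n")
  invisible(x)
}

#' Compound tracked frames into a 3D volume
#'
#' Forward pixel-splatting with mean fusion: every pixel of every frame is
#' mapped through its pose into the voxel grid; a voxel's value is the mean
#' of all contributing pixels and its `hit_count` records how many there
#' were. The bounding box covers all mapped pixels. Mean fusion makes the
#' result invariant to the frame order.
#'
#' @param frames list of [tracked_frame()]s with identical pixel spacing.
#' @param spacing voxel spacing in mm.
#' @return A [us_volume()].
#' @export
compound_volume <- function(frames, spacing) {
  if (length(frames) == 0L) stop("need at least one frame")
  if (spacing <= 0) stop("spacing must be positive")
  ps <- vapply(frames, `[[`, numeric(1), "pixel_spacing")
  if (max(ps) - min(ps) > 1e-9) stop("frames must share one pixel spacing")
  world <- lapply(frames, function(fr) {
    nr <- nrow(fr$image); nc <- ncol(fr$image)
    px <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    w <- rt_apply(fr$pose, frame_pixel_coords(fr, px$row, px$col))
    list(w = w, v = as.numeric(fr$image))
  })
  all_w <- do.call(rbind, lapply(world, `[[`, "w"))
  all_v <- unlist(lapply(world, `[[`, "v"))
  origin <- apply(all_w, 2, min)
  idx <- round(sweep(all_w, 2, origin) / spacing) + 1
  dims <- apply(idx, 2, max)
  lin <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
  n_vox <- prod(dims)
  counts <- tabulate(lin, nbins = n_vox)
  sums <- numeric(n_vox)
  agg <- rowsum(all_v, lin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  vox <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  us_volume(array(vox, dims), spacing, origin, array(counts, dims))
}

# Euclidean distance (in pixels) to the nearest TRUE pixel of a mask.
distance_field <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  # distmap measures object pixels' distance to the nearest background
  # pixel, so invert: surface pixels become background.
  d <- EBImage::distmap(EBImage::Image(1 - mask), metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Gaussian heatmap target from a surface mask
#'
#' Learned-target construction for bone-surface detection: each pixel takes
#' `exp(-d^2 / (2 sigma^2))` where `d` is the Euclidean distance (mm) to the
#' nearest surface pixel, so surface pixels are exactly 1 and the ridge
#' decays with distance. An empty mask yields all zeros.
#'
#' @param surface_mask logical (or 0/1) matrix marking surface pixels.
#' @param sigma Gaussian width in mm (> 0).
#' @param pixel_spacing pixel size in mm (default 1, i.e. sigma in pixels).
#' @return An object of class `us_heatmap`: list with `values` in `[0, 1]`
#'   and `sigma`.
#' @export
make_heatmap_target <- function(surface_mask, sigma, pixel_spacing = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  mask <- matrix(as.logical(surface_mask), nrow(surface_mask), ncol(surface_mask))
  d <- distance_field(mask) * pixel_spacing
  vals <- exp(-d^2 / (2 * sigma^2))
  vals[!is.finite(d)] <- 0
  structure(list(values = vals, sigma = sigma), class = "us_heatmap")
}

#' Classical bone-surface detection on one frame
#'
#' Deterministic per-scanline rule exploiting the acoustic shadow behind
#' bone: in each column, the shallowest sample exceeding
#' `threshold * column max` whose trailing mean (the samples below it) stays
#' under `shadow_frac` of the column peak (with at least 8 trailing samples)
#' is marked as the surface. Columns without such a sample stay unmarked;
#' speckle columns fail the shadow criterion because their trailing mean
#' matches the speckle mean.
#'
#' @param frame a [tracked_frame()] or plain image matrix.
#' @param threshold fraction of the column maximum (default 0.5).
#' @param shadow_frac maximum trailing mean relative to the column peak.
#' @return Logical matrix of the image size marking surface pixels.
#' @export
classical_detect <- function(frame, threshold = 0.5, shadow_frac = 0.18) {
  img <- if (inherits(frame, "tracked_frame")) frame$image else as.matrix(frame)
  if (length(img) == 0L) stop("image must be non-empty")
  nr <- nrow(img)
  mask <- matrix(FALSE, nr, ncol(img))
  for (cc in seq_len(ncol(img))) {
    v <- img[, cc]
    m <- max(v)
    if (m <= 0) next
    for (r in which(v > threshold * m)) {
      below <- v[seq.int(min(r + 2L, nr + 1L), length.out = max(0L, nr - r - 1L))]
      if (length(below) >= 8L && mean(below) < shadow_frac * m) {
        mask[r, cc] <- TRUE
        break
      }
    }
  }
  mask
}

#' Extract a bone-surface point cloud
#'
#' Runs surface detection on tracked frames and maps the detected pixels
#' through their poses into world coordinates; alternatively thresholds an
#' already-compounded volume. With a trained two-loss detector, each
#' frame's predicted spine level is attached to its points.
#'
#' @param x list of [tracked_frame()]s, or a [us_volume()].
#' @param detector `"classical"` or a trained [train_two_loss_detector()]
#'   object.
#' @param min_points minimum number of detected points (error below).
#' @param threshold detection threshold forwarded to the detector.
#' @return A [point_cloud()] in world mm, with per-point level labels when a
#'   learned detector is used.
#' @export
extract_point_cloud <- function(x, detector = "classical", min_points = 50,
                                threshold = 0.5) {
  if (inherits(x, "us_volume")) {
    occ <- which(x$hit_count > 0 & !is.na(x$voxels) &
                   x$voxels > threshold * max(x$voxels, na.rm = TRUE),
                 arr.ind = TRUE)
    pts <- sweep((occ - 1) * x$spacing, 2, x$origin, "+")
    if (nrow(pts) < min_points) {
      stop("insufficient surface: fewer than min_points voxels detected")
    }
    return(point_cloud(pts))
  }
  frames <- x
  pts <- list(); labs <- list()
  learned <- inherits(detector, "two_loss_detector")
  for (fr in frames) {
    mask <- if (learned) {
      detect_surface(detector, fr$image, threshold = threshold)
    } else {
      classical_detect(fr, threshold = threshold)
    }
    hit <- which(mask, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    w <- rt_apply(fr$pose, frame_pixel_coords(fr, hit[, 1], hit[, 2]))
    pts[[length(pts) + 1L]] <- w
    if (learned) {
      labs[[length(labs) + 1L]] <- rep(predict_level(detector, fr$image),
                                       nrow(w))
    }
  }
  n <- sum(vapply(pts, nrow, 1L))
  if (n < min_points) {
    stop("insufficient surface: fewer than min_points pixels detected")
  }
  point_cloud(do.call(rbind, pts),
              if (learned) unlist(labs) else NULL)
}
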