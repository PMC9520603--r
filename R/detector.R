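#' @name detector
#' @title Two-loss bone-surface detector
#' @description
#' A deliberately small learned detector for bone surfaces in ultrasound
#' frames, following the two-loss idea used for sparse spinal sonography:
#' the primary loss regresses a Gaussian heatmap built from the distance
#' field of the bone surface (whose sigma anneals down a schedule as the
#' loss drops, sharpening the target), and an auxiliary loss classifies
#' which spine level a frame belongs to. The network is a per-scanline
#' encoder-decoder (column in, heatmap column out) with a frame-pooled
#' softmax head for the level — small enough to train on a CPU in seconds.
NULL

#' Detector configuration
#'
#' @param mode `"classical"` or `"learned"`.
#' @param sigma_schedule strictly decreasing vector of heatmap sigmas
#'   (pixels); training starts wide and anneals down.
#' @param level_count number of spine levels the auxiliary head predicts.
#' @param threshold heatmap threshold in (0, 1) for surface extraction.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for weight initialisation.
#' @param hidden encoder width (bottleneck units).
#' @param lambda_level weight of the level-classification loss.
#' @param advance_ratio the sigma schedule advances when the running heatmap
#'   loss falls below this ratio of its value when the current sigma
#'   started.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(mode = "learned", sigma_schedule = c(8, 4, 2),
                            level_count = 3, threshold = 0.5, epochs = 400,
                            learning_rate = 0.02, seed = 1, hidden = 48,
                            lambda_level = 0.3, advance_ratio = 0.5) {
  if (!mode %in% c("classical", "learned")) stop("unknown detector mode")
  if (any(diff(sigma_schedule) >= 0)) {
    stop("sigma_schedule must be strictly decreasing")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(mode = mode, sigma_schedule = sigma_schedule,
                 level_count = level_count, threshold = threshold,
                 epochs = epochs, learning_rate = learning_rate, seed = seed,
                 hidden = hidden, lambda_level = lambda_level,
                 advance_ratio = advance_ratio),
            class = "detector_config")
}

#' Synthetic detector training set
#'
#' Generates ultrasound-like frames whose bone-surface depth band depends on
#' the spine level (deeper and larger for caudal levels, as in lumbar
#' anatomy), rendered with the same ridge/shadow/speckle model as
#' [simulate_us_frame()]. Level labels are balanced.
#'
#' @param n_frames number of frames.
#' @param n_levels number of distinct levels.
#' @param size frame size in pixels (square).
#' @param seed RNG seed.
#' @param speckle_scale Rayleigh speckle scale; 0 gives noiseless frames.
#' @return List with `frames` (matrices), `masks` (logical matrices),
#'   `levels` (integer labels) and `depth_px` (true per-column depths).
#' @export
make_detector_dataset <- function(n_frames = 64, n_levels = 3, size = 64,
                                  seed = 1, speckle_scale = 0) {
  if (n_levels < 1) stop("need at least one level")
  with_seed(seed, {
    levels <- rep(seq_len(n_levels), length.out = n_frames)
    base <- size * (0.2 + 0.5 * (levels - 1) / max(1, n_levels - 1))
    frames <- vector("list", n_frames)
    masks <- vector("list", n_frames)
    depth <- matrix(NA_real_, n_frames, size)
    cols <- seq_len(size)
    rows <- seq_len(size)
    for (i in seq_len(n_frames)) {
      d <- base[i] + stats::runif(1, -2, 2) +
        3 * sin(2 * pi * stats::runif(1, 0.5, 1.5) * cols / size +
                  stats::runif(1, 0, 2 * pi))
      img <- if (speckle_scale > 0) {
        matrix(rrayleigh(size * size, speckle_scale), size, size)
      } else {
        matrix(0, size, size)
      }
      mask <- matrix(FALSE, size, size)
      for (cc in cols) {
        ridge <- exp(-(rows - d[cc])^2 / 2)
        col <- img[, cc]
        col[rows > d[cc] + 1.5] <- 0
        img[, cc] <- pmin(1, col + ridge)
        mask[round(d[cc]), cc] <- TRUE
      }
      frames[[i]] <- img
      masks[[i]] <- mask
      depth[i, ] <- d
    }
    list(frames = frames, masks = masks, levels = levels, depth_px = depth)
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the two-loss detector
#'
#' Full-batch Adam on the heatmap-regression loss plus the auxiliary
#' level-classification loss. The heatmap target for each frame is
#' [make_heatmap_target()] at the current sigma of the schedule; the sigma
#' advances once the epoch loss drops below `advance_ratio` times the loss
#' at the start of the current sigma stage, so the recorded sigma-per-epoch
#' sequence is non-increasing and takes only scheduled values.
#'
#' @param dataset list with `frames`, `masks` and `levels`, e.g. from
#'   [make_detector_dataset()].
#' @param config a [detector_config()].
#' @return An object of class `two_loss_detector` carrying the weights,
#'   config, level dictionary and training `history` (epoch, sigma,
#'   heatmap loss, level loss).
#' @export
train_two_loss_detector <- function(dataset, config = detector_config()) {
  frames <- dataset$frames; masks <- dataset$masks; levels <- dataset$levels
  if (length(frames) < 2L) stop("need at least 2 frames")
  lv_dict <- sort(unique(levels))
  if (config$lambda_level > 0 && length(lv_dict) < 2L) {
    stop("level loss enabled but only one level class present")
  }
  n_rows <- nrow(frames[[1]])
  n_cols <- ncol(frames[[1]])
  nf <- length(frames)
  X <- do.call(rbind, lapply(frames, t))          # (nf*n_cols) x n_rows
  frame_of <- rep(seq_len(nf), each = n_cols)
  dists <- lapply(masks, distance_field)          # pixel distances, cached
  target_at <- function(sigma) {
    do.call(rbind, lapply(dists, function(d) {
      v <- exp(-d^2 / (2 * sigma^2))
      v[!is.finite(d)] <- 0
      t(v)
    }))
  }
  K <- length(lv_dict)
  Yl <- matrix(0, nf, K)
  Yl[cbind(seq_len(nf), match(levels, lv_dict))] <- 1
  h <- config$hidden
  par <- with_seed(config$seed, list(
    W1 = matrix(stats::rnorm(n_rows * h, 0, 1 / sqrt(n_rows)), n_rows, h),
    b1 = rep(0, h),
    W2 = matrix(stats::rnorm(h * n_rows, 0, 1 / sqrt(h)), h, n_rows),
    b2 = rep(0, n_rows),
    W3 = matrix(stats::rnorm(h * K, 0, 1 / sqrt(h)), h, K),
    b3 = rep(0, K)
  ))
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  sched <- config$sigma_schedule
  si <- 1L
  stage_loss <- NA_real_
  history <- data.frame(epoch = integer(0), sigma = numeric(0),
                        loss_heat = numeric(0), loss_level = numeric(0))
  Y <- target_at(sched[si])
  N <- nrow(X)
  pool <- function(H) {
    # frame-mean of hidden codes
    rowsum(H, frame_of) / n_cols
  }
  for (ep in seq_len(config$epochs)) {
    Z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
    H <- tanh(Z1)
    P <- sigmoid(sweep(H %*% par$W2, 2, par$b2, "+"))
    hf <- pool(H)
    logits <- sweep(hf %*% par$W3, 2, par$b3, "+")
    logits <- logits - apply(logits, 1, max)
    sm <- exp(logits) / rowSums(exp(logits))
    loss_heat <- mean((P - Y)^2)
    loss_level <- -mean(rowSums(Yl * log(pmax(sm, 1e-12))))
    history <- rbind(history, data.frame(epoch = ep, sigma = sched[si],
                                         loss_heat = loss_heat,
                                         loss_level = loss_level))
    if (is.na(stage_loss)) stage_loss <- loss_heat
    # gradients
    dP <- 2 * (P - Y) * P * (1 - P) / length(P)
    gW2 <- crossprod(H, dP)
    gb2 <- colSums(dP)
    dH <- dP %*% t(par$W2)
    dlog <- (sm - Yl) * (config$lambda_level / nf)
    gW3 <- crossprod(hf, dlog)
    gb3 <- colSums(dlog)
    dhf <- dlog %*% t(par$W3)
    dH <- dH + dhf[frame_of, , drop = FALSE] / n_cols
    dZ1 <- dH * (1 - H^2)
    gW1 <- crossprod(X, dZ1)
    gb1 <- colSums(dZ1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
    for (nm in names(par)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^ep)
      vhat <- v[[nm]] / (1 - beta2^ep)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (si < length(sched) && loss_heat < config$advance_ratio * stage_loss) {
      si <- si + 1L
      Y <- target_at(sched[si])
      stage_loss <- NA_real_
    }
  }
  structure(list(par = par, config = config, levels_seen = lv_dict,
                 n_rows = n_rows, history = history),
            class = "two_loss_detector")
}

#' @export
print.two_loss_detector <- function(x, ...) {
  cat(sprintf(
    "two_loss_detector: %d-row scanlines, hidden %d, %d levels, %d epochs\n",
    x$n_rows, x$config$hidden, length(x$levels_seen), nrow(x$history)))
  invisible(x)
}

detector_forward <- function(detector, image) {
  X <- t(as.matrix(image))
  H <- tanh(sweep(X %*% detector$par$W1, 2, detector$par$b1, "+"))
  P <- sigmoid(sweep(H %*% detector$par$W2, 2, detector$par$b2, "+"))
  list(heat = t(P), H = H)
}

#' Predict a surface heatmap for one frame
#'
#' @param detector a [train_two_loss_detector()] result.
#' @param image frame matrix (rows = depth).
#' @return Numeric matrix of heatmap values in `[0, 1]`.
#' @export
predict_heatmap <- function(detector, image) {
  detector_forward(detector, image)$heat
}

#' Extract a surface mask from the detector's heatmap
#'
#' Per-column argmax of the predicted heatmap, kept only where the maximum
#' exceeds the threshold.
#'
#' @param detector a [train_two_loss_detector()] result.
#' @param image frame matrix.
#' @param threshold heatmap acceptance threshold (defaults to the config's).
#' @return Logical surface mask.
#' @export
detect_surface <- function(detector, image, threshold = NULL) {
  threshold <- threshold %||% detector$config$threshold
  heat <- predict_heatmap(detector, image)
  mask <- matrix(FALSE, nrow(heat), ncol(heat))
  for (cc in seq_len(ncol(heat))) {
    j <- which.max(heat[, cc])
    if (heat[j, cc] > threshold) mask[j, cc] <- TRUE
  }
  mask
}

#' Predict the spine level of a frame
#'
#' @param detector a [train_two_loss_detector()] result.
#' @param image frame matrix.
#' @return The predicted level label (from the training dictionary).
#' @export
predict_level <- function(detector, image) {
  H <- detector_forward(detector, image)$H
  hf <- colMeans(H)
  logits <- as.numeric(hf %*% detector$par$W3) + detector$par$b3
  detector$levels_seen[which.max(logits)]
}

#' Per-column surface depths of a mask
#'
#' @param mask logical surface mask.
#' @return Numeric vector (one per column) of marked row indices, `NA` for
#'   unmarked columns (the shallowest mark is used if several exist).
#' @export
mask_depths <- function(mask) {
  apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_real_ else w[1]
  })
}

#' Surface detection recall within a pixel tolerance
#'
#' Fraction of columns with a true surface whose detected depth lies within
#' `tol_px` pixels of the truth.
#'
#' @param pred_mask logical predicted mask.
#' @param true_depth_px numeric per-column true depths (NA where no bone).
#' @param tol_px tolerance in pixels.
#' @return Recall in `[0, 1]`.
#' @export
surface_recall <- function(pred_mask, true_depth_px, tol_px = 2) {
  pred <- mask_depths(pred_mask)
  ok <- !is.na(true_depth_px)
  mean(!is.na(pred[ok]) & abs(pred[ok] - true_depth_px[ok]) <= tol_px)
}
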