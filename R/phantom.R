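#' @name phantom
#' @title Parametric lumbar spine phantom
#' @description
#' The phantom stands in for a pre-operative CT model: each vertebra is an
#' analytic union of an ellipsoidal body, two cylindrical pedicles and
#' box-like posterior elements, with a cortical shell of configurable
#' thickness around a cancellous core. All coordinates are mm in a
#' right-handed world frame: x lateral, y anterior (the drilling direction),
#' z axial (caudal stacking of levels). Vertebra size grows slightly per
#' caudal level and the posterior surface deepens, mirroring lumbar anatomy;
#' this also gives ultrasound frames a level-dependent appearance.
NULL

tissue_labels <- c(background = 0L, muscle = 1L, cortical = 2L, cancellous = 3L)

phantom_defaults <- function() {
  list(
    pedicle_width = 3.5,        # outer pedicle diameter, mm
    cortical_thickness = 0.25,  # shell thickness, mm
    pedicle_sep = 18,           # distance between left/right pedicle axes, mm
    pedicle_length = 12,        # pedicle span along y, mm
    body_semi = c(18, 14, 11),  # body ellipsoid semi-axes at the top level, mm
    block_half = c(5, 5),       # posterior element half-extent in x and z, mm
    block_depth = 8,            # posterior element span along -y, mm
    level_pitch = 28,           # axial spacing between levels, mm
    level_scale_step = 0.08,    # per-level body scale increment
    level_offset_step = 1.6,    # per-level posterior surface deepening, mm
    n_surface_points = 1800     # surface samples per level
  )
}

# Geometry record for one level in level-local coordinates.
level_geometry <- function(params, k) {
  s <- min(1 + params$level_scale_step * (k - 1), 1.24)  # keep bodies disjoint
  semi <- params$body_semi * s
  xp <- params$pedicle_sep / 2
  r_out <- params$pedicle_width / 2
  th <- params$cortical_thickness
  # body centre chosen so its posterior surface meets the pedicle end
  yc <- params$pedicle_length + semi[2] * sqrt(1 - (xp / semi[1])^2)
  list(
    scale = s, xp = xp, r_out = r_out, r_in = r_out - th, th = th,
    ped_len = params$pedicle_length,
    body_semi = semi, body_center = c(0, yc, 0),
    block_half = params$block_half,
    block_depth = params$block_depth + params$level_offset_step * (k - 1),
    z0 = (k - 1) * params$level_pitch
  )
}

# Vectorised inside tests on an Nx3 matrix of level-local points. `shrink`
# moves the surface inwards (shrink = cortical thickness gives the core).
inside_body <- function(p, g, shrink = 0) {
  semi <- g$body_semi - shrink
  rowSums(sweep(sweep(p, 2, g$body_center), 2, semi, "/")^2) <= 1
}
inside_pedicle <- function(p, g, side, shrink = 0, ext = 0) {
  # `ext` lengthens the cylinder into the vertebral body; used for the
  # cancellous core so the pedicle-body junction is a continuous corridor
  # rather than walled off by the body shell.
  r <- g$r_out - shrink
  p[, 2] >= 0 & p[, 2] <= g$ped_len + ext &
    (p[, 1] - side * g$xp)^2 + p[, 3]^2 <= r^2
}
inside_block <- function(p, g, side, shrink = 0) {
  abs(p[, 1] - side * g$xp) <= g$block_half[1] - shrink &
    p[, 2] >= -g$block_depth & p[, 2] <= 0 &
    abs(p[, 3]) <= g$block_half[2] - shrink
}

# Tissue label codes for level-local points of one level (0 if outside bone).
level_labels <- function(p, g) {
  core <- inside_body(p, g, g$th) |
    inside_pedicle(p, g, +1, g$th, ext = 2.5) |
    inside_pedicle(p, g, -1, g$th, ext = 2.5) |
    inside_block(p, g, +1, g$th) | inside_block(p, g, -1, g$th)
  outer <- inside_body(p, g) |
    inside_pedicle(p, g, +1) | inside_pedicle(p, g, -1) |
    inside_block(p, g, +1) | inside_block(p, g, -1)
  ifelse(core, tissue_labels[["cancellous"]],
         ifelse(outer, tissue_labels[["cortical"]], tissue_labels[["background"]]))
}

#' Tissue label at world points
#'
#' Analytic label lookup on the phantom solids: cancellous core, cortical
#' shell, muscle (posterior soft tissue, y < 0) or background.
#'
#' @param phantom a [make_spine_phantom()] result.
#' @param points Nx3 matrix of world coordinates in mm.
#' @return Integer vector of label codes (0 background, 1 muscle, 2 cortical,
#'   3 cancellous), with names from the label set.
#' @export
label_points <- function(phantom, points) {
  p <- as_points(points)
  lab <- rep(tissue_labels[["background"]], nrow(p))
  for (lv in phantom$levels) {
    g <- lv$geom
    loc <- p
    loc[, 3] <- loc[, 3] - g$z0
    # quick reject: outside the level's axial slab
    near <- abs(loc[, 3]) <= max(g$body_semi[3], g$block_half[2]) + 1
    if (!any(near)) next
    ll <- level_labels(loc[near, , drop = FALSE], g)
    lab[near] <- pmax(lab[near], ll)
  }
  lab[lab == tissue_labels[["background"]] & p[, 2] < 0] <- tissue_labels[["muscle"]]
  names(lab) <- names(tissue_labels)[lab + 1L]
  lab
}

# Sample points on the outer surface of one level (level-local coordinates).
# Points falling strictly inside another solid are rejected so the sample
# lies on the boundary of the union.
sample_level_surface <- function(g, n, seed) {
  with_seed(seed, {
    n_body <- round(n * 0.5)
    n_ped <- round(n * 0.08)
    n_block <- n - n_body - 2 * n_ped
    u <- matrix(stats::rnorm(3 * n_body), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    body <- sweep(sweep(u, 2, g$body_semi, "*"), 2, g$body_center, "+")
    ped <- do.call(rbind, lapply(c(-1, 1), function(side) {
      th <- stats::runif(n_ped, 0, 2 * pi)
      y <- stats::runif(n_ped, 0, g$ped_len)
      cbind(side * g$xp + g$r_out * cos(th), y, g$r_out * sin(th))
    }))
    block <- do.call(rbind, lapply(c(-1, 1), function(side) {
      m <- round(n_block / 2)
      face <- sample.int(5L, m, replace = TRUE,
                         prob = c(2, 1, 1, 1, 1))  # posterior face weighted up
      fx <- stats::runif(m, -g$block_half[1], g$block_half[1])
      fy <- stats::runif(m, -g$block_depth, 0)
      fz <- stats::runif(m, -g$block_half[2], g$block_half[2])
      x <- side * g$xp + ifelse(face == 2, -g$block_half[1],
                                ifelse(face == 3, g$block_half[1], fx))
      y <- ifelse(face == 1, -g$block_depth, fy)
      z <- ifelse(face == 4, -g$block_half[2],
                  ifelse(face == 5, g$block_half[2], fz))
      cbind(x, y, z)
    }))
    pts <- rbind(body, ped, block)
    comp <- c(rep("body", n_body),
              rep(c("pedicle_L", "pedicle_R"), each = n_ped),
              rep(c("block_L", "block_R"), each = round(n_block / 2)))
    eps <- 1e-6
    inside_other <- rep(FALSE, nrow(pts))
    solids <- list(
      body = function(p) inside_body(p, g, eps),
      pedicle_L = function(p) inside_pedicle(p, g, -1, eps),
      pedicle_R = function(p) inside_pedicle(p, g, +1, eps),
      block_L = function(p) inside_block(p, g, -1, eps),
      block_R = function(p) inside_block(p, g, +1, eps)
    )
    for (nm in names(solids)) {
      sel <- comp != nm
      inside_other[sel] <- inside_other[sel] | solids[[nm]](pts[sel, , drop = FALSE])
    }
    list(points = pts[!inside_other, , drop = FALSE], component = comp[!inside_other])
  })
}

#' Generate a multi-level spine phantom
#'
#' Deterministic for a fixed seed. Each level carries sampled surface points
#' (tagged by component), the body centre, the two pedicle axes, and the
#' analytic geometry used by the tissue-map and simulation routines.
#'
#' @param n_levels number of vertebral levels (>= 1), stacked caudally.
#' @param params named list overriding [phantom_defaults()] entries.
#' @param seed integer RNG seed.
#' @return An object of class `spine_phantom` with `levels` (list of
#'   `vertebra_model`), `world_frame`, `rng_seed` and the resolved `params`.
#' @export
#' @examples
#' ph <- make_spine_phantom(2, seed = 7)
#' ph$levels[[1]]$level_id
make_spine_phantom <- function(n_levels = 3, params = list(), seed = 1) {
  if (!is.numeric(n_levels) || n_levels < 1) {
    stop("n_levels must be a positive integer")
  }
  pars <- merge_params(phantom_defaults(), params, "phantom params")
  num <- unlist(pars[c("pedicle_width", "cortical_thickness", "pedicle_sep",
                       "pedicle_length", "body_semi", "block_half",
                       "block_depth", "level_pitch", "n_surface_points")])
  if (any(num <= 0)) stop("phantom dimensions must be positive")
  if (pars$cortical_thickness >= pars$pedicle_width / 2) {
    stop("cortical_thickness must be below half the pedicle width")
  }
  levels <- lapply(seq_len(n_levels), function(k) {
    g <- level_geometry(pars, k)
    surf <- sample_level_surface(g, pars$n_surface_points, derive_seed(seed, k))
    pts <- surf$points
    pts[, 3] <- pts[, 3] + g$z0
    structure(list(
      level_id = paste0("L", k + 2),
      surface_points = pts,
      component = surf$component,
      body_center = g$body_center + c(0, 0, g$z0),
      pedicle_axes = list(
        L = rbind(c(-g$xp, 0, g$z0), c(-g$xp, g$ped_len, g$z0)),
        R = rbind(c(g$xp, 0, g$z0), c(g$xp, g$ped_len, g$z0))
      ),
      pedicle_width = pars$pedicle_width,
      cortical_thickness = pars$cortical_thickness,
      geom = g
    ), class = "vertebra_model")
  })
  structure(list(levels = levels, world_frame = "phantom",
                 rng_seed = as.integer(seed), params = pars),
            class = "spine_phantom")
}

#' @export
print.spine_phantom <- function(x, ...) {
  cat("spine_phantom:", length(x$levels), "levels (",
      paste(vapply(x$levels, `[[`, "", "level_id"), collapse = ", "),
      "), seed", x$rng_seed, "\n")
  invisible(x)
}

# Look up a level by id, erroring helpfully.
phantom_level <- function(phantom, level_id) {
  ids <- vapply(phantom$levels, `[[`, "", "level_id")
  i <- match(level_id, ids)
  if (is.na(i)) stop(sprintf("unknown level '%s' (have: %s)", level_id,
                             paste(ids, collapse = ", ")))
  phantom$levels[[i]]
}

#' Surface point cloud of a phantom
#'
#' @param phantom a `spine_phantom`.
#' @param level_ids optional subset of level ids; defaults to all levels.
#' @return A [point_cloud()] with per-point level labels.
#' @export
phantom_cloud <- function(phantom, level_ids = NULL) {
  lvs <- phantom$levels
  if (!is.null(level_ids)) {
    lvs <- lapply(level_ids, function(id) phantom_level(phantom, id))
  }
  pts <- do.call(rbind, lapply(lvs, `[[`, "surface_points"))
  lab <- unlist(lapply(lvs, function(lv) rep(lv$level_id, nrow(lv$surface_points))))
  point_cloud(pts, lab)
}
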