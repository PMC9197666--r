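#' Synthetic ground-truth intensity fields
#'
#' Closed-form 3D intensity phantoms used to exercise the reconstruction
#' pipeline where no clinical data exists. Four kinds:
#'
#' * `affine`: `f(p) = a + b . p` — the field an order-1 local fit must
#'   reproduce exactly.
#' * `sphere`: `inside` value where `||p - center|| <= radius`
#'   (boundary-closed), `outside` elsewhere.
#' * `annulus_tube`: a ring-walled tube along the z axis — `wall` value
#'   where `r1 <= radius_xy(p - center) <= r2` (boundary-closed),
#'   `background` elsewhere; emulates the annular cross-section of the
#'   anal sphincter complex at the mm scale.
#' * `checker`: alternating `lo`/`hi` cubes of side `period` — a
#'   worst case for any smoothing estimator.
#'
#' @param kind one of `"affine"`, `"sphere"`, `"annulus_tube"`,
#'   `"checker"`.
#' @param a,b affine intercept and length-3 gradient (intensity, /mm).
#' @param center sphere center (length 3, mm) or tube axis point
#'   (length 2, in-plane mm).
#' @param radius sphere radius (mm).
#' @param inside,outside sphere intensities.
#' @param r1,r2 tube inner/outer wall radii (mm), `r1 < r2`.
#' @param wall,background tube intensities.
#' @param period checker cube side (mm).
#' @param lo,hi checker intensities.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("affine", "sphere", "annulus_tube",
                                  "checker"),
                         a = 0, b = c(0, 0, 0),
                         center = NULL, radius = 10,
                         inside = 100, outside = 0,
                         r1 = 5, r2 = 8, wall = 100, background = 0,
                         period = 4, lo = 0, hi = 100) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    affine = {
      b <- as.numeric(b)
      stopifnot(is.finite(a), length(b) == 3L, all(is.finite(b)))
      list(a = a, b = b)
    },
    sphere = {
      if (is.null(center)) center <- c(0, 0, 0)
      center <- as.numeric(center)
      stopifnot(length(center) == 3L, radius > 0,
                is.finite(inside), is.finite(outside))
      list(center = center, radius = radius,
           inside = inside, outside = outside)
    },
    annulus_tube = {
      if (is.null(center)) center <- c(0, 0)
      center <- as.numeric(center)
      stopifnot(length(center) == 2L, is.finite(wall),
                is.finite(background))
      if (!(r1 > 0 && r1 < r2)) stop("annulus_tube requires 0 < r1 < r2")
      list(center = center, r1 = r1, r2 = r2, wall = wall,
           background = background)
    },
    checker = {
      stopifnot(period > 0, is.finite(lo), is.finite(hi))
      list(period = period, lo = lo, hi = hi)
    })
  structure(c(list(kind = kind), spec), class = "phantom_spec")
}

is_phantom_spec <- function(x) inherits(x, "phantom_spec")

#' Evaluate a phantom field
#'
#' Deterministic, exact closed-form evaluation of the ground-truth
#' intensity at arbitrary world positions.
#'
#' @param spec a [phantom_spec()].
#' @param positions length-3 vector or Nx3 matrix of positions (mm).
#' @return Intensity value(s).
#' @examples
#' evaluate_phantom(phantom_spec("affine", a = 2, b = c(0.5, 0, 0)),
#'                  c(4, 9, 9))  # 4
#' @export
evaluate_phantom <- function(spec, positions) {
  stopifnot(is_phantom_spec(spec))
  p <- if (is.null(dim(positions))) matrix(as.numeric(positions), ncol = 3L)
       else positions
  switch(spec$kind,
    affine = spec$a + drop(p %*% spec$b),
    sphere = {
      d2 <- rowSums(sweep(p, 2L, spec$center, "-")^2)
      ifelse(d2 <= spec$radius^2, spec$inside, spec$outside)
    },
    annulus_tube = {
      r <- sqrt((p[, 1] - spec$center[1])^2 + (p[, 2] - spec$center[2])^2)
      ifelse(r >= spec$r1 & r <= spec$r2, spec$wall, spec$background)
    },
    checker = {
      s <- (floor(p[, 1] / spec$period) + floor(p[, 2] / spec$period) +
            floor(p[, 3] / spec$period)) %% 2
      ifelse(s == 0, spec$lo, spec$hi)
    })
}

#' Simulated sweep configuration
#'
#' Describes a tracked-probe sweep: how many frames, their size and
#' pixel spacing, the trajectory, and the additive noise on observed
#' pixel values. Observed intensity = true field at the pixel's world
#' position + i.i.d. Gaussian noise of standard deviation `noise_sigma`.
#'
#' @param n_frames number of frames (>= 1).
#' @param trajectory `"linear_z"` (parallel x-y planes advanced along z
#'   by `step` mm) or `"fan"` (planes rotated about the world x axis
#'   through the frame origin by `angle_step` degrees per frame,
#'   centred on the sweep midpoint).
#' @param frame_dims length-2 pixel counts (rows, cols).
#' @param frame_spacing length-2 pixel spacing (mm/pixel).
#' @param step frame advance along z (mm/frame), `linear_z` only; must
#'   be non-zero.
#' @param angle_step angular advance (degrees/frame), `fan` only; must
#'   be non-zero.
#' @param frame_origin world position of pixel (0, 0) of the first frame
#'   (and pivot of a fan sweep).
#' @param noise_sigma standard deviation of the i.i.d. Gaussian pixel
#'   noise (intensity units, >= 0).
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   sweeps.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(n_frames = 32L,
                         trajectory = c("linear_z", "fan"),
                         frame_dims = c(32L, 32L),
                         frame_spacing = c(1, 1),
                         step = 1, angle_step = 2,
                         frame_origin = c(0, 0, 0),
                         noise_sigma = 0, seed = 1L) {
  trajectory <- match.arg(trajectory)
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L, length(frame_dims) == 2L,
            all(frame_dims >= 1L),
            length(frame_spacing) == 2L, all(frame_spacing > 0),
            length(frame_origin) == 3L, noise_sigma >= 0)
  if (trajectory == "linear_z" && step == 0)
    stop("degenerate trajectory: step must be non-zero")
  if (trajectory == "fan" && angle_step == 0)
    stop("degenerate trajectory: angle_step must be non-zero")
  structure(list(n_frames = n_frames, trajectory = trajectory,
                 frame_dims = as.integer(frame_dims),
                 frame_spacing = as.numeric(frame_spacing),
                 step = step, angle_step = angle_step,
                 frame_origin = as.numeric(frame_origin),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "sweep_config")
}

# pose of frame f (1-based) under a sweep configuration
sweep_pose <- function(config, f) {
  if (config$trajectory == "linear_z") {
    rigid_pose(diag(3),
               config$frame_origin + c(0, 0, (f - 1) * config$step))
  } else {
    theta <- ((f - 1) - (config$n_frames - 1) / 2) *
      config$angle_step * pi / 180
    pose_compose(rigid_pose(diag(3), config$frame_origin),
                 pose_axis_rotation("x", theta))
  }
}

#' Simulate a tracked freehand sweep over a phantom
#'
#' Generates one [slice_frame()] per trajectory position. Each pixel's
#' observed value is the phantom field at the pixel's world position
#' plus i.i.d. Gaussian noise; poses are exact. Also samples the
#' ground-truth field, noise-free, at the voxel centers of a stated
#' reconstruction grid.
#'
#' @param spec a [phantom_spec()].
#' @param config a [sweep_config()].
#' @param grid a [recon_grid()] for the ground-truth volume, or `NULL`
#'   to fit one around the sweep at `truth_spacing`.
#' @param truth_spacing voxel spacing of the auto-fitted grid (mm).
#' @return List with `frames` (list of `slice_frame`), `truth` (a fully
#'   filled [recon_volume()] of the noise-free field), `grid`, and
#'   `config`.
#' @export
simulate_sweep <- function(spec, config, grid = NULL, truth_spacing = 1) {
  stopifnot(is_phantom_spec(spec), inherits(config, "sweep_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  frames <- vector("list", config$n_frames)
  nr <- config$frame_dims[1]; nc <- config$frame_dims[2]
  for (f in seq_len(config$n_frames)) {
    pose <- sweep_pose(config, f)
    i <- rep(seq_len(nr) - 1L, times = nc)
    j <- rep(seq_len(nc) - 1L, each = nr)
    local <- cbind(i * config$frame_spacing[1],
                   j * config$frame_spacing[2], 0)
    world <- pose_apply(pose, local)
    vals <- evaluate_phantom(spec, world)
    if (config$noise_sigma > 0)
      vals <- vals + rnorm(length(vals), 0, config$noise_sigma)
    frames[[f]] <- slice_frame(matrix(vals, nr, nc), config$frame_spacing,
                               pose)
  }
  if (is.null(grid)) {
    corners <- bind_clouds(lapply(frames, function(fr) {
      crn <- rbind(c(0, 0, 0),
                   c((nr - 1) * config$frame_spacing[1], 0, 0),
                   c(0, (nc - 1) * config$frame_spacing[2], 0),
                   c((nr - 1) * config$frame_spacing[1],
                     (nc - 1) * config$frame_spacing[2], 0))
      sample_cloud(pose_apply(fr$pose, crn), rep(0, 4))
    }))
    grid <- fit_grid(corners, truth_spacing)
  }
  centers <- voxel_to_world(as.matrix(expand.grid(
    seq_len(grid$dims[1]) - 1L, seq_len(grid$dims[2]) - 1L,
    seq_len(grid$dims[3]) - 1L)), grid)
  tv <- array(evaluate_phantom(spec, centers), grid$dims)
  truth <- recon_volume(grid, tv, array(TRUE, grid$dims),
                        array(1L, grid$dims))
  list(frames = frames, truth = truth, grid = grid, config = config)
}

#' Drop a fraction of frames from a sweep
#'
#' Deterministically (given `seed`) retains `ceiling(n * (1 - fraction))`
#' frames, preserving acquisition order, to create empty voxels for the
#' hole-filling stage.
#'
#' @param frames list of [slice_frame()] objects.
#' @param fraction fraction to drop, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return The retained sub-list of frames.
#' @export
drop_frames <- function(frames, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(frames)
  n_keep <- as.integer(ceiling(n * (1 - fraction)))
  if (n_keep == n) return(frames)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  keep <- sort(sample.int(n, n_keep))
  frames[keep]
}

#' Map every frame of a sweep into one sample cloud
#'
#' @param frames list of [slice_frame()] objects.
#' @return A single [sample_cloud()] with all frames' pixels.
#' @export
frames_to_cloud <- function(frames) {
  bind_clouds(lapply(frames, map_slice_to_world))
}
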