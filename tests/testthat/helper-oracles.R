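# Independent oracles and fixture builders, written before (and kept
# independent of) the implementation paths they check.

# Brute-force weighted least squares: explicitly form E'WE and E'WZ with
# a dense diagonal weight matrix and solve with the generic QR solver.
# Returns the full coefficient vector; the intercept is the estimate.
oracle_wls <- function(design, weights, values, ridge = 0) {
  W <- diag(weights, nrow = length(weights))
  A <- t(design) %*% W %*% design
  if (ridge > 0) {
    pen <- diag(c(0, rep(1, ncol(design) - 1L)))
    A <- A + ridge * pen
  }
  b <- t(design) %*% W %*% values
  drop(qr.solve(A, b))
}

# direct (unpooled) RMSE/MAE recomputation
oracle_rmse <- function(a, b) sqrt(mean((a - b)^2))
oracle_mae <- function(a, b) mean(abs(a - b))

# a random well-conditioned local system with n neighbours
random_local_system <- function(n, seed) {
  set.seed(seed)
  offsets <- matrix(runif(3 * n, -2, 2), ncol = 3)
  structure(list(design = cbind(rep(1, n), offsets),
                 weights = runif(n, 0.05, 1),
                 values = runif(n, 0, 100),
                 center = c(0, 0, 0),
                 n = n),
            class = "local_system")
}

# uniformly random proper rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# annulus-tube sweep reconstruction used by several tests: returns the
# simulation, the bin-filled volume and the reconstruction
annulus_pipeline <- function(sigma = 0, seed = 1, drop = 0.3,
                             ksize = 3, order = 1) {
  spec <- phantom_spec("annulus_tube", center = c(15.5, 15.5),
                       r1 = 5, r2 = 8, wall = 100, background = 0)
  cfg <- sweep_config(n_frames = 64, frame_dims = c(32L, 32L),
                      frame_spacing = c(1, 1), step = 0.5,
                      noise_sigma = sigma, seed = seed)
  sw <- simulate_sweep(spec, cfg)
  frames <- if (drop > 0) drop_frames(sw$frames, drop, seed) else sw$frames
  vol <- bin_fill(frames_to_cloud(frames), sw$grid)
  rec <- reconstruct_volume(vol, kernel_params(ksize = ksize,
                                               order = order))
  list(sweep = sw, binned = vol, recon = rec)
}
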