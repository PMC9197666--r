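#' Kernel-regression parameters
#'
#' Configuration of the hole-filling estimator: bandwidth of the Gaussian
#' weight, side of the cubic search neighbourhood, polynomial order of
#' the local fit, and the rules applied when a voxel lacks support.
#'
#' The cubic neighbourhood of side `ksize` spans, per axis, offsets
#' `-(ksize-1)/2 .. (ksize-1)/2` for odd `ksize` and
#' `-ksize/2 .. ksize/2 - 1` for even `ksize` (floor-centred), so even
#' sides such as 6, 8 or 10 are well defined.
#'
#' @param bandwidth Gaussian bandwidth M in mm: positive scalar, or a
#'   positive length-3 vector for per-axis anisotropy. `NULL` (default)
#'   resolves at reconstruction time to `ksize * spacing / 4`, placing
#'   roughly two standard deviations at the cube edge.
#' @param ksize integer >= 2, side of the cubic neighbourhood in voxels.
#' @param order polynomial order of the local fit: 1 (local-linear,
#'   default — intercept plus three slopes) or 0 (Gaussian-weighted mean).
#' @param min_neighbors minimum filled neighbours required before a fit
#'   is attempted; defaults to 8 for order 1 and 1 for order 0.
#' @param ridge small non-negative regulariser added to the slope block
#'   of the normal-matrix diagonal (never the intercept); guards against
#'   coplanar neighbour geometries near volume faces.
#' @param fallback what to do for voxels with insufficient support or a
#'   degenerate system: `"order0"` (weighted-mean estimate, default),
#'   `"expand_once"` (retry once with the cube grown by one voxel per
#'   side, then weighted mean), or `"leave_empty"`.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(bandwidth = NULL, ksize = 3L, order = 1L,
                          min_neighbors = NULL, ridge = 1e-10,
                          fallback = c("order0", "expand_once",
                                       "leave_empty")) {
  fallback <- match.arg(fallback)
  ksize <- as.integer(ksize)
  order <- as.integer(order)
  if (is.na(ksize) || ksize < 2L) stop("ksize must be an integer >= 2")
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  if (!is.null(bandwidth)) {
    bandwidth <- as.numeric(bandwidth)
    if (!length(bandwidth) %in% c(1L, 3L) || any(!is.finite(bandwidth)) ||
        any(bandwidth <= 0))
      stop("bandwidth must be a positive scalar or length-3 vector (mm)")
  }
  if (is.null(min_neighbors)) min_neighbors <- if (order == 1L) 8L else 1L
  min_neighbors <- as.integer(min_neighbors)
  if (is.na(min_neighbors) || min_neighbors < 1L)
    stop("min_neighbors must be an integer >= 1")
  if (order == 1L && min_neighbors < 4L)
    stop("order 1 requires min_neighbors >= 4 (intercept + 3 slopes)")
  if (!is.finite(ridge) || ridge < 0) stop("ridge must be >= 0")
  structure(list(bandwidth = bandwidth, ksize = ksize, order = order,
                 min_neighbors = min_neighbors, ridge = ridge,
                 fallback = fallback),
            class = "kernel_params")
}

is_kernel_params <- function(x) inherits(x, "kernel_params")

# bandwidth as a length-3 vector, applying the default rule if unset
resolve_bandwidth <- function(params, spacing) {
  if (is.null(params$bandwidth)) params$ksize * spacing / 4
  else rep_len(params$bandwidth, 3L)
}

# per-axis cube offsets for side k (floor-centred for even k)
cube_offsets <- function(ksize) {
  if (ksize %% 2L == 1L) seq.int(-(ksize - 1L) %/% 2L, (ksize - 1L) %/% 2L)
  else seq.int(-ksize %/% 2L, ksize %/% 2L - 1L)
}

#' Gaussian kernel weight
#'
#' Unnormalised Gaussian of the bandwidth-scaled distance:
#' `exp(-||delta / M||^2 / 2)` with per-axis division when `bandwidth`
#' is a length-3 vector. Strictly positive, maximal (1) at zero offset,
#' and symmetric in `delta`. The kernel's normalising prefactor is
#' omitted: it cancels between the two sides of the weighted
#' least-squares normal equations.
#'
#' @param delta length-3 offset (mm) or Nx3 matrix of offsets.
#' @param bandwidth positive scalar or length-3 bandwidth M (mm).
#' @return Weight(s) in (0, 1].
#' @examples
#' gaussian_weight(c(0, 0, 0), 2)          # 1
#' gaussian_weight(c(2, 0, 0), 2)          # exp(-1/2)
#' @export
gaussian_weight <- function(delta, bandwidth) {
  bandwidth <- as.numeric(bandwidth)
  if (!length(bandwidth) %in% c(1L, 3L) || any(!is.finite(bandwidth)) ||
      any(bandwidth <= 0))
    stop("bandwidth must be a positive scalar or length-3 vector")
  if (is.null(dim(delta))) {
    if (!all(is.finite(delta))) stop("delta must be finite")
    exp(-sum((as.numeric(delta) / rep_len(bandwidth, 3L))^2) / 2)
  } else {
    if (!all(is.finite(delta))) stop("delta must be finite")
    u <- sweep(delta, 2L, rep_len(bandwidth, 3L), "/")
    exp(-rowSums(u^2) / 2)
  }
}

#' Gather the local weighted system around an empty voxel
#'
#' Collects every *filled* voxel within the `ksize`^3 cube centred on
#' `center_voxel` (excluding the center itself), in deterministic
#' lexicographic offset order, and returns the local-linear design: rows
#' `(1, d1, d2, d3)` with `d = (neighbour - center)` voxel-center offsets
#' in world mm, Gaussian weights of those offsets, and the neighbour
#' intensities.
#'
#' @param volume a [recon_volume()].
#' @param center_voxel length-3 0-based voxel index inside the grid.
#' @param params a [kernel_params()].
#' @return An object of class `local_system`: list with `design` (n x 4),
#'   `weights` (n), `values` (n), `center` (world mm) and `n`. `n = 0`
#'   when no filled voxel lies in the cube.
#' @export
build_local_system <- function(volume, center_voxel, params) {
  stopifnot(is_recon_volume(volume), is_kernel_params(params))
  d <- volume$grid$dims
  cv <- as.integer(center_voxel)
  if (length(cv) != 3L || any(cv < 0L) || any(cv >= d))
    stop("center voxel outside grid")
  off <- cube_offsets(params$ksize)
  # lexicographic in (d1, d2, d3): first axis slowest
  g <- expand.grid(d3 = off, d2 = off, d1 = off,
                   KEEP.OUT.ATTRS = FALSE)[, 3:1]
  g <- as.matrix(g[!(g[, 1] == 0L & g[, 2] == 0L & g[, 3] == 0L), ,
                   drop = FALSE])
  nb <- sweep(g, 2L, cv, "+")
  ok <- nb[, 1] >= 0L & nb[, 1] < d[1] &
        nb[, 2] >= 0L & nb[, 2] < d[2] &
        nb[, 3] >= 0L & nb[, 3] < d[3]
  nb <- nb[ok, , drop = FALSE]
  g <- g[ok, , drop = FALSE]
  lin <- 1L + nb[, 1] + d[1] * (nb[, 2] + d[2] * nb[, 3])
  keep <- volume$filled[lin]
  nb <- nb[keep, , drop = FALSE]
  g <- g[keep, , drop = FALSE]
  lin <- lin[keep]
  delta <- sweep(g, 2L, volume$grid$spacing, "*")
  bw <- resolve_bandwidth(params, volume$grid$spacing)
  w <- gaussian_weight(delta, bw)
  structure(list(design = cbind(rep(1, nrow(delta)), delta),
                 weights = w,
                 values = volume$intensity[lin],
                 center = voxel_to_world(cv, volume$grid),
                 n = nrow(delta)),
            class = "local_system")
}

#' Solve the local weighted least-squares fit
#'
#' Minimises the Gaussian-weighted residual sum of squares
#' `sum_l w_l (z_l - g0 - sum_t g_t d_lt)^2` (order 1) or
#' `sum_l w_l (z_l - g0)^2` (order 0) and returns the fitted intercept —
#' the kernel-regression estimate of the center voxel's intensity — plus
#' diagnostics. Order 0 reduces to the weighted mean of the neighbour
#' values, a convex combination bounded by their range.
#'
#' @param system a `local_system` from [build_local_system()].
#' @param params a [kernel_params()].
#' @return List with `estimate` (the intercept; `NA` unless
#'   `status == "ok"`), `coefficients` (length 1 or 4), `n`, `status`
#'   (`"ok"`, `"insufficient_support"` or `"degenerate"`), and `rcond`
#'   (reciprocal condition estimate of the normal matrix; order 1 only).
#' @export
solve_local_regression <- function(system, params) {
  stopifnot(inherits(system, "local_system"), is_kernel_params(params))
  n <- system$n
  out <- list(estimate = NA_real_, coefficients = NULL, n = n,
              status = "ok", rcond = NA_real_)
  if (n < params$min_neighbors ||
      (params$order == 1L && n < 4L)) {
    out$status <- "insufficient_support"
    return(out)
  }
  w <- system$weights
  z <- system$values
  if (params$order == 0L) {
    # a convex combination; clamp to the neighbour range so floating-
    # point roundoff can never push it outside [min(z), max(z)]
    out$estimate <- min(max(sum(w * z) / sum(w), min(z)), max(z))
    out$coefficients <- out$estimate
    return(out)
  }
  x <- system$design
  a <- crossprod(x, w * x)
  b <- crossprod(x, w * z)
  diag(a)[2:4] <- diag(a)[2:4] + params$ridge
  # sqrt(eps) cut: below it the slopes are not reliably identifiable
  # (e.g. coplanar neighbours), and an unidentifiable slope biases the
  # intercept, so such voxels go to the fallback instead
  out$rcond <- rcond(a)
  if (!is.finite(out$rcond) ||
      out$rcond < sqrt(.Machine$double.eps)) {
    out$status <- "degenerate"
    return(out)
  }
  coef <- tryCatch(drop(solve(a, b)), error = function(e) NULL)
  if (is.null(coef) || !all(is.finite(coef))) {
    out$status <- "degenerate"
    return(out)
  }
  out$coefficients <- coef
  out$estimate <- coef[[1L]]
  out
}

# order-0 weighted-mean estimate over whatever neighbours exist (n >= 1),
# clamped to the neighbour range (convex combination)
.weighted_mean_estimate <- function(system) {
  if (system$n < 1L) return(NA_real_)
  z <- system$values
  min(max(sum(system$weights * z) / sum(system$weights), min(z)), max(z))
}

#' Fill empty voxels by local kernel regression
#'
#' Visits every empty voxel once, in a single pass that reads only the
#' pre-pass filled mask (no progressive filling, so estimates are
#' independent of visit order and of any parallel partition). Each empty
#' voxel with enough filled neighbours in its `ksize`^3 cube receives the
#' fitted intercept of the local Gaussian-weighted polynomial fit;
#' voxels without support follow `params$fallback`. Originally filled
#' voxels are never modified.
#'
#' @param volume a [recon_volume()], typically from [bin_fill()].
#' @param params a [kernel_params()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference R
#'   implementation); both produce the same estimates.
#' @return The reconstructed [recon_volume()]; provenance codes mark how
#'   each voxel was filled, and `fill_report()` on the result returns the
#'   counts `filled_by_kr`, `fallback_filled` and `left_empty` with a
#'   parameter echo.
#' @examples
#' cl <- sample_cloud(matrix(runif(300, 0, 7), ncol = 3),
#'                    rep(5, 100))
#' v <- bin_fill(cl, recon_grid(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8)))
#' r <- reconstruct_volume(v, kernel_params(ksize = 3, order = 0))
#' fill_report(r)$filled_by_kr
#' @export
reconstruct_volume <- function(volume, params = kernel_params(),
                               engine = c("cpp", "r")) {
  stopifnot(is_recon_volume(volume), is_kernel_params(params))
  engine <- match.arg(engine)
  bw <- resolve_bandwidth(params, volume$grid$spacing)
  fb <- match(params$fallback, c("leave_empty", "order0", "expand_once")) - 1L
  if (engine == "cpp") {
    res <- krr_fill_cpp(volume$intensity, volume$filled,
                        volume$grid$dims, volume$grid$spacing,
                        params$ksize, bw, params$order,
                        params$min_neighbors, params$ridge, fb)
    intensity <- array(res$intensity, volume$grid$dims)
    prov <- array(res$provenance, volume$grid$dims)
  } else {
    intensity <- volume$intensity
    prov <- volume$provenance
    empties <- which(!volume$filled, arr.ind = TRUE) - 1L
    # freeze the resolved bandwidth so an expand_once retry keeps it
    paramsR <- params
    paramsR$bandwidth <- bw
    est <- .estimate_empty_voxels(volume, empties, paramsR)
    lin <- which(!volume$filled)
    intensity[lin] <- est$value
    prov[lin] <- est$code
  }
  filled <- prov > 0L
  out <- recon_volume(volume$grid, intensity, filled, volume$count, prov)
  report <- list(filled_by_kr = sum(prov == 2L),
                 fallback_filled = sum(prov == 3L),
                 left_empty = sum(prov == 0L),
                 params = list(bandwidth = bw, ksize = params$ksize,
                               order = params$order,
                               min_neighbors = params$min_neighbors,
                               ridge = params$ridge,
                               fallback = params$fallback,
                               engine = engine))
  attr(out, "fill_report") <- report
  attr(out, "deposit_summary") <- attr(volume, "deposit_summary")
  out
}

# reference R path: estimate a set of empty voxels from the pre-pass state
.estimate_empty_voxels <- function(volume, empties, params) {
  n <- nrow(empties)
  value <- rep(NA_real_, n)
  code <- integer(n)
  if (n == 0L) return(list(value = value, code = code))
  p0 <- params
  for (i in seq_len(n)) {
    sys <- build_local_system(volume, empties[i, ], p0)
    fit <- solve_local_regression(sys, p0)
    if (fit$status == "ok") {
      value[i] <- fit$estimate
      code[i] <- 2L
      next
    }
    if (p0$fallback == "leave_empty") next
    if (p0$fallback == "expand_once") {
      pw <- p0; pw$ksize <- p0$ksize + 2L
      sysw <- build_local_system(volume, empties[i, ], pw)
      fitw <- solve_local_regression(sysw, pw)
      if (fitw$status == "ok") {
        value[i] <- fitw$estimate
        code[i] <- 3L
        next
      }
      sys <- sysw  # weighted-mean fallback over the expanded cube
    }
    est <- .weighted_mean_estimate(sys)
    if (!is.na(est)) {
      value[i] <- est
      code[i] <- 3L
    }
  }
  list(value = value, code = code)
}

#' Fill report of a reconstructed volume
#'
#' @param volume a [recon_volume()] produced by [reconstruct_volume()].
#' @return List with counts `filled_by_kr`, `fallback_filled`,
#'   `left_empty` and the parameter echo under `params`.
#' @export
fill_report <- function(volume) {
  r <- attr(volume, "fill_report")
  if (is.null(r)) stop("volume carries no fill report")
  r
}
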