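#' Reconstruction voxel grid
#'
#' Defines an axis-aligned voxel lattice in world coordinates. Voxel
#' indices are 0-based throughout the package: voxel `v = (v1, v2, v3)`
#' has its center at `origin + v * spacing` (mm).
#'
#' @param origin length-3 world position of the center of voxel
#'   (0, 0, 0), in mm.
#' @param spacing length-3 strictly positive voxel spacing (mm/voxel).
#' @param dims length-3 positive integer voxel counts per axis.
#' @return An object of class `recon_grid`.
#' @export
recon_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be a finite length-3 vector (mm)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm/voxel)")
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be three positive integers")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "recon_grid")
}

is_recon_grid <- function(x) inherits(x, "recon_grid")

#' @export
print.recon_grid <- function(x, ...) {
  cat(sprintf("recon_grid: %d x %d x %d voxels, spacing (%s) mm, origin (%s) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-12) {
  all(a$dims == b$dims) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol
}

#' Fit a grid around a sample cloud
#'
#' Axis-aligned bounding box of the cloud, padded by one voxel on every
#' side, at the requested spacing.
#'
#' @param cloud a [sample_cloud()].
#' @param spacing scalar or length-3 voxel spacing (mm).
#' @return A [recon_grid()] containing every sample strictly in-bounds.
#' @export
fit_grid <- function(cloud, spacing = 1) {
  stopifnot(inherits(cloud, "sample_cloud"), nrow(cloud$positions) > 0L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  lo <- apply(cloud$positions, 2L, min)
  hi <- apply(cloud$positions, 2L, max)
  origin <- lo - spacing
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / spacing)) + 2L)
  recon_grid(origin, spacing, dims)
}

#' Map world positions to voxel indices
#'
#' Nearest-voxel-center assignment: per axis,
#' `index = floor((p - origin) / spacing + 0.5)` (round half up). Indices
#' are 0-based; positions whose index falls outside `[0, dims)` on any
#' axis are flagged out-of-bounds rather than raising an error.
#'
#' @param positions length-3 vector or Nx3 matrix of world positions (mm).
#' @param grid a [recon_grid()].
#' @return A list with `index` (Nx3 integer matrix, 0-based; rows of
#'   out-of-bounds positions are NA) and `in_bounds` (logical N-vector).
#' @examples
#' g <- recon_grid(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8))
#' world_to_voxel(c(2.4, 0, 5.6), g)$index
#' @export
world_to_voxel <- function(positions, grid) {
  stopifnot(is_recon_grid(grid))
  p <- if (is.null(dim(positions))) matrix(as.numeric(positions), ncol = 3L)
       else positions
  idx <- floor(sweep(sweep(p, 2L, grid$origin, "-"), 2L, grid$spacing, "/")
               + 0.5)
  ok <- idx[, 1] >= 0 & idx[, 1] < grid$dims[1] &
        idx[, 2] >= 0 & idx[, 2] < grid$dims[2] &
        idx[, 3] >= 0 & idx[, 3] < grid$dims[3]
  idx[!ok, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  list(index = idx, in_bounds = ok)
}

#' Voxel centers in world coordinates
#'
#' @param index length-3 vector or Nx3 matrix of 0-based voxel indices.
#' @param grid a [recon_grid()].
#' @return World positions (mm) of the voxel centers, Nx3 or length-3.
#' @export
voxel_to_world <- function(index, grid) {
  stopifnot(is_recon_grid(grid))
  if (is.null(dim(index)))
    grid$origin + as.numeric(index) * grid$spacing
  else
    sweep(sweep(index, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Reconstruction volume
#'
#' Voxel grid plus intensities, a filled mask, a per-voxel contributing
#' sample count and a provenance code (0 empty, 1 bin-filled, 2 filled by
#' kernel regression, 3 filled by the fallback rule). Empty voxels carry
#' `NA` intensity; the mask, not a sentinel intensity, is authoritative.
#'
#' @param grid a [recon_grid()].
#' @param intensity dims-shaped numeric array, `NA` where empty.
#' @param filled dims-shaped logical array.
#' @param count dims-shaped non-negative integer array.
#' @param provenance optional dims-shaped integer array (defaults to the
#'   mask: 1 where filled, 0 elsewhere).
#' @return An object of class `recon_volume`.
#' @export
recon_volume <- function(grid, intensity, filled, count, provenance = NULL) {
  stopifnot(is_recon_grid(grid))
  d <- grid$dims
  stopifnot(all(dim(intensity) == d), all(dim(filled) == d),
            all(dim(count) == d))
  if (any(filled & !is.finite(intensity)))
    stop("intensity must be finite wherever filled")
  if (is.null(provenance)) {
    # before hole-filling a voxel is filled iff it received samples
    if (any(filled != (count >= 1L)))
      stop("filled mask must match count >= 1")
    provenance <- array(0L, d)
    provenance[filled] <- 1L
  }
  structure(list(grid = grid, intensity = intensity,
                 filled = filled, count = count, provenance = provenance),
            class = "recon_volume")
}

is_recon_volume <- function(x) inherits(x, "recon_volume")

#' @export
print.recon_volume <- function(x, ...) {
  nf <- sum(x$filled)
  cat(sprintf("recon_volume: %d x %d x %d voxels, %d filled (%.1f%%)\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              nf, 100 * nf / prod(x$grid$dims)))
  invisible(x)
}

#' Deposit scattered samples into a voxel grid (initial filling stage)
#'
#' Each sample is assigned to the voxel whose center is nearest (round
#' half up per axis); a voxel receiving several samples stores their
#' arithmetic mean. Out-of-bounds samples are dropped and counted. An
#' empty cloud yields a valid all-empty volume.
#'
#' @param cloud a [sample_cloud()].
#' @param grid a [recon_grid()], or `NULL` to auto-fit one around the
#'   cloud (bounding box padded by one voxel) at `spacing`.
#' @param spacing voxel spacing used only when `grid` is `NULL`.
#' @return A [recon_volume()]; `deposit_summary()` on the result gives
#'   the deposited/dropped counts.
#' @examples
#' cl <- sample_cloud(rbind(c(1, 1, 1), c(1, 1, 1.2)), c(10, 20))
#' v <- bin_fill(cl, recon_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4)))
#' v$intensity[2, 2, 2]  # mean of the two colliding samples
#' @export
bin_fill <- function(cloud, grid = NULL, spacing = 1) {
  stopifnot(inherits(cloud, "sample_cloud"))
  if (is.null(grid)) grid <- fit_grid(cloud, spacing)
  d <- grid$dims
  n <- length(cloud$intensities)
  intensity <- array(NA_real_, d)
  count <- array(0L, d)
  dropped <- 0L
  if (n > 0L) {
    vx <- world_to_voxel(cloud$positions, grid)
    keep <- vx$in_bounds
    dropped <- sum(!keep)
    if (any(keep)) {
      lin <- 1L + vx$index[keep, 1L] +
        d[1L] * (vx$index[keep, 2L] + d[2L] * vx$index[keep, 3L])
      # average in sorted linear-index order so the per-voxel mean is
      # independent of sample order to the last bit, summing residuals
      # about a per-bin reference so constant-valued bins average exactly
      z <- cloud$intensities[keep]
      o <- order(lin, z)
      lin_s <- lin[o]; z_s <- z[o]
      grp <- c(TRUE, lin_s[-1] != lin_s[-length(lin_s)])
      ref <- z_s[grp][cumsum(grp)]
      s <- rowsum(z_s - ref, lin_s, reorder = TRUE)
      cnt <- drop(rowsum(rep(1L, length(lin_s)), lin_s, reorder = TRUE))
      at <- as.integer(rownames(s))
      intensity[at] <- z_s[grp] + drop(s) / cnt
      count[at] <- cnt
    }
  }
  filled <- count >= 1L
  vol <- recon_volume(grid, intensity, filled, count)
  attr(vol, "deposit_summary") <- list(n = n, deposited = n - dropped,
                                       dropped = dropped)
  vol
}

#' Deposit summary of a bin-filled volume
#'
#' @param volume a [recon_volume()] produced by [bin_fill()].
#' @return List with `n`, `deposited` and `dropped` sample counts.
#' @export
deposit_summary <- function(volume) {
  s <- attr(volume, "deposit_summary")
  if (is.null(s)) stop("volume carries no deposit summary")
  s
}
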