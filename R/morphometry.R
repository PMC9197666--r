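#' Clock-position wall thickness on an axial plane
#'
#' Mirrors the clinical protocol of measuring sphincter-ring wall
#' thickness at the 12, 3, 6 and 9 o'clock directions on an axial
#' ultrasound plane. From `center` a ray is cast outward along each
#' clock direction (12 = +y, 3 = +x, 6 = -y, 9 = -x, in-plane world
#' axes), the intensity is sampled by bilinear interpolation every
#' `step` mm, and the thickness is the length of the first
#' above-threshold run: the distance from the first sample `>=
#' threshold` to the subsequent first sample `< threshold`. A direction
#' with no above-threshold sample before the volume boundary is
#' reported not-found; a run still above threshold at the boundary is
#' measured to the last in-bounds sample.
#'
#' Empty (unfilled) voxels are treated as background (below any finite
#' threshold) so holes never read as wall.
#'
#' @param volume a [recon_volume()].
#' @param plane 0-based z index of the axial plane.
#' @param center length-2 in-plane world coordinates (mm) of the ray
#'   origin; must lie inside the plane.
#' @param threshold intensity separating wall from background; default
#'   is the midpoint of the plane's filled-intensity range.
#' @param step ray sampling interval (mm); must be positive and no
#'   larger than the smaller in-plane voxel spacing.
#' @return A `thickness_report`: data frame with columns `direction`
#'   (`"12"`, `"3"`, `"6"`, `"9"`), `thickness_mm` and `found`, with the
#'   plane, center, threshold and step recorded as attributes.
#' @examples
#' sw <- simulate_sweep(phantom_spec("annulus_tube", center = c(12, 12)),
#'                      sweep_config(n_frames = 8, frame_dims = c(25, 25)))
#' clock_thickness(sw$truth, plane = 4, center = c(12, 12),
#'                 threshold = 50, step = 0.25)
#' @export
clock_thickness <- function(volume, plane, center, threshold = NULL,
                            step = 0.25) {
  stopifnot(is_recon_volume(volume))
  g <- volume$grid
  plane <- as.integer(plane)
  if (plane < 0L || plane >= g$dims[3]) stop("plane outside volume")
  center <- as.numeric(center)
  if (length(center) != 2L) stop("center must be a length-2 in-plane point")
  lo <- g$origin[1:2]
  hi <- g$origin[1:2] + (g$dims[1:2] - 1L) * g$spacing[1:2]
  if (any(center < lo) || any(center > hi))
    stop("center outside plane extent")
  if (step <= 0 || step > min(g$spacing[1:2]))
    stop("step must be positive and <= the in-plane voxel spacing")

  img <- volume$intensity[, , plane + 1L]
  img[!volume$filled[, , plane + 1L]] <- -Inf
  if (is.null(threshold)) {
    v <- img[is.finite(img)]
    if (length(v) == 0L) stop("plane has no filled voxels")
    threshold <- (min(v) + max(v)) / 2
  }

  dirs <- list(`12` = c(0, 1), `3` = c(1, 0), `6` = c(0, -1),
               `9` = c(-1, 0))
  res <- lapply(names(dirs), function(nm) {
    u <- dirs[[nm]]
    # max in-bounds ray length along this direction
    lim <- function(t) {
      if (u[t] > 0) (hi[t] - center[t]) / u[t]
      else if (u[t] < 0) (lo[t] - center[t]) / u[t]
      else Inf
    }
    tmax <- min(lim(1), lim(2))
    ts <- seq(0, tmax, by = step)
    pts <- cbind(center[1] + ts * u[1], center[2] + ts * u[2])
    vals <- .bilinear_sample(img, g, pts)
    above <- vals >= threshold
    start <- which(above)[1]
    if (is.na(start))
      return(data.frame(direction = nm, thickness_mm = NA_real_,
                        found = FALSE))
    stop_at <- which(!above & seq_along(above) > start)[1]
    end <- if (is.na(stop_at)) length(ts) else stop_at - 1L
    data.frame(direction = nm, thickness_mm = ts[end] - ts[start],
               found = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "plane") <- plane
  attr(out, "center") <- center
  attr(out, "threshold") <- threshold
  attr(out, "step") <- step
  class(out) <- c("thickness_report", "data.frame")
  out
}

# bilinear interpolation of a 2D image defined on voxel centers
# origin + index*spacing; empty voxels already carry -Inf
.bilinear_sample <- function(img, grid, pts) {
  fx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  fy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  x0 <- pmin(pmax(floor(fx), 0), grid$dims[1] - 2L)
  y0 <- pmin(pmax(floor(fy), 0), grid$dims[2] - 2L)
  tx <- fx - x0
  ty <- fy - y0
  i0 <- x0 + 1L; j0 <- y0 + 1L
  v00 <- img[cbind(i0, j0)]
  v10 <- img[cbind(i0 + 1L, j0)]
  v01 <- img[cbind(i0, j0 + 1L)]
  v11 <- img[cbind(i0 + 1L, j0 + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' @export
print.thickness_report <- function(x, ...) {
  cat(sprintf("clock thickness on plane %d (threshold %.3g, step %.3g mm):\n",
              attr(x, "plane"), attr(x, "threshold"), attr(x, "step")))
  print.data.frame(x, ...)
  invisible(x)
}
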