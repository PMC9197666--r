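#' Rigid pose (rotation + translation)
#'
#' A rigid transform mapping slice-local coordinates (mm) to world
#' coordinates (mm): `p_world = R p_local + t`. The rotation must be a
#' proper orthonormal 3x3 matrix (determinant +1).
#'
#' @param rotation 3x3 orthonormal matrix, determinant +1.
#' @param translation numeric length-3 translation (mm).
#' @param tol tolerance for the orthonormality / determinant check.
#' @return An object of class `rigid_pose` with elements `rotation` and
#'   `translation`.
#' @examples
#' p <- rigid_pose(diag(3), c(1, 2, 3))
#' pose_apply(p, c(0, 0, 0))
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0),
                       tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop("rotation must be a finite 3x3 matrix")
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite length-3 vector")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g)", err))
  if (abs(det(rotation) - 1) > tol)
    stop(sprintf("rotation must have determinant +1 (got %.12g)",
                 det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("rigid_pose\n  rotation:\n")
  print(x$rotation)
  cat("  translation (mm):", format(x$translation), "\n")
  invisible(x)
}

is_rigid_pose <- function(x) inherits(x, "rigid_pose")

#' Apply a rigid pose to points
#'
#' @param pose a [rigid_pose()].
#' @param points numeric length-3 vector or Nx3 matrix of points (mm).
#' @return Points in the target frame, same shape as the input.
#' @export
pose_apply <- function(pose, points) {
  stopifnot(is_rigid_pose(pose))
  if (is.null(dim(points))) {
    drop(pose$rotation %*% as.numeric(points)) + pose$translation
  } else {
    sweep(points %*% t(pose$rotation), 2L, pose$translation, "+")
  }
}

#' Compose two rigid poses
#'
#' `pose_compose(a, b)` returns the pose that applies `b` first, then `a`.
#'
#' @param a,b [rigid_pose()] objects.
#' @return The composed `rigid_pose`.
#' @export
pose_compose <- function(a, b) {
  stopifnot(is_rigid_pose(a), is_rigid_pose(b))
  rigid_pose(a$rotation %*% b$rotation,
             drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid pose
#'
#' @param pose a [rigid_pose()].
#' @return The inverse `rigid_pose`, with
#'   `pose_compose(pose, pose_inverse(pose))` equal to the identity.
#' @export
pose_inverse <- function(pose) {
  stopifnot(is_rigid_pose(pose))
  rt <- t(pose$rotation)
  rigid_pose(rt, drop(-rt %*% pose$translation))
}

#' Rotation about a coordinate axis
#'
#' Convenience constructor for poses rotating about the world x, y or z
#' axis, mainly for building simulated probe trajectories.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle rotation angle in radians.
#' @param translation optional translation (mm), default zero.
#' @return A `rigid_pose`.
#' @export
pose_axis_rotation <- function(axis = c("x", "y", "z"), angle,
                               translation = c(0, 0, 0)) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  rot <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
    y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
    z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
  rigid_pose(rot, translation)
}

#' A calibrated 2D B-scan frame
#'
#' One grayscale ultrasound frame together with its pixel spacing and the
#' rigid pose placing it in the world frame. Pixel (i, j) (0-based row,
#' column) sits at slice-local coordinates
#' `(i * spacing[1], j * spacing[2], 0)` mm; the pose maps these to world
#' coordinates.
#'
#' @param pixels numeric matrix of intensities (arbitrary units, finite).
#' @param spacing length-2 positive pixel spacing (mm/pixel), row then
#'   column.
#' @param pose a [rigid_pose()] mapping slice-local to world coordinates.
#' @return An object of class `slice_frame`.
#' @export
slice_frame <- function(pixels, spacing, pose) {
  pixels <- as.matrix(pixels)
  spacing <- as.numeric(spacing)
  if (length(pixels) == 0L) stop("pixels must be non-empty")
  if (!all(is.finite(pixels))) stop("pixel intensities must be finite")
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two strictly positive values (mm/pixel)")
  if (!is_rigid_pose(pose)) stop("pose must be a rigid_pose")
  structure(list(pixels = pixels, spacing = spacing, pose = pose),
            class = "slice_frame")
}

is_slice_frame <- function(x) inherits(x, "slice_frame")

#' Scattered (position, intensity) samples in the world frame
#'
#' @param positions Nx3 numeric matrix of world coordinates (mm).
#' @param intensities numeric length-N vector of sample intensities.
#' @return An object of class `sample_cloud`.
#' @export
sample_cloud <- function(positions, intensities) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  intensities <- as.numeric(intensities)
  if (nrow(positions) != length(intensities))
    stop("positions and intensities must have the same length")
  if (length(intensities) > 0L &&
      (!all(is.finite(positions)) || !all(is.finite(intensities))))
    stop("positions and intensities must be finite")
  structure(list(positions = positions, intensities = intensities),
            class = "sample_cloud")
}

#' @export
print.sample_cloud <- function(x, ...) {
  cat(sprintf("sample_cloud: %d points\n", nrow(x$positions)))
  invisible(x)
}

#' Map a B-scan frame into the world frame
#'
#' Converts every pixel of a calibrated frame into a world-frame sample:
#' pixel (i, j), 0-based, maps to
#' `pose$rotation %*% c(i * spacing[1], j * spacing[2], 0) + pose$translation`
#' and carries its intensity unchanged.
#'
#' @param frame a [slice_frame()].
#' @return A [sample_cloud()] with one sample per pixel.
#' @examples
#' f <- slice_frame(matrix(1:6, 2, 3), c(1, 1), rigid_pose())
#' map_slice_to_world(f)
#' @export
map_slice_to_world <- function(frame) {
  stopifnot(is_slice_frame(frame))
  nr <- nrow(frame$pixels); nc <- ncol(frame$pixels)
  i <- rep(seq_len(nr) - 1L, times = nc)
  j <- rep(seq_len(nc) - 1L, each = nr)
  local <- cbind(i * frame$spacing[1], j * frame$spacing[2], 0)
  sample_cloud(pose_apply(frame$pose, local), as.vector(frame$pixels))
}

#' Combine sample clouds
#'
#' @param ... [sample_cloud()] objects.
#' @return A single `sample_cloud` with the samples concatenated in order.
#' @export
bind_clouds <- function(...) {
  clouds <- list(...)
  if (length(clouds) == 1L && is.list(clouds[[1]]) &&
      !inherits(clouds[[1]], "sample_cloud"))
    clouds <- clouds[[1]]
  sample_cloud(do.call(rbind, lapply(clouds, `[[`, "positions")),
               unlist(lapply(clouds, `[[`, "intensities"), use.names = FALSE))
}
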