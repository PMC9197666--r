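# MetaImage (MHD + RAW) volume input/output plus pose tables and frame
# stacks. MetaImage is used because its plain-text header carries the
# grid origin and spacing, so world coordinates survive a round trip.
# Arrays are written little-endian; MET_FLOAT (float32) by default or
# MET_DOUBLE for lossless doubles.

#' Write a reconstruction volume as MetaImage (MHD + RAW)
#'
#' Writes `<path>.mhd` (text header with dims, spacing and origin) plus
#' `<path>.raw`, and a companion fill mask `<path>_mask.mhd/.raw`
#' (MET_UCHAR, 1 = filled). Empty voxels are written as 0 in the
#' intensity file; the mask is authoritative.
#'
#' @param volume a [recon_volume()].
#' @param path output path without extension.
#' @param type `"float"` (MET_FLOAT, float32) or `"double"`
#'   (MET_DOUBLE, lossless for R numerics).
#' @return `path`, invisibly.
#' @export
write_volume_mhd <- function(volume, path, type = c("float", "double")) {
  stopifnot(is_recon_volume(volume))
  type <- match.arg(type)
  intensity <- volume$intensity
  intensity[!volume$filled] <- 0
  .write_mhd(intensity, volume$grid, path,
             if (type == "float") "MET_FLOAT" else "MET_DOUBLE")
  mask <- array(as.integer(volume$filled), volume$grid$dims)
  .write_mhd(mask, volume$grid, paste0(path, "_mask"), "MET_UCHAR")
  invisible(path)
}

#' Read a MetaImage volume written by [write_volume_mhd()]
#'
#' Reads `<path>.mhd` and, when present, the companion
#' `<path>_mask.mhd`; without a mask every voxel is taken as filled.
#'
#' @param path path without extension, as given to
#'   [write_volume_mhd()].
#' @return A [recon_volume()] (count is 1 where filled, 0 elsewhere —
#'   per-sample counts are not serialised).
#' @export
read_volume_mhd <- function(path) {
  v <- .read_mhd(paste0(path, ".mhd"))
  mask_path <- paste0(path, "_mask.mhd")
  filled <- if (file.exists(mask_path)) .read_mhd(mask_path)$data >= 1
            else array(TRUE, v$grid$dims)
  intensity <- v$data
  intensity[!filled] <- NA_real_
  recon_volume(v$grid, intensity, filled,
               array(as.integer(filled), v$grid$dims))
}

.write_mhd <- function(data, grid, path, element_type) {
  raw_name <- paste0(basename(path), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", grid$dims[1], grid$dims[2],
                   grid$dims[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g", grid$spacing[1],
                   grid$spacing[2], grid$spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g", grid$origin[1],
                   grid$origin[2], grid$origin[3]),
           paste("ElementType =", element_type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, paste0(path, ".mhd"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  vals <- as.vector(data)
  switch(element_type,
    MET_FLOAT = writeBin(as.numeric(vals), con, size = 4L,
                         endian = "little"),
    MET_DOUBLE = writeBin(as.numeric(vals), con, size = 8L,
                          endian = "little"),
    MET_UCHAR = writeBin(as.raw(vals), con),
    stop("unsupported ElementType: ", element_type))
}

.read_mhd <- function(header_path) {
  if (!file.exists(header_path)) stop("no such file: ", header_path)
  lines <- readLines(header_path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop(sprintf("%s: missing header field '%s'",
                               header_path, key))
    vals[i]
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- if ("Offset" %in% keys)
    as.numeric(strsplit(get("Offset"), "\\s+")[[1]]) else c(0, 0, 0)
  etype <- get("ElementType")
  raw_file <- file.path(dirname(header_path), get("ElementDataFile"))
  if (!file.exists(raw_file))
    stop(sprintf("%s: ElementDataFile '%s' not found", header_path,
                 raw_file))
  n <- prod(dims)
  con <- file(raw_file, "rb")
  on.exit(close(con))
  data <- switch(etype,
    MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8L, endian = "little"),
    MET_UCHAR = as.numeric(readBin(con, "raw", n)),
    stop(sprintf("%s: unsupported ElementType '%s'", header_path, etype)))
  if (length(data) != n)
    stop(sprintf("%s: raw file has %d values, header promises %d",
                 header_path, length(data), n))
  list(data = array(data, dims), grid = recon_grid(origin, spacing, dims))
}

#' Write per-frame poses to CSV
#'
#' One row per frame: `frame` id plus the 16 entries `m00 .. m33` of the
#' 4x4 homogeneous transform in row-major order.
#'
#' @param frames list of [slice_frame()] objects, or a list of
#'   [rigid_pose()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_poses_csv <- function(frames, path) {
  poses <- lapply(frames, function(f)
    if (is_slice_frame(f)) f$pose else f)
  rows <- lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    stopifnot(is_rigid_pose(p))
    m <- rbind(cbind(p$rotation, p$translation), c(0, 0, 0, 1))
    c(frame = i, setNames(as.vector(t(m)),
                          paste0("m", rep(0:3, each = 4), rep(0:3, 4))))
  })
  df <- as.data.frame(do.call(rbind, rows))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-frame poses from CSV
#'
#' @param path CSV written by [write_poses_csv()] (or any table with a
#'   `frame` column and 16 row-major matrix entries per row).
#' @return Named list of [rigid_pose()] objects, in file order.
#' @export
read_poses_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  if (ncol(df) != 17L)
    stop(sprintf("%s: expected 17 columns (frame + 16 matrix entries), got %d",
                 path, ncol(df)))
  lapply(seq_len(nrow(df)), function(r) {
    vals <- as.numeric(df[r, -1])
    if (any(!is.finite(vals)))
      stop(sprintf("%s: non-finite matrix entry in row %d", path, r))
    m <- matrix(vals, 4L, 4L, byrow = TRUE)
    if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
      stop(sprintf("%s: row %d is not a homogeneous rigid transform", path,
                   r))
    rigid_pose(m[1:3, 1:3], m[1:3, 4])
  })
}

#' Write a frame stack as a 3D MetaImage
#'
#' Stores frame `f`'s pixels as slice `z = f - 1` of a 3D array (all
#' frames must share their pixel dimensions), alongside the pose CSV
#' written by [write_poses_csv()]. The stack's z spacing is nominal
#' (1): geometry lives in the pose file, not the stack header.
#'
#' @param frames list of [slice_frame()] objects.
#' @param path output path without extension; writes `<path>.mhd`,
#'   `<path>.raw` and `<path>_poses.csv`.
#' @return `path`, invisibly.
#' @export
write_frames_mhd <- function(frames, path) {
  stopifnot(length(frames) > 0L, all(vapply(frames, is_slice_frame, TRUE)))
  d <- dim(frames[[1]]$pixels)
  if (!all(vapply(frames, function(f) all(dim(f$pixels) == d), TRUE)))
    stop("all frames must share pixel dimensions")
  sp <- frames[[1]]$spacing
  arr <- array(unlist(lapply(frames, function(f) as.vector(f$pixels))),
               c(d, length(frames)))
  grid <- recon_grid(c(0, 0, 0), c(sp, 1), dim(arr))
  .write_mhd(arr, grid, path, "MET_DOUBLE")
  write_poses_csv(frames, paste0(path, "_poses.csv"))
  invisible(path)
}

#' Read a frame stack written by [write_frames_mhd()]
#'
#' @param path path without extension.
#' @return List of [slice_frame()] objects with their poses.
#' @export
read_frames_mhd <- function(path) {
  v <- .read_mhd(paste0(path, ".mhd"))
  poses <- read_poses_csv(paste0(path, "_poses.csv"))
  if (length(poses) != v$grid$dims[3])
    stop("pose file and frame stack disagree on the number of frames")
  sp <- v$grid$spacing[1:2]
  lapply(seq_len(v$grid$dims[3]), function(f)
    slice_frame(v$data[, , f], sp, poses[[f]]))
}

#' Write a JSON report
#'
#' @param report a named list (fill report, deposit summary, metrics,
#'   thickness report...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "thickness_report"))
    report <- list(plane = attr(report, "plane"),
                   center = attr(report, "center"),
                   threshold = attr(report, "threshold"),
                   step = attr(report, "step"),
                   measurements = as.data.frame(report))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a thickness report as CSV
#'
#' Columns `plane`, `direction`, `thickness_mm`, `found`.
#'
#' @param report a `thickness_report` from [clock_thickness()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_thickness_csv <- function(report, path) {
  stopifnot(inherits(report, "thickness_report"))
  df <- data.frame(plane = attr(report, "plane"),
                   direction = report$direction,
                   thickness_mm = report$thickness_mm,
                   found = report$found)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
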