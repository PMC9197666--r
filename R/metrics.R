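#' Compare a reconstruction against a reference volume
#'
#' Voxelwise error metrics between a reconstructed volume and a
#' reference (typically the noise-free ground truth) on the same grid.
#' `psnr` uses `peak = max(|reference|)` over the compared voxels,
#' `psnr = 10 log10(peak^2 / mse)` in dB.
#'
#' @param recon a [recon_volume()].
#' @param truth a [recon_volume()] on an identical grid.
#' @param mask_policy `"filled_only"` (default): compare only voxels
#'   filled in both volumes; `"all"`: compare every voxel filled in the
#'   reference, with empty reconstruction voxels counted at intensity 0
#'   (black), so unfilled holes penalise the metrics.
#' @return A `metrics_report` list: `rmse`, `mae`, `psnr`, `peak`,
#'   `fill_fraction` (fraction of recon voxels filled),
#'   `n_voxels_compared`.
#' @export
compare_volumes <- function(recon, truth,
                            mask_policy = c("filled_only", "all")) {
  stopifnot(is_recon_volume(recon), is_recon_volume(truth))
  mask_policy <- match.arg(mask_policy)
  if (!grids_equal(recon$grid, truth$grid))
    stop(sprintf(
      "grid mismatch: recon %s vs truth %s",
      paste(recon$grid$dims, collapse = "x"),
      paste(truth$grid$dims, collapse = "x")))
  sel <- if (mask_policy == "filled_only") recon$filled & truth$filled
         else truth$filled
  n <- sum(sel)
  if (n == 0L) stop("no voxels to compare under the given mask policy")
  ri <- recon$intensity
  if (mask_policy == "all") ri[!recon$filled] <- 0
  err <- ri[sel] - truth$intensity[sel]
  mse <- mean(err^2)
  peak <- max(abs(truth$intensity[sel]))
  structure(list(rmse = sqrt(mse),
                 mae = mean(abs(err)),
                 psnr = if (mse == 0) Inf else 10 * log10(peak^2 / mse),
                 peak = peak,
                 fill_fraction = mean(recon$filled),
                 n_voxels_compared = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics: rmse %.6g, mae %.6g, psnr %.4g dB (peak %.4g), fill %.1f%%, n = %d\n",
    x$rmse, x$mae, x$psnr, x$peak, 100 * x$fill_fraction,
    x$n_voxels_compared))
  invisible(x)
}
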