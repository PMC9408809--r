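#' Regional signal-intensity thresholds for LGE segmentation
#'
#' Remote and infarct signal statistics pooled across all slices of a
#' subject define the two classification thresholds:
#' `t_low = mu_remote + 2 sigma_remote` and
#' `t_high = (mu_remote + mu_infarct)/2`. Classification is usable only
#' when `t_low < t_high`; otherwise the thresholds are flagged degenerate.
#' The infarct standard deviation is computed and stored although the
#' classification rule does not use it.
#'
#' @param mu_remote,sigma_remote,mu_infarct,sigma_infarct Intensity
#'   statistics (sigmas >= 0).
#' @return An object of class `seg_thresholds`.
#' @export
seg_thresholds <- function(mu_remote, sigma_remote, mu_infarct,
                           sigma_infarct = NA_real_) {
  if (sigma_remote < 0 || (!is.na(sigma_infarct) && sigma_infarct < 0))
    stop("sigma values must be nonnegative")
  t_low <- mu_remote + 2 * sigma_remote
  t_high <- (mu_remote + mu_infarct) / 2
  structure(list(mu_remote = mu_remote, sigma_remote = sigma_remote,
                 mu_infarct = mu_infarct, sigma_infarct = sigma_infarct,
                 t_low = t_low, t_high = t_high,
                 degenerate = !(t_low < t_high)),
            class = "seg_thresholds")
}

#' @export
print.seg_thresholds <- function(x, ...) {
  cat(sprintf("<seg_thresholds> remote %.4g +/- %.4g, infarct %.4g; t_low = %.4g, t_high = %.4g%s\n",
              x$mu_remote, x$sigma_remote, x$mu_infarct, x$t_low, x$t_high,
              if (x$degenerate) " (DEGENERATE)" else ""))
  invisible(x)
}

roi_to_logical <- function(roi, d3, what) {
  if (inherits(roi, "volume3d")) roi <- roi$data
  roi <- roi != 0
  if (!identical(dim(roi), d3))
    stop(what, " ROI does not lie on the image grid")
  roi
}

#' Estimate segmentation thresholds from remote and infarct ROIs
#'
#' Means and standard deviations are computed pooling ROI voxels across
#' all slices of the subject. The standard deviation uses the population
#' formula (divisor n) by default.
#'
#' @param lge LGE [volume3d()].
#' @param remote_rois,infarct_rois Logical arrays (or volumes/label maps
#'   with nonzero = ROI) on the LGE grid.
#' @param ddof Delta degrees of freedom for the SD (0 = population,
#'   1 = sample).
#' @return A [seg_thresholds()].
#' @export
estimate_region_stats <- function(lge, remote_rois, infarct_rois, ddof = 0) {
  stopifnot(inherits(lge, "volume3d"))
  d3 <- dim(lge$data)
  rr <- roi_to_logical(remote_rois, d3, "remote")
  ir <- roi_to_logical(infarct_rois, d3, "infarct")
  if (!any(rr)) stop("remote ROI required (empty)")
  if (!any(ir)) stop("infarct ROI required (empty)")
  sd_pop <- function(x) {
    n <- length(x)
    if (n - ddof <= 0) return(0)
    sqrt(sum((x - mean(x))^2) / (n - ddof))
  }
  xr <- lge$data[rr]; xi <- lge$data[ir]
  seg_thresholds(mean(xr), sd_pop(xr), mean(xi), sd_pop(xi))
}

#' Classify myocardial voxels into remote, border, and infarct
#'
#' Within the myocardium mask: `SI <= t_low` is remote (1),
#' `t_low < SI < t_high` is border (2), and `SI >= t_high` is infarct (3);
#' voxels outside the mask are background (0). Every myocardial voxel
#' receives exactly one label.
#'
#' @param lge LGE [volume3d()].
#' @param thr A [seg_thresholds()]; must not be degenerate.
#' @param myocardium Logical array (or volume/label map with nonzero =
#'   myocardium) on the LGE grid.
#' @return A [label_map()] on the LGE grid.
#' @export
classify_voxels <- function(lge, thr, myocardium) {
  stopifnot(inherits(lge, "volume3d"), inherits(thr, "seg_thresholds"))
  if (thr$degenerate)
    stop("degenerate thresholds (t_low >= t_high); classification unusable")
  d3 <- dim(lge$data)
  myo <- roi_to_logical(myocardium, d3, "myocardium")
  si <- lge$data
  lab <- array(0L, d3)
  lab[myo & si <= thr$t_low] <- 1L
  lab[myo & si > thr$t_low & si < thr$t_high] <- 2L
  lab[myo & si >= thr$t_high] <- 3L
  label_map(lab, reference = lge)
}
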