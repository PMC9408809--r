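#' Extracellular volume fraction map from pre/post-contrast T1
#'
#' Voxelwise `ECV = (1 - Hct) * dR1_myo / dR1_blood` with
#' `dR1 = 1/T1_post - 1/T1_pre`. Voxels with nonpositive myocardial `dR1`
#' are set to 0 and flagged; values above 1 are flagged but retained
#' (not clipped).
#'
#' @param t1_pre_myo,t1_post_myo Native and post-contrast myocardial T1
#'   maps ([volume3d()], ms) on a common grid.
#' @param t1_pre_blood,t1_post_blood Scalar blood-pool T1 values, ms
#'   (blood `dR1` must be positive).
#' @param hct Hematocrit fraction in `(0, 1)`.
#' @param mask Optional logical array restricting the computation;
#'   defaults to voxels with both T1 values positive.
#' @return List with `ecv` ([volume3d()], `NA` outside the mask) and the
#'   logical `flagged` array.
#' @export
compute_ecv <- function(t1_pre_myo, t1_post_myo, t1_pre_blood,
                        t1_post_blood, hct, mask = NULL) {
  stopifnot(inherits(t1_pre_myo, "volume3d"), inherits(t1_post_myo, "volume3d"))
  if (!same_grid(t1_pre_myo, t1_post_myo))
    stop("pre and post T1 maps must share a grid")
  if (t1_pre_blood <= 0 || t1_post_blood <= 0)
    stop("blood T1 values must be positive")
  if (hct <= 0 || hct >= 1) stop("hct must lie in (0, 1)")
  dr1_blood <- 1 / t1_post_blood - 1 / t1_pre_blood
  if (dr1_blood <= 0) stop("nonpositive blood delta-R1")
  pre <- t1_pre_myo$data; post <- t1_post_myo$data
  if (is.null(mask)) mask <- pre > 0 & post > 0
  ecv <- array(NA_real_, dim(pre))
  dr1 <- 1 / post[mask] - 1 / pre[mask]
  v <- (1 - hct) * dr1 / dr1_blood
  flag_in <- dr1 <= 0 | v > 1
  v[dr1 <= 0] <- 0
  ecv[mask] <- v
  flagged <- array(FALSE, dim(pre))
  flagged[mask] <- flag_in
  list(ecv = vol_like(t1_pre_myo, ecv, intensity_units = "fraction"),
       flagged = flagged)
}
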