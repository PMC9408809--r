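#' Configuration for the infarcted left-ventricle phantom
#'
#' Defines a 5-slice annular LV with an infarct sector and a border rim,
#' imaged twice: an LGE-like acquisition on a diastolic grid and a
#' DWI/cDTI-like acquisition on a systolic grid related to diastole by
#' radial wall thickening plus uniform longitudinal (z) shortening. T1
#' maps are emulated on the cDTI grid. Defaults follow the in vivo swine
#' protocol this package targets: LGE 1.33 x 1.33 x 8 mm voxels, cDTI
#' 2 x 2 x 8 mm, b = 0 and 350 s/mm^2 with 12 directions, S0 SNR of 16,
#' and per-region tensor eigenvalues equal to the reported in vivo median
#' values for remote, border, and infarct myocardium.
#'
#' @param n_slices Number of diastolic LGE slices.
#' @param lge_spacing_mm,cdti_spacing_mm Voxel spacing `(dz, dy, dx)` of
#'   the two grids, mm.
#' @param lge_dim_inplane,cdti_dim_inplane In-plane grid size `(rows, cols)`.
#' @param endo_radius_mm,epi_radius_mm Basal diastolic endo/epicardial
#'   radii, mm.
#' @param apical_taper Fractional linear shrinkage of both radii from base
#'   to apex.
#' @param systolic_wall_thickening Fractional wall thickening in systole.
#' @param systolic_z_scale Uniform longitudinal scale factor in systole
#'   (in `(0, 1]`).
#' @param infarct_sector_deg,border_rim_deg Angular extent of the infarct
#'   sector (at its mid-ventricular maximum) and of the border rim on each
#'   of its sides, degrees.
#' @param infarct_center_deg Angular position of the infarct centre.
#' @param infarct_profile_min Fraction of `infarct_sector_deg` retained at
#'   the most basal and apical slices; the sector bulges sinusoidally to
#'   its full extent at mid-ventricle, emulating the axial shape of a
#'   territorial infarct.
#' @param transmural_extent Radial fraction of the wall, from the
#'   endocardium outward, occupied by the infarct/border sector.
#' @param region_eigenvalues 3 x 3 matrix (rows remote/border/infarct) of
#'   tensor eigenvalues `(e1, e2, e3)` in mm^2/s.
#' @param helix_angle_deg Half-range of the transmural helix sweep of the
#'   primary eigenvector (+/- this angle from endo to epi).
#' @param lge_intensity Named vector `(mu_remote, sigma_remote, mu_infarct,
#'   sigma_infarct)` of LGE signal intensities.
#' @param lge_background Mean and SD of background LGE intensity.
#' @param t1_native_myo_ms Native T1 per region (remote, border, infarct), ms.
#' @param ecv_medians Target regional ECV medians used to derive the
#'   default post-contrast myocardial T1 values.
#' @param t1_blood_ms Native and post-contrast blood T1, ms.
#' @param t1_noise_sd_ms Gaussian noise SD for native and post-contrast T1
#'   maps, ms.
#' @param hct Hematocrit fraction.
#' @param s0 b = 0 signal amplitude.
#' @param snr S0 signal-to-noise ratio of the DWI (Rician noise with
#'   `sigma = s0/snr`); `Inf` disables noise.
#' @param b_nonzero Nonzero b-value, s/mm^2.
#' @param seed Integer seed making the phantom deterministic.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 5L,
                           lge_spacing_mm = c(8, 1.33, 1.33),
                           lge_dim_inplane = c(96L, 96L),
                           cdti_spacing_mm = c(8, 2, 2),
                           cdti_dim_inplane = c(64L, 64L),
                           endo_radius_mm = 15,
                           epi_radius_mm = 27,
                           apical_taper = 0.25,
                           systolic_wall_thickening = 0.10,
                           systolic_z_scale = 0.75,
                           infarct_sector_deg = 90,
                           border_rim_deg = 30,
                           infarct_center_deg = 90,
                           infarct_profile_min = 0.55,
                           transmural_extent = 1.0,
                           region_eigenvalues = rbind(
                             remote  = c(1.94, 1.38, 1.06) * 1e-3,
                             border  = c(2.14, 1.65, 1.24) * 1e-3,
                             infarct = c(2.28, 1.83, 1.42) * 1e-3),
                           helix_angle_deg = 60,
                           lge_intensity = c(mu_remote = 100, sigma_remote = 10,
                                             mu_infarct = 300, sigma_infarct = 20),
                           lge_background = c(20, 5),
                           t1_native_myo_ms = c(remote = 1282, border = 1389,
                                                infarct = 1554),
                           ecv_medians = c(remote = 0.31, border = 0.38,
                                           infarct = 0.47),
                           t1_blood_ms = c(pre = 1700, post = 400),
                           t1_noise_sd_ms = c(native = 30, post = 10),
                           hct = 0.30,
                           s0 = 100,
                           snr = 16,
                           b_nonzero = 350,
                           seed = 1L) {
  if (transmural_extent <= 0 || transmural_extent > 1)
    stop("transmural_extent must lie in (0, 1]")
  if (systolic_z_scale <= 0 || systolic_z_scale > 1)
    stop("systolic_z_scale must lie in (0, 1]")
  if (lge_intensity["mu_infarct"] <=
      lge_intensity["mu_remote"] + 2 * lge_intensity["sigma_remote"])
    stop("mu_infarct must exceed mu_remote + 2 sigma_remote")
  if (infarct_sector_deg + 2 * border_rim_deg > 360)
    stop("sector angles sum to more than 360 degrees")
  if (infarct_sector_deg < 0 || border_rim_deg < 0)
    stop("sector angles must be nonnegative")
  if (endo_radius_mm >= epi_radius_mm) stop("endo radius must be < epi radius")
  fov <- min(lge_dim_inplane[1L] * lge_spacing_mm[2L],
             lge_dim_inplane[2L] * lge_spacing_mm[3L],
             cdti_dim_inplane[1L] * cdti_spacing_mm[2L],
             cdti_dim_inplane[2L] * cdti_spacing_mm[3L])
  if (2 * epi_radius_mm * (1 + systolic_wall_thickening) > 0.95 * fov)
    stop("epicardial radius exceeds the field of view")
  # Post-contrast myocardial T1 chosen so the noise-free regional ECV
  # equals ecv_medians at the configured hematocrit and blood T1.
  dr1_blood <- 1 / t1_blood_ms["post"] - 1 / t1_blood_ms["pre"]
  dr1_myo <- ecv_medians * dr1_blood / (1 - hct)
  t1_post_myo_ms <- 1 / (dr1_myo + 1 / t1_native_myo_ms)
  cfg <- list(n_slices = as.integer(n_slices),
              lge_spacing_mm = lge_spacing_mm,
              lge_dim_inplane = as.integer(lge_dim_inplane),
              cdti_spacing_mm = cdti_spacing_mm,
              cdti_dim_inplane = as.integer(cdti_dim_inplane),
              endo_radius_mm = endo_radius_mm, epi_radius_mm = epi_radius_mm,
              apical_taper = apical_taper,
              systolic_wall_thickening = systolic_wall_thickening,
              systolic_z_scale = systolic_z_scale,
              infarct_sector_deg = infarct_sector_deg,
              border_rim_deg = border_rim_deg,
              infarct_center_deg = infarct_center_deg,
              infarct_profile_min = infarct_profile_min,
              transmural_extent = transmural_extent,
              region_eigenvalues = region_eigenvalues,
              helix_angle_deg = helix_angle_deg,
              lge_intensity = lge_intensity, lge_background = lge_background,
              t1_native_myo_ms = t1_native_myo_ms,
              t1_post_myo_ms = setNames(as.numeric(t1_post_myo_ms),
                                        names(t1_native_myo_ms)),
              ecv_medians = ecv_medians,
              t1_blood_ms = t1_blood_ms, t1_noise_sd_ms = t1_noise_sd_ms,
              hct = hct, s0 = s0, snr = snr, b_nonzero = b_nonzero,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# Diastolic endo/epi radii at diastolic longitudinal position z (mm),
# tapering linearly toward the apex.
diastolic_radii <- function(cfg, z) {
  span <- (cfg$n_slices - 1) * cfg$lge_spacing_mm[1L]
  frac <- if (span > 0) pmin(pmax(z / span, 0), 1) else 0
  tf <- 1 - cfg$apical_taper * frac
  list(endo = cfg$endo_radius_mm * tf, epi = cfg$epi_radius_mm * tf)
}

# Systolic radii at systolic z: the wall thickens by the configured
# fraction with the epicardium held fixed (endocardial inward motion).
systolic_radii <- function(cfg, z_sys) {
  rd <- diastolic_radii(cfg, z_sys / cfg$systolic_z_scale)
  wall <- (rd$epi - rd$endo) * (1 + cfg$systolic_wall_thickening)
  list(endo = rd$epi - wall, epi = rd$epi)
}

# Axial scaling of the infarct sector: smallest at base and apex,
# full extent at mid-ventricle. `zfrac` is the normalized diastolic
# longitudinal position in [0, 1].
infarct_sector_scale <- function(cfg, zfrac) {
  zfrac <- pmin(pmax(zfrac, 0), 1)
  cfg$infarct_profile_min + (1 - cfg$infarct_profile_min) * sin(pi * zfrac)
}

# Truth labels on one slice: polar classification into remote(1)/
# border(2)/infarct(3) within the annulus, 0 outside.
slice_truth_labels <- function(cfg, dim_yx, spacing_yx, endo, epi,
                               sector_scale = 1) {
  co <- inplane_coords(dim_yx, spacing_yx)
  cy <- (dim_yx[1L] - 1) * spacing_yx[1L] / 2
  cx <- (dim_yx[2L] - 1) * spacing_yx[2L] / 2
  r <- sqrt((co$x - cx)^2 + (co$y - cy)^2)
  th <- atan2(co$y - cy, co$x - cx) * 180 / pi
  dth <- abs(((th - cfg$infarct_center_deg + 180) %% 360) - 180)
  lab <- matrix(0L, dim_yx[1L], dim_yx[2L])
  myo <- r >= endo & r <= epi
  lab[myo] <- 1L
  r_ext <- endo + cfg$transmural_extent * (epi - endo)
  half <- sector_scale * cfg$infarct_sector_deg / 2
  sector_ok <- myo & r <= r_ext
  if (cfg$infarct_sector_deg > 0) {
    lab[sector_ok & dth <= half + cfg$border_rim_deg] <- 2L
    lab[sector_ok & dth <= half] <- 3L
  }
  lab
}

truth_label_volume <- function(cfg, phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  span_d <- (cfg$n_slices - 1) * cfg$lge_spacing_mm[1L]
  if (phase == "diastole") {
    dim_yx <- cfg$lge_dim_inplane; sp <- cfg$lge_spacing_mm
    zs <- (seq_len(cfg$n_slices) - 1) * sp[1L]
    radii <- lapply(zs, function(z) diastolic_radii(cfg, z))
    zfrac <- if (span_d > 0) zs / span_d else 0 * zs
  } else {
    dim_yx <- cfg$cdti_dim_inplane; sp <- cfg$cdti_spacing_mm
    span <- span_d * cfg$systolic_z_scale
    zs <- seq(0, span, by = sp[1L])
    radii <- lapply(zs, function(z) systolic_radii(cfg, z))
    zfrac <- if (span > 0) zs / span else 0 * zs
  }
  lab <- array(0L, dim = c(length(zs), dim_yx))
  for (s in seq_along(zs))
    lab[s, , ] <- slice_truth_labels(cfg, dim_yx, sp[2:3],
                                     radii[[s]]$endo, radii[[s]]$epi,
                                     infarct_sector_scale(cfg, zfrac[s]))
  label_map(lab, spacing_mm = sp, slice_z_mm = zs)
}

#' Apply Rician noise to a signal array
#'
#' Returns the magnitude of `(signal + n1, n2)` with independent
#' `n1, n2 ~ N(0, sigma^2)`. With `sigma = 0` the input is returned
#' exactly.
#'
#' @param signal Numeric array or vector of noise-free magnitudes.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Array of the same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signal)
  out <- sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Synthesize a DWI series from a tensor field
#'
#' Monoexponential forward model `S = s0 exp(-b g' D g)` per voxel and
#' gradient entry, with optional Rician noise at `sigma = s0/snr`.
#' Voxels outside the field's validity mask give zero noise-free signal.
#'
#' @param tensors A [tensor_field()] (positive semidefinite where valid).
#' @param scheme A [gradient_scheme()].
#' @param s0 Noise-free b = 0 amplitude (>= 0).
#' @param snr S0 signal-to-noise ratio; `Inf` gives the exact signal.
#' @param seed Optional seed for the noise draws.
#' @return A [dwi_series()].
#' @export
synthesize_dwi <- function(tensors, scheme, s0, snr = Inf, seed = NULL) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(scheme, "gradient_scheme"))
  if (s0 < 0) stop("s0 must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  d3 <- dim(tensors$valid)
  nvox <- prod(d3)
  t6 <- matrix(tensors$tensor6, nrow = nvox, ncol = 6L)
  t6[!as.vector(tensors$valid), ] <- 0
  bq <- scheme$bvals * quadratic_design(scheme$bvecs)  # ngrad x 6
  expo <- t6 %*% t(bq)                                 # nvox x ngrad
  sig <- s0 * exp(-expo)
  sig[!as.vector(tensors$valid), ] <- 0
  sigma <- if (is.finite(snr)) s0 / snr else 0
  ref <- tensor_ref_volume(tensors)
  vols <- lapply(seq_along(scheme$bvals), function(j) {
    v <- sig[, j]
    if (sigma > 0) v <- add_rician_noise(v, sigma)
    vol_like(ref, v, intensity_units = "signal")
  })
  dwi_series(vols, scheme)
}

#' Generate an infarcted-LV phantom study
#'
#' Builds, deterministically for a fixed seed, a complete synthetic study:
#' a diastolic LGE volume with separated remote/infarct intensity
#' distributions (border intensities drawn uniformly between the two
#' classification thresholds), native and post-contrast T1 maps, a
#' systolic DWI series synthesized from per-region ground-truth tensors,
#' and ground-truth label maps in both cardiac phases.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `phantom_study`: list with elements `lge`,
#'   `t1_pre`, `t1_post`, `dwi`, `truth_labels_diastole`,
#'   `truth_labels_systole`, `truth_tensors`, `hct`, and `config`.
#' @export
make_lv_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  lab_d <- truth_label_volume(cfg, "diastole")
  lab_s <- truth_label_volume(cfg, "systole")

  ## LGE intensities on the diastolic grid
  li <- cfg$lge_intensity
  t_low <- li["mu_remote"] + 2 * li["sigma_remote"]
  t_high <- (li["mu_remote"] + li["mu_infarct"]) / 2
  lv <- lab_d$data
  n <- length(lv)
  lge <- rnorm(n, cfg$lge_background[1L], cfg$lge_background[2L])
  lge[lv == 1L] <- rnorm(sum(lv == 1L), li["mu_remote"], li["sigma_remote"])
  lge[lv == 2L] <- runif(sum(lv == 2L), t_low, t_high)
  lge[lv == 3L] <- rnorm(sum(lv == 3L), li["mu_infarct"], li["sigma_infarct"])
  lge <- pmax(lge, 0)
  lge_vol <- vol_like(lab_d, lge, intensity_units = "signal")
  class(lge_vol) <- "volume3d"

  ## T1 maps on the systolic (cDTI) grid
  ls <- lab_s$data
  t1p <- array(0, dim(ls)); t1q <- array(0, dim(ls))
  for (k in 1:3) {
    idx <- which(ls == k)
    t1p[idx] <- cfg$t1_native_myo_ms[k] +
      rnorm(length(idx), 0, cfg$t1_noise_sd_ms["native"])
    t1q[idx] <- cfg$t1_post_myo_ms[k] +
      rnorm(length(idx), 0, cfg$t1_noise_sd_ms["post"])
  }
  ref_s <- vol_like(lab_s, 0); class(ref_s) <- "volume3d"
  t1_pre <- vol_like(ref_s, t1p, intensity_units = "ms")
  t1_post <- vol_like(ref_s, t1q, intensity_units = "ms")

  ## Ground-truth tensors on the systolic grid
  tensors <- phantom_truth_tensors(cfg, lab_s)

  ## DWI: b = 0 followed by 12 diffusion directions
  scheme <- gradient_scheme(c(0, rep(cfg$b_nonzero, 12L)),
                            rbind(c(0, 0, 0), default_directions(12L)))
  dwi <- synthesize_dwi(tensors, scheme, s0 = cfg$s0, snr = cfg$snr)

  structure(list(lge = lge_vol, t1_pre = t1_pre, t1_post = t1_post,
                 dwi = dwi, truth_labels_diastole = lab_d,
                 truth_labels_systole = lab_s, truth_tensors = tensors,
                 hct = cfg$hct, config = cfg),
            class = "phantom_study")
}

# Region tensors with a circumferential primary eigenvector swept by a
# transmural helix angle (+helix at endo to -helix at epi); the secondary
# eigenvector is the cross-myofiber direction in the wall tangent plane
# and the tertiary is radial.
phantom_truth_tensors <- function(cfg, lab_s) {
  d3 <- dim(lab_s$data)
  sp <- lab_s$spacing_mm
  co <- inplane_coords(d3[2:3], sp[2:3])
  cy <- (d3[2L] - 1) * sp[2L] / 2
  cx <- (d3[3L] - 1) * sp[3L] / 2
  r <- sqrt((co$x - cx)^2 + (co$y - cy)^2)
  th <- atan2(co$y - cy, co$x - cx)
  tensor6 <- array(0, dim = c(d3, 6L))
  valid <- lab_s$data > 0L
  for (s in seq_len(d3[1L])) {
    rad <- systolic_radii(cfg, lab_s$slice_z_mm[s])
    lab2 <- lab_s$data[s, , ]
    idx <- which(lab2 > 0L)
    if (length(idx) == 0L) next
    depth <- pmin(pmax((r[idx] - rad$endo) / (rad$epi - rad$endo), 0), 1)
    alpha <- cfg$helix_angle_deg * (1 - 2 * depth) * pi / 180
    ct <- cos(th[idx]); st <- sin(th[idx])
    ca <- cos(alpha); sa <- sin(alpha)
    # basis in (x, y, z): radial (ct, st, 0), circumferential (-st, ct, 0)
    lam <- cfg$region_eigenvalues[lab2[idx], , drop = FALSE]
    e1 <- cbind(-st * ca, ct * ca, sa)
    e2 <- cbind(st * sa, -ct * sa, ca)
    e3 <- cbind(ct, st, 0)
    Dxx <- lam[, 1] * e1[, 1]^2 + lam[, 2] * e2[, 1]^2 + lam[, 3] * e3[, 1]^2
    Dyy <- lam[, 1] * e1[, 2]^2 + lam[, 2] * e2[, 2]^2 + lam[, 3] * e3[, 2]^2
    Dzz <- lam[, 1] * e1[, 3]^2 + lam[, 2] * e2[, 3]^2 + lam[, 3] * e3[, 3]^2
    Dxy <- lam[, 1] * e1[, 1] * e1[, 2] + lam[, 2] * e2[, 1] * e2[, 2] +
      lam[, 3] * e3[, 1] * e3[, 2]
    Dxz <- lam[, 1] * e1[, 1] * e1[, 3] + lam[, 2] * e2[, 1] * e2[, 3] +
      lam[, 3] * e3[, 1] * e3[, 3]
    Dyz <- lam[, 1] * e1[, 2] * e1[, 3] + lam[, 2] * e2[, 2] * e2[, 3] +
      lam[, 3] * e3[, 2] * e3[, 3]
    comp <- list(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
    for (k in 1:6) {
      plane <- tensor6[s, , , k]
      plane[idx] <- comp[[k]]
      tensor6[s, , , k] <- plane
    }
  }
  ref <- vol_like(lab_s, 0); class(ref) <- "volume3d"
  tensor_field(tensor6, valid, ref)
}

# 2D binary erosion by one voxel (3x3 structuring element, 8-neighbour).
erode2d <- function(mask) {
  m <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  for (di in 0:2) for (dj in 0:2)
    m <- m & pad[(1:nr) + di, (1:nc) + dj]
  m
}

#' Automatic phantom ROIs from truth labels
#'
#' Builds remote and infarct regions of interest by eroding the
#' corresponding truth-label masks by one voxel per slice, emulating
#' conservative manually drawn ROIs.
#'
#' @param labels A truth [label_map()].
#' @return List of logical arrays `remote` and `infarct`.
#' @export
phantom_rois <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  d3 <- dim(labels$data)
  out <- list(remote = array(FALSE, d3), infarct = array(FALSE, d3))
  for (s in seq_len(d3[1L])) {
    out$remote[s, , ] <- erode2d(labels$data[s, , ] == 1L)
    out$infarct[s, , ] <- erode2d(labels$data[s, , ] == 3L)
  }
  out
}
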