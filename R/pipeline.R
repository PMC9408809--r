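#' Write a phantom study to disk
#'
#' Exports the LGE volume, T1 maps, DWI series with its bval/bvec
#' gradient table, ground-truth label maps, and a JSON manifest.
#'
#' @param study A [make_lv_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_phantom <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_volume(study$lge, p("lge.nii.gz"))
  write_volume(study$t1_pre, p("t1_native.nii.gz"))
  write_volume(study$t1_post, p("t1_post.nii.gz"))
  write_volume(study$truth_labels_diastole, p("truth_labels_diastole.nii.gz"))
  write_volume(study$truth_labels_systole, p("truth_labels_systole.nii.gz"))
  for (i in seq_along(study$dwi$volumes))
    write_volume(study$dwi$volumes[[i]], p(sprintf("dwi_%02d.nii.gz", i)))
  write_gradient_table(study$dwi$scheme, p("dwi.bval"), p("dwi.bvec"))
  manifest <- list(kind = "lv_phantom",
                   package_version = as.character(utils::packageVersion("cardti")),
                   seed = study$config$seed, hct = study$hct,
                   n_dwi = length(study$dwi$volumes),
                   files = list.files(dir))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Load a pipeline configuration from YAML
#'
#' Reads per-module parameter blocks (segmentation, registration, dti,
#' ecv, stats, sim), input paths, output directory, and seed. Referenced
#' input paths are checked for existence at validation time.
#'
#' @param path Path to a YAML file.
#' @return The configuration list, validated.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in names(cfg$inputs)) {
    f <- cfg$inputs[[field]]
    if (is.character(f) && !file.exists(f))
      stop("validation error: input path for field '", field,
           "' does not exist: ", f)
  }
  cfg
}

#' Run the full regional biomarker pipeline on a study
#'
#' Executes segment -> register -> fit-dti (with MD rejection) ->
#' compute-ecv -> regional statistics, writing summary tables
#' (region-wise mean/median/quartiles, pairwise percent changes with
#' Kruskal-Wallis Bonferroni-adjusted p-values, per-subject table),
#' biomarker maps, a JSON manifest and a structured JSON-lines log.
#'
#' @param study A `phantom_study` (or a list with the same elements:
#'   `lge`, `t1_pre`, `t1_post`, `dwi`, a myocardium source, hct, config).
#' @param out_dir Output directory; `NULL` skips all file output.
#' @param subject_id Subject identifier for the tables.
#' @param remote_roi,infarct_roi Optional ROI masks on the LGE grid; by
#'   default drawn automatically from the diastolic truth labels (eroded
#'   by one voxel).
#' @param md_threshold MD rejection threshold, mm^2/s.
#' @param reg_options Options forwarded to [register_labels()].
#' @param write_maps Write biomarker NIfTI maps (in addition to CSVs).
#' @return List with `labels`, `maps`, `thresholds`, `pooled`, `summary`,
#'   `changes`, `tests`, `rejected_fraction`, `diagnostics`, and output
#'   `paths`.
#' @export
run_pipeline <- function(study, out_dir = NULL, subject_id = "S1",
                         remote_roi = NULL, infarct_roi = NULL,
                         md_threshold = 3e-3, reg_options = list(),
                         write_maps = TRUE) {
  log <- list()
  note <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    log[[length(log) + 1L]] <<- rec
    rec
  }
  ## --- segmentation on the diastolic LGE grid
  if (is.null(remote_roi) || is.null(infarct_roi)) {
    if (is.null(study$truth_labels_diastole))
      stop("ROIs required when the study carries no truth labels")
    rois <- phantom_rois(study$truth_labels_diastole)
    if (is.null(remote_roi)) remote_roi <- rois$remote
    if (is.null(infarct_roi)) infarct_roi <- rois$infarct
  }
  myo_d <- if (!is.null(study$truth_labels_diastole))
    study$truth_labels_diastole$data > 0L else remote_roi | infarct_roi
  thr <- estimate_region_stats(study$lge, remote_roi, infarct_roi)
  labels_d <- classify_voxels(study$lge, thr, myo_d)
  note("segment", t_low = thr$t_low, t_high = thr$t_high,
       n_remote = sum(labels_d$data == 1L),
       n_border = sum(labels_d$data == 2L),
       n_infarct = sum(labels_d$data == 3L))
  ## --- registration onto the cDTI grid
  b0 <- b0_volume(study$dwi)
  reg <- register_labels(labels_d, study$lge, b0, options = reg_options)
  note("register", slice_dice = reg$diagnostics$slice_dice,
       z_scaled = reg$diagnostics$z_scaled)
  ## --- tensor reconstruction and rejection filter
  field <- fit_tensor_loglinear(study$dwi, mask = reg$labels$data > 0L)
  rej <- reject_voxels_md(field, md_threshold)
  note("fit_dti", n_valid = sum(rej$field$valid),
       rejected_fraction = rej$rejected_fraction)
  maps <- invariant_maps(rej$field)
  ## --- ECV (T1 maps share the cDTI grid in this pipeline)
  cfgp <- study$config
  ecvr <- compute_ecv(study$t1_pre, study$t1_post,
                      cfgp$t1_blood_ms["pre"], cfgp$t1_blood_ms["post"],
                      study$hct)
  note("compute_ecv", n_flagged = sum(ecvr$flagged))
  ## --- regional statistics
  all_maps <- c(maps, list(ECV = ecvr$ecv, NativeT1 = study$t1_pre))
  pooled <- pool_by_region(all_maps, reg$labels, subject_id,
                           valid = rej$field$valid)
  summary_tab <- summarize_regions(pooled)
  quantities <- unique(pooled$quantity)
  tests <- list(); changes <- list()
  for (qt in quantities) {
    sub <- pooled[pooled$quantity == qt, ]
    grp <- split(sub$value, sub$region)
    kw <- kruskal_wallis_pairwise(grp)
    kw$quantity <- qt
    tests[[qt]] <- kw
    pc <- data.frame(
      quantity = qt,
      pair = c("border-remote", "infarct-remote", "infarct-border"),
      percent_change = c(
        percent_change_of_medians(grp$border, grp$remote),
        percent_change_of_medians(grp$infarct, grp$remote),
        percent_change_of_medians(grp$infarct, grp$border)),
      stringsAsFactors = FALSE)
    key <- paste(pmin(kw$group1, kw$group2), pmax(kw$group1, kw$group2))
    pckey <- c("border-remote" = "border remote",
               "infarct-remote" = "infarct remote",
               "infarct-border" = "border infarct")
    pc$p_adj <- kw$p_adj[match(pckey[pc$pair], key)]
    changes[[qt]] <- pc
  }
  tests <- do.call(rbind, tests); rownames(tests) <- NULL
  changes <- do.call(rbind, changes); rownames(changes) <- NULL
  note("regional_stats", n_pooled = nrow(pooled))
  ## --- outputs
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write.csv(summary_tab, p("summary_by_region.csv"), row.names = FALSE)
    write.csv(changes, p("percent_changes.csv"), row.names = FALSE)
    per_subj <- changes; per_subj$subject <- subject_id
    write.csv(per_subj, p("per_subject_changes.csv"), row.names = FALSE)
    paths <- list(summary = p("summary_by_region.csv"),
                  changes = p("percent_changes.csv"),
                  per_subject = p("per_subject_changes.csv"))
    write_volume(reg$labels, p("labels_cdti.nii.gz"))
    if (isTRUE(write_maps)) {
      for (nm in names(all_maps)) {
        m <- all_maps[[nm]]
        m$data[!is.finite(m$data)] <- 0
        write_volume(m, p(sprintf("map_%s.nii.gz", nm)))
      }
    }
    manifest <- list(package_version =
                       as.character(utils::packageVersion("cardti")),
                     subject = subject_id,
                     seed = if (!is.null(cfgp$seed)) cfgp$seed else NA,
                     md_threshold = md_threshold,
                     rejected_fraction = rej$rejected_fraction,
                     maps = names(all_maps), tables = names(paths),
                     files = list.files(out_dir))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    writeLines(vapply(log, function(rec)
      jsonlite::toJSON(rec, auto_unbox = TRUE), character(1L)),
      p("pipeline_log.jsonl"))
  }
  list(labels = reg$labels, maps = all_maps, thresholds = thr,
       pooled = pooled, summary = summary_tab, changes = changes,
       tests = tests, rejected_fraction = rej$rejected_fraction,
       diagnostics = reg$diagnostics, log = log, paths = paths)
}
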