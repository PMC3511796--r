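# End-to-end orchestration: subject table in, cluster report out, with a
# QC log and a machine-readable provenance record, so every number in the
# report is reproducible from the record alone.

#' Pipeline run configuration
#'
#' Collects all stage parameters with their standard defaults: 10 discarded
#' volumes, 0.01-0.08 Hz band-pass, 1.5 mm / 1 degree motion limits,
#' 27-voxel ReHo neighborhood, 6 mm map smoothing, voxelwise two-tailed
#' p < 0.01, 5000 Monte-Carlo iterations at corrected alpha 0.01 with
#' face (6) connectivity.
#'
#' @param subject_table path to a tab-separated subject table (see
#'   [generate_cohort()]) or a data.frame.
#' @param out_dir output directory.
#' @param mask path to a mask NIfTI, a [brain_mask()], or NULL (full grid
#'   of the first image).
#' @param tr_s repetition-time override (seconds); default NULL reads it
#'   from each image header.
#' @param n_discard initial volumes to discard.
#' @param bandpass length-2, Hz.
#' @param qc_max_translation_mm,qc_max_rotation_deg motion limits.
#' @param motion_rotation_unit unit of the rotation columns in the motion
#'   files ("radians" for the SPM dialect, or "degrees").
#' @param neighborhood ReHo neighborhood (7/19/27).
#' @param tie_correction KCC tie correction flag.
#' @param smooth_fwhm_mm map smoothing FWHM, mm.
#' @param covariates nuisance covariate columns.
#' @param clinical clinical columns for the post-hoc correlations
#'   (group1 subjects only).
#' @param voxel_p voxelwise two-tailed p threshold.
#' @param mc_iterations Monte-Carlo iterations for the null.
#' @param mc_fwhm_mm `"estimate"` (default) to estimate the simulated-field
#'   smoothness from the second-level residuals, or a number (mm) to fix
#'   it (6 reproduces the nominal-smoothness convention).
#' @param corrected_alpha target corrected (family-wise) alpha.
#' @param connectivity cluster connectivity (6/18/26).
#' @param provenance `"summary"` (per-subject input/output checksums) or
#'   `"stages"` (additionally one checksum per preprocessing stage).
#' @param seed integer seed for the Monte-Carlo null.
#' @return An object of class `run_config`.
#' @export
run_config <- function(subject_table, out_dir, mask = NULL, tr_s = NULL,
                       n_discard = 10L, bandpass = c(0.01, 0.08),
                       qc_max_translation_mm = 1.5, qc_max_rotation_deg = 1,
                       motion_rotation_unit = "radians",
                       neighborhood = 27L, tie_correction = TRUE,
                       smooth_fwhm_mm = 6,
                       covariates = c("age", "sex", "education"),
                       clinical = c("cigarettes_per_day", "years_smoking",
                                    "craving"),
                       voxel_p = 0.01, mc_iterations = 5000L,
                       mc_fwhm_mm = "estimate", corrected_alpha = 0.01,
                       connectivity = 6L, provenance = "summary",
                       seed = 1L) {
  cfg <- list(subject_table = subject_table, out_dir = out_dir, mask = mask,
              tr_s = tr_s, n_discard = as.integer(n_discard),
              bandpass = as.numeric(bandpass),
              qc_max_translation_mm = qc_max_translation_mm,
              qc_max_rotation_deg = qc_max_rotation_deg,
              motion_rotation_unit = match.arg(motion_rotation_unit,
                                               c("radians", "degrees")),
              neighborhood = as.integer(neighborhood),
              tie_correction = isTRUE(tie_correction),
              smooth_fwhm_mm = as.numeric(smooth_fwhm_mm),
              covariates = covariates, clinical = clinical,
              voxel_p = as.numeric(voxel_p),
              mc_iterations = as.integer(mc_iterations),
              mc_fwhm_mm = mc_fwhm_mm,
              corrected_alpha = as.numeric(corrected_alpha),
              connectivity = as.integer(connectivity),
              provenance = match.arg(provenance, c("summary", "stages")),
              seed = as.integer(seed))
  if (length(cfg$bandpass) != 2L || cfg$bandpass[1] >= cfg$bandpass[2])
    stopf("`bandpass` must be c(low, high) with low < high")
  if (!(identical(cfg$mc_fwhm_mm, "estimate") ||
        (is.numeric(cfg$mc_fwhm_mm) && cfg$mc_fwhm_mm >= 0)))
    stopf("`mc_fwhm_mm` must be \"estimate\" or a non-negative number")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error
#' (a typo in a config must never silently fall back to a default).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(y$bandpass)) y$bandpass <- as.numeric(unlist(y$bandpass))
  do.call(run_config, y)
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips losslessly through [read_run_config()] for file-backed
#' configurations.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  y <- y[!vapply(y, is.null, logical(1))]
  if (!is.character(y$subject_table))
    stopf("only file-backed subject tables can be serialized to YAML")
  if (!is.null(y$mask) && !is.character(y$mask))
    stopf("only file-backed masks can be serialized to YAML")
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full ReHo group pipeline
#'
#' Per subject: discard initial volumes, motion QC gate, linear detrend,
#' ideal band-pass, ReHo map, within-mask standardization, Gaussian
#' smoothing.  Then: voxelwise group GLM with nuisance covariates,
#' Monte-Carlo cluster-extent threshold at the corrected alpha, cluster
#' report, and post-hoc partial correlations between cluster-mean
#' standardized ReHo and the clinical variables (group1 subjects,
#' controlling for the nuisance covariates).  All outputs plus a
#' provenance record are written to `config$out_dir`.
#'
#' Motion files may carry one row per acquired volume (truncated to the
#' retained volumes, which are what the QC rule screens) or one row per
#' retained volume; any other row count is an error.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @param null_dist optional precomputed [alphasim_null()] result for this
#'   mask/parameter set; when supplied, its parameters must match the
#'   config (mask, voxel_p, connectivity) and the Monte-Carlo stage is
#'   skipped.  Useful when one extent threshold is applied to many
#'   analyses of the same mask.
#' @return list with `report` (cluster data.frame), `posthoc`
#'   (partial-correlation data.frame), `stat` (the `stat_map`), `null`
#'   (the `mc_null`), `k_threshold`, `t_crit`, `mc_fwhm_used`, `qc`
#'   (per-subject QC table), `excluded`, `reho_paths`, `config`.
#' @export
run_pipeline <- function(config, null_dist = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  tab <- if (is.data.frame(config$subject_table)) config$subject_table else
    read_subject_table(config$subject_table)
  if (!all(c("subject_id", "group", "image_path", "motion_path") %in%
           names(tab)))
    stopf("subject table must have subject_id, group, image_path, motion_path")

  mask <- config$mask
  if (is.character(mask)) mask <- read_mask(mask)

  n <- nrow(tab)
  qc_rows <- vector("list", n)
  maps <- list()
  included <- logical(n)
  reho_paths <- character(n)
  stage_log <- list()
  for (i in seq_len(n)) {
    sid <- tab$subject_id[i]
    bold <- tryCatch(read_bold(tab$image_path[i], tr_s = config$tr_s),
                     error = function(e)
                       stopf("stage read_bold, subject %s: %s", sid,
                             conditionMessage(e)))
    if (is.null(mask))
      mask <- brain_mask(array(TRUE, dim(bold$data)[1:3]), bold$affine)
    nt_orig <- dim(bold$data)[4]

    bold <- stage(sid, "discard_initial_volumes",
                  discard_initial_volumes(bold, config$n_discard))
    nt_kept <- dim(bold$data)[4]

    motion <- stage(sid, "read_motion_params",
                    read_motion_params(tab$motion_path[i],
                                       config$motion_rotation_unit))
    nrm <- nrow(motion$translations)
    if (nrm == nt_orig) {             # truncate to the retained volumes
      keep <- (config$n_discard + 1L):nt_orig
      motion$translations <- motion$translations[keep, , drop = FALSE]
      motion$rotations <- motion$rotations[keep, , drop = FALSE]
    } else if (nrm != nt_kept) {
      stopf("stage qc_motion, subject %s: motion file has %d rows; expected %d (acquired) or %d (retained)",
            sid, nrm, nt_orig, nt_kept)
    }
    qc <- qc_motion(motion, config$qc_max_translation_mm,
                    config$qc_max_rotation_deg)
    qc_rows[[i]] <- data.frame(
      subject_id = sid, qc_pass = qc$pass,
      max_trans_x = qc$max_translation_mm[1],
      max_trans_y = qc$max_translation_mm[2],
      max_trans_z = qc$max_translation_mm[3],
      max_rot_x = qc$max_rotation_deg[1],
      max_rot_y = qc$max_rotation_deg[2],
      max_rot_z = qc$max_rotation_deg[3], stringsAsFactors = FALSE)
    if (!qc$pass) next

    bold <- stage(sid, "detrend_linear", detrend_linear(bold))
    bold <- stage(sid, "bandpass_ideal",
                  bandpass_ideal(bold, filter_spec(config$bandpass[1],
                                                   config$bandpass[2])))
    map <- stage(sid, "reho_map",
                 reho_map(bold, mask, config$neighborhood,
                          config$tie_correction))
    map <- stage(sid, "standardize_reho", standardize_reho(map))
    map <- stage(sid, "smooth_reho", smooth_reho(map, config$smooth_fwhm_mm))
    reho_paths[i] <- file.path(config$out_dir,
                               sprintf("%s_reho.nii.gz", sid))
    write_reho_map(map, reho_paths[i])
    if (config$provenance == "stages")
      stage_log[[length(stage_log) + 1L]] <- data.frame(
        subject_id = sid, stage = "final_reho",
        checksum = object_checksum(map$values), stringsAsFactors = FALSE)
    maps[[length(maps) + 1L]] <- map
    included[i] <- TRUE
  }
  qc_tab <- do.call(rbind, qc_rows)
  excluded <- data.frame(subject_id = tab$subject_id[!included],
                         reason = rep("motion QC", sum(!included)),
                         stringsAsFactors = FALSE)
  inc_tab <- tab[included, , drop = FALSE]
  if (sum(inc_tab$group == "group1") < 2L ||
      sum(inc_tab$group == "group2") < 2L)
    stopf("fewer than 2 subjects per group survive QC")

  design <- build_design_matrix(inc_tab, config$covariates)
  stat <- fit_group_glm(maps, design)
  signed <- threshold_two_tailed(stat, config$voxel_p)
  t_crit <- attr(signed, "t_crit")

  mc_fwhm <- if (identical(config$mc_fwhm_mm, "estimate"))
    estimate_fwhm(stat) else config$mc_fwhm_mm
  null <- null_dist
  if (is.null(null)) {
    null <- alphasim_null(stat$mask, voxel_p = config$voxel_p,
                          fwhm_mm = mc_fwhm,
                          n_iterations = config$mc_iterations,
                          connectivity = config$connectivity,
                          seed = derive_seeds(config$seed, 1L))
  } else {
    stopifnot(inherits(null, "mc_null"))
    if (null$voxel_p != config$voxel_p ||
        null$connectivity != config$connectivity)
      stopf("supplied null distribution used voxel_p=%g/connectivity=%d; config wants %g/%d",
            null$voxel_p, null$connectivity, config$voxel_p,
            config$connectivity)
  }
  k <- extent_threshold(null, config$corrected_alpha)
  report <- report_clusters(stat, t_crit, k, config$connectivity)

  posthoc <- posthoc_correlations(report, maps, inc_tab, config)

  write_outputs(config, mask, stat, null, k, t_crit, mc_fwhm, report,
                posthoc, qc_tab, excluded, tab, reho_paths, stage_log)

  list(report = report, posthoc = posthoc, stat = stat, null = null,
       k_threshold = k, t_crit = t_crit, mc_fwhm_used = mc_fwhm,
       qc = qc_tab, excluded = excluded,
       reho_paths = reho_paths[included], config = config)
}

# Wrap a stage so failures name the stage and subject.
stage <- function(subject_id, name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s, subject %s: %s", name, subject_id,
          conditionMessage(e)))
}

# Post-hoc partial correlations: cluster-mean standardized ReHo vs each
# clinical variable, in group1 subjects, controlling for the nuisance
# covariates.
posthoc_correlations <- function(report, maps, inc_tab, config) {
  empty <- data.frame(cluster = integer(0), variable = character(0),
                      r = numeric(0), p = numeric(0), df = integer(0),
                      n = integer(0), stringsAsFactors = FALSE)
  if (nrow(report) == 0 || length(config$clinical) == 0) return(empty)
  g1 <- which(inc_tab$group == "group1")
  if (length(g1) < length(config$covariates) + 3L) return(empty)
  cov_df <- inc_tab[g1, config$covariates, drop = FALSE]
  C <- do.call(cbind, lapply(cov_df, function(v)
    if (is.numeric(v)) v else as.numeric(factor(v)) - 1))
  C <- C[, apply(C, 2, stats::sd) > 0, drop = FALSE]
  clusters <- attr(report, "cluster_voxels")
  rows <- list()
  for (ci in seq_len(nrow(report))) {
    vox <- clusters[[ci]]
    cmeans <- vapply(maps[g1], function(m) mean(m$values[vox]), numeric(1))
    for (v in config$clinical) {
      cl <- inc_tab[[v]][g1]
      if (is.null(cl) || all(is.na(cl))) next
      pc <- tryCatch(partial_correlation(cl, cmeans, C),
                     error = function(e) NULL)
      if (is.null(pc)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = ci, variable = v, r = pc$r, p = pc$p, df = pc$df,
        n = pc$n, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

write_map_nifti <- function(values, affine, path) {
  im <- RNifti::asNifti(values)
  RNifti::qform(im) <- structure(affine, code = 2L)
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

write_outputs <- function(config, mask, stat, null, k, t_crit, mc_fwhm,
                          report, posthoc, qc_tab, excluded, tab,
                          reho_paths, stage_log) {
  od <- config$out_dir
  write_map_nifti(stat$t_values, stat$mask$affine,
                  file.path(od, "group_tmap.nii.gz"))
  jsonlite::write_json(
    list(df = stat$df, contrast = stat$contrast, t_crit = t_crit,
         voxel_p = config$voxel_p, k_threshold = k,
         mc_fwhm_mm = mc_fwhm),
    file.path(od, "group_tmap.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(iteration = seq_along(null$max_cluster_sizes),
               max_size = null$max_cluster_sizes),
    file.path(od, "mc_null.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(
    null[c("n_iterations", "voxel_p", "fwhm_mm", "connectivity",
           "mask_id", "seed")],
    file.path(od, "mc_null.json"), auto_unbox = TRUE, digits = NA)
  rep_out <- report
  utils::write.table(rep_out, file.path(od, "cluster_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(posthoc, file.path(od, "posthoc_correlations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(qc_tab, file.path(od, "qc_log.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  prov <- list(
    package = "rehopipe",
    package_version = as.character(utils::packageVersion("rehopipe")),
    r_version = R.version.string,
    timestamp = NULL,   # deliberately absent: outputs must be rerun-identical
    config = serializable_config(config),
    seed = config$seed,
    k_threshold = k, t_crit = t_crit, mc_fwhm_mm = mc_fwhm,
    df = stat$df,
    excluded_subjects = excluded,
    input_checksums = data.frame(
      subject_id = tab$subject_id,
      image_md5 = vapply(tab$image_path, file_checksum, character(1)),
      motion_md5 = vapply(tab$motion_path, file_checksum, character(1)),
      stringsAsFactors = FALSE),
    stage_log = if (length(stage_log)) do.call(rbind, stage_log) else NULL)
  jsonlite::write_json(prov, file.path(od, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(od)
}

serializable_config <- function(config) {
  y <- unclass(config)
  if (!is.character(y$subject_table)) y$subject_table <- "<in-memory table>"
  if (!is.null(y$mask) && !is.character(y$mask)) y$mask <- "<in-memory mask>"
  y
}
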