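# Seeded synthetic resting-state cohorts: NIfTI images, SPM-style motion
# files and a subject table with the statistical structure the analysis
# assumes (spatially smooth AR(1) background noise; spherical regions
# whose voxels share a band-limited signal, with group-specific coupling),
# so every downstream stage is testable without scanner data.

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the study design the pipeline targets: two groups of
#' 45 and 44 subjects, 180 volumes at TR = 3 s on a 3 mm isotropic grid,
#' background noise smoothed to 6 mm FWHM with AR(1) temporal
#' autocorrelation 0.3.  Effect regions are spheres whose voxels mix a
#' shared band-limited (0.01-0.08 Hz) signal into their series with a
#' group-specific coupling weight w in \[0, 1): higher w means higher local
#' synchrony, hence higher ReHo.
#'
#' @param n_group1,n_group2 subjects per group (group1 carries the
#'   clinical variables).
#' @param grid_shape length-3 voxel counts.  The full-scale default
#'   (61 x 73 x 61, the 3 mm MNI grid) is faithful but heavy; examples and
#'   tests use smaller grids.
#' @param voxel_size_mm length-3 voxel dimensions, mm.
#' @param n_volumes volumes per run.
#' @param tr_s repetition time, seconds.
#' @param noise_fwhm_mm spatial smoothness imposed on the background noise.
#' @param ar1_coef lag-1 temporal autocorrelation of the background, in
#'   \[0, 1).
#' @param effect_rois list of ROIs, each
#'   `list(center = c(i, j, k), radius = voxels, w1 = , w2 = )` with
#'   1-based center voxel and coupling weights per group in \[0, 1).
#' @param covariate_spec covariate distributions; see
#'   [default_covariate_spec()].
#' @param clinical_link optional
#'   `list(roi = index, variable = name, strength = s)`: subjects' coupling
#'   weight in that ROI is shifted by `0.2 * s` per standard deviation of
#'   the clinical variable, inducing a positive clinical-ReHo correlation.
#' @param origin_mm world coordinate of the grid center voxel; the affine
#'   is RAS-diagonal from `voxel_size_mm`.  Default centers the grid at 0.
#' @param motion_walk_sd length-2: per-step SD of the motion random walk
#'   (translations mm, rotations radians).
#' @param seed integer master seed; identical (config, seed) reproduce the
#'   cohort exactly.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_group1 = 45L, n_group2 = 44L,
                          grid_shape = c(61L, 73L, 61L),
                          voxel_size_mm = c(3, 3, 3),
                          n_volumes = 180L, tr_s = 3,
                          noise_fwhm_mm = 6, ar1_coef = 0.3,
                          effect_rois = list(),
                          covariate_spec = default_covariate_spec(),
                          clinical_link = NULL,
                          origin_mm = NULL,
                          motion_walk_sd = c(0.02, 5e-4),
                          seed = 1L) {
  cfg <- list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
              grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_volumes = as.integer(n_volumes), tr_s = as.numeric(tr_s),
              noise_fwhm_mm = as.numeric(noise_fwhm_mm),
              ar1_coef = as.numeric(ar1_coef),
              effect_rois = effect_rois, covariate_spec = covariate_spec,
              clinical_link = clinical_link,
              origin_mm = origin_mm %||% rep(0, 3),
              motion_walk_sd = as.numeric(motion_walk_sd),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_group1 < 1L || cfg$n_group2 < 1L)
    stopf("both groups need at least one subject (degenerate design): got %d and %d",
          cfg$n_group1, cfg$n_group2)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stopf("`grid_shape` must be 3 positive voxel counts")
  if (cfg$n_volumes < 2L) stopf("`n_volumes` must be at least 2")
  if (cfg$tr_s <= 0) stopf("`tr_s` must be positive")
  if (cfg$ar1_coef < 0 || cfg$ar1_coef >= 1)
    stopf("`ar1_coef` must lie in [0, 1)")
  if (cfg$noise_fwhm_mm < 0) stopf("`noise_fwhm_mm` must be non-negative")
  for (i in seq_along(cfg$effect_rois)) {
    roi <- cfg$effect_rois[[i]]
    if (!all(c("center", "radius", "w1", "w2") %in% names(roi)))
      stopf("ROI %d must have fields center, radius, w1, w2", i)
    if (any(c(roi$w1, roi$w2) < 0) || any(c(roi$w1, roi$w2) >= 1))
      stopf("ROI %d: coupling weights must lie in [0, 1)", i)
    lo <- roi$center - roi$radius
    hi <- roi$center + roi$radius
    if (any(lo < 1) || any(hi > cfg$grid_shape))
      stopf("ROI %d (center %s, radius %g) extends outside the %s grid",
            i, paste(roi$center, collapse = ","), roi$radius,
            paste(cfg$grid_shape, collapse = "x"))
  }
  if (!is.null(cfg$clinical_link)) {
    if (!all(c("roi", "variable", "strength") %in% names(cfg$clinical_link)))
      stopf("`clinical_link` must have fields roi, variable, strength")
    if (cfg$clinical_link$roi > length(cfg$effect_rois))
      stopf("`clinical_link` names ROI %d but only %d ROIs are defined",
            cfg$clinical_link$roi, length(cfg$effect_rois))
  }
  invisible(cfg)
}

#' Default covariate distributions for the synthetic cohort
#'
#' Normal (mean, sd, clamped to a plausible range) for continuous
#' covariates and a female proportion for sex, with group-specific values
#' for age, education and the clinical smoking variables (present for
#' group1 only): age 27.9 +/- 5.6 vs 26.3 +/- 5.8 years, education
#' 13.1 +/- 3.0 vs 15.0 +/- 2.6 years, 8/45 vs 10/44 female, 20.3 +/- 7.6
#' cigarettes/day, 10.2 +/- 5.8 years smoking, craving score 6.41 +/- 1.7.
#'
#' @return Nested list keyed by covariate then group.
#' @export
default_covariate_spec <- function() {
  list(
    age = list(group1 = list(mean = 27.9, sd = 5.6, range = c(19, 39)),
               group2 = list(mean = 26.3, sd = 5.8, range = c(19, 38))),
    sex = list(group1 = list(prop_female = 8 / 45),
               group2 = list(prop_female = 10 / 44)),
    education = list(group1 = list(mean = 13.1, sd = 3.0, range = c(6, 22)),
                     group2 = list(mean = 15.0, sd = 2.6, range = c(6, 22))),
    cigarettes_per_day = list(group1 = list(mean = 20.3, sd = 7.6,
                                            range = c(10, 40))),
    years_smoking = list(group1 = list(mean = 10.2, sd = 5.8,
                                       range = c(1.5, 21))),
    craving = list(group1 = list(mean = 6.41, sd = 1.7, range = c(3, 10)))
  )
}

# RAS-diagonal affine with the grid center voxel at origin_mm.
grid_affine <- function(grid_shape, voxel_size_mm, origin_mm) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size_mm
  aff[1:3, 4] <- origin_mm - voxel_size_mm * (grid_shape - 1) / 2
  aff
}

# 1-based linear indices of the sphere of `radius` voxels around `center`.
roi_voxel_indices <- function(center, radius, grid_shape) {
  rng <- lapply(1:3, function(ax)
    max(1L, floor(center[ax] - radius)):min(grid_shape[ax],
                                            ceiling(center[ax] + radius)))
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  (g$k - 1L) * grid_shape[1] * grid_shape[2] + (g$j - 1L) * grid_shape[1] + g$i
}

# White series restricted to [low, high] Hz by the ideal filter (no DC).
bandlimited_series <- function(nt, tr_s, low_hz = 0.01, high_hz = 0.08) {
  freq <- (seq_len(nt) - 1) / (nt * tr_s)
  freq <- pmin(freq, 1 / tr_s - freq)
  keep <- freq >= low_hz & freq <= high_hz
  keep[1] <- FALSE
  if (!any(keep))
    stopf("no DFT frequency falls in [%g, %g] Hz for %d volumes at TR %g s",
          low_hz, high_hz, nt, tr_s)
  sp <- stats::fft(stats::rnorm(nt))
  sp[!keep] <- 0
  s <- Re(stats::fft(sp, inverse = TRUE)) / nt
  s / stats::sd(s)
}

#' Generate one subject's synthetic BOLD run and motion trace
#'
#' Background: voxelwise AR(1) Gaussian noise (independent across voxels)
#' smoothed spatially to `noise_fwhm_mm` and rescaled to unit standard
#' deviation.  Inside each effect ROI every voxel's series becomes
#' `sqrt(1 - w^2) * background + w * shared`, where `shared` is a
#' band-limited (0.01-0.08 Hz) unit-variance signal common to the ROI and
#' `w` is the subject's group coupling weight (shifted by the clinical
#' link, if configured).  Motion is a small-amplitude 6-parameter random
#' walk in the SPM convention (translations mm, rotations radians).
#'
#' @param config a [cohort_config()].
#' @param subject a one-row data frame or list with at least `group`
#'   (`"group1"`/`"group2"`); clinical fields are used by the clinical
#'   link.
#' @param seed integer seed for this subject.
#' @return list with `bold` (a [bold4d()]) and `motion` (a
#'   [motion_params()], rotations internally in degrees).
#' @export
generate_subject_bold <- function(config, subject, seed) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  dm <- config$grid_shape
  nt <- config$n_volumes
  nvox <- prod(dm)
  with_seed(seed, {
    x <- array(stats::rnorm(nvox * nt), c(dm, nt))
    phi <- config$ar1_coef
    if (phi > 0) {                       # stationary unit-variance AR(1)
      sc <- sqrt(1 - phi^2)
      for (t in 2:nt) x[, , , t] <- phi * x[, , , t - 1] + sc * x[, , , t]
    }
    if (config$noise_fwhm_mm > 0)
      for (t in seq_len(nt))
        x[, , , t] <- gaussian_smooth_3d(x[, , , t], config$noise_fwhm_mm,
                                         config$voxel_size_mm)
    x <- x / stats::sd(x)
    if (length(config$effect_rois) > 0) {
      xm <- matrix(x, nvox, nt)
      grp <- if (identical(subject$group, "group1")) "w1" else "w2"
      for (i in seq_along(config$effect_rois)) {
        roi <- config$effect_rois[[i]]
        w <- roi[[grp]]
        w <- clinical_weight_shift(config, subject, i, w)
        if (w > 0) {
          s <- bandlimited_series(nt, config$tr_s)
          vox <- roi_voxel_indices(roi$center, roi$radius, dm)
          xm[vox, ] <- sqrt(1 - w^2) * xm[vox, ] +
            w * matrix(s, length(vox), nt, byrow = TRUE)
        }
      }
      x <- array(xm, c(dm, nt))
    }
    trans <- apply(matrix(stats::rnorm(nt * 3, 0, config$motion_walk_sd[1]),
                          nt, 3), 2, cumsum)
    rots <- apply(matrix(stats::rnorm(nt * 3, 0, config$motion_walk_sd[2]),
                         nt, 3), 2, cumsum)
    aff <- grid_affine(dm, config$voxel_size_mm, config$origin_mm)
    list(bold = bold4d(x, aff, config$tr_s),
         motion = motion_params(trans, rots, "radians"))
  })
}

# Shift a subject's coupling weight by the configured clinical link
# (group1 only): w + 0.2 * strength * z(clinical), clamped to [0, 0.99].
clinical_weight_shift <- function(config, subject, roi_index, w) {
  link <- config$clinical_link
  if (is.null(link) || link$roi != roi_index ||
      !identical(subject$group, "group1"))
    return(w)
  val <- subject[[link$variable]]
  if (is.null(val) || is.na(val)) return(w)
  spec <- config$covariate_spec[[link$variable]]$group1
  z <- (val - spec$mean) / spec$sd
  min(max(w + 0.2 * link$strength * z, 0), 0.99)
}

#' Generate a full synthetic cohort on disk
#'
#' Draws per-subject covariates from the configured distributions, writes
#' one NIfTI image and one motion file per subject plus a tab-separated
#' subject table, and returns the table.  Clinical smoking variables are
#' present for group1 subjects only.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @return data.frame with columns subject_id, group, age, sex, education,
#'   cigarettes_per_day, years_smoking, craving, image_path, motion_path;
#'   also written as `participants.tsv` in `out_dir`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stopf("output directory %s is not writable", out_dir)
  n <- config$n_group1 + config$n_group2
  seeds <- derive_seeds(config$seed, n + 1L)
  tab <- with_seed(seeds[n + 1L], draw_covariates(config))
  tab$image_path <- file.path(out_dir,
                              sprintf("%s_bold.nii.gz", tab$subject_id))
  tab$motion_path <- file.path(out_dir,
                               sprintf("%s_motion.txt", tab$subject_id))
  for (i in seq_len(n)) {
    sub <- generate_subject_bold(config, as.list(tab[i, ]), seeds[i])
    write_bold(sub$bold, tab$image_path[i])
    # motion written in the SPM dialect: radians
    utils::write.table(cbind(sub$motion$translations,
                      sub$motion$rotations * pi / 180),
                tab$motion_path[i], row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(tab, file.path(out_dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

draw_covariates <- function(config) {
  spec <- config$covariate_spec
  n1 <- config$n_group1
  n2 <- config$n_group2
  draw_num <- function(s, n) {
    v <- stats::rnorm(n, s$mean, s$sd)
    if (!is.null(s$range)) v <- pmin(pmax(v, s$range[1]), s$range[2])
    round(v, 1)
  }
  draw_sex <- function(s, n)
    ifelse(stats::runif(n) < s$prop_female, "F", "M")
  tab <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n1 + n2)),
    group = rep(c("group1", "group2"), c(n1, n2)),
    age = c(draw_num(spec$age$group1, n1), draw_num(spec$age$group2, n2)),
    sex = c(draw_sex(spec$sex$group1, n1), draw_sex(spec$sex$group2, n2)),
    education = c(draw_num(spec$education$group1, n1),
                  draw_num(spec$education$group2, n2)),
    cigarettes_per_day = c(draw_num(spec$cigarettes_per_day$group1, n1),
                           rep(NA_real_, n2)),
    years_smoking = c(draw_num(spec$years_smoking$group1, n1),
                      rep(NA_real_, n2)),
    craving = c(draw_num(spec$craving$group1, n1), rep(NA_real_, n2)),
    stringsAsFactors = FALSE
  )
  tab
}

#' Read a subject table written by [generate_cohort()]
#'
#' @param path tab-separated file with the `participants.tsv` columns.
#' @return data.frame.
#' @export
read_subject_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
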