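# Gaussian-field smoothness estimation from second-level residuals, in
# the first-differences tradition of AFNI's 3dFWHMx / SPM's smoothness
# module: for a smooth field, the variance of neighboring-voxel
# differences relative to the field variance determines the equivalent
# Gaussian FWHM per axis.

#' Estimate the spatial smoothness (FWHM) of residual maps
#'
#' For each residual map and axis, computes the classic first-difference
#' estimate FWHM = d * sqrt(-2 log(2) / log(1 - s_d^2 / (2 s^2))), where d
#' is the voxel size, s_d^2 the variance of differences between in-mask
#' neighbor pairs along the axis and s^2 the field variance; axis
#' estimates are combined by geometric mean and averaged over maps.
#'
#' @param stat a `stat_map` from [fit_group_glm()] (its per-subject
#'   residuals and analysis mask are used), or a numeric matrix of
#'   residuals (subjects x in-mask voxels) if `mask` is given.
#' @param mask optional [brain_mask()] when `stat` is a matrix.
#' @return estimated isotropic FWHM in mm.
#' @export
estimate_fwhm <- function(stat, mask = NULL) {
  if (inherits(stat, "stat_map")) {
    resid <- stat$residuals
    mask <- stat$mask
  } else {
    resid <- as.matrix(stat)
    if (is.null(mask)) stopf("`mask` is required when passing raw residuals")
  }
  dm <- dim(mask$data)
  vs <- voxel_sizes(mask$affine)
  inm <- which(mask$data)
  per_map <- apply(resid, 1, function(rv) {
    vol <- array(NA_real_, dm)
    vol[inm] <- rv
    s2 <- stats::var(rv)
    fw <- numeric(3)
    for (ax in 1:3) {
      a <- switch(ax,
                  vol[-1, , , drop = FALSE] - vol[-dm[1], , , drop = FALSE],
                  vol[, -1, , drop = FALSE] - vol[, -dm[2], , drop = FALSE],
                  vol[, , -1, drop = FALSE] - vol[, , -dm[3], drop = FALSE])
      d <- a[!is.na(a)]
      if (length(d) < 2L || s2 <= 0) return(NA_real_)
      ratio <- stats::var(d) / (2 * s2)
      fw[ax] <- if (ratio >= 1) vs[ax] else   # rougher than white noise
        vs[ax] * sqrt(-2 * log(2) / log(1 - ratio))
    }
    exp(mean(log(fw)))
  })
  mean(per_map, na.rm = TRUE)
}
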