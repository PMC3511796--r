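# Second-level inference: voxelwise two-sample GLM on standardized,
# smoothed ReHo maps with nuisance covariates, two-tailed voxel
# thresholding, and post-hoc partial correlations with clinical variables.

#' Build the second-level design matrix
#'
#' Columns: intercept, group indicator (group1 = 1, group2 = 0), then one
#' column per covariate.  Continuous covariates are mean-centered (the
#' group coefficient and its t are unchanged by centering; conditioning
#' improves); `sex` becomes an indicator (M = 1).
#'
#' @param subjects data.frame with a `group` column (`"group1"`/`"group2"`)
#'   and the covariate columns.
#' @param covariates character vector of covariate column names (default
#'   age, sex, education; use `character(0)` for a plain two-sample test).
#' @return numeric matrix, one row per subject, with column names; errors
#'   if the design is rank-deficient, naming the collinear columns.
#' @export
build_design_matrix <- function(subjects,
                                covariates = c("age", "sex", "education")) {
  if (!all(subjects$group %in% c("group1", "group2")))
    stopf("`group` must be 'group1' or 'group2'")
  X <- cbind(intercept = 1, group = as.numeric(subjects$group == "group1"))
  for (cv in covariates) {
    v <- subjects[[cv]]
    if (is.null(v)) stopf("covariate column '%s' not found", cv)
    col <- if (is.numeric(v)) v - mean(v) else as.numeric(factor(v)) - 1
    if (stats::sd(col) == 0) {       # no variance, no information
      warning(sprintf("covariate '%s' is constant; dropped from the design", cv))
      next
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  X
}

#' Voxelwise group GLM on a stack of ReHo maps
#'
#' Ordinary least squares of each voxel's map values on the design; the
#' returned t statistic is coefficient(group) / SE, with df = N - p.
#' Voxels flagged in any subject's map (K < 2 edge policy) are excluded
#' from the analysis mask.
#'
#' @param maps list of standardized [reho_map()] objects on a common grid.
#' @param design matrix from [build_design_matrix()], rows in map order;
#'   must contain a `group` column.
#' @return An object of class `stat_map`: `t_values` (3D array, 0 outside
#'   the analysis mask), `df`, `contrast`, `mask` (a [brain_mask()] of the
#'   analyzed voxels).
#' @export
fit_group_glm <- function(maps, design) {
  stopifnot(length(maps) >= 2L, is.matrix(design),
            nrow(design) == length(maps))
  if (!"group" %in% colnames(design))
    stopf("design has no 'group' column")
  if (sum(design[, "group"] == 1) < 2L || sum(design[, "group"] == 0) < 2L)
    stopf("need at least 2 subjects per group")
  dm <- dim(maps[[1]]$values)
  for (m in maps) {
    stopifnot(inherits(m, "reho_map"))
    if (!all(dim(m$values) == dm)) stopf("maps are on different grids")
    if (!m$standardized)
      stopf("maps must be standardized before group inference")
  }
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  amask <- maps[[1]]$mask$data
  for (m in maps) amask <- amask & !m$flagged
  vox <- which(amask)
  Y <- vapply(maps, function(m) m$values[vox], numeric(length(vox)))  # V x N
  N <- ncol(Y)
  p <- ncol(design)
  df <- N - p
  if (df < 1L) stopf("no residual degrees of freedom (N = %d, p = %d)", N, p)
  XtXinv <- chol2inv(chol(crossprod(design)))
  B <- XtXinv %*% crossprod(design, t(Y))              # p x V
  resid <- t(Y) - design %*% B                         # N x V
  sigma2 <- colSums(resid^2) / df
  g <- which(colnames(design) == "group")
  se <- sqrt(sigma2 * XtXinv[g, g])
  tval <- ifelse(se > 0, B[g, ] / se, 0)
  t3 <- array(0, dm)
  t3[vox] <- tval
  structure(list(t_values = t3, df = as.integer(df),
                 contrast = "group1 - group2",
                 mask = brain_mask(amask, maps[[1]]$mask$affine),
                 residuals = resid),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s grid, contrast %s, df = %d\n",
              paste(dim(x$t_values), collapse = " x "), x$contrast, x$df))
  invisible(x)
}

#' Two-tailed voxelwise threshold of a t map
#'
#' @param stat a `stat_map` from [fit_group_glm()].
#' @param voxel_p two-tailed per-voxel p threshold (default 0.01).
#' @return integer 3D array: +1 where t > t_crit, -1 where t < -t_crit,
#'   0 elsewhere, with `t_crit` (the upper voxel_p/2 quantile of t(df))
#'   attached as attribute `"t_crit"`.
#' @export
threshold_two_tailed <- function(stat, voxel_p = 0.01) {
  stopifnot(inherits(stat, "stat_map"), voxel_p > 0, voxel_p < 1)
  t_crit <- stats::qt(1 - voxel_p / 2, df = stat$df)
  out <- array(0L, dim(stat$t_values))
  out[stat$mask$data & stat$t_values > t_crit] <- 1L
  out[stat$mask$data & stat$t_values < -t_crit] <- -1L
  attr(out, "t_crit") <- t_crit
  out
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on
#' \[intercept + covariates\]; with k covariates the two-tailed p comes
#' from t = r sqrt((N - 2 - k) / (1 - r^2)) on N - 2 - k degrees of
#' freedom.  With no covariates this reduces to the plain Pearson
#' correlation test.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix / data.frame (one row per subject) or
#'   NULL.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0) else {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    C
  }
  k <- ncol(C)
  if (n <= k + 2) stopf("need more than %d observations for %d covariates",
                        k + 2, k)
  ok <- stats::complete.cases(x, y, C)
  if (!all(ok)) {
    x <- x[ok]; y <- y[ok]; C <- C[ok, , drop = FALSE]
    n <- length(x)
    if (n <= k + 2) stopf("too few complete observations (%d) for %d covariates",
                          n, k)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("x or y is constant; correlation undefined")
  X <- cbind(1, C)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  df <- n - 2L - k
  # a variable perfectly explained by the covariates has (numerically)
  # zero residual: its partial correlation with anything is 0
  tolx <- 1e-10 * stats::sd(x)
  toly <- 1e-10 * stats::sd(y)
  if (stats::sd(rx) <= tolx || stats::sd(ry) <= toly)
    return(list(r = 0, p = 1, df = as.integer(df), n = as.integer(n)))
  r <- stats::cor(rx, ry)
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), df = as.integer(df),
       n = as.integer(n))
}
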