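# Regional homogeneity: Kendall's coefficient of concordance (KCC) between
# a voxel's time series and its nearest neighbors, computed voxelwise,
# followed by within-mask standardization and Gaussian smoothing.

#' Kendall's coefficient of concordance (KCC)
#'
#' Concordance of K time series over n time points.  Each series is
#' converted to mid-ranks over time; with R_t the rank sum at time point t
#' and S = sum_t (R_t - mean(R))^2,
#'
#'   W = 12 S / (K^2 (n^3 - n) - K sum_j T_j),
#'
#' where T_j = sum over tie groups g of series j of (t_g^3 - t_g) is the
#' standard tie correction (dropped when `tie_correction = FALSE`).
#' W = 1 for identical rank orderings; the null expectation under
#' independence is 1/K.
#'
#' @param series_matrix K x n numeric matrix, one time series per row.
#' @param tie_correction apply the mid-rank tie correction (default TRUE).
#' @return W in \[0, 1\].  An all-constant set of series has an undefined
#'   rank ordering; W is defined as 0 there, with a warning.
#' @export
kcc <- function(series_matrix, tie_correction = TRUE) {
  x <- as.matrix(series_matrix)
  K <- nrow(x)
  n <- ncol(x)
  if (K < 2L) stopf("KCC needs at least 2 series, got %d", K)
  if (n < 2L) stopf("KCC needs at least 2 time points, got %d", n)
  rk <- t(apply(x, 1, rank))                  # mid-ranks over time
  Rt <- colSums(rk)
  S <- sum((Rt - mean(Rt))^2)
  tie_sum <- if (tie_correction) sum(apply(x, 1, tie_term)) else 0
  den <- K^2 * (n^3 - n) - K * tie_sum
  if (den <= 0) {
    warning("all series constant over time; KCC undefined, returning 0")
    return(0)
  }
  min(max(12 * S / den, 0), 1)
}

# Tie correction term for one series: sum over tie groups of (t^3 - t).
tie_term <- function(v) {
  tab <- tabulate(match(v, unique(v)))
  sum(tab^3 - tab)
}

# Row-wise mid-ranks and tie terms for a V x T matrix in one order() pass;
# rows containing ties fall back to rank().  Returns list(ranks, tie_term).
rank_rows <- function(M) {
  V <- nrow(M)
  nt <- ncol(M)
  o <- order(row(M), M)                      # group by row, sort by value
  rk <- numeric(V * nt)
  rk[o] <- rep.int(seq_len(nt), V)           # within-row sort positions
  s <- M[o]
  samerow <- rep(c(FALSE, rep(TRUE, nt - 1L)), V)
  dup <- samerow & c(FALSE, s[-1] == s[-length(s)])
  tiet <- numeric(V)
  if (any(dup)) {                            # mid-rank fallback where tied
    tie_rows <- unique(((which(dup) - 1L) %/% nt) + 1L)
    for (v in tie_rows) {
      rk[v + (seq_len(nt) - 1L) * V] <- rank(M[v, ])
      tiet[v] <- tie_term(M[v, ])
    }
  }
  list(ranks = matrix(rk, V, nt), tie_term = tiet)
}

# Relative voxel offsets for the 7 / 19 / 27 neighborhood (center included):
# faces only, faces + edges, faces + edges + corners.
neighborhood_offsets <- function(neighborhood) {
  neighborhood <- as.integer(neighborhood)
  if (!neighborhood %in% c(7L, 19L, 27L))
    stopf("`neighborhood` must be one of 7, 19, 27")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  g[ord <= switch(as.character(neighborhood), "7" = 1, "19" = 2, "27" = 3), ,
    drop = FALSE]
}

#' Voxelwise ReHo (Kendall's W) map
#'
#' For each in-mask voxel, computes [kcc()] over the voxel's own time
#' series and those of its in-mask neighbors under the chosen neighborhood
#' (6, 18 or 26 neighbors plus the center).  At mask edges the available
#' in-mask neighbors are used with correspondingly reduced K; voxels left
#' with K < 2 are set to 0 and flagged.
#'
#' @param bold a preprocessed [bold4d()].
#' @param mask a [brain_mask()] on the same grid.
#' @param neighborhood 7, 19 or 27 (default 27: center + 26 neighbors).
#' @param tie_correction apply the mid-rank tie correction (default TRUE).
#' @return An object of class `reho_map`: fields `values` (3D array, 0
#'   outside mask), `mask`, `flagged` (logical 3D array, in-mask voxels
#'   with K < 2), `n_timepoints`, `neighborhood`, `standardized`,
#'   `smoothed_fwhm_mm`.
#' @export
reho_map <- function(bold, mask, neighborhood = 27L, tie_correction = TRUE) {
  stopifnot(inherits(bold, "bold4d"), inherits(mask, "brain_mask"))
  if (!same_grid(dim(bold$data), dim(mask$data)))
    stopf("bold (%s) and mask (%s) are on different grids",
          paste(dim(bold$data)[1:3], collapse = "x"),
          paste(dim(mask$data), collapse = "x"))
  dm <- dim(bold$data)
  nt <- dm[4]
  nvox <- prod(dm[1:3])
  m <- mask$data
  idx <- which(m)

  # mid-ranks over time for every in-mask series; zero elsewhere so
  # out-of-mask neighbors drop out of all the sums below
  M <- matrix(bold$data, nrow = nvox)
  rr <- rank_rows(M[idx, , drop = FALSE])
  rk <- matrix(0, nvox, nt)
  rk[idx, ] <- rr$ranks
  tiemap <- numeric(nvox)
  if (tie_correction) tiemap[idx] <- rr$tie_term

  # accumulate rank sums / K / tie terms over the neighborhood by shifting
  # linear voxel indices; T x V layout keeps the memory access contiguous
  rk_t <- t(rk)
  mnum <- as.numeric(m)
  iv <- rep.int(seq_len(dm[1]), dm[2] * dm[3])
  jv <- rep.int(rep.int(seq_len(dm[2]), rep.int(dm[1], dm[2])), dm[3])
  kv <- rep.int(seq_len(dm[3]), rep.int(dm[1] * dm[2], dm[3]))

  offs <- neighborhood_offsets(neighborhood)
  rsum <- matrix(0, nt, nvox)        # rank sums over the K series
  kmap <- numeric(nvox)              # K per voxel
  tsum <- numeric(nvox)              # summed tie terms over the K series
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    off_lin <- d[1] + d[2] * dm[1] + d[3] * dm[1] * dm[2]
    val <- which(iv + d[1] >= 1L & iv + d[1] <= dm[1] &
                 jv + d[2] >= 1L & jv + d[2] <= dm[2] &
                 kv + d[3] >= 1L & kv + d[3] <= dm[3])
    src <- val + off_lin
    rsum[, val] <- rsum[, val] + rk_t[, src]
    kmap[val] <- kmap[val] + mnum[src]
    tsum[val] <- tsum[val] + tiemap[src]
  }

  # S = sum_t (R_t - K (n+1)/2)^2, vectorized over voxels
  ctr <- kmap * (nt + 1) / 2
  S <- array(colSums((rsum - rep(ctr, each = nt))^2), dm[1:3])
  kmap <- array(kmap, dm[1:3])
  tsum <- array(tsum, dm[1:3])
  den <- kmap^2 * (nt^3 - nt) - kmap * tsum
  W <- array(0, dm[1:3])
  ok <- m & kmap >= 2 & den > 0
  W[ok] <- pmin(pmax(12 * S[ok] / den[ok], 0), 1)
  flagged <- m & (kmap < 2 | den <= 0)

  structure(list(values = W, mask = mask, flagged = flagged,
                 n_timepoints = nt, neighborhood = as.integer(neighborhood),
                 standardized = FALSE, smoothed_fwhm_mm = NULL),
            class = "reho_map")
}

#' @export
print.reho_map <- function(x, ...) {
  cat(sprintf(
    "<reho_map> %s grid, %d-voxel neighborhood, n = %d time points\n",
    paste(dim(x$values), collapse = " x "), x$neighborhood, x$n_timepoints))
  cat(sprintf("  standardized: %s; smoothed: %s; flagged voxels: %d\n",
              x$standardized,
              if (is.null(x$smoothed_fwhm_mm)) "no" else
                paste0(x$smoothed_fwhm_mm, " mm FWHM"),
              sum(x$flagged)))
  invisible(x)
}

#' Standardize a ReHo map by its within-mask mean
#'
#' Divides every in-mask value by the mean ReHo over the mask (flagged
#' K < 2 voxels excluded from the mean), so the standardized map has mask
#' mean 1 and maps are comparable across subjects.
#'
#' @param map a [reho_map()].
#' @return The standardized `reho_map`.
#' @export
standardize_reho <- function(map) {
  stopifnot(inherits(map, "reho_map"))
  sel <- map$mask$data & !map$flagged
  mu <- mean(map$values[sel])
  if (!is.finite(mu) || mu <= 0)
    stopf("within-mask mean ReHo is %g; cannot standardize a degenerate map", mu)
  map$values[map$mask$data] <- map$values[map$mask$data] / mu
  map$standardized <- TRUE
  map
}

#' Smooth a ReHo map with an isotropic Gaussian kernel
#'
#' Masked smoothing: the kernel is renormalized over in-mask, unflagged
#' voxels so no zeros leak in from outside, and the result is re-zeroed
#' outside the mask.  Voxel sizes are taken from the mask affine.
#'
#' @param map a [reho_map()].
#' @param fwhm_mm kernel FWHM in mm (default 6; 0 = identity).
#' @return The smoothed `reho_map` with `smoothed_fwhm_mm` set.
#' @export
smooth_reho <- function(map, fwhm_mm = 6) {
  stopifnot(inherits(map, "reho_map"), fwhm_mm >= 0)
  vs <- voxel_sizes(map$mask$affine)
  sel <- map$mask$data & !map$flagged
  map$values <- gaussian_smooth_3d(map$values, fwhm_mm, vs, mask = sel)
  map$smoothed_fwhm_mm <- fwhm_mm
  map
}

#' Write a ReHo map as NIfTI plus a JSON metadata sidecar
#'
#' The sidecar (same path with `.json` extension) records neighborhood,
#' n_timepoints, standardization state, smoothing FWHM and the flagged
#' voxel count, so a map's provenance travels with it.
#'
#' @param map a [reho_map()].
#' @param path output NIfTI path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_reho_map <- function(map, path) {
  stopifnot(inherits(map, "reho_map"))
  im <- RNifti::asNifti(map$values)
  RNifti::qform(im) <- structure(map$mask$affine, code = 2L)
  RNifti::sform(im) <- structure(map$mask$affine, code = 2L)
  RNifti::writeNifti(im, path)
  meta <- list(neighborhood = map$neighborhood,
               n_timepoints = map$n_timepoints,
               standardized = map$standardized,
               smoothed_fwhm_mm = map$smoothed_fwhm_mm,
               n_flagged = sum(map$flagged),
               flagged_voxels = which(map$flagged))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a ReHo map written by [write_reho_map()]
#'
#' @param path NIfTI path; the JSON sidecar must sit next to it.
#' @param mask optional [brain_mask()]; defaults to values != 0 or the
#'   full grid if a mask cannot be inferred.
#' @return A [reho_map()].
#' @export
read_reho_map <- function(path, mask = NULL) {
  im <- RNifti::readNifti(path)
  vals <- bare_array(im)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  aff <- bare_affine(im)
  fl <- as.integer(unlist(meta$flagged_voxels))
  if (is.null(mask)) {
    md <- array(vals != 0, dim(vals))
    md[fl] <- TRUE
    if (!any(md)) md[] <- TRUE
    mask <- brain_mask(md, aff)
  }
  flagged <- array(FALSE, dim(vals))
  flagged[fl] <- TRUE
  structure(list(values = vals, mask = mask, flagged = flagged,
                 n_timepoints = meta$n_timepoints,
                 neighborhood = meta$neighborhood,
                 standardized = isTRUE(meta$standardized),
                 smoothed_fwhm_mm = meta$smoothed_fwhm_mm),
            class = "reho_map")
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
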