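# Monte-Carlo cluster-extent correction in the AlphaSim tradition:
# simulate smoothed Gaussian null fields inside the analysis mask,
# threshold voxelwise (two-tailed), record the maximum cluster size per
# iteration, and derive the minimum extent controlling the family-wise
# error at a target corrected alpha.  Cluster labeling, null simulation
# and observed-map reporting all share the same connectivity rule.

# Neighbor offsets for 6 (face), 18 (face+edge) or 26 (face+edge+corner)
# connectivity; center excluded.
connectivity_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("`connectivity` must be one of 6, 18, 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  g[ord >= 1 & ord <= switch(as.character(connectivity),
                             "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
}

#' Label connected clusters of a signed binary map
#'
#' Connected components are computed separately within the +1 and -1
#' voxel sets under the chosen 3D connectivity; every active voxel belongs
#' to exactly one cluster.
#'
#' @param signed_map integer 3D array with values -1, 0, +1.
#' @param connectivity 6 (face), 18 (face + edge) or 26 (face + edge +
#'   corner); default 6.
#' @return list of clusters, each `list(sign, size, voxels)` with 1-based
#'   linear voxel indices, ordered by decreasing size.
#' @export
label_clusters <- function(signed_map, connectivity = 6L) {
  dm <- dim(signed_map)
  stopifnot(length(dm) == 3L)
  offs <- connectivity_offsets(connectivity)
  out <- list()
  for (sgn in c(1L, -1L)) {
    act <- which(signed_map == sgn)
    if (length(act) == 0L) next
    labs <- label_components(act, dm, offs)
    for (l in unique(labs)) {
      vox <- act[labs == l]
      out[[length(out) + 1L]] <- list(sign = sgn, size = length(vox),
                                      voxels = sort(vox))
    }
  }
  out[order(vapply(out, `[[`, integer(1), "size"), decreasing = TRUE)]
}

# Connected components over a set of active linear indices via iterative
# frontier expansion (vectorized BFS).  Returns a component id per active
# voxel.
label_components <- function(active, dm, offs) {
  nact <- length(active)
  pos <- array(0L, dm)            # active-voxel rank lookup, 0 = inactive
  pos[active] <- seq_len(nact)
  ii <- ((active - 1L) %% dm[1]) + 1L
  jj <- (((active - 1L) %/% dm[1]) %% dm[2]) + 1L
  kk <- ((active - 1L) %/% (dm[1] * dm[2])) + 1L
  off_lin <- offs[, 1] + offs[, 2] * dm[1] + offs[, 3] * dm[1] * dm[2]
  labs <- integer(nact)
  cur <- 0L
  for (s in seq_len(nact)) {
    if (labs[s] != 0L) next
    cur <- cur + 1L
    labs[s] <- cur
    frontier <- s
    while (length(frontier) > 0L) {
      nbr <- integer(0)
      for (o in seq_len(nrow(offs))) {
        fi <- ii[frontier] + offs[o, 1]
        fj <- jj[frontier] + offs[o, 2]
        fk <- kk[frontier] + offs[o, 3]
        okf <- fi >= 1L & fi <= dm[1] & fj >= 1L & fj <= dm[2] &
          fk >= 1L & fk <= dm[3]
        if (!any(okf)) next
        cand <- pos[active[frontier[okf]] + off_lin[o]]
        nbr <- c(nbr, cand[cand != 0L])
      }
      nbr <- unique(nbr[labs[nbr] == 0L])
      labs[nbr] <- cur
      frontier <- nbr
    }
  }
  labs
}

#' Monte-Carlo null distribution of maximum cluster sizes
#'
#' Per iteration: the mask's bounding grid is filled with i.i.d. standard
#' Gaussian noise, smoothed to `fwhm_mm`, restricted to the mask and
#' re-standardized to zero mean / unit variance within it, thresholded
#' two-tailed at `voxel_p`, and the maximum cluster size over both signs
#' recorded.
#'
#' @param mask a [brain_mask()].
#' @param voxel_p two-tailed per-voxel p (default 0.01).
#' @param fwhm_mm smoothness of the simulated fields, mm (default 6).
#' @param n_iterations Monte-Carlo iterations (default 5000).
#' @param connectivity cluster connectivity, 6/18/26 (default 6).
#' @param seed integer seed.
#' @return An object of class `mc_null`: `max_cluster_sizes` (integer per
#'   iteration) plus all simulation parameters and a mask checksum.
#' @export
alphasim_null <- function(mask, voxel_p = 0.01, fwhm_mm = 6,
                          n_iterations = 5000L, connectivity = 6L,
                          seed = 1L) {
  stopifnot(inherits(mask, "brain_mask"), voxel_p > 0, voxel_p < 1,
            fwhm_mm >= 0, n_iterations >= 1L)
  dm <- dim(mask$data)
  vs <- voxel_sizes(mask$affine)
  m <- mask$data
  inm <- which(m)
  zc <- stats::qnorm(1 - voxel_p / 2)
  maxes <- integer(n_iterations)
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      x <- array(stats::rnorm(prod(dm)), dm)
      if (fwhm_mm > 0) x <- gaussian_smooth_3d(x, fwhm_mm, vs)
      v <- x[inm]
      v <- (v - mean(v)) / stats::sd(v)
      sgn <- array(0L, dm)
      sgn[inm[v > zc]] <- 1L
      sgn[inm[v < -zc]] <- -1L
      cl <- label_clusters(sgn, connectivity)
      maxes[it] <- if (length(cl)) cl[[1]]$size else 0L
    }
  })
  structure(list(max_cluster_sizes = maxes,
                 n_iterations = as.integer(n_iterations),
                 voxel_p = voxel_p, fwhm_mm = fwhm_mm,
                 connectivity = as.integer(connectivity),
                 mask_id = object_checksum(mask$data),
                 seed = as.integer(seed)),
            class = "mc_null")
}

#' @export
print.mc_null <- function(x, ...) {
  cat(sprintf(
    "<mc_null> %d iterations, voxel p = %g (two-tailed), FWHM = %g mm, %d-connectivity\n",
    x$n_iterations, x$voxel_p, x$fwhm_mm, x$connectivity))
  cat(sprintf("  max cluster sizes: median %g, 95%% %g, 99%% %g\n",
              stats::median(x$max_cluster_sizes),
              stats::quantile(x$max_cluster_sizes, 0.95),
              stats::quantile(x$max_cluster_sizes, 0.99)))
  invisible(x)
}

#' Cluster-extent threshold for a target corrected alpha
#'
#' The smallest integer k such that the fraction of null iterations whose
#' maximum cluster size reaches k is at most `corrected_alpha`; clusters
#' of size >= k are declared significant.
#'
#' @param null an `mc_null` from [alphasim_null()].
#' @param corrected_alpha target two-tailed family-wise alpha (default
#'   0.01).
#' @return integer k (voxels).
#' @export
extent_threshold <- function(null, corrected_alpha = 0.01) {
  stopifnot(inherits(null, "mc_null"), corrected_alpha > 0)
  if (corrected_alpha >= 1) return(1L)
  sizes <- null$max_cluster_sizes
  for (k in seq_len(max(sizes) + 1L)) {
    if (mean(sizes >= k) <= corrected_alpha) return(as.integer(k))
  }
  as.integer(max(sizes) + 1L)   # unreachable; loop always returns
}

#' Threshold a t map and report surviving clusters
#'
#' Applies the voxelwise threshold `t_crit` two-tailed, labels clusters
#' under `connectivity`, keeps those of size >= `k`, and reports each
#' cluster's peak |t| voxel with its world (mm) coordinate from the mask
#' affine.  Peak ties break deterministically to the smallest linear voxel
#' index.
#'
#' @param stat a `stat_map` from [fit_group_glm()].
#' @param t_crit voxelwise critical t (e.g. from [threshold_two_tailed()]).
#' @param k minimum cluster extent in voxels (from [extent_threshold()]).
#' @param connectivity 6/18/26 (default 6); must match the null.
#' @return data.frame with one row per significant cluster: sign, size,
#'   peak_t, i, j, k (1-based voxel indices), x_mm, y_mm, z_mm, label
#'   (free-text, NA), ordered by decreasing size; attributes `k_threshold`
#'   and `t_crit`.
#' @export
report_clusters <- function(stat, t_crit, k, connectivity = 6L) {
  stopifnot(inherits(stat, "stat_map"), t_crit > 0, k >= 1)
  dm <- dim(stat$t_values)
  sgn <- array(0L, dm)
  sgn[stat$mask$data & stat$t_values > t_crit] <- 1L
  sgn[stat$mask$data & stat$t_values < -t_crit] <- -1L
  cl <- label_clusters(sgn, connectivity)
  cl <- Filter(function(x) x$size >= k, cl)
  rows <- lapply(cl, function(x) {
    tv <- stat$t_values[x$voxels]
    peak <- x$voxels[which.max(abs(tv))]   # voxels sorted: smallest index wins ties
    ijk <- arrayInd(peak, dm)
    xyz <- voxel_to_world(stat$mask$affine, ijk)
    data.frame(sign = if (x$sign > 0) "+" else "-", size = x$size,
               peak_t = stat$t_values[peak],
               i = ijk[1], j = ijk[2], k = ijk[3],
               x_mm = xyz[1], y_mm = xyz[2], z_mm = xyz[3],
               label = NA_character_, stringsAsFactors = FALSE)
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(0), size = integer(0), peak_t = numeric(0),
               i = integer(0), j = integer(0), k = integer(0),
               x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
               label = character(0), stringsAsFactors = FALSE)
  attr(rep, "k_threshold") <- as.integer(k)
  attr(rep, "t_crit") <- t_crit
  attr(rep, "cluster_voxels") <- lapply(cl, `[[`, "voxels")
  rep
}
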