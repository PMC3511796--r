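# Independent oracle implementations and small fixture builders.  These
# deliberately use naive, loop-based algorithms so they share no code path
# with the package internals they check.

# Kendall's W by the textbook rank-sum formula, with mid-ranks computed by
# pairwise counting (no call to rank()).
brute_kcc <- function(x, tie_correction = TRUE) {
  K <- nrow(x)
  n <- ncol(x)
  rk <- matrix(0, K, n)
  for (j in 1:K) {
    for (t in 1:n) {
      rk[j, t] <- 1 + sum(x[j, ] < x[j, t]) +
        0.5 * (sum(x[j, ] == x[j, t]) - 1)
    }
  }
  Rt <- colSums(rk)
  S <- sum((Rt - mean(Rt))^2)
  Tsum <- 0
  if (tie_correction) {
    for (j in 1:K) {
      for (u in unique(x[j, ])) {
        m <- sum(x[j, ] == u)
        Tsum <- Tsum + (m^3 - m)
      }
    }
  }
  den <- K^2 * (n^3 - n) - K * Tsum
  if (den <= 0) return(0)
  12 * S / den
}

# Connected components by explicit stack-based flood fill over array
# coordinates.
flood_fill_clusters <- function(bin, connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  offs <- g[ord >= 1 & ord <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
            drop = FALSE]
  dm <- dim(bin)
  labs <- array(0L, dm)
  cur <- 0L
  for (s in which(bin)) {
    if (labs[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    labs[s] <- cur
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      ijk <- arrayInd(v, dm)
      for (o in seq_len(nrow(offs))) {
        p <- ijk + offs[o, ]
        if (all(p >= 1) && all(p <= dm)) {
          li <- (p[3] - 1L) * dm[1] * dm[2] + (p[2] - 1L) * dm[1] + p[1]
          if (bin[li] && labs[li] == 0L) {
            labs[li] <- cur
            stack <- c(stack, li)
          }
        }
      }
    }
  }
  lapply(split(which(labs > 0), labs[labs > 0]), sort)
}

# RAS affine with given isotropic voxel size, grid centered at the origin.
test_affine <- function(voxel = 3, dims = NULL, origin = NULL) {
  aff <- diag(c(rep(voxel, 3), 1))
  if (!is.null(dims))
    aff[1:3, 4] <- (origin %||% c(0, 0, 0)) - voxel * (dims - 1) / 2
  aff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

full_mask <- function(dims, voxel = 3) {
  brain_mask(array(TRUE, dims), test_affine(voxel, dims))
}

noise_bold <- function(dims, nt, voxel = 3, tr = 3, seed = 1) {
  set.seed(seed)
  bold4d(array(rnorm(prod(dims) * nt), c(dims, nt)),
         test_affine(voxel, dims), tr)
}

# In-memory per-subject pipeline (preprocess + ReHo), shared by the
# synthetic-data property tests.
subject_reho <- function(cfg, subject, seed, mask, n_discard = 10,
                         smooth = NULL) {
  sub <- generate_subject_bold(cfg, subject, seed)
  b <- discard_initial_volumes(sub$bold, n_discard)
  b <- bandpass_ideal(detrend_linear(b), filter_spec())
  m <- reho_map(b, mask, 27)
  if (!is.null(smooth)) m <- smooth_reho(standardize_reho(m), smooth)
  m
}

# In-memory cohort -> second-level stat map under the scaled study
# conditions, without touching disk.
cohort_stat <- function(cfg, mask, n_discard = 10, smooth = 6,
                        standardize_only = FALSE) {
  n <- cfg$n_group1 + cfg$n_group2
  seeds <- rehopipe:::derive_seeds(cfg$seed, n + 1L)
  tab <- rehopipe:::with_seed(seeds[n + 1L],
                              rehopipe:::draw_covariates(cfg))
  maps <- lapply(seq_len(n), function(i) {
    sub <- generate_subject_bold(cfg, as.list(tab[i, ]), seeds[i])
    b <- discard_initial_volumes(sub$bold, n_discard)
    b <- bandpass_ideal(detrend_linear(b), filter_spec())
    m <- standardize_reho(reho_map(b, mask, 27))
    if (!standardize_only) m <- smooth_reho(m, smooth)
    m
  })
  X <- suppressWarnings(build_design_matrix(tab))
  list(stat = fit_group_glm(maps, X), tab = tab, maps = maps)
}
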