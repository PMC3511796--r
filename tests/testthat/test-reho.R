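test_that("kcc hits the closed-form concordance landmarks", {
  expect_equal(kcc(rbind(1:7, 1:7, 1:7)), 1)                    # identical orderings
  expect_equal(kcc(rbind(c(2, 5, 9), exp(c(2, 5, 9)))), 1)      # monotone copies
  expect_equal(kcc(rbind(1:4, 4:1)), 0)                         # K=2 discordant
  expect_equal(kcc(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))), 4 / 9)
  expect_error(kcc(matrix(1:5, 1)), "2 series")
  expect_error(kcc(matrix(1:2, 2, 1)), "2 time points")
  expect_warning(w0 <- kcc(rbind(rep(1, 5), rep(2, 5))), "constant")
  expect_equal(w0, 0)
})

test_that("kcc matches a brute-force rank-sum oracle on random instances", {
  set.seed(101)
  for (rep in 1:200) {
    K <- sample(2:8, 1)
    n <- sample(3:15, 1)
    x <- if (rep %% 3 == 0) {
      matrix(sample(1:4, K * n, TRUE), K, n)   # heavy ties
    } else {
      matrix(rnorm(K * n), K, n)
    }
    expect_equal(kcc(x), brute_kcc(x), tolerance = 1e-12)
    expect_equal(kcc(x, tie_correction = FALSE),
                 brute_kcc(x, tie_correction = FALSE), tolerance = 1e-12)
  }
})

test_that("kcc is rank-invariant and equals mapped mean Spearman correlation", {
  set.seed(102)
  x <- matrix(rnorm(5 * 12), 5, 12)
  # strictly monotone transform of one series leaves W unchanged
  y <- x
  y[2, ] <- exp(3 * y[2, ])
  expect_equal(kcc(y), kcc(x), tolerance = 1e-12)
  expect_equal(kcc(x + 100), kcc(x), tolerance = 1e-12)
  # W = ((K-1) rho_bar + 1) / K on tie-free data
  for (K in c(2, 3, 5)) {
    for (n in c(5, 20)) {
      z <- matrix(rnorm(K * n), K, n)
      rho <- cor(t(z), method = "spearman")
      rho_bar <- mean(rho[upper.tri(rho)])
      expect_equal(kcc(z), ((K - 1) * rho_bar + 1) / K, tolerance = 1e-12)
    }
  }
})

test_that("kcc null mean over i.i.d. data is close to 1/K", {
  set.seed(103)
  for (K in c(3, 27)) {
    ws <- replicate(400, kcc(matrix(rnorm(K * 20), K, 20)))
    expect_lt(abs(mean(ws) - 1 / K), 3 * sd(ws) / sqrt(length(ws)))
  }
})

test_that("reho_map agrees with scalar kcc voxel by voxel, edges included", {
  set.seed(104)
  dims <- c(5, 4, 4)
  b <- noise_bold(dims, 12, seed = 104)
  m <- array(runif(prod(dims)) > 0.2, dims)
  m[2, 2, 2] <- TRUE
  msk <- brain_mask(m, test_affine(3, dims))
  rmap <- reho_map(b, msk, 27)
  offs <- rehopipe:::neighborhood_offsets(27)
  for (vx in list(c(2, 2, 2), c(1, 1, 1), c(5, 4, 4), c(3, 2, 3))) {
    if (!m[vx[1], vx[2], vx[3]]) next
    sers <- list()
    for (o in seq_len(nrow(offs))) {
      p <- vx + offs[o, ]
      if (all(p >= 1) && all(p <= dims) && m[p[1], p[2], p[3]])
        sers[[length(sers) + 1]] <- b$data[p[1], p[2], p[3], ]
    }
    expected <- if (length(sers) >= 2) kcc(do.call(rbind, sers)) else 0
    expect_equal(rmap$values[vx[1], vx[2], vx[3]], expected,
                 tolerance = 1e-12)
  }
})

test_that("identical monotone series everywhere give W = 1 in-mask", {
  dims <- c(4, 4, 4)
  nt <- 10
  series <- cumsum(runif(nt) + 0.1)
  b <- bold4d(array(rep(series, each = prod(dims)), c(dims, nt)),
              test_affine(3, dims), 3)
  msk <- full_mask(dims)
  rmap <- reho_map(b, msk, 27)
  expect_true(all(abs(rmap$values[msk$data] - 1) < 1e-12))
})

test_that("null mean ReHo of interior voxels is near 1/27", {
  nseeds <- 6
  means <- numeric(nseeds)
  interior <- array(FALSE, c(12, 12, 12))
  interior[2:11, 2:11, 2:11] <- TRUE
  for (s in seq_len(nseeds)) {
    b <- noise_bold(c(12, 12, 12), 170, seed = 200 + s)
    rmap <- reho_map(b, full_mask(c(12, 12, 12)), 27)
    means[s] <- mean(rmap$values[interior])
  }
  se <- sd(means) / sqrt(nseeds)
  expect_lt(abs(mean(means) - 1 / 27), 3 * max(se, 1e-4))
})

test_that("time shuffling destroys planted synchrony down to the null level", {
  # spatially independent background so the no-synchrony level is 1/K
  cfg <- cohort_config(n_group1 = 1, n_group2 = 1, grid_shape = c(12, 12, 12),
                       n_volumes = 60, tr_s = 3, seed = 77,
                       noise_fwhm_mm = 0,
                       effect_rois = list(list(center = c(6, 6, 6),
                                               radius = 2.5, w1 = 0.8,
                                               w2 = 0.8)))
  sub <- generate_subject_bold(cfg, list(group = "group1"), 77)
  msk <- full_mask(c(12, 12, 12))
  roi <- rehopipe:::roi_voxel_indices(c(6, 6, 6), 2.5, c(12, 12, 12))
  w_sync <- mean(reho_map(sub$bold, msk, 27)$values[roi])
  set.seed(78)
  shuf <- sub$bold
  for (v in roi) {                 # independent time shuffle per ROI voxel
    ijk <- arrayInd(v, c(12, 12, 12))
    shuf$data[ijk[1], ijk[2], ijk[3], ] <-
      shuf$data[ijk[1], ijk[2], ijk[3], sample(60)]
  }
  w_shuf <- mean(reho_map(shuf, msk, 27)$values[roi])
  expect_gt(w_sync, 5 * (1 / 27))
  expect_lt(abs(w_shuf - 1 / 27), 0.01)
})

test_that("single-voxel masks and K<2 voxels are flagged and zeroed", {
  dims <- c(5, 5, 5)
  m <- array(FALSE, dims)
  m[3, 3, 3] <- TRUE
  b <- noise_bold(dims, 10, seed = 9)
  rmap <- reho_map(b, brain_mask(m, test_affine(3, dims)), 27)
  expect_true(rmap$flagged[3, 3, 3])
  expect_equal(rmap$values[3, 3, 3], 0)
  expect_error(standardize_reho(rmap), "degenerate")
})

test_that("standardization scales the mask mean to 1 and is idempotent", {
  dims <- c(6, 6, 6)
  b <- noise_bold(dims, 20, seed = 10)
  msk <- full_mask(dims)
  rmap <- reho_map(b, msk, 27)
  uni <- rmap
  uni$values[msk$data] <- 0.5
  expect_equal(standardize_reho(uni)$values[msk$data],
               rep(1, sum(msk$data)))
  std <- standardize_reho(rmap)
  expect_true(std$standardized)
  expect_equal(mean(std$values[msk$data]), 1, tolerance = 1e-10)
  twice <- standardize_reho(std)
  expect_equal(twice$values, std$values, tolerance = 1e-12)
})

test_that("map smoothing: identity at 0, constant-preserving, Gaussian impulse", {
  dims <- c(6, 6, 6)
  b <- noise_bold(dims, 20, seed = 12)
  msk <- full_mask(dims)
  rmap <- standardize_reho(reho_map(b, msk, 27))
  expect_equal(smooth_reho(rmap, 0)$values, rmap$values)
  cmap <- rmap
  cmap$values[msk$data] <- 2.5
  sm <- smooth_reho(cmap, 6)
  expect_equal(sm$values[msk$data], rep(2.5, sum(msk$data)),
               tolerance = 1e-12)

  # unit impulse on a large unmasked grid reproduces the separable
  # truncated-Gaussian kernel built independently here
  g <- array(0, c(21, 21, 21))
  g[11, 11, 11] <- 1
  out <- gaussian_smooth_3d(g, 6, c(3, 3, 3))
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  kern3 <- outer(outer(k1, k1), k1)
  win <- 11 + (-r:r)
  expect_lt(max(abs(out[win, win, win] - kern3)), 1e-6)
  expect_lt(max(abs(out[1:5, , ])), 1e-12)
})

test_that("ReHo maps round-trip through NIfTI with their sidecar metadata", {
  dims <- c(6, 6, 6)
  b <- noise_bold(dims, 15, seed = 14)
  msk <- full_mask(dims)
  m <- smooth_reho(standardize_reho(reho_map(b, msk, 19)), 6)
  f <- tempfile(fileext = ".nii.gz")
  write_reho_map(m, f)
  m2 <- read_reho_map(f, mask = msk)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_equal(m2$neighborhood, 19)
  expect_equal(m2$n_timepoints, m$n_timepoints)
  expect_true(m2$standardized)
  expect_equal(m2$smoothed_fwhm_mm, 6)
  unlink(c(f, sub("\\.nii\\.gz$", ".json", f)))
})
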