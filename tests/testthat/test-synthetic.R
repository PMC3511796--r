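test_that("cohort configuration enforces its invariants", {
  expect_error(cohort_config(n_group1 = 0), "degenerate")
  expect_error(cohort_config(ar1_coef = 1), "ar1")
  expect_error(cohort_config(
    grid_shape = c(10, 10, 10),
    effect_rois = list(list(center = c(5, 5, 5), radius = 2, w1 = 1,
                            w2 = 0))), "weights")
  expect_error(cohort_config(
    grid_shape = c(10, 10, 10),
    effect_rois = list(list(center = c(9, 5, 5), radius = 3, w1 = 0.5,
                            w2 = 0))), "ROI 1")
  expect_error(cohort_config(
    grid_shape = c(10, 10, 10),
    effect_rois = list(list(center = c(5, 5, 5), radius = 2, w1 = 0.5,
                            w2 = 0)),
    clinical_link = list(roi = 2, variable = "craving", strength = 0.5)),
    "ROI 2")
})

test_that("the same seed reproduces a subject's data exactly", {
  cfg <- cohort_config(n_group1 = 2, n_group2 = 2, grid_shape = c(8, 8, 8),
                       n_volumes = 20, seed = 5,
                       effect_rois = list(list(center = c(4, 4, 4),
                                               radius = 2, w1 = 0.5,
                                               w2 = 0.1)))
  a <- generate_subject_bold(cfg, list(group = "group1"), 99)
  b <- generate_subject_bold(cfg, list(group = "group1"), 99)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$motion, b$motion)
  c <- generate_subject_bold(cfg, list(group = "group1"), 100)
  expect_false(identical(a$bold$data, c$bold$data))
})

test_that("generated cohorts have the study's group sizes and table layout", {
  td <- file.path(tempdir(), "cohort-default")
  unlink(td, recursive = TRUE)
  # group sizes left at their defaults; image scale reduced for the test
  cfg <- cohort_config(grid_shape = c(6, 6, 6), n_volumes = 8, seed = 42)
  tab <- generate_cohort(cfg, td)
  expect_equal(sum(tab$group == "group1"), 45)
  expect_equal(sum(tab$group == "group2"), 44)
  expect_equal(names(tab),
               c("subject_id", "group", "age", "sex", "education",
                 "cigarettes_per_day", "years_smoking", "craving",
                 "image_path", "motion_path"))
  # clinical fields present iff group1
  expect_true(all(!is.na(tab$cigarettes_per_day[tab$group == "group1"])))
  expect_true(all(is.na(tab$cigarettes_per_day[tab$group == "group2"])))
  expect_true(all(is.na(tab$craving[tab$group == "group2"])))
  # files exist; table round-trips; motion files are 6-column, one row/volume
  expect_true(all(file.exists(tab$image_path)))
  expect_true(all(file.exists(tab$motion_path)))
  tab2 <- read_subject_table(file.path(td, "participants.tsv"))
  expect_equal(tab2$subject_id, tab$subject_id)
  expect_equal(tab2$age, tab$age)
  mot <- as.matrix(read.table(tab$motion_path[1]))
  expect_equal(dim(mot), c(8, 6))
  # drawn covariates sit in the configured ranges
  expect_true(all(tab$age >= 19 & tab$age <= 39))
  expect_true(all(tab$craving[tab$group == "group1"] >= 3 &
                  tab$craving[tab$group == "group1"] <= 10))
  expect_true(all(tab$sex %in% c("F", "M")))
  unlink(td, recursive = TRUE)
})

test_that("a rerun of generate_cohort reproduces files bit-for-bit", {
  td1 <- file.path(tempdir(), "rep1")
  td2 <- file.path(tempdir(), "rep2")
  unlink(c(td1, td2), recursive = TRUE)
  cfg <- cohort_config(n_group1 = 2, n_group2 = 2, grid_shape = c(6, 6, 6),
                       n_volumes = 8, seed = 31)
  t1 <- generate_cohort(cfg, td1)
  t2 <- generate_cohort(cfg, td2)
  expect_equal(t1$age, t2$age)
  expect_equal(t1$sex, t2$sex)
  b1 <- read_bold(t1$image_path[1])
  b2 <- read_bold(t2$image_path[1])
  expect_identical(b1$data, b2$data)
  expect_identical(readLines(t1$motion_path[3]), readLines(t2$motion_path[3]))
  unlink(c(td1, td2), recursive = TRUE)
})

test_that("zero coupling makes ROI voxels indistinguishable from background", {
  dims <- c(12, 12, 12)
  msk <- full_mask(dims)
  roi <- rehopipe:::roi_voxel_indices(c(6, 6, 6), 2.5, dims)
  interior <- array(FALSE, dims)
  interior[3:10, 3:10, 3:10] <- TRUE
  far <- setdiff(which(interior),
                 rehopipe:::roi_voxel_indices(c(6, 6, 6), 4.5, dims))
  diffs <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_group1 = 1, n_group2 = 1, grid_shape = dims,
                         n_volumes = 40, seed = 4000 + s,
                         effect_rois = list(list(center = c(6, 6, 6),
                                                 radius = 2.5, w1 = 0,
                                                 w2 = 0)))
    m <- subject_reho(cfg, list(group = "group1"), 4000 + s, msk)
    mean(m$values[roi]) - mean(m$values[far])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("differential coupling raises group1 in-ROI ReHo (one-sided t)", {
  dims <- c(10, 10, 10)
  msk <- full_mask(dims)
  roi <- rehopipe:::roi_voxel_indices(c(5, 5, 5), 2, dims)
  cfg <- cohort_config(n_group1 = 20, n_group2 = 20, grid_shape = dims,
                       n_volumes = 40, seed = 606,
                       effect_rois = list(list(center = c(5, 5, 5),
                                               radius = 2, w1 = 0.8,
                                               w2 = 0)))
  seeds <- rehopipe:::derive_seeds(cfg$seed, 40)
  m1 <- vapply(1:20, function(i)
    mean(subject_reho(cfg, list(group = "group1"), seeds[i],
                      msk)$values[roi]), numeric(1))
  m2 <- vapply(21:40, function(i)
    mean(subject_reho(cfg, list(group = "group2"), seeds[i],
                      msk)$values[roi]), numeric(1))
  tt <- t.test(m1, m2, alternative = "greater", var.equal = TRUE)
  expect_lt(tt$p.value, 0.01)
})

test_that("in-ROI ReHo is monotone in the coupling weight", {
  dims <- c(10, 10, 10)
  msk <- full_mask(dims)
  roi <- rehopipe:::roi_voxel_indices(c(5, 5, 5), 2, dims)
  ws <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(ws, function(w) {
    cfg <- cohort_config(n_group1 = 1, n_group2 = 1, grid_shape = dims,
                         n_volumes = 40, seed = 900,
                         effect_rois = list(list(center = c(5, 5, 5),
                                                 radius = 2, w1 = w,
                                                 w2 = 0)))
    mean(vapply(1:10, function(s)
      mean(subject_reho(cfg, list(group = "group1"), 900 + s,
                        msk)$values[roi]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the clinical link induces a positive craving-ReHo correlation", {
  dims <- c(12, 12, 12)
  msk <- full_mask(dims)
  roi <- rehopipe:::roi_voxel_indices(c(6, 6, 6), 2.5, dims)
  hits <- 0
  nseeds <- 5
  for (s in seq_len(nseeds)) {
    cfg <- cohort_config(n_group1 = 45, n_group2 = 2, grid_shape = dims,
                         n_volumes = 40, seed = 3000 + s,
                         effect_rois = list(list(center = c(6, 6, 6),
                                                 radius = 2.5, w1 = 0.5,
                                                 w2 = 0)),
                         clinical_link = list(roi = 1, variable = "craving",
                                              strength = 0.6))
    seeds <- rehopipe:::derive_seeds(cfg$seed, 48)
    tab <- rehopipe:::with_seed(seeds[48],
                                rehopipe:::draw_covariates(cfg))
    means <- vapply(1:45, function(i)
      mean(subject_reho(cfg, as.list(tab[i, ]), seeds[i],
                        msk)$values[roi]), numeric(1))
    ct <- cor.test(tab$craving[1:45], means, alternative = "greater")
    hits <- hits + (ct$p.value < 0.05)
  }
  expect_gte(hits, ceiling(nseeds / 2) + 1)
})

test_that("the background AR(1) coefficient is realized in the series", {
  cfg <- cohort_config(n_group1 = 1, n_group2 = 1, grid_shape = c(8, 8, 8),
                       n_volumes = 120, noise_fwhm_mm = 0, ar1_coef = 0.3,
                       seed = 21)
  sub <- generate_subject_bold(cfg, list(group = "group1"), 21)
  acs <- apply(matrix(sub$bold$data, ncol = 120), 1, function(y)
    cor(y[-1], y[-120]))
  expect_lt(abs(mean(acs) - 0.3), 0.02)
})
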