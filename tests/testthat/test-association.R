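test_that("voxel-wise Pearson honours affine structure and the generator", {
  set.seed(9)
  a <- array(rnorm(216), c(6, 6, 6))
  mask <- array(FALSE, c(6, 6, 6))
  mask[2:5, 2:5, 2:5] <- TRUE
  expect_equal(voxelwise_pearson(a, a, mask), 1)
  expect_equal(voxelwise_pearson(a, -2 * a + 3, mask), -1)
  # symmetry and affine invariance
  b <- array(rnorm(216), c(6, 6, 6))
  expect_equal(voxelwise_pearson(a, b, mask), voxelwise_pearson(b, a, mask))
  expect_equal(voxelwise_pearson(a, b, mask),
               voxelwise_pearson(3 * a + 1, 0.5 * b - 2, mask),
               tolerance = 1e-12)
  # forced-correlation construction
  forced <- a
  forced[mask] <- forced_correlation_field(a[mask], 0.45, seed = 2)
  expect_lt(abs(voxelwise_pearson(a, forced, mask) - 0.45), 1e-8)
  expect_lt(abs(pearson_oracle(a[mask], forced[mask]) - 0.45), 1e-8)

  const <- array(1, c(6, 6, 6))
  expect_error(voxelwise_pearson(a, const, mask), "zero variance in ROI")
})

test_that("pairwise-complete voxels drive the correlation", {
  a <- array(rnorm(64), c(4, 4, 4))
  b <- array(rnorm(64), c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  a2 <- a; a2[1] <- NA
  b2 <- b; b2[2] <- Inf
  r <- voxelwise_pearson(a2, b2, mask)
  keep <- 3:64
  expect_equal(r, pearson_oracle(a[keep], b[keep]), tolerance = 1e-12)
})

test_that("Fisher transform matches atanh with clamping near the poles", {
  expect_equal(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.3), atanh(0.3))
  expect_equal(atanh(0.3), 0.3095196, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(tanh(fisher_transform(r)), r, tolerance = 1e-12)
  expect_warning(z1 <- fisher_transform(1), "clamped")
  expect_true(is.finite(z1))
  expect_error(fisher_transform(1.001), "exceed")
})

test_that("cohort association produces one record per available cell", {
  coh <- generate_cohort(tiny_config(n_subjects = 10), seed = 3)
  maps <- lapply(coh$subjects, function(s) s$maps)
  assoc <- cohort_association(maps, coh$roi_masks, c("atlas", "fa", "md"),
                              atlas = coh$atlas)
  # 10 subjects x 3 ROIs x 3 modalities, all atlas-eligible ROIs
  expect_equal(nrow(assoc), 10 * 3 * 3)
  expect_true(all(abs(assoc$z - atanh(assoc$r)) < 1e-12))
  expect_true(all(assoc$n_voxels >= 3))

  # exact mode: every record matches its ground-truth rho
  rho <- coh$truth$target_voxel_rho
  for (k in seq_len(nrow(assoc))) {
    expect_lt(abs(assoc$r[k] - rho[assoc$roi_id[k], assoc$modality_id[k]]),
              1e-8)
  }

  # missing modality: record skipped with a log
  maps2 <- maps
  maps2[[1]]$fa <- NULL
  maps2[[2]]$fa <- NULL
  expect_message(
    assoc2 <- cohort_association(maps2, coh$roi_masks, c("fa", "md")),
    "skipped 2")
  expect_equal(sum(assoc2$modality_id == "fa"), 8 * 3)
  expect_equal(sum(assoc2$modality_id == "md"), 10 * 3)
  expect_equal(nrow(attr(assoc2, "skipped")), 2)
})

test_that("white matter is excluded from the atlas arm", {
  rois <- list(whole_cortex = array(TRUE, c(3, 3, 3)),
               white_matter = array(TRUE, c(3, 3, 3)))
  set.seed(5)
  atlas <- array(rnorm(27), c(3, 3, 3))
  maps <- list(s1 = list(amyloid = array(rnorm(27), c(3, 3, 3)),
                         fa = array(rnorm(27), c(3, 3, 3))))
  assoc <- cohort_association(maps, rois, c("atlas", "fa"), atlas = atlas)
  expect_false(any(assoc$roi_id == "white_matter" &
                     assoc$modality_id == "atlas"))
  expect_true(any(assoc$roi_id == "white_matter" & assoc$modality_id == "fa"))
})

test_that("clinical matrices are pairwise-complete with per-cell n", {
  set.seed(12)
  n <- 20
  tab <- data.frame(subject_id = seq_len(n), age = rnorm(n), bmi = rnorm(n))
  rm <- cbind(roiA = rnorm(n), roiB = rnorm(n))
  rm[, "roiA"] <- tab$age  # identical variable: r = 1
  cm <- clinical_matrix(tab, rm, c("age", "bmi"))
  expect_equal(cm$r["roiA", "age"], 1)
  expect_equal(cm$n["roiA", "age"], n)

  tab2 <- tab
  tab2$bmi[1:(n - 2)] <- NA  # only 2 complete pairs left
  cm2 <- clinical_matrix(tab2, rm, c("age", "bmi"))
  expect_true(is.na(cm2$r["roiA", "bmi"]))
  expect_equal(cm2$n["roiA", "bmi"], 2L)
  # pairwise (not listwise): the age column keeps all n subjects
  expect_equal(cm2$n["roiA", "age"], n)
})
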