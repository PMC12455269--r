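test_that("volume-fraction downsampling is exact", {
  m <- array(FALSE, c(4, 4, 4))
  m[1:2, 1:2, 1:2] <- TRUE          # one full coarse cell
  m[3:4, 1:2, 1:2] <- TRUE
  m[4, 2, 2] <- FALSE               # 7/8 cell
  fr <- downsample_mask_fraction(m, 2)
  expect_equal(fr[1, 1, 1], 1.0)
  expect_equal(fr[2, 1, 1], 0.875)
  expect_equal(fr[1, 2, 2], 0.0)
  expect_error(downsample_mask_fraction(array(TRUE, c(5, 4, 4)), 2),
               "divisible")
})

test_that("threshold boundary is inclusive at 0.9", {
  fr <- array(c(0.875, 0.9, 1.0, 0.0), c(4, 1, 1))
  th <- threshold_mask(fr, 0.9)
  expect_equal(as.logical(th), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(threshold_mask(fr, 0), "tau")
  expect_error(threshold_mask(fr, 1.2), "tau")
})

test_that("thresholded masks shrink monotonically in tau", {
  set.seed(7)
  m <- array(runif(8^3) > 0.4, c(8, 8, 8))
  fr <- downsample_mask_fraction(m, 2)
  sizes <- sapply(c(0.1, 0.25, 0.5, 0.75, 0.9, 1), function(tau) {
    sum(threshold_mask(fr, tau))
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("downsampling conserves fine-grid voxel counts", {
  set.seed(11)
  for (rep in 1:5) {
    m <- array(runif(8^3) > runif(1, 0.2, 0.8), c(8, 8, 8))
    fr <- downsample_mask_fraction(m, 2)
    expect_identical(sum(fr * 8), as.double(sum(m)))
  }
  # a union of full coarse cells survives threshold(0.9) exactly
  m2 <- array(FALSE, c(8, 8, 8))
  m2[1:4, 1:2, 1:2] <- TRUE  # 2 coarse cells
  m2[7:8, 7:8, 7:8] <- TRUE  # 1 coarse cell
  th <- threshold_mask(downsample_mask_fraction(m2, 2), 0.9)
  expect_equal(sum(th), 3L)
  expect_equal(sum(m2), 3L * 8L)
})

test_that("ROI value extraction uses a fixed ordering and drops non-finite voxels", {
  map <- array(5, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4))
  mask[1:2, 1, 1] <- TRUE
  mask[1, 2, 1] <- TRUE
  ex <- extract_roi_values(map, mask)
  expect_equal(ex$mean, 5)
  expect_equal(ex$n, 3)

  one <- array(FALSE, c(4, 4, 4))
  one[3, 3, 3] <- TRUE
  map[3, 3, 3] <- 9.5
  expect_equal(extract_roi_values(map, one)$mean, 9.5)

  # ordering: first index fastest
  mp <- array(seq_len(8), c(2, 2, 2))
  expect_equal(extract_roi_values(mp, array(TRUE, c(2, 2, 2)))$values,
               as.numeric(1:8))

  big <- array(rnorm(1000), c(10, 10, 10))
  bm <- array(FALSE, c(10, 10, 10))
  bm[1:10, 1:10, 1] <- TRUE
  big[c(1, 50)] <- c(NA, Inf)
  expect_message(ex2 <- extract_roi_values(big, bm, "test_roi"),
                 "2 non-finite")
  expect_equal(ex2$n, 98)
  expect_equal(ex2$n_excluded, 2)

  empty <- array(NA_real_, c(2, 2, 2))
  expect_error(extract_roi_values(empty, array(TRUE, c(2, 2, 2)), "roiX"),
               "roiX")
})

test_that("the white-matter ROI is flagged out of the atlas comparison", {
  tab <- default_roi_table()
  expect_false(tab$include_in_atlas_comparison[tab$roi_id == "white_matter"])
  expect_equal(sum(tab$include_in_atlas_comparison), 7)
})
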