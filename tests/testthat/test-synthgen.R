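test_that("forced correlation fields reproduce the requested rho exactly", {
  set.seed(42)
  base <- rnorm(500)
  for (rho in c(-0.8, -0.3, 0, 0.45, 0.9)) {
    y <- forced_correlation_field(base, rho, seed = 7)
    expect_lt(abs(pearson_oracle(y, base) - rho), 1e-8)
  }
  # near-unit rho: output nearly proportional to the base
  y1 <- forced_correlation_field(base, 1 - 1e-9, seed = 3)
  expect_gt(pearson_oracle(y1, base), 1 - 1e-6)
})

test_that("forced correlation rejects degenerate inputs", {
  expect_error(forced_correlation_field(rep(2, 10), 0.5, 1), "zero-variance")
  expect_error(forced_correlation_field(rnorm(10), 1, 1), "inside")
  expect_error(forced_correlation_field(rnorm(10), -1.2, 1), "inside")
  expect_error(forced_correlation_field(rnorm(2), 0.5, 1), "at least 3")
})

test_that("BOLD generator places the requested spectral fraction in band", {
  b <- generate_bold_volume(c(6, 6, 6), 488, 0.8, band_fraction = 0.8,
                            seed = 2)
  expect_equal(dim(b), c(6, 6, 6, 488))
  expect_equal(attr(b, "tr"), 0.8)
  f <- compute_falff(b, tr = 0.8)
  expect_lt(abs(mean(f) - 0.8), 0.05)
  f1 <- compute_falff(generate_bold_volume(c(5, 5, 4), 488, 0.8, 1,
                                           seed = 4), tr = 0.8)
  expect_true(all(f1 >= 0.99))
  f0 <- compute_falff(generate_bold_volume(c(5, 5, 4), 488, 0.8, 0,
                                           seed = 4), tr = 0.8)
  expect_true(all(f0 <= 0.05))
  expect_error(generate_bold_volume(c(4, 4, 4), 488, 0.8, 1.2, seed = 1),
               "band_fraction")
  expect_error(generate_bold_volume(c(4, 4, 4), 8, 0.8, 0.5, seed = 1),
               "n_vols")
})

test_that("BOLD coupling raises regional homogeneity monotonically", {
  rh <- sapply(c(0, 0.4, 0.9), function(cp) {
    mean(compute_reho(generate_bold_volume(c(5, 5, 5), 64, 0.8, 0.5,
                                           coupling = cp, seed = 9)))
  })
  expect_true(all(diff(rh) > 0))
})

test_that("DWI signals follow the tensor model exactly at zero noise", {
  gt <- default_gradient_table()
  expect_equal(length(gt$bvals), 100)
  expect_equal(sum(gt$bvals == 0), 7)
  expect_setequal(unique(gt$bvals[gt$bvals > 0]), c(1500, 3000))

  # b = 0 volumes give exactly s0
  iso <- array(c(7e-4, 7e-4, 7e-4, 0, 0, 0), c(1, 1, 1, 6))
  sig <- generate_dwi_signals(iso, gt, s0 = 900, noise_sd = 0)
  expect_equal(unname(sig$signals[1, 1, 1, gt$bvals == 0]), rep(900, 7))
  # isotropic closed form: s0 * exp(-b * d) for any direction
  expect_equal(unname(sig$signals[1, 1, 1, which(gt$bvals == 1500)[1]]),
               900 * exp(-1500 * 7e-4), tolerance = 1e-12)
  expect_error(gradient_table(c(-1, 0), matrix(0, 2, 3)), "negative b")
})

test_that("identical seeds give bit-identical cohorts", {
  c1 <- generate_cohort(tiny_config(), seed = 31)
  c2 <- generate_cohort(tiny_config(), seed = 31)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$clinical, c2$clinical)
  c3 <- generate_cohort(tiny_config(), seed = 32)
  expect_false(identical(c1$subjects[[1]]$maps$amyloid,
                         c3$subjects[[1]]$maps$amyloid))
})

test_that("exact-mode cohorts reproduce the imposed voxel-wise rho", {
  coh <- generate_cohort(tiny_config(), seed = 5)
  rho <- coh$truth$target_voxel_rho
  for (s in seq_along(coh$subjects)) {
    maps <- coh$subjects[[s]]$maps
    for (roi in rownames(rho)) {
      m <- coh$roi_masks[[roi]]
      r_atlas <- pearson_oracle(maps$amyloid[m], coh$atlas[m])
      expect_lt(abs(r_atlas - rho[roi, "atlas"]), 1e-8)
      for (mod in c("fa", "md")) {
        r <- pearson_oracle(maps$amyloid[m], maps[[mod]][m])
        expect_lt(abs(r - rho[roi, mod]), 1e-8)
      }
    }
  }
})

test_that("exact-mode clinical correlations match the imposed matrix", {
  coh <- generate_cohort(tiny_config(), seed = 8)
  rois <- rownames(coh$truth$target_voxel_rho)
  rm <- sapply(rois, function(roi) {
    sapply(coh$subjects, function(s) mean(s$maps$amyloid[coh$roi_masks[[roi]]]))
  })
  vars <- c("age", "bmi", "grip_strength", "fluid_cognition",
            "crystallised_cognition")
  x <- cbind(rm, as.matrix(coh$clinical[, vars]))
  colnames(x) <- c(paste0("amyloid_", rois), vars)
  cc <- cor(x)
  tgt <- coh$truth$clinical_corr[colnames(x), colnames(x)]
  expect_lt(max(abs(cc - tgt)), 1e-8)
  # identity blocks force orthogonality exactly
  expect_lt(abs(cc["age", "bmi"]), 1e-8)
})

test_that("infeasible ROI geometry is rejected", {
  bad <- tiny_config()
  bad$roi_geometry$entorhinal$hi <- c(99, 3, 2)
  expect_error(generate_cohort(bad, seed = 1), "infeasible")
  overlap <- tiny_config()
  overlap$roi_geometry$temporal <- overlap$roi_geometry$entorhinal
  expect_error(generate_cohort(overlap, seed = 1), "overlap")
})

test_that("cohort config validates its statistical inputs", {
  expect_error(cohort_config(tau = 1.5), "tau")
  bad_rho <- default_target_rho()
  bad_rho[1, 2] <- 1.2
  expect_error(cohort_config(target_voxel_rho = bad_rho), "inside")
  bad_corr <- default_clinical_corr()
  bad_corr[1, 2] <- 0.9; bad_corr[2, 1] <- 0.9
  bad_corr[1, 3] <- -0.9; bad_corr[3, 1] <- -0.9
  bad_corr[2, 3] <- 0.9; bad_corr[3, 2] <- 0.9
  expect_error(cohort_config(clinical_corr = bad_corr),
               "positive semidefinite")
})
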