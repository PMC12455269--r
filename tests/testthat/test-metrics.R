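# helper: pack a voxel x time matrix into a 4D series along the first axis
series_from_matrix <- function(m) {
  array(m, c(nrow(m), 1, 1, ncol(m)))
}

test_that("ReHo equals the direct Kendall's W evaluation", {
  set.seed(21)
  for (rep in 1:5) {
    n_vox <- sample(3:5, 1)
    m_t <- sample(6:12, 1)
    sm <- matrix(rnorm(n_vox * m_t), n_vox, m_t)
    if (rep == 3) sm[1, 1:3] <- sm[1, 4]  # inject ties
    ser <- series_from_matrix(sm)
    rh <- compute_reho(ser, neighbourhood = 7)
    # a voxel whose truncated neighbourhood covers the whole column
    mid <- 2
    nb <- max(1, mid - 1):min(n_vox, mid + 1)
    expect_equal(rh[mid, 1, 1], kendall_w_oracle(sm[nb, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("ReHo endpoints: identical series give 1, reversed ranks give 0", {
  base <- rnorm(10)
  same <- series_from_matrix(rbind(base, base, base))
  expect_equal(unname(compute_reho(same, neighbourhood = 7)[2, 1, 1]), 1)

  x <- 1:8
  rev2 <- series_from_matrix(rbind(x, rev(x)))
  expect_equal(unname(compute_reho(rev2, neighbourhood = 7)[1, 1, 1]), 0)

  flat <- series_from_matrix(matrix(3, 3, 6))
  expect_message(rh <- compute_reho(flat, neighbourhood = 7), "degenerate")
  expect_true(all(rh == 0))
})

test_that("ReHo is invariant to strictly monotone transforms and bounded", {
  set.seed(4)
  ser <- generate_bold_volume(c(4, 4, 4), 32, 0.8, 0.5, coupling = 0.5,
                              seed = 12)
  r1 <- compute_reho(ser)
  r2 <- compute_reho(exp(2 * ser))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("fALFF separates in-band from out-of-band oscillations", {
  t_s <- (0:487) * 0.8
  in_band <- array(rep(sin(2 * pi * 0.05 * t_s), each = 4), c(2, 2, 1, 488))
  expect_true(all(compute_falff(in_band, tr = 0.8) >= 0.99))
  out_band <- array(rep(sin(2 * pi * 0.3 * t_s), each = 4), c(2, 2, 1, 488))
  expect_true(all(compute_falff(out_band, tr = 0.8) <= 0.05))
  # amplitude scaling leaves fALFF untouched
  mixed <- array(rnorm(4 * 488), c(2, 2, 1, 488))
  expect_equal(compute_falff(mixed, tr = 0.8),
               compute_falff(50 * mixed, tr = 0.8), tolerance = 1e-12)
  expect_error(compute_falff(mixed, tr = 0.8, band = c(0.01, 2)), "Nyquist")
})

test_that("white-noise fALFF matches the in-band bin fraction", {
  set.seed(17)
  wn <- array(rnorm(1200 * 488), c(12, 10, 10, 488))
  f <- compute_falff(wn, tr = 0.8)
  # 0.09 Hz of the 0.625 Hz positive-frequency span
  expect_lt(abs(mean(f) - 0.144), 0.02)
})

test_that("wDeCe equals brute force on small instances", {
  set.seed(31)
  for (rep in 1:4) {
    n_vox <- sample(5:20, 1)
    sm <- matrix(rnorm(n_vox * 16), n_vox, 16)
    sparsity <- sample(c(0.1, 0.3, 0.5, 1), 1)
    got <- compute_wdece(series_from_matrix(sm), sparsity = sparsity)
    expect_equal(as.numeric(got[, 1, 1]), wdece_oracle(sm, sparsity),
                 tolerance = 1e-12)
    # retained edge count is exactly ceil(sparsity x positive edges)
    cm <- cor(t(sm))
    n_pos <- sum(cm[upper.tri(cm)] > 0)
    expect_equal(attr(got, "n_edges_retained"),
                 as.integer(ceiling(sparsity * n_pos)))
  }
})

test_that("wDeCe of identical series at sparsity 1 is n - 1", {
  base <- rnorm(12)
  sm <- matrix(rep(base, each = 6), 6, 12)
  got <- compute_wdece(series_from_matrix(sm), sparsity = 1)
  expect_equal(as.numeric(got[, 1, 1]), rep(5, 6), tolerance = 1e-12)
})

test_that("WLLS tensor fitting recovers noiseless tensors", {
  gt <- default_gradient_table()
  # isotropic: MD exact, FA zero
  iso <- array(c(7e-4, 7e-4, 7e-4, 0, 0, 0), c(1, 1, 1, 6))
  sig <- generate_dwi_signals(iso, gt, s0 = 1000, noise_sd = 0)
  fit <- fit_dti_wlls(sig$signals[1, 1, 1, ], gt)
  expect_equal(fit$md, 7e-4, tolerance = 1e-12)
  expect_equal(fit$fa, 0, tolerance = 1e-10)

  # prolate tensor: closed-form FA
  pro <- array(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0), c(1, 1, 1, 6))
  sigp <- generate_dwi_signals(pro, gt, s0 = 1000, noise_sd = 0)
  fitp <- fit_dti_wlls(sigp$signals[1, 1, 1, ], gt)
  expect_equal(fitp$fa, fa_oracle(c(1.7e-3, 0.3e-3, 0.3e-3)),
               tolerance = 1e-10)
  expect_equal(fa_oracle(c(1.7e-3, 0.3e-3, 0.3e-3)), 0.79902,
               tolerance = 1e-5)

  # arbitrary PSD tensors: max abs element error < 1e-10
  tf <- random_tensor_field(c(2, 2, 2), seed = 44)
  sigs <- generate_dwi_signals(tf, gt, s0 = 800, noise_sd = 0)
  flat <- matrix(tf, 8, 6)
  for (v in 1:8) {
    idx <- arrayInd(v, c(2, 2, 2))
    fitv <- fit_dti_wlls(sigs$signals[idx[1], idx[2], idx[3], ], gt)
    truth <- matrix(c(flat[v, 1], flat[v, 4], flat[v, 5],
                      flat[v, 4], flat[v, 2], flat[v, 6],
                      flat[v, 5], flat[v, 6], flat[v, 3]), 3, 3)
    expect_lt(max(abs(fitv$D - truth)), 1e-10)
    expect_equal(fitv$s0, 800, tolerance = 1e-8)
  }
})

test_that("tensor fitting rejects degenerate schemes", {
  bad <- gradient_table(c(0, rep(1500, 8)),
                        rbind(c(0, 0, 0),
                              matrix(rep(c(1, 0, 0), 8), 8, 3, byrow = TRUE)))
  expect_error(fit_dti_wlls(rep(100, 9), bad), "insufficient gradient")
  gt <- default_gradient_table()
  expect_error(fit_dti_wlls(rep(100, 5), gt), "counts differ")
})

test_that("motion screening uses a strict threshold with a passing boundary", {
  expect_true(motion_screen(rep(0, 10), voxel_size = 2)$pass)
  res <- motion_screen(c(0.5, 5, 0.2), voxel_size = 2)
  expect_false(res$pass)
  expect_equal(res$offending, 2L)
  expect_true(motion_screen(c(1, 4.0), voxel_size = 2)$pass)
})
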