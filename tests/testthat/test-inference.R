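test_that("sign-flip test matches exhaustive enumeration", {
  # all d equal and positive: only the identity pattern reaches T
  z <- rep(atanh(0.3) + 0.2, 10)
  res <- signflip_effect_size_test(z, r0 = 0.3)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 1024L)
  expect_equal(res$p, 1 / 1024)

  # random small samples against the expand.grid oracle
  set.seed(61)
  for (rep in 1:4) {
    n <- sample(5:9, 1)
    zr <- atanh(0.3) + rnorm(n, sd = 0.3)
    got <- signflip_effect_size_test(zr, r0 = 0.3)
    d <- abs(zr) - atanh(0.3)
    expect_equal(got$p, signflip_p_oracle(d))
    expect_equal(got$t_stat, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)
  }
})

test_that("sign-flip degenerate and symmetric cases behave as documented", {
  z0 <- rep(atanh(0.3), 8)
  res0 <- signflip_effect_size_test(z0, r0 = 0.3)
  expect_equal(res0$p, 1)
  expect_equal(res0$t_stat, 0)

  # symmetric deviations: T = 0 and p is large; with equal magnitudes the
  # null is a discrete lattice whose zero ties count as extreme, so the
  # exhaustive p exceeds the continuous-case 1/2
  d <- c(rep(0.2, 5), rep(-0.2, 5))
  z <- atanh(0.3) + d  # |z| - atanh(0.3) = d since all positive
  res <- signflip_effect_size_test(z, r0 = 0.3)
  expect_equal(res$t_stat, 0, tolerance = 1e-12)
  expect_gte(res$p, 0.5)
  expect_lte(res$p, 0.8)

  expect_error(signflip_effect_size_test(c(0.1, 0.2), r0 = 0.3), "at least 3")
})

test_that("sign-flip Monte-Carlo branch is reproducible and smoothed", {
  z <- atanh(0.3) + rnorm(25, 0.1, 0.2)
  a <- signflip_effect_size_test(z, n_perm = 500, seed = 7)
  b <- signflip_effect_size_test(z, n_perm = 500, seed = 7)
  expect_identical(a$p, b$p)
  expect_false(a$exhaustive)
  expect_gte(a$p, 1 / 501)
})

test_that("permutation correlation test is exact for small n", {
  # y = x with distinct equally spaced values: only the identity and the
  # value-reversing permutation reach |r| = 1
  x <- c(6, 2, 10, 4, 8)
  res <- permutation_corr_test(x, x)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 120L)
  expect_equal(res$p, 2 / 120)
  expect_equal(res$r, 1)

  # package enumeration agrees with an independent count at n = 5
  set.seed(33)
  xx <- rnorm(5); yy <- rnorm(5)
  got <- permutation_corr_test(xx, yy)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  r_obs <- cor(xx, yy)
  count <- sum(apply(perms, 1, function(p) abs(cor(xx, yy[p])) >= abs(r_obs)))
  expect_equal(got$p, count / 120)

  expect_error(permutation_corr_test(rnorm(5), rep(1, 5)), "constant")
})

test_that("permutation correlation p-values are calibrated under the null", {
  set.seed(71)
  rej <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    p <- permutation_corr_test(rnorm(35), rnorm(35), n_perm = 200,
                               seed = i)$p
    if (p <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.03)
})

test_that("Storey q-values reduce to BH step-up at pi0 = 1", {
  expect_equal(as.numeric(storey_fdr(rep(1, 5))), rep(1, 5))
  q <- storey_fdr(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(as.numeric(q), rep(0.04, 4))
  expect_equal(as.numeric(storey_fdr(0.37, pi0 = 1)), 0.37)

  set.seed(91)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    got <- as.numeric(storey_fdr(p, pi0 = 1))
    expect_equal(got, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_equal(got, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_error(storey_fdr(c(0.5, 0)), "0, 1")
  expect_error(storey_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("estimated pi0 approaches 1 for uniform p-values", {
  set.seed(101)
  p <- runif(2000)
  q <- storey_fdr(p)
  expect_gt(attr(q, "pi0"), 0.85)
  # q monotone non-decreasing in sorted p
  expect_true(all(diff(as.numeric(q)[order(p)]) >= -1e-15))
})

test_that("group differences use pooled t and uncorrected chi-squared", {
  g <- rep(c("a", "b"), each = 6)
  tab <- data.frame(v = rep(c(1, 2, 3, 4, 5, 6), 2), grp = g)
  res <- group_difference(tab, "grp", "v")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # balanced contingency: no association
  tab2 <- data.frame(cat = rep(c("x", "y"), 20),
                     grp = rep(c("a", "b"), each = 20))
  res2 <- group_difference(tab2, "grp", "cat")
  expect_equal(res2$statistic, 0, tolerance = 1e-12)

  # hand-computed chi-squared for {{20,5},{5,20}}
  cat_v <- c(rep("x", 20), rep("y", 5), rep("x", 5), rep("y", 20))
  tab3 <- data.frame(cat = cat_v, grp = rep(c("a", "b"), each = 25))
  res3 <- group_difference(tab3, "grp", "cat")
  o <- matrix(c(20, 5, 5, 20), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(res3$statistic, sum((o - e)^2 / e), tolerance = 1e-12)

  expect_error(group_difference(tab, rep("a", 12), "v"), "binary")
})

test_that("profile similarity recovers identity and sign structure", {
  set.seed(55)
  n <- 20
  tab <- data.frame(age = rnorm(n), bmi = rnorm(n))
  rm <- cbind(r1 = rnorm(n), r2 = rnorm(n), r3 = rnorm(n))
  am <- clinical_matrix(tab, rm, c("age", "bmi"))
  res <- similarity_of_profiles(am, rm, tab, c("age", "bmi"),
                                n_perm = 200, seed = 3)
  expect_equal(res$r_sim, 1, tolerance = 1e-12)
  expect_equal(res$n_cells, 6)
  neg <- am$r * -1
  res2 <- similarity_of_profiles(neg, rm, tab, c("age", "bmi"),
                                 n_perm = 200, seed = 3)
  expect_equal(res2$r_sim, -1, tolerance = 1e-12)
  # reproducibility
  res3 <- similarity_of_profiles(am, rm, tab, c("age", "bmi"),
                                 n_perm = 200, seed = 3)
  expect_identical(res$p, res3$p)
})

test_that("similarity p-values are calibrated for independent structure", {
  set.seed(77)
  rej <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    n <- 25
    tab <- data.frame(age = rnorm(n), bmi = rnorm(n), grip = rnorm(n))
    rm_a <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(NULL, paste0("r", 1:4)))
    rm_m <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(NULL, paste0("r", 1:4)))
    mm <- clinical_matrix(tab, rm_m, c("age", "bmi", "grip"))
    p <- similarity_of_profiles(mm, rm_a, tab, c("age", "bmi", "grip"),
                                n_perm = 120, seed = i)$p
    if (p <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.035)
})
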