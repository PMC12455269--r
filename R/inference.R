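#' One-sample sign-flip permutation test of |Fisher z| against an
#' effect-size null
#'
#' Tests whether the absolute per-subject Fisher-transformed voxel-wise
#' correlations exceed a medium effect-size threshold `r0` (default 0.3,
#' placed on the Fisher-z scale as `atanh(r0)`). The statistic is the
#' one-sample t value of `d_i = |z_i| - atanh(r0)`; its null distribution
#' is built by randomly sign-flipping the `d_i` (valid when d is symmetric
#' about 0 under the null). The rejection region is one-sided
#' (`T* >= T_obs`).
#'
#' For `n <= 20` subjects all `2^n` sign patterns are enumerated and the
#' p-value is the exact pattern fraction `#\{T* >= T\} / 2^n` (the identity
#' pattern counts, so p > 0). Otherwise `n_perm` random sign vectors are
#' drawn and the Phipson-Smyth smoothed estimate
#' `(1 + #\{T* >= T\}) / (1 + n_perm)` is returned.
#'
#' Degenerate case: if every `d_i` is exactly 0 the statistic is defined as
#' 0 and p = 1. If all `d_i` are equal and non-zero, the observed sd is 0
#' and T is +/-Inf; the enumeration handles this through IEEE comparisons
#' (only the all-same-sign pattern reaches +/-Inf).
#'
#' @param z per-subject Fisher z values for one (ROI, modality) cell.
#' @param r0 effect-size null on the correlation scale; default 0.3.
#' @param n_perm random sign flips when enumeration is infeasible;
#'   default 10000.
#' @param seed integer seed for the random branch.
#' @param exhaustive_limit largest n for exhaustive enumeration (default 20).
#' @return Object of class `effect_size_test`: list with `n`, `mean_abs_r`,
#'   `mean_abs_z`, `t_stat`, `p`, `n_perm` (actual null size), `exhaustive`,
#'   `r0`, `seed`.
#' @export
signflip_effect_size_test <- function(z, r0 = 0.3, n_perm = 10000,
                                      seed = 1, exhaustive_limit = 20) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 3) stop("need at least 3 finite z values", call. = FALSE)
  if (r0 <= 0 || r0 >= 1) stop("r0 must lie in (0, 1)", call. = FALSE)
  d <- abs(z) - atanh(r0)
  ssq <- sum(d^2)

  t_from_mean <- function(mn) {
    # sum d_i^2 is invariant under sign flips, so sd* follows from mean*
    v <- (ssq - n * mn^2) / (n - 1)
    v <- pmax(v, 0)
    se <- sqrt(v / n)
    ifelse(se > 0, mn / se, ifelse(mn > 0, Inf, ifelse(mn < 0, -Inf, 0)))
  }

  if (all(d == 0)) {
    res <- list(t_stat = 0, p = 1, n_perm = 0L, exhaustive = TRUE)
  } else if (n <= exhaustive_limit) {
    total <- 2^n
    chunk <- 2^13
    starts <- seq(0, total - 1, by = chunk)
    pow <- 2^(seq_len(n) - 1)
    t_obs <- NULL
    count <- 0
    for (s0 in starts) {
      ids <- s0 + seq_len(min(chunk, total - s0)) - 1
      signs <- 1 - 2 * (outer(ids, pow, function(a, b) (a %/% b) %% 2))
      mn <- as.numeric(signs %*% d) / n
      ts <- t_from_mean(mn)
      # the identity pattern (all +1) is id 0: its T* is the observed
      # statistic on the same floating-point path as the null values.
      # Structural ties (equal |d| values) are counted as extreme via a
      # small relative tolerance, keeping the test conservative.
      if (s0 == 0) t_obs <- ts[1]
      thr <- if (is.finite(t_obs)) t_obs - 1e-12 * (1 + abs(t_obs)) else t_obs
      count <- count + sum(ts >= thr)
    }
    res <- list(t_stat = t_obs, p = count / total,
                n_perm = as.integer(total), exhaustive = TRUE)
  } else {
    t_obs <- t_from_mean(mean(d))
    set.seed(as.integer(seed))
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    mn <- as.numeric(signs %*% d) / n
    thr <- if (is.finite(t_obs)) t_obs - 1e-12 * (1 + abs(t_obs)) else t_obs
    count <- sum(t_from_mean(mn) >= thr)
    res <- list(t_stat = t_obs, p = (1 + count) / (1 + n_perm),
                n_perm = as.integer(n_perm), exhaustive = FALSE)
  }
  structure(c(list(n = n, mean_abs_r = mean(abs(tanh(z))),
                   mean_abs_z = mean(abs(z)), r0 = r0, seed = seed), res),
            class = "effect_size_test")
}

#' @export
print.effect_size_test <- function(x, ...) {
  cat(sprintf(
    "Sign-flip effect-size test: n %d, mean |r| %.3f, T %.3f, p %.4g (%s null of %d)\n",
    x$n, x$mean_abs_r, x$t_stat, x$p,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm))
  invisible(x)
}

# all n! permutations of 1..n, one per row, in a deterministic order:
# each value leads in turn, followed by the permutations of the rest
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(v) {
    rest <- sub
    rest[rest >= v] <- rest[rest >= v] + 1L
    cbind(v, rest, deparse.level = 0)
  }))
}

#' Permutation test of a Pearson correlation
#'
#' Two-sided test on `|r|` built by permuting `y` against `x`. For
#' `n <= 7` pairwise-complete pairs, all `n!` permutations are enumerated
#' and the p-value is the exact fraction `#\{|r*| >= |r_obs|\} / n!`;
#' otherwise `n_perm` random permutations are drawn with Phipson-Smyth
#' smoothing `(1 + count) / (1 + n_perm)`.
#'
#' @param x,y subject-value vectors (pairwise-complete pairs used).
#' @param n_perm random permutations, default 10000.
#' @param seed integer seed for the random branch.
#' @param exhaustive_limit largest n for exhaustive enumeration (default 7).
#' @return List with `r`, `p`, `n`, `n_perm`, `exhaustive`, `seed`.
#' @export
permutation_corr_test <- function(x, y, n_perm = 10000, seed = 1,
                                  exhaustive_limit = 7) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairwise-complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input", call. = FALSE)
  }
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  r_of <- function(yy) {
    yc <- yy - mean(yy)
    sum(xc * yc) / (sx * sqrt(sum(yc^2)))
  }
  r_obs <- r_of(y)
  if (n <= exhaustive_limit) {
    perms <- .all_permutations(n)
    rs <- apply(perms, 1, function(idx) r_of(y[idx]))
    p <- sum(abs(rs) >= abs(r_obs)) / nrow(perms)
    list(r = r_obs, p = p, n = n, n_perm = nrow(perms),
         exhaustive = TRUE, seed = seed)
  } else {
    set.seed(as.integer(seed))
    count <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(r_of(y[sample.int(n)])) >= abs(r_obs)) count <- count + 1L
    }
    list(r = r_obs, p = (1 + count) / (1 + n_perm), n = n,
         n_perm = as.integer(n_perm), exhaustive = FALSE, seed = seed)
  }
}

#' Group differences in clinical variables
#'
#' Continuous variables are compared with a pooled-variance two-sample
#' two-tailed Student's t test; categorical variables with a Pearson
#' chi-squared test without continuity correction. FDR adjustment (Storey
#' q-values) is applied across all variables in the call.
#'
#' @param table data.frame of per-subject values.
#' @param group binary grouping vector (or name of a column in `table`).
#' @param variables column names to test.
#' @param pi0 passed to [storey_fdr()]; `NULL` estimates pi0.
#' @return data.frame with `variable`, `type`, `statistic`, `p`, `q`.
#' @export
group_difference <- function(table, group, variables, pi0 = NULL) {
  if (is.character(group) && length(group) == 1) group <- table[[group]]
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must be binary", call. = FALSE)
  if (any(tabulate(g) == 0)) stop("empty group", call. = FALSE)
  rows <- lapply(variables, function(v) {
    val <- table[[v]]
    if (is.numeric(val)) {
      ok <- is.finite(val)
      if (min(table(g[ok])) < 2) {
        stop(sprintf("variable '%s': each group needs >= 2 values", v),
             call. = FALSE)
      }
      tt <- stats::t.test(val[ok] ~ g[ok], var.equal = TRUE)
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      ok <- !is.na(val)
      ct <- suppressWarnings(
        stats::chisq.test(table(g[ok], val[ok]), correct = FALSE))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ct$statistic), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  # chi-squared on a no-association table yields p = 1 exactly; keep in (0,1]
  out$q <- as.numeric(storey_fdr(pmin(out$p, 1), pi0 = pi0))
  out
}

#' Similarity of a metric's clinical-association profile to the amyloid
#' profile
#'
#' The clinical-association matrix of one MRI metric (ROIs x clinical
#' variables, Pearson r) is vectorised and correlated with the vectorised
#' amyloid clinical-association matrix computed from per-subject ROI-mean
#' amyloid values. Significance is assessed by permuting the amyloid
#' ROI-mean rows across subjects, recomputing the amyloid matrix each time,
#' and comparing `|r_sim*|` with the observed value (two-sided,
#' Phipson-Smyth smoothing). The permutation scheme is this package's
#' construction for the vectorised-matrix statistic.
#'
#' @param metric_matrix a `clinical_matrix` (or its `r` matrix) for one
#'   MRI metric.
#' @param amyloid_roi_means matrix (subjects x ROIs) of per-subject
#'   ROI-mean amyloid values.
#' @param cohort_table clinical data.frame, rows aligned with
#'   `amyloid_roi_means`.
#' @param variables clinical columns used in the matrices.
#' @param n_perm number of subject-level permutations, default 10000.
#' @param seed integer seed.
#' @return Object of class `similarity_result`: list with `r_sim`, `p`,
#'   `n_cells`, `amyloid_matrix`.
#' @export
similarity_of_profiles <- function(metric_matrix, amyloid_roi_means,
                                   cohort_table, variables = NULL,
                                   n_perm = 10000, seed = 1) {
  mm <- if (inherits(metric_matrix, "clinical_matrix")) metric_matrix$r
        else as.matrix(metric_matrix)
  if (is.null(variables)) {
    num <- vapply(cohort_table, is.numeric, logical(1))
    variables <- setdiff(names(cohort_table)[num], c("subject_id", "group"))
  }
  am <- clinical_matrix(cohort_table, amyloid_roi_means, variables)
  if (!identical(dimnames(mm), dimnames(am$r))) {
    stop("metric and amyloid matrices must share row/col labels",
         call. = FALSE)
  }
  perm_mats <- .permuted_amyloid_matrices(amyloid_roi_means, cohort_table,
                                          variables, n_perm, seed)
  null_rs <- .similarity_null(mm, am$r, perm_mats)
  r_obs <- null_rs$observed
  p <- (1 + sum(abs(null_rs$null) >= abs(r_obs))) / (1 + n_perm)
  structure(list(r_sim = r_obs, p = p, n_cells = null_rs$n_cells,
                 amyloid_matrix = am, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "similarity_result")
}

# Precompute the subject-permutation null of the amyloid clinical matrix:
# one permuted (ROIs x variables) Pearson matrix per draw, stored as a
# (n_perm x cells) matrix so several metric profiles can reuse one null.
# The missingness pattern of the clinical table is fixed, so per-cell n is
# invariant under row permutation of roi_means.
.permuted_amyloid_matrices <- function(roi_means, cohort_table, variables,
                                       n_perm, seed) {
  cmat <- as.matrix(cohort_table[, variables, drop = FALSE])
  ns <- nrow(roi_means)
  set.seed(as.integer(seed))
  out <- matrix(NA_real_, n_perm, ncol(roi_means) * length(variables))
  for (b in seq_len(n_perm)) {
    pm <- suppressWarnings(
      stats::cor(roi_means[sample.int(ns), , drop = FALSE], cmat,
                 use = "pairwise.complete.obs"))
    out[b, ] <- as.numeric(pm)
  }
  out
}

# observed r_sim of a metric profile plus its null, given precomputed
# permuted amyloid matrices
.similarity_null <- function(mm, amyloid_r, perm_mats) {
  shared <- which(is.finite(mm) & is.finite(amyloid_r))
  if (length(shared) < 3) {
    stop("need at least 3 shared non-missing cells", call. = FALSE)
  }
  obs <- .pearson(mm[shared], amyloid_r[shared])
  v1 <- mm[shared]
  pm <- perm_mats[, shared, drop = FALSE]
  ok <- rowSums(!is.finite(pm)) == 0
  pm <- pm[ok, , drop = FALSE]
  v1c <- v1 - mean(v1)
  s1 <- sqrt(sum(v1c^2))
  pmc <- pm - rowMeans(pm)
  null <- as.numeric(pmc %*% v1c) / (s1 * sqrt(rowSums(pmc^2)))
  list(observed = obs, null = null[is.finite(null)],
       n_cells = length(shared))
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Profile similarity: r_sim %.3f over %d cells, p %.4g\n",
              x$r_sim, x$n_cells, x$p))
  invisible(x)
}
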