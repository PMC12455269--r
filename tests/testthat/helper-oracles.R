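# Independent oracle implementations, deliberately coded from the defining
# formulas (not by calling package internals), used to cross-check the
# package's computations.

# Pearson correlation straight from the definitional formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Kendall's coefficient of concordance computed term by term:
# n judges (voxels) rank m objects (time points); mid-ranks for ties with
# the tie-correction term
kendall_w_oracle <- function(series_matrix) {
  n <- nrow(series_matrix)
  m <- ncol(series_matrix)
  rk <- t(apply(series_matrix, 1, rank))
  rt <- numeric(m)
  for (t in seq_len(m)) rt[t] <- sum(rk[, t])
  s <- sum((rt - mean(rt))^2)
  tie <- 0
  for (j in seq_len(n)) {
    for (cnt in table(series_matrix[j, ])) tie <- tie + cnt^3 - cnt
  }
  12 * s / (n^2 * (m^3 - m) - n * tie)
}

# Exhaustive sign-flip null via expand.grid over all sign patterns
signflip_p_oracle <- function(d) {
  n <- length(d)
  t_of <- function(x) mean(x) / (sd(x) / sqrt(n))
  t_obs <- t_of(d)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  ts <- apply(grid, 1, function(s) t_of(s * d))
  sum(ts >= t_obs) / nrow(grid)
}

# Benjamini-Hochberg step-up directly from the sorted definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) {
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force weighted degree centrality: enumerate every pair, keep the
# top ceiling(sparsity * #positive) positive correlations (ties by edge
# order), and sum incident weights
wdece_oracle <- function(series_matrix, sparsity) {
  n <- nrow(series_matrix)
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- cor(series_matrix[i, ], series_matrix[j, ])
      edges <- rbind(edges, c(i, j, r))
    }
  }
  pos <- edges[edges[, 3] > 0, , drop = FALSE]
  if (nrow(pos) == 0) return(numeric(n))
  k <- ceiling(sparsity * nrow(pos))
  keep <- pos[order(-pos[, 3], seq_len(nrow(pos)))[seq_len(k)], ,
              drop = FALSE]
  deg <- numeric(n)
  for (e in seq_len(nrow(keep))) {
    deg[keep[e, 1]] <- deg[keep[e, 1]] + keep[e, 3]
    deg[keep[e, 2]] <- deg[keep[e, 2]] + keep[e, 3]
  }
  deg
}

# Closed-form fractional anisotropy from eigenvalues
fa_oracle <- function(lambda) {
  lb <- mean(lambda)
  sqrt(3 / 2) * sqrt(sum((lambda - lb)^2)) / sqrt(sum(lambda^2))
}

# A small cohort configuration usable in exact mode (n >= p + 2) on a
# coarse 8^3 analysis grid with three ROIs
tiny_config <- function(mode = "exact", n_subjects = 14, ...) {
  rois <- c("entorhinal", "temporal", "whole_cortex")
  vars <- c("age", "bmi", "grip_strength", "fluid_cognition",
            "crystallised_cognition")
  ids <- c(paste0("amyloid_", rois), vars)
  r <- diag(length(ids))
  dimnames(r) <- list(ids, ids)
  r[1:3, 1:3] <- 0.5
  diag(r) <- 1
  r["amyloid_entorhinal", "bmi"] <- r["bmi", "amyloid_entorhinal"] <- 0.4
  rho <- default_target_rho()[rois, c("atlas", "fa", "md")]
  geometry <- list(
    entorhinal = list(lo = c(1, 1, 1), hi = c(3, 3, 2)),
    temporal = list(lo = c(5, 1, 1), hi = c(8, 4, 3)),
    whole_cortex = list(lo = c(1, 5, 4), hi = c(6, 8, 8))
  )
  cohort_config(n_subjects = n_subjects, grid_hires = c(16, 16, 16),
                factor = 2, mode = mode, target_voxel_rho = rho,
                clinical_corr = r, roi_geometry = geometry,
                reference_geometry = list(lo = c(5, 5, 1), hi = c(8, 8, 2)),
                ...)
}
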