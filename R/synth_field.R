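#' Generate a field with an exact sample correlation to a base field
#'
#' Construction: standardise the base; draw Gaussian noise; residualise the
#' noise against the base (and the constant), restandardise; mix with
#' weights `rho` and `sqrt(1 - rho^2)`. Because the noise component is
#' exactly orthogonal to the base in the sample, the sample Pearson
#' correlation of output and base equals `rho` to floating-point precision.
#' This is the primitive the synthetic cohort uses to impose known
#' voxel-wise correlation structure.
#'
#' @param base numeric vector of voxel values (length >= 3, non-constant).
#' @param rho target sample correlation, strictly inside `(-1, 1)`.
#' @param seed integer seed for the noise draw.
#' @return Numeric vector of the same length, with sample mean 0 and sample
#'   standard deviation 1, whose sample correlation with `base` is `rho`.
#' @export
forced_correlation_field <- function(base, rho, seed) {
  if (length(base) < 3) stop("base must have at least 3 voxels", call. = FALSE)
  if (!all(is.finite(base))) stop("base must be finite", call. = FALSE)
  if (stats::sd(base) == 0) stop("zero-variance base", call. = FALSE)
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("rho must lie strictly inside (-1, 1)", call. = FALSE)
  }
  n <- length(base)
  b <- (base - mean(base)) / stats::sd(base)
  set.seed(as.integer(seed))
  repeat {
    e <- stats::rnorm(n)
    e <- e - mean(e)
    e <- e - b * (sum(e * b) / sum(b * b))
    if (stats::sd(e) > 0) break
  }
  e <- e / stats::sd(e)
  y <- rho * b + sqrt(1 - rho^2) * e
  y / stats::sd(y)
}

# Population-correlation analogue: mixes standardised base with fresh noise
# using population weights, so the sample correlation fluctuates around rho
# with sd ~ (1 - rho^2) / sqrt(n). Used by the cohort generator's sampling
# mode.
.sampled_correlation_field <- function(base, rho, seed) {
  if (stats::sd(base) == 0) stop("zero-variance base", call. = FALSE)
  n <- length(base)
  b <- (base - mean(base)) / stats::sd(base)
  set.seed(as.integer(seed))
  rho * b + sqrt(1 - rho^2) * stats::rnorm(n)
}
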