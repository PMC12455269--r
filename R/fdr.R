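#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the null proportion pi0 from the p-value distribution on the
#' lambda grid 0.05, 0.10, ..., 0.95 -- `pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda))` -- smooths `pi0(lambda)` with a cubic smoothing spline
#' (df = 3) and evaluates it at the largest lambda, capping at 1. Q-values
#' are then the step-up quantities `pi0 * m * p_(i) / i`, enforced monotone
#' non-decreasing in sorted p. Supplying `pi0 = 1` reduces the procedure
#' exactly to Benjamini-Hochberg step-up values.
#'
#' @param p p-values in `(0, 1]`.
#' @param pi0 optional fixed null proportion; `NULL` (default) estimates it.
#' @param lambda grid for pi0 estimation.
#' @return Numeric vector of q-values in the original order, with attribute
#'   `pi0`.
#' @export
storey_fdr <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    # guard rails: cap at 1, floor at 1/m so q-values stay positive when
    # every p is small
    pi0 <- min(1, max(pi0, 1 / m))
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]", call. = FALSE)
  }
  o <- order(p)
  ps <- p[o]
  q <- pi0 * m * ps / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}
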