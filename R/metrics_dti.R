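#' Fit a diffusion tensor by constrained weighted linear least squares
#'
#' Log-transformed signals are fitted to the log-linear tensor design; an
#' ordinary least-squares solution initialises the weights, which are then
#' set to the squared model-predicted signals and the fit re-solved for
#' `iterations` rounds (weighted linear least squares, WLLS). The
#' constraint is applied spectrally: negative eigenvalues of the fitted
#' tensor are clipped to zero, and fractional anisotropy (FA) and mean
#' diffusivity (MD) are computed from the clipped spectrum.
#'
#' Non-positive signals are clipped to a documented floor of
#' `1e-6 * max(signal)` before the log transform.
#'
#' @param signals numeric vector of per-gradient signals for one voxel.
#' @param gradients a [gradient_table()]; at least 7 measurements including
#'   at least one b0.
#' @param iterations number of reweighting rounds (default 2).
#' @return An object of class `tensor_fit`: list with `s0`, `D` (3x3
#'   symmetric, mm^2/s), `evals` (clipped, decreasing), `fa`, `md`.
#' @examples
#' gt <- default_gradient_table()
#' D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
#' tf <- array(c(D[1,1], D[2,2], D[3,3], 0, 0, 0), c(1, 1, 1, 6))
#' sig <- generate_dwi_signals(tf, gt, s0 = 1000, noise_sd = 0)
#' fit <- fit_dti_wlls(sig$signals[1, 1, 1, ], gt)
#' c(fit$fa, fit$md)
#' @export
fit_dti_wlls <- function(signals, gradients, iterations = 2) {
  stopifnot(inherits(gradients, "gradient_table"))
  b <- gradients$bvals
  g <- gradients$bvecs
  if (length(signals) != length(b)) {
    stop("signal and gradient counts differ", call. = FALSE)
  }
  if (length(b) < 7 || !any(b == 0)) {
    stop("need at least 7 measurements including one b0", call. = FALSE)
  }
  s <- as.numeric(signals)
  floor_val <- 1e-6 * max(s, na.rm = TRUE)
  if (!is.finite(floor_val) || floor_val <= 0) {
    stop("signals contain no positive values", call. = FALSE)
  }
  s <- pmax(s, floor_val)
  x <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(x)$rank < 7) stop("insufficient gradient scheme", call. = FALSE)
  y <- log(s)
  beta <- qr.solve(x, y)
  for (it in seq_len(iterations)) {
    w <- exp(x %*% beta)^2  # squared predicted signals (up to s0 scale)
    xw <- x * as.numeric(w)
    beta <- solve(crossprod(x, xw), crossprod(xw, y))
  }
  beta <- as.numeric(beta)
  d <- .tensor_from_vec(beta[c(2, 3, 4, 5, 6, 7)])
  ev <- eigen(d, symmetric = TRUE, only.values = TRUE)$values
  ev_clipped <- sort(pmax(ev, 0), decreasing = TRUE)
  md <- mean(ev_clipped)
  ss <- sum(ev_clipped^2)
  fa <- if (ss == 0) 0 else {
    sqrt(1.5) * sqrt(sum((ev_clipped - md)^2)) / sqrt(ss)
  }
  structure(list(s0 = exp(beta[1]), D = d, evals = ev_clipped,
                 fa = fa, md = md),
            class = "tensor_fit")
}

#' Fit FA and MD maps over a 4D DWI volume
#'
#' Applies [fit_dti_wlls()] voxel-wise within a mask.
#'
#' @param dwi 4D array `c(shape, n_gradients)`.
#' @param gradients a [gradient_table()].
#' @param mask logical 3D array or NULL for all voxels.
#' @param iterations reweighting rounds passed through.
#' @return List of 3D arrays `fa` and `md` (NA outside the mask).
#' @export
fit_dti_volume <- function(dwi, gradients, mask = NULL, iterations = 2) {
  d <- dim(dwi)
  stopifnot(length(d) == 4)
  shape <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  .check_same_grid(array(0, shape), mask, "DWI and mask")
  fa <- array(NA_real_, shape)
  md <- array(NA_real_, shape)
  flat <- matrix(dwi, prod(shape), d[4])
  for (v in which(as.logical(mask))) {
    fit <- fit_dti_wlls(flat[v, ], gradients, iterations)
    fa[v] <- fit$fa
    md[v] <- fit$md
  }
  list(fa = fa, md = md)
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("Diffusion tensor fit: FA %.4f, MD %.4g mm^2/s\n", x$fa, x$md))
  invisible(x)
}
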