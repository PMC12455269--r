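#' Build the default two-shell gradient table
#'
#' Emulates the study's diffusion acquisition: b = 1500 and 3000 s/mm^2
#' across 93 directions plus 7 interleaved b0 volumes. Directions are
#' quasi-uniform points on the sphere from a Fibonacci lattice, split 46/47
#' between the two shells; the table is deterministic.
#'
#' @param n_dirs total number of diffusion-weighted directions (default 93).
#' @param n_b0 number of b0 volumes (default 7).
#' @param shells b-values of the two shells in s/mm^2.
#' @return A `gradient_table`: list with `bvals` (length `n_dirs + n_b0`)
#'   and `bvecs` (3-column matrix of unit vectors; zero rows for b0).
#' @export
default_gradient_table <- function(n_dirs = 93, n_b0 = 7,
                                   shells = c(1500, 3000)) {
  stopifnot(n_dirs >= 6, n_b0 >= 1, all(shells > 0))
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n1 <- floor(n_dirs / 2)
  bvals <- c(rep(0, n_b0),
             rep(shells[1], n1),
             rep(shells[2], n_dirs - n1))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  gradient_table(bvals, bvecs)
}

#' Construct and validate a gradient table
#'
#' @param bvals non-negative b-values in s/mm^2.
#' @param bvecs matrix (n x 3) of gradient directions; unit norm where
#'   b > 0, zero rows allowed for b = 0.
#' @return A validated `gradient_table` object.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3) stop("bvecs must have 3 columns", call. = FALSE)
  if (length(bvals) != nrow(bvecs)) {
    stop("bvals and bvecs counts differ", call. = FALSE)
  }
  if (any(bvals < 0)) stop("negative b-value", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    stop(sprintf("%d non-b0 direction(s) are not unit-norm", sum(bad)),
         call. = FALSE)
  }
  dimnames(bvecs) <- NULL
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_table")
}

#' Generate a smooth positive-semidefinite diffusion-tensor field
#'
#' Tensors are built as `D = R diag(lambda) R'` with random rotations and
#' eigenvalues drawn around physiological white/grey-matter diffusivities
#' (order 1e-3 mm^2/s), guaranteeing positive semidefiniteness by
#' construction.
#'
#' @param shape 3D grid dimensions.
#' @param seed integer seed.
#' @param lambda_range range of eigenvalue draws in mm^2/s.
#' @return Array `c(shape, 6)` of tensor components in the fixed order
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @export
random_tensor_field <- function(shape, seed = 1,
                                lambda_range = c(0.2e-3, 2.2e-3)) {
  stopifnot(length(shape) == 3)
  set.seed(as.integer(seed))
  n <- prod(shape)
  out <- matrix(0, n, 6)
  for (v in seq_len(n)) {
    lam <- sort(stats::runif(3, lambda_range[1], lambda_range[2]),
                decreasing = TRUE)
    a <- matrix(stats::rnorm(9), 3, 3)
    q <- qr.Q(qr(a))
    d <- q %*% diag(lam) %*% t(q)
    out[v, ] <- c(d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3])
  }
  array(out, c(shape, 6))
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Standard monoexponential tensor model `S = S0 * exp(-b g' D g)` per voxel
#' and gradient, with optional additive Gaussian noise. At `noise_sd = 0`
#' signals are exactly the model prediction, so a weighted-least-squares fit
#' recovers the tensors to numerical precision.
#'
#' @param tensor_field array `c(shape, 6)` of tensor components
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in mm^2/s; tensors must be positive
#'   semidefinite.
#' @param gradients a [gradient_table()].
#' @param s0 baseline (b = 0) signal, positive.
#' @param seed integer seed for the noise draw.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @return List with `signals` (4D array `c(shape, n_gradients)`) and
#'   `gradients` (the table passed in).
#' @export
generate_dwi_signals <- function(tensor_field, gradients, s0 = 1000,
                                 seed = 1, noise_sd = 0) {
  stopifnot(inherits(gradients, "gradient_table"), s0 > 0, noise_sd >= 0)
  d <- dim(tensor_field)
  if (length(d) != 4 || d[4] != 6) {
    stop("tensor_field must be an array with 6 component planes",
         call. = FALSE)
  }
  shape <- d[1:3]
  n <- prod(shape)
  tmat <- matrix(tensor_field, n, 6)
  # PSD check on the stated eigen structure
  for (v in seq_len(min(n, 64))) {
    dd <- .tensor_from_vec(tmat[v, ])
    if (min(eigen(dd, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      stop("tensor field contains non-positive-semidefinite tensors",
           call. = FALSE)
    }
  }
  b <- gradients$bvals
  g <- gradients$bvecs
  # quadratic-form design: g' D g for the packed component order
  q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  expo <- tmat %*% t(q * b)  # n_vox x n_grad
  sig <- s0 * exp(-expo)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    sig <- sig + stats::rnorm(length(sig), sd = noise_sd)
  }
  list(signals = array(sig, c(shape, length(b))), gradients = gradients)
}

.tensor_from_vec <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}
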