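#' Regional homogeneity (ReHo) as Kendall's coefficient of concordance
#'
#' For every voxel inside the mask, the time courses of the voxel and its
#' cubic neighbourhood (truncated at mask and volume borders) are ranked
#' within-voxel over time (mid-ranks for ties), and Kendall's W is computed:
#' `W = 12 * S / (n^2 (m^3 - m) - n * T)` with `n` neighbourhood voxels,
#' `m` time points, `S` the sum of squared deviations of the per-time rank
#' sums from their mean, and `T` the tie-correction sum. `W` lies in
#' `[0, 1]`. Neighbourhoods where W is undefined (all series constant, or
#' fewer than 2 voxels available) emit 0 and are counted in the
#' `degenerate_count` attribute.
#'
#' @param series 4D numeric array (3D grid x time).
#' @param mask logical 3D array or NULL for all voxels.
#' @param neighbourhood 7, 19 or 27: faces only, faces+edges, or the full
#'   3x3x3 cube, in each case including the centre voxel.
#' @return 3D array of W values in `[0, 1]` (NA outside the mask), with
#'   attribute `degenerate_count`.
#' @export
compute_reho <- function(series, mask = NULL, neighbourhood = 27) {
  d <- dim(series)
  stopifnot(length(d) == 4)
  if (d[4] < 2) stop("need at least 2 time points", call. = FALSE)
  if (!neighbourhood %in% c(7, 19, 27)) {
    stop("neighbourhood must be one of 7, 19, 27", call. = FALSE)
  }
  shape <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  .check_same_grid(array(0, shape), mask, "series grid and mask")

  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  off <- switch(as.character(neighbourhood),
                "7"  = off[ord <= 1, , drop = FALSE],
                "19" = off[ord <= 2, , drop = FALSE],
                "27" = off)

  m <- d[4]
  flat <- matrix(series, prod(shape), m)
  # within-voxel time ranks with mid-ranks for ties, precomputed once
  ranks <- matrix(NA_real_, prod(shape), m)
  vox_idx <- which(as.logical(mask))
  for (v in vox_idx) ranks[v, ] <- rank(flat[v, ], ties.method = "average")
  # per-voxel tie correction sum(t^3 - t) over tie groups
  tie_corr <- numeric(prod(shape))
  for (v in vox_idx) {
    tab <- table(flat[v, ])
    tie_corr[v] <- sum(tab^3 - tab)
  }

  out <- array(NA_real_, shape)
  degenerate <- 0L
  lin <- function(i, j, k) i + (j - 1) * shape[1] + (k - 1) * shape[1] * shape[2]
  for (v in vox_idx) {
    k <- (v - 1) %/% (shape[1] * shape[2]) + 1
    rem <- (v - 1) %% (shape[1] * shape[2])
    j <- rem %/% shape[1] + 1
    i <- rem %% shape[1] + 1
    ni <- i + off[, 1]; nj <- j + off[, 2]; nk <- k + off[, 3]
    ok <- ni >= 1 & ni <= shape[1] & nj >= 1 & nj <= shape[2] &
      nk >= 1 & nk <= shape[3]
    nb <- lin(ni[ok], nj[ok], nk[ok])
    nb <- nb[mask[nb]]
    n <- length(nb)
    if (n < 2) {
      out[v] <- 0
      degenerate <- degenerate + 1L
      next
    }
    rt <- colSums(ranks[nb, , drop = FALSE])
    s <- sum((rt - mean(rt))^2)
    denom <- n^2 * (m^3 - m) - n * sum(tie_corr[nb])
    if (denom <= 0) {
      out[v] <- 0
      degenerate <- degenerate + 1L
    } else {
      out[v] <- min(1, max(0, 12 * s / denom))
    }
  }
  if (degenerate > 0) {
    message(sprintf("compute_reho: %d degenerate neighbourhood(s) set to 0",
                    degenerate))
  }
  attr(out, "degenerate_count") <- degenerate
  out
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Each voxel's series is demeaned, linearly detrended and Hann-tapered,
#' then transformed with the discrete Fourier transform and summarised as
#' the ratio of summed spectral amplitude (square root of periodogram
#' power) over the frequency band to the summed amplitude over all
#' positive-frequency bins (the zero-frequency bin is excluded from the
#' denominator). The taper confines the spectral leakage of oscillations
#' whose period does not divide the scan length, which would otherwise
#' smear amplitude far outside the band; a tapered periodogram leaves the
#' flat expectation for white noise unchanged. Values lie in `[0, 1]`;
#' constant series emit 0 with a logged count.
#'
#' @param series 4D numeric array with attribute `tr`, or pass `tr`.
#' @param tr repetition time in seconds.
#' @param band frequency band in Hz, default `c(0.01, 0.1)`.
#' @param mask logical 3D array or NULL for all voxels.
#' @return 3D array of fALFF values (NA outside the mask), attribute
#'   `degenerate_count`.
#' @export
compute_falff <- function(series, tr = attr(series, "tr"),
                          band = c(0.01, 0.1), mask = NULL) {
  d <- dim(series)
  stopifnot(length(d) == 4)
  if (is.null(tr) || tr <= 0) stop("tr must be positive", call. = FALSE)
  m <- d[4]
  if (band[2] > 1 / (2 * tr) + 1e-12) {
    stop("band upper edge exceeds the Nyquist frequency", call. = FALSE)
  }
  nf <- m %/% 2
  freqs <- seq_len(nf) / (m * tr)
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) {
    stop("no Fourier bins inside the requested band at this length/TR",
         call. = FALSE)
  }
  shape <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  .check_same_grid(array(0, shape), mask, "series grid and mask")

  flat <- t(matrix(series, prod(shape), m))  # time x voxel
  vox_idx <- which(as.logical(mask))
  flat <- flat[, vox_idx, drop = FALSE]
  # demean + linear detrend via projection onto [1, t]
  tt <- seq_len(m) - (m + 1) / 2
  x <- cbind(1, tt)
  flat <- flat - x %*% solve(crossprod(x), crossprod(x, flat))
  # periodic Hann: a component on an exact Fourier bin spreads over exactly
  # three bins, so the generator's one-bin band guard contains it
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / m))
  amp <- Mod(stats::mvfft(flat * hann))[1 + seq_len(nf), , drop = FALSE]
  denom <- colSums(amp)
  num <- colSums(amp[in_band, , drop = FALSE])
  vals <- ifelse(denom > 0, num / denom, 0)
  degenerate <- sum(denom <= 0)
  if (degenerate > 0) {
    message(sprintf("compute_falff: %d constant series set to 0", degenerate))
  }
  out <- array(NA_real_, shape)
  out[vox_idx] <- vals
  attr(out, "degenerate_count") <- degenerate
  out
}

#' Weighted degree centrality (wDeCe) at a sparsity threshold
#'
#' All pairwise Pearson correlations among mask voxels' time courses form a
#' weighted graph; only positive-weight edges are candidates, and the top
#' `sparsity` fraction of them (exactly `ceiling(sparsity * n_positive)`
#' edges, ties broken deterministically by edge index) is retained. Each
#' voxel's wDeCe is the sum of retained edge weights incident to it.
#' Zero-variance voxels are excluded from the graph with a logged count and
#' emit 0.
#'
#' @param series 4D numeric array.
#' @param mask logical 3D array or NULL for all voxels.
#' @param sparsity fraction of positive edges to retain, in `(0, 1]`;
#'   default 0.1.
#' @return 3D array of degree sums (NA outside the mask), attributes
#'   `excluded_count` and `n_edges_retained`.
#' @export
compute_wdece <- function(series, mask = NULL, sparsity = 0.1) {
  d <- dim(series)
  stopifnot(length(d) == 4)
  if (sparsity <= 0 || sparsity > 1) {
    stop("sparsity must lie in (0, 1]", call. = FALSE)
  }
  shape <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  .check_same_grid(array(0, shape), mask, "series grid and mask")
  vox_idx <- which(as.logical(mask))
  if (length(vox_idx) < 2) stop("need at least 2 voxels in mask", call. = FALSE)
  flat <- matrix(series, prod(shape), d[4])[vox_idx, , drop = FALSE]
  sds <- apply(flat, 1, stats::sd)
  excluded <- sum(sds == 0)
  keep <- sds > 0
  if (excluded > 0) {
    message(sprintf("compute_wdece: excluded %d zero-variance voxel(s)",
                    excluded))
  }
  out <- array(NA_real_, shape)
  out[vox_idx] <- 0
  active <- vox_idx[keep]
  n <- length(active)
  n_ret <- 0L
  if (n >= 2) {
    cm <- stats::cor(t(flat[keep, , drop = FALSE]))
    iu <- which(upper.tri(cm))
    w <- cm[iu]
    pos <- which(w > 0)
    if (length(pos) > 0) {
      k <- as.integer(ceiling(sparsity * length(pos)))
      ord <- pos[order(-w[pos], pos)]
      sel <- ord[seq_len(k)]
      n_ret <- k
      deg <- numeric(n)
      rows <- ((iu[sel] - 1) %% n) + 1
      cols <- ((iu[sel] - 1) %/% n) + 1
      for (e in seq_along(sel)) {
        deg[rows[e]] <- deg[rows[e]] + w[sel[e]]
        deg[cols[e]] <- deg[cols[e]] + w[sel[e]]
      }
      out[active] <- deg
    }
  }
  attr(out, "excluded_count") <- excluded
  attr(out, "n_edges_retained") <- n_ret
  out
}

#' Screen a framewise-displacement series against a voxel-unit threshold
#'
#' A run fails if any frame's root-mean-squared voxel displacement strictly
#' exceeds `threshold_voxels * voxel_size` (a frame exactly at the boundary
#' passes).
#'
#' @param displacement per-frame RMS displacement in mm.
#' @param voxel_size voxel size in mm.
#' @param threshold_voxels threshold in voxel units, default 2.
#' @return List with `pass` (logical), `offending` (frame indices),
#'   `threshold_mm`.
#' @export
motion_screen <- function(displacement, voxel_size, threshold_voxels = 2) {
  if (!all(is.finite(displacement))) {
    stop("displacement series must be finite", call. = FALSE)
  }
  stopifnot(voxel_size > 0, threshold_voxels > 0)
  thr <- threshold_voxels * voxel_size
  bad <- which(displacement > thr)
  list(pass = length(bad) == 0, offending = bad, threshold_mm = thr)
}
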