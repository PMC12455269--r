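#' Generate a BOLD-like 4D series with controlled low-frequency band power
#'
#' Each voxel's series is synthesised in the frequency domain: random
#' amplitudes and phases are assigned to the discrete Fourier bins, with the
#' total spectral amplitude split between the low-frequency band
#' (0.01-0.1 Hz) and the out-of-band bins in proportion
#' `band_fraction : 1 - band_fraction`. The fractional amplitude of
#' low-frequency fluctuations (fALFF) of the generated voxels therefore
#' equals `band_fraction` in expectation. A `coupling` weight mixes every
#' voxel with one shared volume-wide signal of the same spectral profile, so
#' neighbouring voxels share signal and regional homogeneity (ReHo) is
#' monotone in `coupling`.
#'
#' @param shape 3D grid dimensions.
#' @param n_vols number of time points (>= 16).
#' @param tr repetition time in seconds (> 0). The study acquisition this
#'   emulates is 488 volumes at TR 0.8 s.
#' @param band_fraction target fraction of spectral amplitude inside
#'   0.01-0.1 Hz, in `[0, 1]`.
#' @param coupling shared-signal mixing weight in `[0, 1]`; 0 gives
#'   independent voxels.
#' @param seed integer seed.
#' @param band frequency band in Hz; default `c(0.01, 0.1)`.
#' @return 4D numeric array `c(shape, n_vols)` with attribute `tr`.
#' @export
generate_bold_volume <- function(shape, n_vols, tr, band_fraction,
                                 coupling = 0, seed = 1,
                                 band = c(0.01, 0.1)) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (n_vols < 16) stop("n_vols must be at least 16", call. = FALSE)
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  if (!is.finite(band_fraction) || band_fraction < 0 || band_fraction > 1) {
    stop("band_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (coupling < 0 || coupling > 1) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  m <- as.integer(n_vols)
  # positive-frequency bins, Nyquist bin (even m) left empty to avoid its
  # real-phase special case
  nf <- if (m %% 2 == 0) m %/% 2 - 1 else (m - 1) %/% 2
  df <- 1 / (m * tr)
  freqs <- seq_len(nf) * df
  # in-band amplitude is placed one bin inside the band edges so that the
  # one-bin-wide leakage of a tapered spectral estimate stays in-band
  in_band <- freqs >= band[1] + df & freqs <= band[2] - df
  if (!any(in_band)) in_band <- freqs >= band[1] & freqs <= band[2]
  out_band <- freqs < band[1] - df | freqs > band[2] + df
  if (!any(out_band)) out_band <- !(freqs >= band[1] & freqs <= band[2])
  if (band_fraction > 0 && !any(in_band)) {
    stop("no Fourier bins inside the requested band at this length/TR",
         call. = FALSE)
  }
  if (band_fraction < 1 && !any(out_band)) {
    stop("no Fourier bins outside the requested band at this length/TR",
         call. = FALSE)
  }
  n_vox <- prod(shape)
  set.seed(as.integer(seed))

  tt <- seq_len(m) - (m + 1) / 2
  # one spectral group (a set of Fourier bins) with random amplitudes and
  # phases, orthogonalised against the linear trend inside the group's own
  # span so that the metric's detrending step cannot smear amplitude across
  # the band boundary, then scaled to the requested total amplitude
  make_group <- function(bins, amp_total) {
    if (length(bins) == 0 || amp_total <= 0) return(numeric(m))
    a <- abs(stats::rnorm(length(bins))) + 1e-12
    ph <- stats::runif(length(bins), 0, 2 * pi)
    spec <- complex(length.out = m)
    spec[1 + bins] <- a * exp(1i * ph)
    spec[m + 1 - bins] <- Conj(spec[1 + bins])
    s <- Re(stats::fft(spec, inverse = TRUE))
    u <- sin(2 * pi * bins[1] * (seq_len(m) - 1) / m)
    bu <- sum(tt * u)
    if (abs(bu) > 1e-8) s <- s - (sum(tt * s) / bu) * u
    amp <- Mod(stats::fft(s))[1 + seq_len(nf)]
    s * amp_total / sum(amp)
  }
  make_signal <- function() {
    make_group(which(in_band), band_fraction) +
      make_group(which(out_band), 1 - band_fraction)
  }

  shared <- make_signal()
  out <- array(0, c(shape, m))
  flat <- matrix(0, n_vox, m)
  for (v in seq_len(n_vox)) {
    flat[v, ] <- sqrt(1 - coupling) * make_signal() + sqrt(coupling) * shared
  }
  out <- array(t(flat), c(m, shape))
  out <- aperm(out, c(2, 3, 4, 1))
  attr(out, "tr") <- tr
  out
}
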