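# analytic signal via FFT (Hilbert transform); x should be band-limited,
# mean-removed. Returns complex series.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# 10% cosine (Tukey) taper
tukey_taper <- function(n, frac = 0.1) {
  w <- rep(1, n)
  m <- max(1L, floor(frac * n / 2))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp
  w
}

# band-filter + analytic phase of one window
window_phase <- function(x, rate, band) {
  x <- (x - mean(x)) * tukey_taper(length(x))
  xf <- fft_bandpass(x, rate, band[1], band[2])
  Arg(analytic_signal(xf))
}

#' Phase-locking value of two series in a band
#'
#' `PLV = |mean_t exp(i (phi_x(t) - phi_y(t)))|` with analytic-signal phases
#' of the band-filtered, mean-removed, cosine-tapered inputs. 1 for a
#' constant phase difference, ~`1/sqrt(n)` for independent phases. Returns a
#' flagged `NA` if either channel has zero amplitude.
#'
#' @param x,y Equal-length numeric series.
#' @param rate Sampling rate, Hz.
#' @param band `c(low, high)` analysis band in Hz (within Nyquist).
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(x, y, rate, band) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, zero_amplitude = TRUE))
  dphi <- window_phase(x, rate, band) - window_phase(y, rate, band)
  Mod(mean(exp(1i * dphi)))
}

# Welch cross-spectral segments: complex cross-spectra of Hann-tapered
# segments (length len/2, 50% overlap) at the in-band frequency bins
cross_spectra <- function(x, y, rate, band, seg_len = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- max(8L, floor(n / 2))
  hop <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  freqs <- (1:floor(seg_len / 2)) * rate / seg_len
  bins <- which(freqs >= band[1] & freqs <= band[2]) + 1L
  if (!length(bins)) return(NULL)
  out <- matrix(0i, length(starts), length(bins))
  for (s in seq_along(starts)) {
    i <- starts[s]:(starts[s] + seg_len - 1L)
    X <- stats::fft((x[i] - mean(x[i])) * w)
    Y <- stats::fft((y[i] - mean(y[i])) * w)
    out[s, ] <- X[bins] * Conj(Y[bins])
  }
  out
}

#' Weighted phase-lag index of two series in a band
#'
#' `wPLI = |E[Im(S_xy)]| / E[|Im(S_xy)|]` over Welch cross-spectral segments
#' (half-window segments, 50% overlap, Hann taper) averaged across the
#' in-band frequency bins. 1 for a consistently lagged pair, 0 for zero-lag
#' (purely real cross-spectrum) coupling, and defined as 0 when the
#' denominator vanishes. Returns a flagged `NA` when a channel has zero
#' amplitude or no frequency bin falls inside the band.
#'
#' @inheritParams plv
#' @return wPLI in `[0, 1]`.
#' @export
wpli <- function(x, y, rate, band) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, zero_amplitude = TRUE))
  S <- cross_spectra(x, y, rate, band)
  if (is.null(S)) return(structure(NA_real_, no_bins_in_band = TRUE))
  im <- Im(S)
  den <- mean(abs(im))
  if (den == 0) return(0)
  abs(mean(im)) / den
}

#' Temporal-coherence flag for one window
#'
#' A window is temporally coherent (TC = 1) only if its gated coherence
#' statistic strictly exceeds the chosen percentile (default 75th) of the
#' surrogate null of the same statistic; ties fail the gate. Under the null
#' the flag rate is `1 - percentile/100` by construction.
#'
#' @param statistic Observed coherence statistic (e.g. mean pairwise wPLI).
#' @param surrogate_stats Numeric vector of >= 20 surrogate values of the
#'   same statistic.
#' @param percentile Gate percentile (default 75).
#' @return Integer 0/1.
#' @export
tc_flag <- function(statistic, surrogate_stats, percentile = 75) {
  surrogate_stats <- surrogate_stats[is.finite(surrogate_stats)]
  if (length(surrogate_stats) < 20)
    stop("need >= 20 surrogate values for the TC gate")
  thr <- stats::quantile(surrogate_stats, percentile / 100, names = FALSE)
  as.integer(is.finite(statistic) && statistic > thr)
}

# gate pairs: non-stim channel pairs with non-empty modality-band overlap.
# With cross_only, only cross-modality pairs are gated on: the
# temporal-coherence question is whether the distinct carrier streams bind
# within tau, and same-stream pairs couple at near-zero lag where the
# phase-lag index is insensitive by construction.
gate_pairs <- function(channels, cross_only = FALSE) {
  idx <- which(channels$modality != "stim")
  if (length(idx) < 2) return(NULL)
  cmb <- utils::combn(idx, 2)
  out <- data.frame(i = cmb[1, ], j = cmb[2, ])
  if (cross_only) {
    keep <- channels$modality[out$i] != channels$modality[out$j]
    if (any(keep)) out <- out[keep, , drop = FALSE]
  }
  out$lo <- pmax(channels$band_low[out$i], channels$band_low[out$j])
  out$hi <- pmin(channels$band_high[out$i], channels$band_high[out$j])
  out[out$lo < out$hi, , drop = FALSE]
}
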