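#' Phase-randomized surrogate of a time series
#'
#' Randomizes the Fourier phases of all non-DC, non-Nyquist bins while
#' keeping the amplitude spectrum bit-exact, so the surrogate preserves the
#' power spectrum and autocorrelation of the input but destroys any phase
#' structure (including cross-channel relations when channels are surrogated
#' independently). Output is real-valued. A constant series is returned
#' unchanged with attribute `degenerate = TRUE`.
#'
#' @param x Numeric series, length >= 8, finite.
#' @param seed Optional integer seed for reproducibility.
#' @return Surrogate series of the same length.
#' @export
phase_shuffle <- function(x, seed = NULL) {
  stopifnot(length(x) >= 8, all(is.finite(x)))
  if (stats::sd(x) == 0) {
    return(structure(x, degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  X <- stats::fft(x)
  # DC (bin 1) and, for even n, Nyquist (bin n/2 + 1) stay untouched
  free <- if (n %% 2 == 0) seq(2, n / 2) else seq(2, (n + 1) / 2)
  phi <- stats::runif(length(free), 0, 2 * pi)
  X[free] <- Mod(X[free]) * exp(1i * phi)
  X[n + 2 - free] <- Conj(X[free])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Iterated amplitude-adjusted Fourier transform surrogate
#'
#' IAAFT surrogate: alternates between imposing the original amplitude
#' spectrum in the Fourier domain and rank-remapping to the original value
#' distribution, so the sorted values of the output equal the sorted input
#' exactly while the spectrum converges to the original as iterations grow.
#'
#' @param x Numeric series, length >= 8.
#' @param iters Number of iterations (>= 1, default 50).
#' @param seed Optional integer seed.
#' @return Surrogate series (a permutation of `x`).
#' @export
iaaft <- function(x, iters = 50, seed = NULL) {
  stopifnot(length(x) >= 8, all(is.finite(x)), iters >= 1)
  if (stats::sd(x) == 0) {
    return(structure(x, degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  amp <- Mod(stats::fft(x))
  xs <- sort(x)
  y <- sample(x)
  for (i in seq_len(iters)) {
    Y <- stats::fft(y)
    # impose amplitudes, keep phases (guard zero-magnitude bins)
    m <- Mod(Y)
    ph <- ifelse(m > 0, Y / m, 1)
    z <- Re(stats::fft(amp * ph, inverse = TRUE)) / n
    y <- xs[rank(z, ties.method = "first")]
  }
  y
}

#' Summarize a surrogate null distribution
#'
#' @param values Numeric vector of surrogate metric values (>= 20 for gating
#'   use).
#' @return List of class `pts_null_summary`: `mean`, `sd`, `percentile_75`,
#'   `n`, and the full `sample`.
#' @export
null_summary <- function(values) {
  values <- values[is.finite(values)]
  structure(list(mean = mean(values), sd = stats::sd(values),
                 percentile_75 = unname(stats::quantile(values, 0.75)),
                 n = length(values), sample = values),
            class = "pts_null_summary")
}

#' z-score an observed metric against its surrogate null
#'
#' Places heterogeneous metrics on a common scale:
#' `z = (observed - mean(null)) / sd(null)`. When the null is degenerate
#' (zero spread) the z-score is defined as 0 and flagged.
#'
#' @param observed Observed metric value.
#' @param null A [null_summary()] built from >= 20 surrogates.
#' @return z-score (attribute `degenerate = TRUE` when the null sd is 0).
#' @export
zscore_vs_null <- function(observed, null) {
  if (null$n < 20) stop("null must be built from >= 20 surrogates")
  if (!is.finite(observed)) return(NA_real_)
  if (null$sd == 0) return(structure(0, degenerate = TRUE))
  (observed - null$mean) / null$sd
}

# surrogate of one multichannel window: channels surrogated independently
surrogate_window <- function(W, method = c("iaaft", "phase_shuffle"),
                             iaaft_iters = 50) {
  method <- match.arg(method)
  S <- W
  for (j in seq_len(ncol(W))) {
    S[, j] <- if (method == "iaaft") iaaft(W[, j], iters = iaaft_iters)
    else phase_shuffle(W[, j])
  }
  S
}
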