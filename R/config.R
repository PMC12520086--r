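#' Analysis configuration for the PTS pipeline
#'
#' Builds the nested configuration list consumed by [compute_pts()]. Defaults
#' follow the preregistered plant protocol: binding window `tau = 2` s,
#' reflexive-coherence threshold `phi = 0.75`, generic window tier (windows of
#' `3 * tau` at 50% overlap), 10-minute epochs, and 100 surrogates for the
#' null model.
#'
#' @param tau Binding window in seconds. All generic-tier window geometry is
#'   derived from it (window length `3 * tau`, step half that).
#' @param phi Reflexive-coherence threshold in `[0, 1]` applied to window PTS
#'   values and to the epoch window-fraction gate.
#' @param tier Window tier: `"generic"` (3 tau, 50% overlap), `"leaf"`
#'   (6 s window, 5 s step), `"whole_organ"` (30 s window, 15 s step) or
#'   `"both"` (leaf and whole-organ tiers combined; an epoch is coherent only
#'   if both tiers pass).
#' @param epoch_s Epoch length in seconds (non-overlapping, from t = 0;
#'   a trailing partial epoch is dropped).
#' @param surrogates List: `n` (number of surrogates pooled into the null),
#'   `method` (`"iaaft"` or `"phase_shuffle"`), `iaaft_iters`, `seed`, and
#'   `max_null_windows` (windows the pooled null draws from).
#' @param metrics List of estimator settings: `symbolizer` (ordinal embedding
#'   `m`, lag in samples — `NULL` means `0.1 * tau` seconds at the recording
#'   rate — and quantile bin count), `ais_k` (symbol history), `te_history`,
#'   `slope_fit_range_hz`, `max_triplets` for the integration score, and
#'   `subslices` used by the synergy term.
#' @param gate List: `statistic` (`"wpli"` or `"plv"`) and `percentile` of the
#'   surrogate null that the statistic must exceed for temporal coherence.
#' @return A list of class `pts_config`.
#' @seealso [pts_config_test_scale()]
#' @export
#' @examples
#' cfg <- pts_config(tau = 2)
#' cfg$phi
pts_config <- function(tau = 2,
                       phi = 0.75,
                       tier = c("generic", "leaf", "whole_organ", "both"),
                       epoch_s = 600,
                       surrogates = list(),
                       metrics = list(),
                       gate = list()) {
  tier <- match.arg(tier)
  stopifnot(tau > 0, phi > 0, phi < 1, epoch_s > 0)
  sur <- utils::modifyList(list(
    n = 100L, method = "phase_shuffle", iaaft_iters = 50L, seed = 17L,
    max_null_windows = 24L
  ), surrogates)
  if (sur$n < 20L) stop("surrogates$n must be >= 20 for gating use")
  met <- utils::modifyList(list(
    symbolizer = list(scheme = "quantile_bins", m = 3L, lag = NULL, bins = 3L),
    ais_k = 2L,
    te_history = 1L,
    horizon_s = NULL,          # prediction horizon; NULL = tau / 10
    slope_fit_range_hz = NULL,  # NULL = 0.01-5 Hz scaled by (2 s / tau)
    max_triplets = 30L,
    subslices = 12L
  ), metrics)
  gt <- utils::modifyList(list(statistic = "wpli", percentile = 75), gate)
  if (!gt$statistic %in% c("wpli", "plv")) stop("gate$statistic must be 'wpli' or 'plv'")
  structure(list(tau = tau, phi = phi, tier = tier, epoch_s = epoch_s,
                 surrogates = sur, metrics = met, gate = gt),
            class = "pts_config")
}

#' Reduced-scale configuration preset
#'
#' Same analysis settings as [pts_config()] but with 20 surrogates, intended
#' for 50 Hz desk-scale runs where the full 100-surrogate null is unnecessary.
#'
#' @inheritParams pts_config
#' @param ... Passed through to [pts_config()].
#' @return A `pts_config` list.
#' @export
pts_config_test_scale <- function(tau = 2, ...) {
  args <- list(...)
  sur <- utils::modifyList(list(n = 20L), args$surrogates %||% list())
  args$surrogates <- sur
  do.call(pts_config, c(list(tau = tau), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symbol lag in samples: explicit config value, else 0.1 * tau seconds at the
# recording rate (so ordinal patterns span a fixed fraction of the binding
# window regardless of rate)
symbol_lag <- function(config, rate, tau = config$tau) {
  lag <- config$metrics$symbolizer$lag
  if (is.null(lag)) lag <- max(1L, as.integer(round(0.1 * tau * rate)))
  as.integer(lag)
}

# AIS/TE prediction horizon in samples: explicit config value (seconds), else
# a quarter binding window
horizon_samples <- function(config, rate, tau = config$tau) {
  h <- config$metrics$horizon_s
  if (is.null(h)) h <- tau / 10
  max(1L, as.integer(round(h * rate)))
}
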