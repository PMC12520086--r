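#' Map metric z-scores to normalized strengths
#'
#' Componentwise standard-normal CDF of the surrogate z-scores, giving
#' pattern strengths in `[0, 1]` (0.5 at the null, ~1 far above it). The raw
#' z-scores are kept alongside in all outputs.
#'
#' @param z Numeric vector of z-scores.
#' @return Vector of strengths in `[0, 1]`.
#' @export
strength_from_z <- function(z) stats::pnorm(z)

#' Central pattern strength
#'
#' Median of the five normalized pattern strengths of a window. `NA` (window
#' invalid) if any component is undefined.
#'
#' @param strength Numeric 5-vector of strengths in `[0, 1]`.
#' @return Median strength in `[0, 1]`.
#' @export
p_bar <- function(strength) {
  stopifnot(length(strength) == 5)
  if (anyNA(strength)) return(NA_real_)
  stats::median(strength)
}

#' Window-level Pattern-Temporal Synergy
#'
#' `PTS = p_bar * s_bar` when the temporal-coherence gate passes
#' (`tc = 1`), exactly 0 otherwise.
#'
#' @param p_bar,s_bar Values in `[0, 1]`.
#' @param tc Binary gate flag.
#' @return PTS in `[0, 1]`.
#' @export
window_pts <- function(p_bar, s_bar, tc) {
  stopifnot(all(p_bar >= 0 & p_bar <= 1, na.rm = TRUE),
            all(s_bar >= 0 & s_bar <= 1, na.rm = TRUE))
  ifelse(tc == 1, p_bar * s_bar, 0)
}

#' Normalized pairwise synergy of pattern sub-series about a global state
#'
#' Sub-series variant of the mean-synergy term: for every unordered pair of
#' five pattern score sub-series, the Williams-Beer synergy of the (3-quantile
#' binned) pair about the discretized global-state series, normalized by the
#' joint mutual information `I(pair; state)`. Because the sub-slice series
#' are short, every information term is first corrected for its plug-in
#' small-sample bias by subtracting its mean under seeded state
#' permutations (a term not exceeding its permutation baseline is 0, and a
#' pair whose bias-corrected joint information vanishes scores 0). For a
#' deterministic relation such as `state = XOR(pair)` the normalized synergy
#' is 1 and the correction vanishes with sample size. S-bar is the mean over
#' the 10 pairs, clipped to `[0, 1]`.
#'
#' @param scores Matrix of pattern scores, sub-slices in rows, 5 pattern
#'   columns.
#' @param state Integer state symbol per sub-slice.
#' @param n_perm State permutations used for the bias correction.
#' @param seed Seed for the permutation draw.
#' @return List with `pair_synergy` (10 values) and `s_bar`.
#' @export
synergy_profile <- function(scores, state, n_perm = 20L, seed = 1L) {
  stopifnot(nrow(scores) == length(state), ncol(scores) == 5)
  if (length(unique(state)) < 2)
    return(structure(list(pair_synergy = rep(0, 10), s_bar = 0),
                     degenerate = TRUE))
  bins <- apply(scores, 2, function(v) {
    if (stats::sd(v) == 0) rep(1L, length(v))
    else symbolize(v, "quantile_bins", n_bins = 3L)
  })
  state <- match(state, sort(unique(state)))
  Kt <- max(state)
  n <- length(state)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  perms <- cbind(seq_len(n),
                 vapply(seq_len(n_perm), function(p) sample.int(n),
                        integer(n)))
  cmb <- utils::combn(5, 2)
  npair <- ncol(cmb)
  ncol_tot <- npair * (n_perm + 1L)
  # columns: pair 1 (obs, perms...), pair 2 (obs, perms...), ...
  codes <- matrix(0L, n, ncol_tot)
  cc <- 0L
  for (k in seq_len(npair)) {
    pair_code <- bins[, cmb[1, k]] + 3L * (bins[, cmb[2, k]] - 1L)
    for (p in seq_len(n_perm + 1L)) {
      cc <- cc + 1L
      codes[, cc] <- pair_code + 9L * (state[perms[, p]] - 1L)
    }
  }
  counts <- matrix(tabulate(as.vector(codes) +
                              rep((seq_len(ncol_tot) - 1L) * 9L * Kt,
                                  each = n),
                            nbins = ncol_tot * 9L * Kt), 9L * Kt, ncol_tot)
  wb <- wb_batch_terms(counts, 3L, 3L, Kt)
  vals <- numeric(npair)
  for (k in seq_len(npair)) {
    ob <- (k - 1L) * (n_perm + 1L) + 1L
    pm <- (ob + 1L):(ob + n_perm)
    jmi <- wb$joint_mi[ob] - mean(wb$joint_mi[pm])
    if (jmi <= 1e-9) { vals[k] <- 0; next }
    ix <- max(0, wb$mi_x[ob] - mean(wb$mi_x[pm]))
    iy <- max(0, wb$mi_y[ob] - mean(wb$mi_y[pm]))
    rr <- max(0, wb$redundancy[ob] - mean(wb$redundancy[pm]))
    vals[k] <- min(1, max(0, (jmi - ix - iy + rr) / jmi))
  }
  list(pair_synergy = vals, s_bar = min(1, max(0, mean(vals))))
}

# SNR proxy weights: signal variance over first-difference noise-floor variance
snr_weights <- function(W) {
  w <- apply(W, 2, function(x) {
    v <- stats::var(x)
    nf <- stats::var(diff(x)) / 2
    if (nf <= 0) 1 else v / nf
  })
  w / sum(w)
}

# mean pairwise symbolic TE over all ordered channel pairs, with the
# destination-past entropies cached per channel. Each pair's TE is corrected
# for plug-in occupancy bias by subtracting the TE obtained after cyclically
# rotating the source (a source-shuffle null that preserves both series'
# dynamics but breaks their alignment); negative corrected values clamp to 0.
te_pairs_score <- function(syms, h, horizon = 1L, weights = NULL) {
  C <- length(syms)
  n <- length(syms[[1]]) - h - horizon + 1L
  past <- vector("list", C); nxt <- vector("list", C)
  Kp <- Kn <- integer(C)
  for (j in seq_len(C)) {
    s <- syms[[j]]
    if (h == 1L) {
      p <- s[seq_len(n)]
    } else {
      K <- max(s); p <- integer(n); mult <- 1L
      for (l in seq_len(h)) {
        p <- p + (s[seq_len(n) + l - 1L] - 1L) * mult
        mult <- mult * K
      }
      p <- match(p, sort.int(unique(p)))
    }
    past[[j]] <- p; nxt[[j]] <- s[seq_len(n) + h + horizon - 1L]
    Kp[j] <- max(p); Kn[j] <- max(nxt[[j]])
  }
  h_dp <- h_dndp <- numeric(C)
  for (j in seq_len(C)) {
    h_dp[j] <- entropy_bits(tabulate(past[[j]], Kp[j]))
    h_dndp[j] <- entropy_bits(tabulate(nxt[[j]] + Kn[j] * (past[[j]] - 1L),
                                       Kn[j] * Kp[j]))
  }
  rot <- function(v) v[c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))]
  past_r <- lapply(past, rot)
  if (is.null(weights)) weights <- rep(1, C)
  acc <- 0; wsum <- 0
  for (s in seq_len(C)) for (d in seq_len(C)) {
    if (s == d) next
    te_of <- function(sp) {
      h_spdp <- entropy_bits(tabulate(sp + Kp[s] * (past[[d]] - 1L),
                                      Kp[s] * Kp[d]))
      h_all <- entropy_bits(tabulate(
        nxt[[d]] + Kn[d] * (sp - 1L) + Kn[d] * Kp[s] * (past[[d]] - 1L),
        Kn[d] * Kp[s] * Kp[d]))
      h_dndp[d] + h_spdp - h_all - h_dp[d]
    }
    w <- weights[s] * weights[d]
    acc <- acc + w * max(0, te_of(past[[s]]) - te_of(past_r[[s]]))
    wsum <- wsum + w
  }
  acc / wsum
}

# per-tier precomputed window context shared by observed and surrogate
# evaluations: Welch segment geometry, per-pair frequency bins, and the
# per-channel phase-extraction bands
window_context <- function(win_n, rate, pairs, chans, config) {
  seg_len <- max(8L, floor(win_n / 2))
  hop <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, win_n - seg_len + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  freqs <- (1:floor(seg_len / 2)) * rate / seg_len
  bins <- lapply(seq_len(nrow(pairs)), function(r)
    which(freqs >= pairs$lo[r] & freqs <= pairs$hi[r]) + 1L)
  ch_lo <- chans$band_low; ch_hi <- chans$band_high
  if (isTRUE(config$gate$tau_band %||% TRUE)) {
    ch_lo <- pmax(ch_lo, 1 / (3 * config$tau))
    ch_hi <- pmin(ch_hi, 1 / config$tau)
  }
  # per-channel 1/f-slope fit ranges: the aperiodic background is fitted
  # inside the channel's own passband, and only channels whose usable range
  # spans at least a factor of 3 in frequency carry the flux score
  fit <- config$metrics$slope_fit_range_hz
  if (is.null(fit)) fit <- c(0.01, 5) * 2 / config$tau
  fres_w <- rate / max(8L, floor(win_n / 4))  # Welch resolution at this tier
  s_lo <- pmax(fit[1], chans$band_low, 2 * rate / win_n, fres_w)
  s_hi <- pmin(fit[2], chans$band_high, rate / 2)
  slope_ok <- s_hi / s_lo >= 3 & floor(s_hi / fres_w) - ceiling(s_lo / fres_w) + 1 >= 5
  if (!any(slope_ok)) {  # fall back to the widest-band channel
    slope_ok <- seq_len(nrow(chans)) == which.max(chans$band_high / chans$band_low)
  }
  phase_channels <- sort(unique(c(pairs$i, pairs$j)))
  # band-capacity channel weights: a channel's window-scale information
  # content scales with the bandwidth it resolves, so the self-reference and
  # responsiveness scores weight channels by passband width
  bw <- pmax(pmin(chans$band_high, rate / 2) - chans$band_low, 1e-6)
  ch_w <- bw / sum(bw)
  # combined band-pass + analytic-signal FFT mask per phase channel
  hmask <- numeric(win_n)
  if (win_n %% 2 == 0) {
    hmask[c(1, win_n / 2 + 1)] <- 1
    hmask[2:(win_n / 2)] <- 2
  } else {
    hmask[1] <- 1
    hmask[2:((win_n + 1) / 2)] <- 2
  }
  masks <- vector("list", nrow(chans))
  for (ch in phase_channels)
    masks[[ch]] <- fft_band_response(win_n, rate, ch_lo[ch], ch_hi[ch]) * hmask
  # fixed complete graph for the Louvain step, with the edge -> adjacency
  # index map
  C <- nrow(chans)
  g <- igraph::make_full_graph(C)
  el <- igraph::as_edgelist(g)
  list(win_n = win_n, seg_len = seg_len, starts = starts, hann = hann,
       pairs = pairs, bins = bins,
       masks = masks, phase_channels = phase_channels,
       slope_channels = which(slope_ok),
       slope_lo = s_lo, slope_hi = s_hi, ch_weights = ch_w,
       graph = g, edge_idx = el[, 1] + (el[, 2] - 1) * C,
       taper = tukey_taper(win_n))
}

# evaluate the five pattern metrics and coherence statistics on one window.
# W: band-limited plant-channel matrix; stim: optional stimulus vector.
# The identical code path is used for observed and surrogate windows so that
# estimator quirks cancel in the z-scores.
window_eval <- function(W, stim, rate, config, lag, horizon, triplets, ctx,
                        louvain_seed = 1L) {
  sy <- config$metrics$symbolizer
  C <- ncol(W)
  syms <- lapply(seq_len(C), function(j)
    symbolize(W[, j], sy$scheme, m = sy$m, lag = lag, n_bins = sy$bins))

  # self-reference: band-capacity-weighted mean AIS over channels, with the
  # prediction horizon and history spacing spanning real signal innovation
  ais_v <- sum(ctx$ch_weights * vapply(syms, function(s)
    as.numeric(ais(s, config$metrics$ais_k, horizon = horizon,
                   spacing = lag)), 0))

  # division-creation: Louvain Q of the |rank-correlation| graph (fixed
  # complete graph, per-window weights)
  A <- functional_graph(W)
  w <- A[ctx$edge_idx]
  if (sum(w) == 0) {
    q_v <- 0
  } else {
    old <- .Random.seed_get()
    set.seed(louvain_seed)
    cl <- igraph::cluster_louvain(ctx$graph, weights = w)
    q_v <- igraph::modularity(ctx$graph, igraph::membership(cl), weights = w)
    .Random.seed_set(old)
  }

  # integration: band-capacity-weighted mean Williams-Beer synergy over
  # sampled channel triplets (batched decomposition across triplets)
  nb <- config$metrics$symbolizer$bins
  bins <- lapply(seq_len(C), function(j)
    symbolize(W[, j], "quantile_bins", n_bins = nb))
  R <- nrow(triplets)
  nW <- nrow(W)
  codes <- vapply(seq_len(R), function(r)
    bins[[triplets$x[r]]] + nb * (bins[[triplets$y[r]]] - 1L) +
      nb * nb * (bins[[triplets$t[r]]] - 1L), integer(nW))
  counts <- matrix(tabulate(as.vector(codes) +
                              rep((seq_len(R) - 1L) * nb^3, each = nW),
                            nbins = R * nb^3), nb^3, R)
  syn <- wb_batch(counts, nb, nb, nb)$synergy
  wtr <- ctx$ch_weights[triplets$x] * ctx$ch_weights[triplets$y] *
    ctx$ch_weights[triplets$t]
  pid_v <- sum(wtr * syn) / sum(wtr)

  # raw mean-synergy statistic: average pairwise Williams-Beer synergy of
  # channel pairs about the quantile-binned global state, where each pair's
  # state is the summed activity of the REMAINING channels (leave-two-out,
  # so the state is never built from the pair itself); z-scored downstream
  # against the same surrogate null as the pattern metrics
  cmu <- colMeans(W)
  csd <- sqrt(pmax(colSums(W^2) / nW - cmu^2, 0))
  csd[csd == 0] <- 1
  Zc <- (W - rep(cmu, each = nW)) / rep(csd, each = nW)
  tot <- rowSums(Zc)
  spairs <- ctx$sbar_pairs
  scodes <- vapply(seq_len(nrow(spairs)), function(r) {
    rest <- tot - Zc[, spairs$i[r]] - Zc[, spairs$j[r]]
    if (stats::sd(rest) == 0) rest <- stats::runif(nW)
    st <- symbolize(rest, "quantile_bins", n_bins = nb)
    bins[[spairs$i[r]]] + nb * (bins[[spairs$j[r]]] - 1L) +
      nb * nb * (st - 1L)
  }, integer(nW))
  scnt <- matrix(tabulate(as.vector(scodes) +
                            rep((seq_len(nrow(spairs)) - 1L) * nb^3,
                                each = nW),
                          nbins = nrow(spairs) * nb^3), nb^3, nrow(spairs))
  sbar_v <- mean(wb_batch(scnt, nb, nb, nb)$synergy)

  # responsiveness: stimulus-driven TE when a stim channel varies, else mean
  # pairwise TE
  h <- config$metrics$te_history
  if (!is.null(stim) && length(unique(stim)) > 1) {
    ssym <- match(stim, sort(unique(stim)))[seq_along(syms[[1]])]
    te_each <- vapply(seq_len(C), function(j)
      as.numeric(symbolic_te(ssym, syms[[j]], h, horizon = horizon)), 0)
    te_v <- sum(snr_weights(W) * te_each)
  } else {
    te_v <- te_pairs_score(syms, h, horizon = horizon,
                           weights = ctx$ch_weights)
  }

  # flux: mean aperiodic 1/f slope over slope-eligible channels, fitted
  # inside each channel's passband
  slope_v <- mean(vapply(ctx$slope_channels, function(j)
    as.numeric(spectral_slope(W[, j], rate,
                              c(ctx$slope_lo[j], ctx$slope_hi[j]))), 0))

  # coherence: analytic phases per distinct band for PLV; shared Welch
  # segment FFTs for wPLI
  pairs <- ctx$pairs
  np <- nrow(pairs)
  plv_vals <- wpli_vals <- rep(NA_real_, np)
  n <- nrow(W)
  P <- matrix(NA_real_, n, C)
  for (ch in ctx$phase_channels) {
    x <- (W[, ch] - mean(W[, ch])) * ctx$taper
    X <- stats::fft(x)
    P[, ch] <- Arg(stats::fft(X * ctx$masks[[ch]], inverse = TRUE))
  }
  segf <- lapply(seq_len(C), function(ch) {
    segs <- vapply(ctx$starts, function(s) {
      seg <- W[s:(s + ctx$seg_len - 1L), ch]
      (seg - mean(seg)) * ctx$hann
    }, numeric(ctx$seg_len))
    stats::mvfft(segs)
  })
  for (r in seq_len(np)) {
    dphi <- P[, pairs$i[r]] - P[, pairs$j[r]]
    plv_vals[r] <- Mod(mean(exp(1i * dphi)))
    bn <- ctx$bins[[r]]
    im <- Im(segf[[pairs$i[r]]][bn, , drop = FALSE] *
               Conj(segf[[pairs$j[r]]][bn, , drop = FALSE]))
    den <- mean(abs(im))
    wpli_vals[r] <- if (den == 0) 0 else abs(mean(im)) / den
  }
  list(ais = ais_v, q = q_v, pid = pid_v, te = te_v, slope = slope_v,
       sbar_raw = sbar_v,
       plv_mean = mean(plv_vals, na.rm = TRUE),
       wpli_mean = mean(wpli_vals, na.rm = TRUE))
}

# seeded sample of unordered channel pairs for the mean-synergy statistic
sample_channel_pairs <- function(C, max_pairs, seed) {
  cmb <- utils::combn(C, 2)
  out <- data.frame(i = cmb[1, ], j = cmb[2, ])
  if (nrow(out) > max_pairs) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed + 1L)
    out <- out[sample.int(nrow(out), max_pairs), ]
  }
  out
}

# seeded sample of channel triplets (pair + target) for the integration score
sample_triplets <- function(C, max_triplets, seed) {
  cmb <- utils::combn(C, 2)
  all <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    others <- setdiff(seq_len(C), cmb[, k])
    data.frame(x = cmb[1, k], y = cmb[2, k], t = others)
  }))
  if (nrow(all) > max_triplets) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
    all <- all[sample.int(nrow(all), max_triplets), ]
  }
  all
}

#' Compute window- and epoch-level Pattern-Temporal Synergy
#'
#' Runs the full PTS pipeline on one recording: band-limits each channel to
#' its modality band, slides windows of the configured tier across the
#' session, computes the five pattern metrics per window, z-scores them
#' against a pooled surrogate null (channels surrogated independently),
#' converts z-scores to strengths, applies the wPLI temporal-coherence gate
#' against the 75th percentile of the surrogate null, forms
#' `PTS = p_bar * s_bar` for gated windows (0 otherwise), and classifies
#' non-overlapping epochs by the dual gate (at least 75% of valid windows
#' with PTS above `phi`).
#'
#' @param rec A [pts_recording()] (already on its analysis grid; use
#'   [resample_to_grid()] first for asynchronous inputs).
#' @param config A [pts_config()]; defaults to `pts_config(tau = rec$tau)`.
#' @param qc Optional per-epoch QC table (see [qc_filter()]).
#' @param preprocess Band-limit channels before analysis (default TRUE; set
#'   FALSE if `rec` is already filtered).
#' @return Object of class `pts_result`: `windows` and `epochs` data frames,
#'   `null` summaries, `diagnostics` (including the fraction of
#'   temporally-coherent windows), and the `config`. With `tier = "both"`,
#'   component results are in `$tiers` and `epochs` holds the combined
#'   verdict (coherent only if both tiers pass).
#' @export
compute_pts <- function(rec, config = NULL, qc = NULL, preprocess = TRUE) {
  if (is.null(config)) config <- pts_config(tau = rec$tau)
  if (preprocess) rec <- bandlimit(rec)
  if (config$tier == "both") {
    tiers <- lapply(c("leaf", "whole_organ"), function(tr) {
      cf <- config; cf$tier <- tr
      compute_pts(rec, cf, qc = qc, preprocess = FALSE)
    })
    names(tiers) <- c("leaf", "whole_organ")
    ep <- tiers$leaf$epochs
    common <- seq_len(min(nrow(ep), nrow(tiers$whole_organ$epochs)))
    ep <- ep[common, ]
    ep$coherent <- ep$coherent & tiers$whole_organ$epochs$coherent[common]
    out <- tiers$leaf
    out$tiers <- tiers
    out$epochs <- ep
    out$config <- config
    return(out)
  }

  rate <- rec$rate
  plan <- make_windows(rec$duration, config$tau, config$tier)
  nw <- nrow(plan$windows)
  if (!nw) stop("recording shorter than one analysis window")
  win_n <- round(plan$window_s * rate)
  starts <- round(plan$windows$start_s * rate) + 1

  plant_idx <- which(rec$channels$modality != "stim")
  stim_idx <- which(rec$channels$modality == "stim")
  # a channel whose band cannot complete min_band_cycles oscillations inside
  # one window carries no window-scale pattern information at this tier;
  # slow streams (O2, heat) enter through the whole-organ tier instead
  min_cyc <- config$metrics$min_band_cycles %||% 1.5
  resolvable <- rec$channels$band_high >= min_cyc / plan$window_s
  plant_idx <- plant_idx[resolvable[plant_idx]]
  if (length(plant_idx) < 3)
    stop("fewer than 3 channels resolve oscillations at this window length")
  X <- rec$data[, plant_idx, drop = FALSE]
  stim <- if (length(stim_idx)) rec$data[, stim_idx[1]] else NULL
  chans <- rec$channels[plant_idx, ]
  lag <- symbol_lag(config, rate)
  horizon <- horizon_samples(config, rate)
  pairs <- gate_pairs(chans)
  if (isTRUE(config$gate$tau_band %||% TRUE)) {
    # restrict gating to synchrony at binding-window timescales
    pairs$lo <- pmax(pairs$lo, 1 / (3 * config$tau))
    pairs$hi <- pmin(pairs$hi, 1 / config$tau)
    pairs <- pairs[pairs$lo < pairs$hi, , drop = FALSE]
  }
  # drop pairs whose band holds no cross-spectral bin at this window length
  seg_len <- max(8L, floor(win_n / 2))
  fres <- rate / seg_len
  has_bin <- floor(pairs$hi / fres) >= pmax(1, ceiling(pairs$lo / fres))
  pairs <- pairs[has_bin, , drop = FALSE]
  if (!nrow(pairs)) stop("no channel pair with a resolvable band overlap")
  ctx <- window_context(win_n, rate, pairs, chans, config)
  triplets <- sample_triplets(ncol(X), config$metrics$max_triplets,
                              config$surrogates$seed)
  ctx$sbar_pairs <- sample_channel_pairs(ncol(X), 10L, config$surrogates$seed)

  slice <- function(i) {
    idx <- starts[i]:(starts[i] + win_n - 1L)
    X[idx, , drop = FALSE]
  }
  stim_slice <- function(i) {
    if (is.null(stim)) NULL else stim[starts[i]:(starts[i] + win_n - 1L)]
  }

  # pooled surrogate null over a spread of windows
  K <- min(config$surrogates$max_null_windows, nw)
  null_wins <- unique(round(seq(1, nw, length.out = K)))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$surrogates$seed)
  nS <- config$surrogates$n
  null_vals <- matrix(NA_real_, nS, 8,
                      dimnames = list(NULL, c("ais", "q", "pid", "te", "slope",
                                              "sbar_raw", "plv_mean",
                                              "wpli_mean")))
  for (d in seq_len(nS)) {
    wi <- null_wins[((d - 1) %% length(null_wins)) + 1]
    S <- surrogate_window(slice(wi), config$surrogates$method,
                          config$surrogates$iaaft_iters)
    ev <- window_eval(S, NULL, rate, config, lag, horizon, triplets, ctx,
                      louvain_seed = config$surrogates$seed)
    null_vals[d, ] <- unlist(ev)
  }
  nulls <- apply(null_vals, 2, null_summary, simplify = FALSE)
  gate_stat <- paste0(config$gate$statistic, "_mean")
  tc_thr <- stats::quantile(nulls[[gate_stat]]$sample,
                            config$gate$percentile / 100, names = FALSE)

  # observed windows
  metr <- matrix(NA_real_, nw, 8, dimnames = dimnames(null_vals))
  for (i in seq_len(nw)) {
    ev <- window_eval(slice(i), stim_slice(i), rate, config, lag, horizon,
                      triplets, ctx, louvain_seed = config$surrogates$seed)
    metr[i, ] <- unlist(ev)
  }

  z <- sapply(c("ais", "q", "pid", "te", "slope"), function(mname)
    vapply(metr[, mname], function(v)
      as.numeric(zscore_vs_null(v, nulls[[mname]])), 0))
  strength <- strength_from_z(z)
  pbar <- apply(strength, 1, p_bar)
  sbar <- strength_from_z(vapply(metr[, "sbar_raw"], function(v)
    as.numeric(zscore_vs_null(v, nulls[["sbar_raw"]])), 0))
  sbar[!is.finite(sbar)] <- 0
  tc <- as.integer(is.finite(metr[, gate_stat]) & metr[, gate_stat] > tc_thr)

  valid <- !is.na(pbar)
  if (!is.null(rec$bad_intervals) && nrow(rec$bad_intervals)) {
    for (r in seq_len(nrow(rec$bad_intervals))) {
      hit <- plan$windows$start_s < rec$bad_intervals$end_s[r] &
        plan$windows$end_s > rec$bad_intervals$start_s[r]
      valid <- valid & !hit
    }
  }
  pts <- ifelse(valid, window_pts(ifelse(valid, pbar, 0), sbar, tc), NA_real_)

  windows <- data.frame(index = seq_len(nw),
                        start_s = plan$windows$start_s,
                        end_s = plan$windows$end_s,
                        valid = valid)
  windows <- cbind(windows, as.data.frame(metr))
  colnames(z) <- paste0("z_", colnames(z))
  windows <- cbind(windows, as.data.frame(z))
  st <- as.data.frame(strength)
  colnames(st) <- paste0("strength_", c("ais", "q", "pid", "te", "slope"))
  windows <- cbind(windows, st)
  windows$p_bar <- pbar
  windows$s_bar <- sbar
  windows$tc <- tc
  windows$pts <- pts

  # block (condition) assignment by window midpoint
  if (!is.null(rec$blocks)) {
    mid <- (windows$start_s + windows$end_s) / 2
    bi <- findInterval(mid, rec$blocks$start_s)
    bi[bi == 0 | mid >= rec$blocks$end_s[pmax(bi, 1)]] <- NA
    windows$block <- rec$blocks$name[bi]
  } else {
    windows$block <- rec$condition
  }

  ep <- make_epochs(rec$duration, config$epoch_s, plan)
  ep <- qc_filter(ep, qc)
  windows$epoch <- NA_integer_
  verdicts <- lapply(seq_len(nrow(ep)), function(e) {
    wi <- ep$windows[[e]]
    windows$epoch[wi] <<- ep$index[e]
    classify_epoch(windows[wi, ], config$phi, qc_pass = ep$qc_pass[e])
  })
  epochs <- data.frame(index = ep$index, start_s = ep$start_s,
                       end_s = ep$end_s, qc_pass = ep$qc_pass,
                       n_valid = vapply(verdicts, `[[`, 0, "n_valid_windows"),
                       frac_above_phi = vapply(verdicts, `[[`, 0, "frac_above_phi"),
                       coherent = vapply(verdicts, `[[`, TRUE, "coherent"),
                       median_pts = vapply(verdicts, `[[`, 0, "median_pts"),
                       mad_pts = vapply(verdicts, `[[`, 0, "mad_pts"))
  if (!is.null(rec$blocks)) {
    mid <- (epochs$start_s + epochs$end_s) / 2
    bi <- findInterval(mid, rec$blocks$start_s)
    bi[bi == 0 | mid >= rec$blocks$end_s[pmax(bi, 1)]] <- NA
    epochs$block <- rec$blocks$name[bi]
  } else epochs$block <- rec$condition

  structure(list(
    windows = windows, epochs = epochs, null = nulls,
    diagnostics = list(
      tc_window_fraction = mean(tc[valid]),
      tc_threshold = tc_thr,
      n_windows = nw, tier = config$tier,
      window_s = plan$window_s, step_s = plan$step_s),
    plant_id = rec$plant_id, config = config),
    class = "pts_result")
}

#' @export
print.pts_result <- function(x, ...) {
  cat("<pts_result> plant", x$plant_id, "| tier", x$diagnostics$tier, "\n")
  v <- x$windows$valid
  cat(sprintf("  %d windows (%d valid), TC fraction %.2f\n",
              nrow(x$windows), sum(v), x$diagnostics$tc_window_fraction))
  cat(sprintf("  median window PTS %.3f | %d/%d epochs coherent\n",
              stats::median(x$windows$pts[v], na.rm = TRUE),
              sum(x$epochs$coherent), nrow(x$epochs)))
  invisible(x)
}

#' Summarize window PTS by condition block
#'
#' @param result A `pts_result` (or list of them, pooled).
#' @return `data.frame` per block: window counts, median and MAD of window
#'   PTS, fraction of windows clearing `phi`, and epoch-level grand median.
#' @export
summarize_blocks <- function(result) {
  results <- if (inherits(result, "pts_result")) list(result) else result
  win <- do.call(rbind, lapply(results, function(r)
    r$windows[r$windows$valid, c("block", "pts")]))
  ep <- do.call(rbind, lapply(results, function(r)
    r$epochs[r$epochs$qc_pass, c("block", "median_pts")]))
  phi <- results[[1]]$config$phi
  blocks <- unique(stats::na.omit(win$block))
  do.call(rbind, lapply(blocks, function(b) {
    w <- win$pts[win$block %in% b]
    e <- ep$median_pts[ep$block %in% b]
    data.frame(block = b, n_windows = length(w),
               median_pts = stats::median(w),
               mad_pts = stats::mad(w, constant = 1),
               frac_ge_phi = mean(w >= phi),
               epoch_grand_median = stats::median(e))
  }))
}
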