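#' Default modality frequency bands
#'
#' Physiology-appropriate carrier bands for the four plant signal modalities:
#' cytosolic Ca2+ waves 0.05-0.5 Hz, phloem surface voltage 0.2-5 Hz, O2
#' micro-flux 1e-3-0.1 Hz and heat flux 1e-2-0.1 Hz. Stimulus channels carry
#' no band and are never filtered.
#'
#' @return Named list of `c(low, high)` in Hz.
#' @export
modality_bands <- function() {
  list(ca      = c(0.05, 0.5),
       voltage = c(0.2, 5),
       o2      = c(1e-3, 0.1),
       heat    = c(1e-2, 0.1),
       stim    = c(NA_real_, NA_real_))
}

#' Construct a channel descriptor
#'
#' @param name Channel identifier (must match a data column).
#' @param modality One of `"ca"`, `"voltage"`, `"o2"`, `"heat"`, `"stim"`.
#' @param native_rate Native sampling rate in Hz (> 0).
#' @param units Free-text units.
#' @param band Optional `c(low, high)` band in Hz; defaults to the modality
#'   band from [modality_bands()].
#' @return A one-row `data.frame` with the channel metadata.
#' @export
channel <- function(name, modality, native_rate, units = "", band = NULL) {
  modality <- match.arg(modality, names(modality_bands()))
  if (!is.numeric(native_rate) || native_rate <= 0)
    stop("native_rate must be > 0 for channel ", name)
  if (is.null(band)) band <- modality_bands()[[modality]]
  if (modality != "stim" && !(band[1] < band[2]))
    stop("band low must be below band high for channel ", name)
  data.frame(name = as.character(name), modality = modality,
             native_rate = native_rate, units = units,
             band_low = band[1], band_high = band[2],
             stringsAsFactors = FALSE)
}

#' Construct a multichannel recording
#'
#' A recording holds channel metadata, a samples-by-channels data matrix on a
#' common uniform grid, the grid rate, the binding window `tau`, and optional
#' condition/block annotations. Time is in seconds with t = 0 at the first
#' sample; windows are half-open `[start, end)`.
#'
#' @param data Numeric matrix, samples in rows, one column per channel.
#' @param channels `data.frame` of channel metadata (one row per column of
#'   `data`, see [channel()]).
#' @param rate Sampling rate of the common grid, Hz.
#' @param tau Binding window in seconds (> 0).
#' @param plant_id Identifier of the specimen.
#' @param condition `"baseline"`, `"ether"`, `"washout"`, or `"session"` for
#'   multi-block sessions annotated via `blocks`.
#' @param blocks Optional `data.frame(name, start_s, end_s)` tiling the
#'   session with condition blocks.
#' @param bad_intervals Optional `data.frame(start_s, end_s)` of intervals
#'   invalidated by long gaps; windows overlapping them are excluded.
#' @return An object of class `pts_recording`.
#' @export
pts_recording <- function(data, channels, rate, tau, plant_id = "plant1",
                          condition = c("baseline", "ether", "washout", "session"),
                          blocks = NULL, bad_intervals = NULL) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (ncol(data) != nrow(channels))
    stop("data has ", ncol(data), " columns but channels describes ", nrow(channels))
  if (anyNA(data)) stop("recording data must contain no missing samples")
  stopifnot(rate > 0, tau > 0)
  colnames(data) <- channels$name
  if (!is.null(blocks)) {
    blocks <- blocks[order(blocks$start_s), , drop = FALSE]
    if (nrow(blocks) > 1 && any(blocks$start_s[-1] < blocks$end_s[-nrow(blocks)] - 1e-9))
      stop("condition blocks overlap")
  }
  structure(list(data = data, channels = channels, rate = rate, tau = tau,
                 duration = nrow(data) / rate, plant_id = plant_id,
                 condition = condition, blocks = blocks,
                 bad_intervals = bad_intervals),
            class = "pts_recording")
}

#' @export
print.pts_recording <- function(x, ...) {
  cat("<pts_recording> plant", x$plant_id, "-", x$condition, "\n")
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s), tau = %g s\n",
              ncol(x$data), nrow(x$data), x$rate, x$duration, x$tau))
  cat("  modalities:", paste(x$channels$modality, collapse = " "), "\n")
  invisible(x)
}

#' Read a recording from a delimited table and JSON sidecar
#'
#' The table must have a monotone `time_s` first column and one column per
#' channel; the sidecar lists every data column with its modality, native
#' rate, units and optional band. Time origin is shifted to zero. Gaps in the
#' time base shorter than three sample periods are bridged linearly; longer
#' gaps are recorded as bad intervals that invalidate overlapping windows.
#'
#' @param table_path Path to the CSV/TSV data table.
#' @param sidecar_path Path to the JSON channel-metadata sidecar.
#' @param tau Binding window in seconds (sidecar value used if present).
#' @param plant_id,condition Overrides for the sidecar values.
#' @return A [pts_recording()].
#' @export
read_recording <- function(table_path, sidecar_path, tau = NULL,
                           plant_id = NULL, condition = NULL) {
  tab <- data.table::fread(table_path, data.table = FALSE)
  if (!"time_s" %in% names(tab))
    stop("table must have a 'time_s' first column")
  side <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  meta <- side$channels
  data_cols <- setdiff(names(tab), "time_s")
  missing <- setdiff(data_cols, meta$name)
  if (length(missing))
    stop("sidecar is missing metadata for column(s): ",
         paste(missing, collapse = ", "))
  absent <- setdiff(meta$name, data_cols)
  if (length(absent))
    stop("table is missing channel column(s): ", paste(absent, collapse = ", "))

  t <- tab$time_s
  if (any(diff(t) <= 0))
    stop("time column must be strictly increasing (duplicated or non-monotone timestamps)")
  t <- t - t[1]
  dt <- stats::median(diff(t))
  rate <- 1 / dt

  # snap onto the uniform grid; bridge short gaps, flag long ones
  n <- floor(t[length(t)] / dt) + 1
  grid <- (seq_len(n) - 1) * dt
  bad <- NULL
  gaps <- which(diff(t) > 3 * dt)
  if (length(gaps)) {
    bad <- data.frame(start_s = t[gaps], end_s = t[gaps + 1])
    warning(length(gaps), " gap(s) longer than 3 sample periods; enclosing windows will be invalidated")
  }
  X <- sapply(meta$name, function(cn) stats::approx(t, tab[[cn]], xout = grid)$y)

  chans <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    band <- if (!is.null(meta$band_hz)) unlist(meta$band_hz[i]) else NULL
    if (length(band) != 2 || anyNA(band)) band <- NULL
    channel(meta$name[i], meta$modality[i], meta$native_rate_hz[i],
            meta$units[i] %||% "", band)
  }))
  pts_recording(X, chans, rate = rate,
                tau = tau %||% side$tau_s %||% 2,
                plant_id = plant_id %||% side$plant_id %||% "plant1",
                condition = condition %||% side$condition %||% "baseline",
                blocks = if (!is.null(side$blocks)) as.data.frame(side$blocks) else NULL,
                bad_intervals = bad)
}

#' Write a recording to a delimited table and JSON sidecar
#'
#' Inverse of [read_recording()]: writes `<prefix>.csv` with a `time_s`
#' column plus one column per channel, and `<prefix>.json` with the channel
#' metadata, tau, plant id, condition and blocks.
#'
#' @param rec A [pts_recording()].
#' @param prefix Output path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(rec, prefix) {
  tab <- data.frame(time_s = (seq_len(nrow(rec$data)) - 1) / rec$rate)
  tab <- cbind(tab, as.data.frame(rec$data))
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  data.table::fwrite(tab, csv)
  side <- list(
    channels = data.frame(
      name = rec$channels$name, modality = rec$channels$modality,
      native_rate_hz = rec$channels$native_rate, units = rec$channels$units,
      band_hz = I(lapply(seq_len(nrow(rec$channels)), function(i)
        c(rec$channels$band_low[i], rec$channels$band_high[i])))),
    tau_s = rec$tau, plant_id = rec$plant_id, condition = rec$condition)
  if (!is.null(rec$blocks)) side$blocks <- rec$blocks
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, js))
}

# Fourier-domain resampling with implicit anti-alias brick wall: exact for
# band-limited content, bounded edge transients (the ends are mirrored to
# suppress wrap-around)
fft_resample <- function(x, n_out) {
  n <- length(x)
  pad <- min(n, 256L)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  np <- length(xp)
  np_out <- round(np * n_out / n)
  X <- stats::fft(xp)
  half <- floor(min(np, np_out) / 2)
  Y <- complex(np_out)
  Y[1] <- X[1]
  Y[2:(half + 1)] <- X[2:(half + 1)]
  Y[np_out - seq_len(half - 1) + 1] <- X[np - seq_len(half - 1) + 1]
  y <- Re(stats::fft(Y, inverse = TRUE)) / np
  pad_out <- round(pad * n_out / n)
  y[(pad_out + 1):(pad_out + n_out)]
}

#' Resample a recording onto a common uniform grid
#'
#' Fourier-domain resampling with implicit anti-alias cutoff of every
#' channel onto the target rate (exact for band-limited content; linear
#' interpolation is never used for downsampling). Duration is preserved to
#' within one sample period. Stimulus channels are resampled by zero-order
#' hold to keep them binary.
#'
#' @param rec A [pts_recording()].
#' @param rate Target rate in Hz (default 500, the common analysis grid).
#' @return A [pts_recording()] at `rate`.
#' @export
resample_to_grid <- function(rec, rate = 500) {
  stopifnot(rate > 0)
  if (abs(rate - rec$rate) < 1e-9) return(rec)
  fastest <- max(rec$channels$native_rate)
  if (rate > 10 * fastest)
    warning("target rate exceeds 10x the fastest native rate; upsampling artifact risk")
  n_in <- nrow(rec$data)
  n_out <- floor(n_in * rate / rec$rate)
  t_out <- (seq_len(n_out) - 1) / rate
  t_in <- (seq_len(n_in) - 1) / rec$rate
  X <- matrix(0, n_out, ncol(rec$data))
  for (j in seq_len(ncol(rec$data))) {
    if (rec$channels$modality[j] == "stim") {
      # zero-order hold: step/binary signals must stay step/binary
      X[, j] <- rec$data[findInterval(t_out, t_in), j]
    } else {
      X[, j] <- fft_resample(rec$data[, j], n_out)
    }
  }
  out <- rec
  out$data <- X
  colnames(out$data) <- rec$channels$name
  out$rate <- rate
  out$duration <- n_out / rate
  out
}

# frequency response of the zero-phase band-pass below, on the two-sided
# FFT grid of length n
fft_band_response <- function(n, rate, low, high, notch_hz = NULL) {
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)  # two-sided -> folded frequency
  H <- rep(1, n)
  if (!is.na(low) && low > 0) {
    w <- 0.2 * low
    H <- H * ifelse(f <= low - w, 0,
                    ifelse(f >= low + w, 1,
                           0.5 * (1 - cos(pi * (f - (low - w)) / (2 * w)))))
  }
  if (!is.na(high) && high < rate / 2) {
    w <- 0.2 * high
    H <- H * ifelse(f >= high + w, 0,
                    ifelse(f <= high - w, 1,
                           0.5 * (1 + cos(pi * (f - (high - w)) / (2 * w)))))
  }
  if (!is.null(notch_hz)) {
    for (f0 in notch_hz) {
      if (f0 < rate / 2) {
        bw <- 1  # +-1 Hz stop band
        H <- H * ifelse(abs(f - f0) >= bw, 1, (abs(f - f0) / bw)^2)
      }
    }
  }
  H
}

# zero-phase FFT band-pass with raised-cosine edges; band in Hz.
# transition width = 20% of each edge frequency. Stable at arbitrarily low
# normalized frequencies where IIR designs are not.
fft_bandpass <- function(x, rate, low, high, notch_hz = NULL) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  H <- fft_band_response(n, rate, low, high, notch_hz)
  Re(stats::fft(X * H, inverse = TRUE)) / n
}

#' Band-limit recording channels to their modality bands
#'
#' Zero-phase band-pass of each non-stimulus channel to its declared band,
#' with 50/60 Hz notches applied to voltage channels. A band edge at or above
#' Nyquist is clipped to Nyquist with a warning. Stimulus channels pass
#' through untouched.
#'
#' @param rec A [pts_recording()].
#' @param channels Channel names to filter (default all non-stim channels).
#' @return The filtered [pts_recording()].
#' @export
bandlimit <- function(rec, channels = NULL) {
  nyq <- rec$rate / 2
  idx <- which(rec$channels$modality != "stim")
  if (!is.null(channels)) idx <- intersect(idx, match(channels, rec$channels$name))
  for (j in idx) {
    lo <- rec$channels$band_low[j]
    hi <- rec$channels$band_high[j]
    if (hi >= nyq) {
      warning("band upper edge for ", rec$channels$name[j],
              " at/above Nyquist; clipped")
      hi <- nyq * 0.999
      rec$channels$band_high[j] <- hi
    }
    notch <- if (rec$channels$modality[j] == "voltage") c(50, 60) else NULL
    rec$data[, j] <- fft_bandpass(rec$data[, j], rec$rate, lo, hi, notch)
  }
  rec
}

#' Plan sliding analysis windows
#'
#' Builds the maximal left-aligned set of half-open windows `[start, end)`
#' contained in `[0, duration)`. The `generic` tier uses windows of `3 * tau`
#' with 50% overlap; the `leaf` preset uses the literal 6 s window / 5 s
#' step; `whole_organ` uses 30 s / 15 s.
#'
#' @param duration_s Recording duration, seconds.
#' @param tau_s Binding window, seconds (generic tier only).
#' @param tier `"generic"`, `"leaf"` or `"whole_organ"`.
#' @return A list of class `pts_window_plan` with `window_s`, `step_s`,
#'   `tier` and a `windows` data.frame (`start_s`, `end_s`).
#' @export
#' @examples
#' make_windows(60, 2, "generic")$windows   # 19 windows of 6 s every 3 s
make_windows <- function(duration_s, tau_s,
                         tier = c("generic", "leaf", "whole_organ")) {
  tier <- match.arg(tier)
  geom <- switch(tier,
                 generic = c(3 * tau_s, 1.5 * tau_s),
                 leaf = c(6, 5),
                 whole_organ = c(30, 15))
  window_s <- geom[1]; step_s <- geom[2]
  stopifnot(window_s > 0, step_s > 0)
  if (duration_s < window_s) {
    warning("duration shorter than one window; empty plan")
    starts <- numeric(0)
  } else {
    n <- floor((duration_s - window_s) / step_s) + 1
    starts <- (seq_len(n) - 1) * step_s
  }
  structure(list(window_s = window_s, step_s = step_s, tier = tier,
                 windows = data.frame(start_s = starts,
                                      end_s = starts + window_s)),
            class = "pts_window_plan")
}

#' Partition a recording into fixed-length epochs
#'
#' Non-overlapping epochs contiguous from t = 0; a trailing partial epoch is
#' dropped. Windows are assigned to the epoch containing their midpoint.
#'
#' @param duration_s Recording duration, seconds.
#' @param epoch_s Epoch length, seconds (default 600).
#' @param plan Optional [make_windows()] plan used to attach member windows.
#' @return `data.frame(index, start_s, end_s)` with a `windows` list-column
#'   of member window indices when `plan` is given.
#' @export
make_epochs <- function(duration_s, epoch_s = 600, plan = NULL) {
  n <- floor(duration_s / epoch_s)
  ep <- data.frame(index = seq_len(n),
                   start_s = (seq_len(n) - 1) * epoch_s,
                   end_s = seq_len(n) * epoch_s)
  if (!is.null(plan) && nrow(plan$windows)) {
    mid <- (plan$windows$start_s + plan$windows$end_s) / 2
    ep$windows <- lapply(seq_len(n), function(i)
      which(mid >= ep$start_s[i] & mid < ep$end_s[i]))
  }
  ep
}

#' Apply signal-quality exclusion rules to epochs
#'
#' An epoch fails QC when mean photobleaching exceeds 5 %/min, electrode
#' impedance rises above 5 Mohm, or O2 probe drift exceeds 2% of span per
#' hour (all strict inequalities). Failed epochs are excluded from all
#' downstream statistics.
#'
#' @param epochs Epoch table from [make_epochs()].
#' @param qc `data.frame(epoch_index, photobleach_pct_per_min, impedance_mohm,
#'   o2_drift_pct_per_hr)`, one row per epoch; missing rows pass with a
#'   warning.
#' @return `epochs` with a logical `qc_pass` column.
#' @export
qc_filter <- function(epochs, qc = NULL) {
  epochs$qc_pass <- rep(TRUE, nrow(epochs))
  if (is.null(qc) || !nrow(qc)) {
    if (is.null(qc)) return(epochs)
    warning("empty QC table; all epochs pass")
    return(epochs)
  }
  vals <- as.matrix(qc[, c("photobleach_pct_per_min", "impedance_mohm",
                           "o2_drift_pct_per_hr")])
  if (any(vals < 0, na.rm = TRUE)) stop("negative QC values")
  m <- match(epochs$index, qc$epoch_index)
  if (anyNA(m)) warning("QC record missing for ", sum(is.na(m)),
                        " epoch(s); they pass by default")
  ok <- !is.na(m)
  fail <- qc$photobleach_pct_per_min[m[ok]] > 5 |
    qc$impedance_mohm[m[ok]] > 5 |
    qc$o2_drift_pct_per_hr[m[ok]] > 2
  epochs$qc_pass[ok] <- !fail
  epochs
}

#' Read a stimulus/event table
#'
#' @param path CSV with header `onset_s,duration_s,kind,params`.
#' @return Validated `data.frame` sorted by onset.
#' @export
read_events <- function(path) {
  ev <- data.table::fread(path, data.table = FALSE)
  validate_events(ev)
}

validate_events <- function(ev) {
  if (!nrow(ev)) return(ev)
  if (any(ev$onset_s < 0)) stop("event onsets must be non-negative")
  if (any(ev$duration_s < 0)) stop("event durations must be >= 0")
  kinds <- c("blue_light", "acoustic", "glutamate", "tap")
  if (!all(ev$kind %in% kinds))
    stop("unknown event kind; expected one of ", paste(kinds, collapse = ", "))
  ev[order(ev$onset_s), , drop = FALSE]
}
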