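#' Classify one epoch by the dual PTS gate
#'
#' An epoch shows sustained reflexive coherence only when at least 75% of
#' its valid windows have a PTS strictly exceeding `phi` (and the epoch
#' passes QC). The epoch is also summarized by median PTS and its (raw)
#' median absolute deviation over valid windows.
#'
#' @param windows Window table (needs `valid` and `pts` columns) for the
#'   epoch.
#' @param phi Threshold in (0, 1), default 0.75.
#' @param qc_pass Logical QC verdict for the epoch.
#' @param frac_required Required fraction of windows above `phi` (0.75).
#' @return List: `n_valid_windows`, `frac_above_phi`, `coherent`,
#'   `median_pts`, `mad_pts`, `flag`.
#' @export
classify_epoch <- function(windows, phi = 0.75, qc_pass = TRUE,
                           frac_required = 0.75) {
  stopifnot(phi > 0, phi < 1)
  p <- windows$pts[windows$valid & !is.na(windows$pts)]
  if (!length(p)) {
    return(list(n_valid_windows = 0L, frac_above_phi = 0,
                coherent = FALSE, median_pts = NA_real_, mad_pts = NA_real_,
                flag = "insufficient data"))
  }
  frac <- mean(p > phi)
  list(n_valid_windows = length(p), frac_above_phi = frac,
       coherent = isTRUE(frac >= frac_required && qc_pass),
       median_pts = stats::median(p),
       mad_pts = stats::mad(p, constant = 1),
       flag = NA_character_)
}

window_pts_of <- function(x, block = NULL) {
  if (inherits(x, "pts_result")) {
    w <- x$windows[x$windows$valid & !is.na(x$windows$pts), ]
    if (!is.null(block)) w <- w[w$block %in% block, ]
    return(w$pts)
  }
  x[is.finite(x)]
}

#' Baseline-coherence verdict (H1)
#'
#' Supported when at least 75% of the baseline analysis windows have a PTS
#' at or above `phi` (inclusive). `not_evaluated` without baseline windows.
#'
#' @param baseline Numeric window PTS values, or a `pts_result` (its
#'   baseline block is used).
#' @param phi Threshold, default 0.75.
#' @return `"supported"`, `"rejected"` or `"not_evaluated"`, with
#'   attribute `fraction`.
#' @export
decide_h1 <- function(baseline, phi = 0.75) {
  p <- window_pts_of(baseline, "baseline")
  if (!length(p)) return("not_evaluated")
  frac <- mean(p >= phi)
  structure(if (frac >= 0.75) "supported" else "rejected", fraction = frac)
}

#' Anesthetic-collapse verdict (H2)
#'
#' Evaluated only when H1 is supported. Supported when the PTS of the
#' steady-state ether block falls below `phi` for strictly more than 50% of
#' its windows and the block median is below `phi`.
#'
#' @param ether Numeric window PTS values of the ether block, or a
#'   `pts_result`.
#' @param h1 The H1 verdict.
#' @param phi Threshold, default 0.75.
#' @return `"supported"`, `"not_supported"` or `"not_evaluated"`.
#' @export
decide_h2 <- function(ether, h1 = "supported", phi = 0.75) {
  if (!identical(as.character(h1), "supported")) return("not_evaluated")
  p <- window_pts_of(ether, "ether")
  if (!length(p)) return("not_evaluated")
  ok <- mean(p < phi) > 0.5 && stats::median(p) < phi
  structure(if (ok) "supported" else "not_supported",
            frac_below = mean(p < phi), median = stats::median(p))
}

#' Detect post-wash-out stabilization of a PTS trace
#'
#' Scans a smoothed (rolling-median) window PTS trace for the first point
#' where the relative change stays below 5% across three consecutive
#' windows; returns the index of the first stabilized window or `NA` when
#' the trace never stabilizes.
#'
#' @param pts Window PTS values in temporal order.
#' @param rel_tol Relative-change tolerance (default 0.05).
#' @param run Number of consecutive windows required (default 3).
#' @param smooth Rolling-median half-width in windows (default 7; 0 disables
#'   smoothing).
#' @return Index into `pts`, or `NA_integer_`.
#' @export
stabilization_index <- function(pts, rel_tol = 0.05, run = 3L, smooth = 7L) {
  pts <- as.numeric(pts)
  n <- length(pts)
  if (n < run + 1) return(NA_integer_)
  tr <- if (smooth > 0 && n >= 2 * smooth + 1)
    as.numeric(zoo::rollmedian(zoo::zoo(pts), 2 * smooth + 1, fill = "extend"))
  else pts
  ref <- pmax(abs(tr[-n]), 1e-6)
  rc <- abs(diff(tr)) / ref
  ok <- rc < rel_tol
  for (i in seq_len(length(ok) - run + 1)) {
    if (all(ok[i:(i + run - 1)])) return(i)
  }
  NA_integer_
}

#' Wash-out recovery verdict (H3)
#'
#' Evaluated only when H2 is supported. The wash-out trace is tracked until
#' it stabilizes (relative change below 5% across three consecutive
#' windows); H3 is supported when the post-stabilization median PTS returns
#' to within +-10% of the individual's own baseline median and the phi gate
#' holds again (at least 75% of post-stabilization windows at or above
#' `phi`). Failure to stabilize within the session is a disconfirmation.
#'
#' @param washout Window PTS values of the wash-out block (temporal order),
#'   or a `pts_result`.
#' @param baseline_median Median PTS of the same plant's baseline windows.
#' @param h2 The H2 verdict.
#' @param phi Threshold, default 0.75.
#' @return `"supported"`, `"not_supported"` or `"not_evaluated"`, with
#'   diagnostic attributes (`stabilization_index`, `recovery_ratio`, and the
#'   auxiliary 90%-of-baseline and within-8% recovery descriptors).
#' @export
decide_h3 <- function(washout, baseline_median, h2 = "supported", phi = 0.75) {
  if (!identical(as.character(h2), "supported")) return("not_evaluated")
  p <- window_pts_of(washout, "washout")
  if (!length(p) || !is.finite(baseline_median) || baseline_median <= 0)
    return("not_evaluated")
  si <- stabilization_index(p)
  if (is.na(si)) return(structure("not_supported", stabilization_index = NA))
  post <- p[si:length(p)]
  med <- stats::median(post)
  ratio <- med / baseline_median
  gate <- mean(post >= phi) >= 0.75
  ok <- abs(ratio - 1) <= 0.10 && gate
  structure(if (ok) "supported" else "not_supported",
            stabilization_index = si, recovery_ratio = ratio,
            gate_fraction = mean(post >= phi),
            ge_90pct_of_baseline = ratio >= 0.9,
            within_8pct = abs(ratio - 1) <= 0.08)
}

#' Preregistered decision cascade for one plant
#'
#' Applies the H1 (baseline coherence), H2 (anesthetic collapse) and H3
#' (wash-out recovery) rules to the window PTS values of a session; H2 is
#' evaluated only if H1 is supported, H3 only if H2 is.
#'
#' @param result A `pts_result` for a session with baseline/ether/washout
#'   blocks, or a list with elements `baseline`, `ether`, `washout` of
#'   window PTS values.
#' @param phi Threshold, default 0.75.
#' @return List of class `pts_decision`: verdicts `h1`, `h2`, `h3`, block
#'   medians, and the stabilization time (seconds into the wash-out block,
#'   `NA` if never).
#' @export
decide_hypotheses <- function(result, phi = 0.75) {
  if (inherits(result, "pts_result")) {
    w <- result$windows[result$windows$valid & !is.na(result$windows$pts), ]
    get <- function(b) w$pts[w$block %in% b]
    blocks <- list(baseline = get("baseline"), ether = get("ether"),
                   washout = get("washout"))
    step_s <- result$diagnostics$step_s
  } else {
    blocks <- result
    step_s <- NA_real_
  }
  h1 <- decide_h1(blocks$baseline, phi)
  h2 <- decide_h2(blocks$ether, h1, phi)
  base_med <- if (length(blocks$baseline)) stats::median(blocks$baseline) else NA
  h3 <- decide_h3(blocks$washout, base_med, h2, phi)
  si <- attr(h3, "stabilization_index")
  structure(list(
    h1 = as.character(h1), h2 = as.character(h2), h3 = as.character(h3),
    baseline_median = base_med,
    ether_median = if (length(blocks$ether)) stats::median(blocks$ether) else NA,
    washout_median = if (length(blocks$washout)) stats::median(blocks$washout) else NA,
    stabilization_s = if (!is.null(si) && length(si) && is.finite(si) && is.finite(step_s))
      (si - 1) * step_s else NA_real_,
    h1_fraction = attr(h1, "fraction"),
    h3_recovery_ratio = attr(h3, "recovery_ratio")),
    class = "pts_decision")
}

#' @export
print.pts_decision <- function(x, ...) {
  cat("<pts_decision> H1:", x$h1, "| H2:", x$h2, "| H3:", x$h3, "\n")
  cat(sprintf("  medians baseline %.3f / ether %.3f / washout %.3f\n",
              x$baseline_median, x$ether_median, x$washout_median))
  invisible(x)
}

#' Paired-samples Cohen's d with stratified bootstrap CI
#'
#' `d = mean(a - b) / sd(a - b)` with a percentile bootstrap confidence
#' interval from resampling plants (the experimental unit) with replacement.
#'
#' @param a,b Paired per-plant values (equal length >= 3).
#' @param n_boot Bootstrap resamples (default 5000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List: `d`, `ci` (length 2), `n`, `flag`.
#' @export
cohens_d_paired <- function(a, b, n_boot = 5000L, conf = 0.95, seed = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0)
    return(list(d = NA_real_, ci = c(NA_real_, NA_real_), n = length(d),
                flag = "zero variance of differences"))
  est <- mean(d) / s
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    di <- d[sample.int(length(d), replace = TRUE)]
    si <- stats::sd(di)
    if (si == 0) NA_real_ else mean(di) / si
  }, 0)
  ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(d = est, ci = ci, n = length(d), flag = NA_character_)
}

#' Cluster-based permutation test of paired window PTS
#'
#' Paired t-statistics are computed per window position across plants;
#' clusters are maximal runs of contiguous windows with `|t|` above the
#' two-sided alpha = 0.05 critical value, scored by the sum of `|t|`
#' (cluster mass). The null distribution of the maximal cluster mass is
#' built by random within-plant condition flips, controlling the familywise
#' error rate without normality assumptions.
#'
#' @param a,b Matrices of window PTS, plants in rows, aligned window
#'   positions in columns (`a` and `b` are the two paired conditions).
#' @param n_perm Number of permutations (>= 500, default 1000).
#' @param seed Integer seed.
#' @param alpha Cluster-forming threshold (default 0.05, two-sided).
#' @return `data.frame` of clusters (`start`, `end`, `mass`, `p`); zero rows
#'   with attribute `p_max = 1` when no window is suprathreshold.
#' @export
cluster_permutation_test <- function(a, b, n_perm = 1000L, seed = 1L,
                                     alpha = 0.05) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)), n_perm >= 500)
  n <- nrow(a)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  tstat <- function(D) {
    mu <- colMeans(D)
    s <- apply(D, 2, stats::sd)
    ifelse(s == 0, 0, mu / (s / sqrt(n)))
  }
  clusters_of <- function(tv) {
    supra <- abs(tv) > tcrit
    if (!any(supra)) return(NULL)
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(keep, function(k)
                 sum(abs(tv[starts[k]:ends[k]])), 0))
  }
  D <- a - b
  obs <- clusters_of(tstat(D))
  if (is.null(obs))
    return(structure(data.frame(start = integer(), end = integer(),
                                mass = numeric(), p = numeric()), p_max = 1))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    fl <- sample(c(-1, 1), n, replace = TRUE)
    cl <- clusters_of(tstat(D * fl))
    if (is.null(cl)) 0 else max(cl$mass)
  }, 0)
  obs$p <- vapply(obs$mass, function(m)
    (1 + sum(null_max >= m)) / (n_perm + 1), 0)
  structure(obs, p_max = min(obs$p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via [stats::p.adjust()]; values flagged
#' significant at level `q`.
#'
#' @param p_values Numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return `data.frame(p, q_value, significant)`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, q_value = adj, significant = adj <= q)
}

#' Write a results JSON for one or more analyzed sessions
#'
#' Emits `{config, windows[], epochs[], conditions{}, decisions{}, stats{}}`
#' for downstream tooling; optionally a flat per-window CSV.
#'
#' @param results A `pts_result` or list of them (one per plant).
#' @param path Output JSON path.
#' @param csv_path Optional path for a flat window-level CSV.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, csv_path = NULL) {
  if (inherits(results, "pts_result")) results <- list(results)
  conds <- summarize_blocks(results)
  decisions <- lapply(results, function(r)
    tryCatch(unclass(decide_hypotheses(r, r$config$phi)),
             error = function(e) NULL))
  names(decisions) <- vapply(results, `[[`, "", "plant_id")
  payload <- list(
    config = unclass(results[[1]]$config),
    windows = lapply(results, function(r)
      r$windows[, c("index", "start_s", "end_s", "valid", "p_bar", "s_bar",
                    "tc", "pts", "block")]),
    epochs = lapply(results, `[[`, "epochs"),
    conditions = conds,
    decisions = decisions,
    stats = list())
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  if (!is.null(csv_path)) {
    flat <- do.call(rbind, lapply(results, function(r) {
      data.frame(plant_id = r$plant_id,
                 window_start_s = r$windows$start_s,
                 p_bar = r$windows$p_bar, s_bar = r$windows$s_bar,
                 tc = r$windows$tc, pts = r$windows$pts)
    }))
    data.table::fwrite(flat, csv_path)
  }
  invisible(path)
}
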