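#' Symbolize a series by ordinal patterns or quantile bins
#'
#' Ordinal scheme: each position `t` is coded by the rank order of
#' `(x[t], x[t+lag], ..., x[t+(m-1)*lag])` (ties broken by position), giving
#' one of `m!` symbols; the symbol series is shorter than the input by
#' `(m-1)*lag`. Quantile scheme: values are cut at empirical quantiles into
#' `n_bins` symbols of (near) equal occupancy.
#'
#' @param x Numeric series.
#' @param scheme `"ordinal"` or `"quantile_bins"`.
#' @param m Ordinal embedding dimension (2..5).
#' @param lag Ordinal embedding lag in samples (>= 1).
#' @param n_bins Bin count for the quantile scheme (>= 2).
#' @return Integer symbol series (values `1..K`).
#' @export
symbolize <- function(x, scheme = c("ordinal", "quantile_bins"),
                      m = 3L, lag = 1L, n_bins = 3L) {
  scheme <- match.arg(scheme)
  if (scheme == "quantile_bins") {
    stopifnot(n_bins >= 2)
    qs <- stats::quantile(x, probs = seq_len(n_bins - 1) / n_bins,
                          names = FALSE, type = 7)
    return(findInterval(x, unique(qs)) + 1L)
  }
  stopifnot(m >= 2, m <= 5, lag >= 1)
  n <- length(x) - (m - 1L) * lag
  if (n < 1) stop("series too short for ordinal embedding")
  cols <- lapply(0:(m - 1L), function(j) x[seq_len(n) + j * lag])
  # rank-vector encoding in base m (injective over permutations), position
  # tiebreak; recoded densely to 1..m! via a fixed lookup table
  code <- integer(n)
  for (j in seq_len(m)) {
    less <- integer(n)
    for (k in seq_len(m)) {
      if (k == j) next
      less <- less + as.integer(cols[[k]] < cols[[j]] |
                                  (cols[[k]] == cols[[j]] & k < j))
    }
    code <- code + less * m^(j - 1)
  }
  ordinal_lut(m)[code + 1L]
}

# dense symbol ids for all rank-vector codes of dimension m (cached)
.ordinal_luts <- new.env(parent = emptyenv())
ordinal_lut <- function(m) {
  key <- as.character(m)
  lut <- .ordinal_luts[[key]]
  if (is.null(lut)) {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    codes <- sort(vapply(perms(0:(m - 1L)),
                         function(r) sum(r * m^(seq_len(m) - 1L)), 0))
    lut <- integer(m^m)
    lut[codes + 1L] <- seq_along(codes)
    .ordinal_luts[[key]] <- lut
  }
  lut
}

# plug-in Shannon entropy (bits) from integer symbol counts
entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# plug-in mutual information I(A;B) in bits from aligned symbol series
mi_bits <- function(a, b) {
  Ka <- max(a); Kb <- max(b)
  j <- tabulate(a + Ka * (b - 1L), nbins = Ka * Kb)
  entropy_bits(tabulate(a, Ka)) + entropy_bits(tabulate(b, Kb)) -
    entropy_bits(j)
}

#' Active information storage of a symbol series
#'
#' Plug-in mutual information, in bits, between the `k`-symbol past and the
#' next symbol: `AIS = I(past_k ; next)`. Measures how much of a signal's
#' future is predictable from its own history (the self-reference proxy).
#' Returns `NA` with attribute `too_short = TRUE` when fewer than
#' `10 * (k + 1)` symbols are available.
#'
#' @param sym Integer symbol series (from [symbolize()]).
#' @param k History length in symbols (default 2).
#' @param horizon Positions ahead of the history at which the predicted
#'   symbol is taken (default 1 = the next symbol). Pipelines over
#'   oversampled series use horizons spanning real signal innovation.
#' @param spacing Positions between consecutive history symbols (default 1).
#'   Oversampled series use wider spacing so the history is not redundant.
#' @return AIS in bits (>= 0), or flagged `NA` for too-short input.
#' @export
ais <- function(sym, k = 2L, horizon = 1L, spacing = 1L) {
  span <- (k - 1L) * spacing + 1L
  n <- length(sym) - span - horizon + 1L
  if (length(sym) < 10 * (k + 1) || n < 10)
    return(structure(NA_real_, too_short = TRUE))
  K <- max(sym)
  past <- integer(n)
  mult <- 1L
  for (j in seq_len(k)) {
    past <- past + (sym[seq_len(n) + (j - 1L) * spacing] - 1L) * mult
    mult <- mult * K
  }
  past <- past + 1L
  nxt <- sym[seq_len(n) + span + horizon - 1L]
  # dense recode of past states to keep tables small
  up <- sort(unique(past))
  past <- match(past, up)
  max(0, mi_bits(past, nxt))
}

#' Functional connectivity graph of a window
#'
#' Complete weighted graph over channels with edge weight the absolute
#' Spearman rank correlation of the band-limited signals; a constant channel
#' contributes zero-weight edges. This is the input to the modularity
#' (division-creation) score.
#'
#' @param W Samples-by-channels matrix (>= 3 channels).
#' @return Symmetric weight matrix with zero diagonal.
#' @export
functional_graph <- function(W) {
  stopifnot(ncol(W) >= 3)
  n <- nrow(W)
  sds <- sqrt((colSums(W^2) - colSums(W)^2 / n) / (n - 1))
  A <- matrix(0, ncol(W), ncol(W))
  ok <- sds > 0
  if (sum(ok) >= 2) {
    C <- suppressWarnings(stats::cor(W[, ok, drop = FALSE], method = "spearman"))
    C[!is.finite(C)] <- 0
    A[ok, ok] <- abs(C)
  }
  diag(A) <- 0
  dimnames(A) <- list(colnames(W), colnames(W))
  A
}

#' Louvain modularity of a weighted graph
#'
#' Modularity Q of the best partition found by Louvain community detection
#' with a seed-controlled, reproducible node order.
#'
#' @param A Symmetric non-negative weight matrix (or an `igraph` graph).
#' @param seed Integer seed controlling Louvain tie-breaking.
#' @return Modularity Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(A, seed = 1L) {
  if (!igraph::is_igraph(A)) {
    if (!nrow(A)) stop("empty graph")
    if (any(A < 0)) stop("weights must be non-negative")
    A <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  }
  if (igraph::gorder(A) == 0) stop("empty graph")
  if (igraph::ecount(A) == 0 || sum(igraph::E(A)$weight) == 0) return(0)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  cl <- igraph::cluster_louvain(A)
  igraph::modularity(A, igraph::membership(cl),
                     weights = igraph::E(A)$weight)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Williams-Beer PID from a joint probability (or count) array p[x, y, t]
# returns synergy (bits, >= 0) plus the decomposition terms
williams_beer <- function(p) {
  d <- dim(p)
  Kx <- d[1]; Ky <- d[2]; Kt <- d[3]
  p <- p / sum(p)
  m <- matrix(p, Kx * Ky, Kt)
  pt <- colSums(m)
  pxy <- rowSums(m)
  px <- rowSums(matrix(pxy, Kx, Ky))
  py <- colSums(matrix(pxy, Kx, Ky))
  pxt <- rowsum(m, group = rep.int(seq_len(Kx), Ky), reorder = TRUE)
  pyt <- rowsum(m, group = rep(seq_len(Ky), each = Kx), reorder = TRUE)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  Ht <- H(pt)
  Ixt <- H(px) + Ht - H(pxt)
  Iyt <- H(py) + Ht - H(pyt)
  Ixyt <- H(pxy) + Ht - H(m)
  # redundancy = sum_t p(t) min_source I_spec(T = t; S)
  spec_info <- function(pst, ps) {
    L <- matrix(0, nrow(pst), ncol(pst))
    idx <- pst > 0
    L[idx] <- pst[idx] * log2(pst[idx] / (outer(ps, pt)[idx]))
    out <- colSums(L)
    out[pt > 0] <- out[pt > 0] / pt[pt > 0]
    out[pt <= 0] <- 0
    out
  }
  R <- sum(pt * pmin(spec_info(pxt, px), spec_info(pyt, py)))
  syn <- Ixyt - (Ixt - R) - (Iyt - R) - R
  list(synergy = max(0, syn), redundancy = R,
       unique_x = max(0, Ixt - R), unique_y = max(0, Iyt - R),
       joint_mi = Ixyt)
}

# batched Williams-Beer decomposition: counts is a (Kx*Ky*Kt) x M matrix of
# joint counts (cell index x fastest, then y, then t), one column per
# decomposition problem. Returns synergy and joint MI vectors of length M.
wb_batch <- function(counts, Kx, Ky, Kt) {
  P <- counts / rep(colSums(counts), each = nrow(counts))
  M <- ncol(P)
  x_of <- rep_len(seq_len(Kx), Kx * Ky * Kt)
  y_of <- rep_len(rep(seq_len(Ky), each = Kx), Kx * Ky * Kt)
  t_of <- rep(seq_len(Kt), each = Kx * Ky)
  ent <- function(Q) -colSums(Q * log2(Q + (Q == 0)))
  pt <- rowsum(P, t_of)
  pxy <- rowsum(P, x_of + Kx * (y_of - 1L))
  px <- rowsum(pxy, rep_len(seq_len(Kx), Kx * Ky))
  py <- rowsum(pxy, rep(seq_len(Ky), each = Kx))
  pxt <- rowsum(P, x_of + Kx * (t_of - 1L))
  pyt <- rowsum(P, y_of + Ky * (t_of - 1L))
  Ht <- ent(pt)
  Ixt <- ent(px) + Ht - ent(pxt)
  Iyt <- ent(py) + Ht - ent(pyt)
  Ixyt <- ent(pxy) + Ht - ent(P)
  spec <- function(pst, ps, Ks) {
    ps_e <- ps[rep_len(seq_len(Ks), Ks * Kt), , drop = FALSE]
    pt_e <- pt[rep(seq_len(Kt), each = Ks), , drop = FALSE]
    L <- matrix(0, Ks * Kt, M)
    idx <- pst > 0
    L[idx] <- pst[idx] * log2(pst[idx] / (ps_e[idx] * pt_e[idx]))
    S <- rowsum(L, rep(seq_len(Kt), each = Ks))
    S[pt > 0] <- S[pt > 0] / pt[pt > 0]
    S[pt <= 0] <- 0
    S
  }
  sx <- spec(pxt, px, Kx)
  sy <- spec(pyt, py, Ky)
  smin <- sx
  sel <- sy < sx
  smin[sel] <- sy[sel]
  R <- colSums(pt * smin)
  syn <- Ixyt - Ixt - Iyt + R
  list(synergy = pmax(0, syn), joint_mi = Ixyt,
       mi_x = Ixt, mi_y = Iyt, redundancy = R)
}
wb_batch_terms <- wb_batch

#' Williams-Beer synergy of two sources about a target
#'
#' Partial-information-decomposition synergy (bits): the information about
#' the target available only from the two sources jointly,
#' `I(X,Y;T) - unique_X - unique_Y - redundancy`, with redundancy given by
#' the Williams-Beer minimal specific information `I_min`. Canonical values:
#' 1 bit for `T = XOR(X, Y)` with fair independent bits, 0.5 bit for AND.
#' Returns 0 with attribute `degenerate = TRUE` for a constant target.
#'
#' @param x,y Integer symbol series for the two sources.
#' @param target Integer symbol series for the target, aligned with `x`, `y`.
#' @return Synergy in bits (>= 0).
#' @export
pid_synergy <- function(x, y, target) {
  stopifnot(length(x) == length(y), length(y) == length(target))
  if (length(unique(target)) < 2)
    return(structure(0, degenerate = TRUE))
  Kx <- max(x); Ky <- max(y); Kt <- max(target)
  p <- array(tabulate(x + Kx * (y - 1L) + Kx * Ky * (target - 1L),
                      nbins = Kx * Ky * Kt), dim = c(Kx, Ky, Kt))
  williams_beer(p)$synergy
}

#' Symbolic transfer entropy between two symbol series
#'
#' Plug-in transfer entropy in bits,
#' `TE = I(dest_next ; source_past | dest_past)`, with `history` symbols of
#' source and destination past. Captures directed information flow from
#' source to destination; 0 (flagged) when the source has no variation.
#'
#' @param source,dest Aligned integer symbol series.
#' @param history Past length in symbols (>= 1).
#' @param horizon Positions ahead of the history at which the predicted
#'   symbol is taken (default 1 = the next symbol).
#' @return TE in bits (>= 0).
#' @export
symbolic_te <- function(source, dest, history = 1L, horizon = 1L) {
  stopifnot(length(source) == length(dest), history >= 1)
  if (length(unique(source)) < 2)
    return(structure(0, flag_constant_source = TRUE))
  h <- as.integer(history)
  n <- length(dest) - h - horizon + 1L
  if (n < 10) return(structure(NA_real_, too_short = TRUE))
  embed_past <- function(s) {
    K <- max(s)
    p <- integer(n); mult <- 1L
    for (j in seq_len(h)) {
      p <- p + (s[seq_len(n) + j - 1L] - 1L) * mult
      mult <- mult * K
    }
    match(p, sort(unique(p)))
  }
  sp <- embed_past(source)
  dp <- embed_past(dest)
  dn <- dest[seq_len(n) + h + horizon - 1L]
  # I(dn; sp | dp) = H(dn,dp) + H(sp,dp) - H(dn,sp,dp) - H(dp)
  Kdn <- max(dn); Ksp <- max(sp); Kdp <- max(dp)
  H <- function(cnt) entropy_bits(cnt)
  h_dp <- H(tabulate(dp, Kdp))
  h_dndp <- H(tabulate(dn + Kdn * (dp - 1L), Kdn * Kdp))
  h_spdp <- H(tabulate(sp + Ksp * (dp - 1L), Ksp * Kdp))
  h_all <- H(tabulate(dn + Kdn * (sp - 1L) + Kdn * Ksp * (dp - 1L),
                      Kdn * Ksp * Kdp))
  max(0, h_dndp + h_spdp - h_all - h_dp)
}

# Welch power spectral density: Hann taper, 50% overlap
# returns list(freq, psd) excluding DC
welch_psd <- function(x, rate, seg_len = max(8L, floor(length(x) / 4))) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  U <- sum(w^2)
  nf <- floor(seg_len / 2)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1L)]
    (seg - mean(seg)) * w
  }, numeric(seg_len))
  P <- Mod(stats::mvfft(segs))^2 / (U * rate)
  list(freq = (1:nf) * rate / seg_len,
       psd = rowMeans(P[2:(nf + 1L), , drop = FALSE]))
}

#' Aperiodic 1/f spectral slope of a window
#'
#' Ordinary least-squares slope of `log10(PSD)` on `log10(f)` over the fit
#' range, from a Welch periodogram (Hann taper, segments of a quarter
#' window, 50% overlap). Points more than 2.5 residual SDs from the fit
#' (oscillatory peaks) are excluded iteratively before the final fit. The
#' effective lower fit edge is raised to `2 / window_duration` so at least
#' two cycles of the slowest fitted frequency fit in the window. Returns a
#' flagged `NA` when fewer than 5 PSD points fall in range.
#'
#' @param x Numeric window.
#' @param rate Sampling rate, Hz.
#' @param fit_range_hz `c(low, high)` fit range in Hz (default 0.01-5).
#' @return Slope beta (dimensionless; ~0 for white noise, ~-2 for Brownian
#'   noise).
#' @export
spectral_slope <- function(x, rate, fit_range_hz = c(0.01, 5)) {
  ps <- welch_psd(x, rate)
  lo <- max(fit_range_hz[1], 2 * rate / length(x))
  hi <- min(fit_range_hz[2], rate / 2)
  sel <- ps$freq >= lo & ps$freq <= hi & ps$psd > 0
  if (sum(sel) < 5) return(structure(NA_real_, too_few_points = TRUE))
  lf <- log10(ps$freq[sel]); lp <- log10(ps$psd[sel])
  ols <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
    c(my - b * mx, b)
  }
  keep <- rep(TRUE, length(lf))
  for (it in 1:5) {
    cf <- ols(lf[keep], lp[keep])
    res <- lp[keep] - (cf[1] + cf[2] * lf[keep])
    s <- stats::sd(res)
    if (s == 0) break
    out <- abs(res) > 2.5 * s
    if (!any(out) || sum(keep) - sum(out) < 5) break
    keep[which(keep)[out]] <- FALSE
  }
  ols(lf[keep], lp[keep])[2]
}
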