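test_that("active information storage matches analytic cases", {
  # alternating two-symbol sequence: H(next)=1 bit, fully predicted by past
  expect_equal(ais(rep(1:2, 100), k = 1), 1, tolerance = 1e-3)
  # period-4 cycle over 4 symbols: 2 bits
  expect_equal(ais(rep(1:4, 50), k = 1), 2, tolerance = 1e-3)
  # i.i.d. symbols carry (almost) no storage at n = 1e4
  set.seed(1)
  expect_lt(ais(sample(1:4, 1e4, TRUE), k = 1), 0.01)
  # too-short windows are flagged
  short <- ais(rep(1:2, 5), k = 2)
  expect_true(is.na(short) && isTRUE(attr(short, "too_short")))
})

test_that("ordinal symbolization is invariant to monotone rescaling", {
  set.seed(2)
  x <- cumsum(rnorm(500))
  s1 <- symbolize(x, "ordinal", m = 3, lag = 2)
  expect_identical(s1, symbolize(5 * x - 2, "ordinal", m = 3, lag = 2))
  expect_identical(s1, symbolize(exp(x / max(abs(x))), "ordinal", m = 3,
                                 lag = 2))
  # and so are the information metrics computed on them
  expect_equal(ais(s1, 2), ais(symbolize(x^3 + x, "ordinal", 3, 2), 2),
               tolerance = 1e-9)
})

test_that("functional graphs weight channel pairs by |rank correlation|", {
  set.seed(3)
  x <- rnorm(5000)
  W <- cbind(x, x, -x, rnorm(5000))
  A <- functional_graph(W)
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 1)   # anti-correlation counts in absolute value
  expect_lt(A[1, 4], 0.05)
  expect_equal(diag(A), rep(0, 4), ignore_attr = TRUE)
  # constant channel contributes zero-weight edges
  W2 <- cbind(x, rep(1, 5000), rnorm(5000))
  expect_equal(sum(functional_graph(W2)[2, ]), 0)
})

test_that("Louvain modularity matches analytic and brute-force values", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  expect_equal(modularity_q(A), 0.5, tolerance = 1e-9)
  K <- matrix(1, 6, 6); diag(K) <- 0
  expect_equal(modularity_q(K), 0, tolerance = 1e-9)
  # two 4-cliques joined by one bridge: Louvain finds the global optimum
  B <- A
  B[4, 5] <- B[5, 4] <- 1
  expect_equal(modularity_q(B), modularity_bruteforce(B), tolerance = 1e-9)
  expect_error(modularity_q(matrix(0, 0, 0)), "empty")
})

test_that("Williams-Beer synergy reproduces the canonical PID examples", {
  set.seed(4)
  x <- sample(0:1, 6000, TRUE)
  y <- sample(0:1, 6000, TRUE)
  expect_equal(pid_synergy(x + 1L, y + 1L, xor(x, y) + 1L), 1,
               tolerance = 0.01)
  expect_equal(pid_synergy(x + 1L, y + 1L, (x & y) + 1L), 0.5,
               tolerance = 0.02)
  expect_equal(as.numeric(pid_synergy(x + 1L, y + 1L, x + 1L)), 0,
               tolerance = 1e-9)
  degen <- pid_synergy(x + 1L, y + 1L, rep(1L, 6000))
  expect_equal(as.numeric(degen), 0)
  expect_true(isTRUE(attr(degen, "degenerate")))
})

test_that("batched Williams-Beer equals the independent oracle", {
  set.seed(5)
  for (i in 1:10) {
    x <- sample(1:3, 60, TRUE); y <- sample(1:3, 60, TRUE)
    t <- sample(1:3, 60, TRUE)
    cnt <- tabulate(x + 3L * (y - 1L) + 9L * (t - 1L), 27)
    got <- wb_batch(matrix(cnt, ncol = 1), 3, 3, 3)
    tab <- expand.grid(x = 1:3, y = 1:3, t = 1:3)
    tab$prob <- cnt / sum(cnt)
    want <- wb_oracle(tab)
    expect_equal(got$synergy, max(0, want$synergy), tolerance = 1e-9)
    expect_equal(got$joint_mi, want$joint_mi, tolerance = 1e-9)
  }
})

test_that("symbolic transfer entropy captures directed flow", {
  set.seed(6)
  x <- sample(0:1, 4000, TRUE)
  y <- c(0L, x[-4000])  # y is x delayed by one step
  expect_equal(symbolic_te(x + 1L, y + 1L, history = 1), 1, tolerance = 0.01)
  expect_lt(symbolic_te(y + 1L, x + 1L, history = 1), 0.01)
  # independent AR(1) series show only plug-in bias at n = 1e4
  a <- symbolize(as.numeric(arima.sim(list(ar = .5), 1e4)), "quantile_bins",
                 n_bins = 2)
  b <- symbolize(as.numeric(arima.sim(list(ar = .5), 1e4)), "quantile_bins",
                 n_bins = 2)
  expect_lt(symbolic_te(a, b, history = 1), 0.02)
  # constant source is flagged zero
  z <- symbolic_te(rep(1L, 100), y[1:100] + 1L)
  expect_equal(as.numeric(z), 0)
})

test_that("spectral slope recovers known exponents", {
  set.seed(7)
  beta_white <- mean(replicate(20, spectral_slope(rnorm(2^14), 50)))
  expect_lt(abs(beta_white), 0.2)
  beta_brown <- mean(replicate(10, spectral_slope(cumsum(rnorm(2^14)), 50)))
  expect_lt(abs(beta_brown + 2), 0.3)
  # inverse-FFT shaped spectrum with beta = -1.5 is recovered within 0.1
  shape <- function(n, beta, rate) {
    f <- (seq_len(n) - 1) / n * rate
    f <- pmin(f, rate - f)
    g <- ifelse(f > 0, f^(beta / 2), 0)
    Re(fft(fft(rnorm(n)) * g, inverse = TRUE)) / n
  }
  b <- mean(replicate(10, spectral_slope(shape(2^14, -1.5, 50), 50)))
  expect_lt(abs(b + 1.5), 0.1)
  # too few in-range points is flagged
  flagged <- spectral_slope(rnorm(64), 50, fit_range_hz = c(0.01, 0.05))
  expect_true(is.na(flagged))
})

test_that("information metrics are non-negative on arbitrary inputs", {
  set.seed(8)
  for (i in 1:20) {
    s1 <- symbolize(rnorm(300), "quantile_bins", n_bins = 3)
    s2 <- symbolize(cumsum(rnorm(300)), "ordinal", 3, 3)
    k <- min(length(s1), length(s2))
    expect_gte(ais(s1, 2), 0)
    expect_gte(symbolic_te(s1[1:k], s2[1:k], 1), 0)
    expect_gte(as.numeric(pid_synergy(s1[1:k], s2[1:k], rev(s1)[1:k])), 0)
  }
})
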