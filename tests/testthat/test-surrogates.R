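test_that("phase randomization preserves the amplitude spectrum exactly", {
  set.seed(11)
  for (n in c(256, 255)) {  # even and odd lengths
    x <- rnorm(n)
    s <- phase_shuffle(x, seed = 5)
    expect_lt(max(abs(Mod(fft(s)) - Mod(fft(x)))) / max(Mod(fft(x))), 1e-9)
    expect_true(is.numeric(s))
  }
  cst <- rep(3, 64)
  out <- phase_shuffle(cst, seed = 1)
  expect_identical(as.numeric(out), as.numeric(cst))
  expect_true(isTRUE(attr(out, "degenerate")))
})

test_that("phase-randomized surrogates keep the autocorrelation of AR(1)", {
  set.seed(21)
  d <- replicate(20, {
    x <- as.numeric(arima.sim(list(ar = 0.9), 1024))
    ac_x <- acf(x, plot = FALSE, lag.max = 1)$acf[2]
    ac_s <- acf(phase_shuffle(x), plot = FALSE, lag.max = 1)$acf[2]
    ac_s - ac_x
  })
  expect_lt(abs(mean(d)), 0.05)
})

test_that("IAAFT preserves the exact value distribution and converges", {
  set.seed(31)
  x <- rnorm(512)^3  # heavy-tailed marginal
  y <- iaaft(x, iters = 50, seed = 7)
  expect_identical(sort(y), sort(x))
  # spectral mismatch below 1% after 50 iterations for white noise
  w <- rnorm(512)
  ws <- iaaft(w, iters = 50, seed = 8)
  rel <- sqrt(sum((Mod(fft(ws)) - Mod(fft(w)))^2) / sum(Mod(fft(w))^2))
  expect_lt(rel, 0.01)
  # binary series stays a permutation
  b <- rep(c(0, 1), length.out = 64)
  expect_setequal(unique(iaaft(b, 10, seed = 2)), c(0, 1))
})

test_that("z-scoring against the null behaves per contract", {
  null <- null_summary(c(rnorm(30, 3, 1)))
  null$mean <- 3; null$sd <- 1
  expect_equal(zscore_vs_null(5, null), 2)
  expect_equal(zscore_vs_null(null$mean, null), 0)
  degen <- null_summary(rep(2, 25))
  z <- zscore_vs_null(5, degen)
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_error(zscore_vs_null(1, null_summary(rnorm(5))), ">= 20")
})

test_that("seeded surrogates are bit-identical and de-phase coupled pairs", {
  set.seed(41)
  x <- as.numeric(arima.sim(list(ar = 0.8), 512))
  expect_identical(phase_shuffle(x, seed = 9), phase_shuffle(x, seed = 9))
  expect_identical(iaaft(x, 20, seed = 9), iaaft(x, 20, seed = 9))

  # surrogating two coupled channels independently destroys their
  # phase locking (Monte-Carlo over seeds)
  rate <- 20
  t <- (seq_len(600) - 1) / rate
  drops <- replicate(30, {
    ph <- cumsum(rnorm(600, sd = 0.05)) + 2 * pi * 0.5 * t
    a <- sin(ph) + 0.3 * rnorm(600)
    b <- sin(ph + 1) + 0.3 * rnorm(600)
    p0 <- plv(a, b, rate, c(0.2, 1))
    p1 <- plv(phase_shuffle(a), phase_shuffle(b), rate, c(0.2, 1))
    p0 - p1
  })
  expect_gt(mean(drops), 0)
})

test_that("metric z-scores are unbiased under their own null", {
  set.seed(51)
  z <- replicate(100, {
    x <- rnorm(400)
    sym <- symbolize(x, "quantile_bins", n_bins = 3)
    obs <- ais(sym, k = 1)
    nulls <- replicate(25, ais(symbolize(phase_shuffle(x),
                                         "quantile_bins", n_bins = 3), k = 1))
    (obs - mean(nulls)) / sd(nulls)
  })
  expect_lt(abs(mean(z)), 0.2)
})
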