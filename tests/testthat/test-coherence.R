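test_that("phase-locking value matches analytic sinusoid cases", {
  rate <- 50
  t <- (seq_len(5000) - 1) / rate
  a <- sin(2 * pi * 1 * t)
  b <- sin(2 * pi * 1 * t + pi / 2)
  expect_equal(plv(a, a, rate, c(0.5, 2)), 1, tolerance = 1e-6)
  expect_equal(plv(a, b, rate, c(0.5, 2)), 1, tolerance = 1e-5)
  set.seed(9)
  expect_lt(plv(rnorm(10000), rnorm(10000), rate, c(0.5, 20)), 0.05)
  flg <- plv(a, rep(0, length(a)), rate, c(0.5, 2))
  expect_true(is.na(flg) && isTRUE(attr(flg, "zero_amplitude")))
})

test_that("weighted phase-lag index separates lagged from zero-lag coupling", {
  rate <- 50
  t <- (seq_len(5000) - 1) / rate
  a <- sin(2 * pi * 1 * t)
  b <- sin(2 * pi * 1 * t + pi / 2)   # quarter-cycle lag
  expect_equal(wpli(a, b, rate, c(0.5, 2)), 1, tolerance = 1e-9)
  expect_equal(wpli(a, 2 * a, rate, c(0.5, 2)), 0, tolerance = 1e-9)
  set.seed(10)
  w <- mean(replicate(20, wpli(rnorm(10000), rnorm(10000), rate, c(0.5, 20))))
  expect_lt(w, 0.1)
})

test_that("coherence measures are symmetric and bounded", {
  set.seed(11)
  rate <- 20
  x <- as.numeric(arima.sim(list(ar = 0.7), 800))
  y <- as.numeric(arima.sim(list(ar = 0.7), 800))
  expect_equal(plv(x, y, rate, c(0.2, 5)), plv(y, x, rate, c(0.2, 5)),
               tolerance = 1e-12)
  expect_equal(wpli(x, y, rate, c(0.2, 5)), wpli(y, x, rate, c(0.2, 5)),
               tolerance = 1e-12)
  for (i in 1:10) {
    v <- plv(rnorm(256), rnorm(256), rate, c(0.5, 5))
    w <- wpli(rnorm(256), rnorm(256), rate, c(0.5, 5))
    expect_true(v >= 0 && v <= 1)
    expect_true(w >= 0 && w <= 1)
  }
})

test_that("phase jitter monotonically degrades synchrony", {
  set.seed(12)
  rate <- 50
  t <- (seq_len(3000) - 1) / rate
  jit_grid <- seq(0, 2.25, length.out = 10)
  med_plv <- med_wpli <- numeric(10)
  for (k in seq_along(jit_grid)) {
    vals <- replicate(12, {
      ph <- 2 * pi * 1 * t + cumsum(rnorm(3000, sd = 0.02))
      a <- sin(ph) + 0.1 * rnorm(3000)
      b <- sin(ph + 1 + jit_grid[k] *
                 as.numeric(stats::filter(rnorm(3000, sd = 0.18), 0.95,
                                          method = "recursive"))) +
        0.1 * rnorm(3000)
      c(plv(a, b, rate, c(0.5, 2)), wpli(a, b, rate, c(0.5, 2)))
    })
    med_plv[k] <- median(vals[1, ])
    med_wpli[k] <- median(vals[2, ])
  }
  expect_lt(cor(jit_grid, med_plv, method = "spearman"), -0.9)
  expect_lt(cor(jit_grid, med_wpli, method = "spearman"), -0.9)
})

test_that("the TC gate fires at the nominal null rate", {
  # trivial threshold cases
  expect_equal(tc_flag(0.9, rep(0.4, 25)), 1L)
  expect_equal(tc_flag(0.4, rep(0.4, 25)), 0L)  # ties fail, strict >
  expect_error(tc_flag(0.5, rnorm(10)), ">= 20")
  # gating surrogate draws against their own null fires ~25% of the time
  set.seed(13)
  rates <- replicate(200, {
    null <- runif(40)
    tc_flag(runif(1), null)
  })
  expect_lt(abs(mean(rates) - 0.25), 0.07)
})

test_that("gate pairs honour band overlap and the cross-modality option", {
  chans <- rbind(channel("ca1", "ca", 20), channel("ca2", "ca", 20),
                 channel("v1", "voltage", 500), channel("o1", "o2", 1),
                 channel("h1", "heat", 5), channel("s1", "stim", 20))
  all <- gate_pairs(chans, cross_only = FALSE)
  # voltage x o2 and voltage x heat have empty band overlap, stim excluded
  nm <- paste(chans$name[all$i], chans$name[all$j])
  expect_false(any(grepl("s1", nm)))
  expect_false("v1 o1" %in% nm || "v1 h1" %in% nm)
  expect_true(all(all$lo < all$hi))
  cross <- gate_pairs(chans, cross_only = TRUE)
  expect_false(any(chans$modality[cross$i] == chans$modality[cross$j]))
})
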