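short_proto <- function(seed = 5, minutes = 6, blocks = NULL, ...) {
  if (is.null(blocks))
    blocks <- data.frame(name = "baseline", start_min = 0,
                         end_min = minutes)
  pts_protocol(n_plants = 2, session_min = minutes, blocks = blocks,
               rate_hz = 50, seed = seed, ...)
}

test_that("identical protocol, plant and seed give bit-identical output", {
  p <- short_proto()
  r1 <- simulate_recording(p, 1, 5)
  r2 <- simulate_recording(p, 1, 5)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(p, 2, 5)
  expect_false(identical(r1$data, r3$data))
})

test_that("ether stretch draws stay in the three-to-five-fold range", {
  p <- short_proto(minutes = 9, blocks = data.frame(
    name = c("baseline", "ether", "washout"),
    start_min = c(0, 3, 6), end_min = c(3, 6, 9)))
  draws <- sapply(1:10, function(i)
    attr(simulate_recording(p, i, 5), "regime_draws")$delay_stretch)
  expect_true(all(draws >= 3 & draws <= 5))
})

test_that("generated channels concentrate power in their declared bands", {
  p <- short_proto(minutes = 30)
  rec <- simulate_recording(p, 1, 5)
  for (j in which(rec$channels$modality %in% c("ca", "voltage"))) {
    x <- rec$data[, j]
    X <- Mod(fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) / length(x) * rec$rate
    f <- pmin(f, rec$rate - f)
    inband <- f >= rec$channels$band_low[j] * 0.8 &
      f <= rec$channels$band_high[j] * 1.2
    expect_gt(sum(X[inband]) / sum(X), 0.8)
  }
  expect_false(anyNA(rec$data))
  expect_true(all(is.finite(rec$data)))
})

test_that("overlapping protocol blocks are rejected", {
  expect_error(pts_protocol(blocks = data.frame(
    name = c("baseline", "ether"), start_min = c(0, 50),
    end_min = c(60, 120)), session_min = 120), "overlap")
  expect_error(pts_protocol(blocks = data.frame(
    name = c("baseline", "ether"), start_min = c(0, 80),
    end_min = c(60, 120)), session_min = 120), "tile")
})

test_that("ether decoheres the wave: baseline beats ether wPLI", {
  # direct Monte-Carlo on the generator output, bypassing the full pipeline
  wins <- function(rec, from_s, to_s, n = 12) {
    fastc <- which(rec$channels$modality %in% c("ca", "voltage"))
    starts <- round(seq(from_s, to_s - 6, length.out = n) * rec$rate) + 1
    sapply(starts, function(s) {
      W <- rec$data[s:(s + 299), fastc]
      mean(c(wpli(W[, 1], W[, 4], 50, c(1/6, 0.5)),
             wpli(W[, 2], W[, 5], 50, c(1/6, 0.5)),
             wpli(W[, 3], W[, 6], 50, c(1/6, 0.5))), na.rm = TRUE)
    })
  }
  p <- short_proto(minutes = 24, blocks = data.frame(
    name = c("baseline", "ether", "washout"),
    start_min = c(0, 8, 16), end_min = c(8, 16, 24)))
  diffs <- sapply(1:10, function(i) {
    rec <- bandlimit(simulate_recording(p, i, 11))
    mean(wins(rec, 60, 420)) - mean(wins(rec, 660, 900))
  })
  expect_gt(mean(diffs > 0), 0.85)
})

test_that("stimulus schedules inject events and a stim channel", {
  p <- short_proto(minutes = 6, stimuli = TRUE)
  rec <- simulate_recording(p, 1, 5)
  ev <- attr(rec, "events")
  expect_true(all(ev$kind == "blue_light"))
  expect_true(all(diff(ev$onset_s) == 60))
  expect_true("stim" %in% rec$channels$modality)
  sc <- rec$data[, rec$channels$modality == "stim"]
  expect_setequal(unique(sc), c(0, 1))
})

test_that("the figure protocol spans 18 ten-minute epochs", {
  proto <- fig_protocol(n_plants = 3)
  expect_equal(proto$session_min, 180)
  ep <- make_epochs(proto$session_min * 60, 600)
  expect_equal(nrow(ep), 18)
  expect_equal(proto$blocks$name, c("baseline", "ether", "washout"))
})

test_that("tau pairs share a drive and identical seeds reproduce exactly", {
  p1 <- simulate_tau_pair(2, 2, coupling = 1, seed = 3, n_windows = 20)
  p2 <- simulate_tau_pair(2, 2, coupling = 1, seed = 3, n_windows = 20)
  expect_identical(p1$rec_a$data, p2$rec_a$data)
  expect_identical(p1$rec_b$data, p2$rec_b$data)
  # the two systems of a pair are distinct realizations
  expect_false(identical(p1$rec_a$data, p1$rec_b$data))
  # drive is a deterministic function of real time
  expect_equal(p1$drive(c(0, 10, 100)), p2$drive(c(0, 10, 100)))
})
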