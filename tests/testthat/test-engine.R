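test_that("z-scores map to strengths through the normal CDF", {
  expect_equal(strength_from_z(0), 0.5)
  expect_gt(strength_from_z(8), 1 - 1e-9)
  expect_equal(strength_from_z(-1.6449), 0.05, tolerance = 1e-3)
})

test_that("central pattern strength is the median of five components", {
  expect_equal(p_bar(c(0.1, 0.2, 0.5, 0.8, 0.9)), 0.5)
  expect_equal(p_bar(rep(0.7, 5)), 0.7)
  expect_equal(p_bar(c(0, 0, 1, 1, 1)), 1)
  expect_true(is.na(p_bar(c(0.1, NA, 0.5, 0.8, 0.9))))
})

test_that("window PTS is the gated product", {
  expect_equal(window_pts(0.9, 0.8, 1), 0.72)
  expect_equal(window_pts(0.9, 0.8, 0), 0)
  expect_equal(window_pts(1, 1, 1), 1)
  # vectorized and always inside [0, 1]
  p <- runif(100); s <- runif(100); tc <- rbinom(100, 1, 0.5)
  v <- window_pts(p, s, tc)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(v[tc == 0] == 0))
})

test_that("sub-series synergy profile solves the engineered XOR case", {
  set.seed(14)
  n <- 400
  a <- sample(0:1, n, TRUE)
  b <- sample(0:1, n, TRUE)
  state <- xor(a, b) + 1L
  scores <- cbind(a, b, rnorm(n), rnorm(n), rnorm(n))
  sp <- synergy_profile(scores, state)
  # the engineered pair (patterns 1, 2) carries pure synergy about the state
  expect_equal(sp$pair_synergy[1], 1, tolerance = 1e-2)
  expect_true(all(sp$pair_synergy >= 0 & sp$pair_synergy <= 1))
  expect_true(sp$s_bar >= 0 && sp$s_bar <= 1)
  # degenerate state
  expect_equal(synergy_profile(scores, rep(1L, n))$s_bar, 0)
})

test_that("epoch classification applies the 75% dual gate", {
  mkwin <- function(pts) data.frame(valid = rep(TRUE, length(pts)),
                                    pts = pts)
  nine <- classify_epoch(mkwin(c(rep(0.9, 9), rep(0.1, 3))), phi = 0.75)
  expect_true(nine$coherent)
  expect_equal(nine$frac_above_phi, 0.75)
  eight <- classify_epoch(mkwin(c(rep(0.9, 8), rep(0.1, 4))), phi = 0.75)
  expect_false(eight$coherent)
  none <- classify_epoch(mkwin(numeric(0)), phi = 0.75)
  expect_false(none$coherent)
  expect_equal(none$flag, "insufficient data")
  # QC failure vetoes coherence
  expect_false(classify_epoch(mkwin(rep(0.9, 10)), qc_pass = FALSE)$coherent)
  # verdict invariant under window reordering
  set.seed(15)
  p <- runif(40)
  a <- classify_epoch(mkwin(p))
  b <- classify_epoch(mkwin(sample(p)))
  expect_equal(a$coherent, b$coherent)
  expect_equal(a$median_pts, b$median_pts)
})

test_that("the H1-H3 decision cascade follows the preregistered logic", {
  expect_equal(as.character(decide_h1(c(rep(0.8, 80), rep(0.1, 20)))),
               "supported")
  expect_equal(as.character(decide_h1(c(rep(0.8, 74), rep(0.1, 26)))),
               "rejected")
  expect_equal(as.character(decide_h1(c(rep(0.75, 75), rep(0.1, 25)))),
               "supported")  # >= is inclusive at both thresholds
  expect_equal(decide_h1(numeric(0)), "not_evaluated")

  eth_low <- c(rep(0.2, 60), rep(0.9, 40))
  expect_equal(as.character(decide_h2(eth_low, h1 = "supported")), "supported")
  expect_equal(as.character(decide_h2(c(rep(0.2, 50), rep(0.9, 50)),
                                      h1 = "supported")), "not_supported")
  expect_equal(decide_h2(eth_low, h1 = "rejected"), "not_evaluated")

  base_med <- 0.8
  wash_ok <- rep(0.8 * 0.95, 50)
  expect_equal(as.character(decide_h3(wash_ok, base_med, h2 = "supported")),
               "supported")
  wash_low <- rep(0.8 * 0.85, 50)
  expect_equal(as.character(decide_h3(wash_low, base_med, h2 = "supported")),
               "not_supported")
  # a trace that never stabilizes is a disconfirmation
  set.seed(16)
  unstable <- abs(cumsum(rnorm(60, sd = 2)))
  unstable <- unstable / max(unstable)
  res <- decide_h3(unstable * rep(c(0.1, 0.9), 30), base_med,
                   h2 = "supported")
  expect_true(res %in% c("not_supported", "supported"))
  expect_equal(decide_h3(wash_ok, base_med, h2 = "not_supported"),
               "not_evaluated")
  # cascade wiring: h2 not evaluated unless h1 supported, h3 unless h2
  dec <- decide_hypotheses(list(baseline = rep(0.2, 50),
                                ether = rep(0.1, 50),
                                washout = rep(0.8, 50)))
  expect_equal(dec$h1, "rejected")
  expect_equal(dec$h2, "not_evaluated")
  expect_equal(dec$h3, "not_evaluated")
})

test_that("stabilization detection finds flat runs", {
  flatafter <- c(seq(0.1, 0.8, length.out = 20), rep(0.8, 30))
  i <- stabilization_index(flatafter, smooth = 0)
  expect_true(is.finite(i) && i <= 25)
  expect_true(is.na(stabilization_index(c(1, 2), smooth = 0)))
})

test_that("paired Cohen's d and its bootstrap behave", {
  d <- cohens_d_paired(c(1.5, 1.4, 1.6), c(1.0, 1.0, 1.0), n_boot = 500)
  expect_equal(d$d, 5, tolerance = 1e-9)
  same <- cohens_d_paired(1:5, 1:5)
  expect_true(is.na(same$d))
  expect_match(same$flag, "zero variance")
  # CI contains the point estimate in (almost) all seeded runs
  set.seed(17)
  hits <- replicate(100, {
    a <- rnorm(12, 1); b <- rnorm(12)
    r <- cohens_d_paired(a, b, n_boot = 200, seed = sample.int(1e6, 1))
    r$ci[1] <= r$d && r$d <= r$ci[2]
  })
  expect_gte(mean(hits), 0.99)
})

test_that("cluster permutation test controls errors and finds real blocks", {
  set.seed(18)
  # identical conditions -> no suprathreshold window, p = 1
  a <- matrix(rnorm(8 * 40), 8)
  out <- cluster_permutation_test(a, a, n_perm = 500)
  expect_equal(attr(out, "p_max"), 1)
  # power: a contiguous 2-SD shift over 30% of windows is detected
  hits <- replicate(20, {
    a <- matrix(rnorm(8 * 40), 8)
    b <- a
    b[, 15:26] <- b[, 15:26] - 2
    cl <- cluster_permutation_test(a, b, n_perm = 500,
                                   seed = sample.int(1e6, 1))
    nrow(cl) > 0 && min(cl$p) < 0.05 &&
      any(cl$start <= 26 & cl$end >= 15)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment reproduces hand-computed q-values", {
  out <- bh_fdr(c(0.01, 0.02, 0.9))
  expect_equal(out$q_value, c(0.03, 0.03, 0.9))
  expect_equal(bh_fdr(0.01)$q_value, 0.01)
  expect_equal(bh_fdr(rep(1, 4))$q_value, rep(1, 4))
  expect_false(any(diff(sort(out$q_value)) < 0))
})
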