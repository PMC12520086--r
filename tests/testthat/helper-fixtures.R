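# shared fixtures and independent oracles

# tiny two-channel recording on a uniform grid
toy_recording <- function(n = 2000, rate = 20, tau = 2) {
  t <- (seq_len(n) - 1) / rate
  chans <- rbind(channel("ca1", "ca", rate),
                 channel("v1", "voltage", rate),
                 channel("v2", "voltage", rate))
  X <- cbind(sin(2 * pi * 0.3 * t), sin(2 * pi * 1 * t + 1),
             cos(2 * pi * 0.7 * t))
  pts_recording(X, chans, rate = rate, tau = tau)
}

# independent Williams-Beer oracle: direct computation from an explicit
# joint probability table over (x, y, t), all terms from first principles
wb_oracle <- function(p) {
  # p: data.frame(x, y, t, prob)
  H <- function(tab) { q <- tab[tab > 0]; -sum(q * log2(q)) }
  marg <- function(vars) {
    agg <- aggregate(p$prob, by = lapply(vars, function(v) p[[v]]), sum)
    agg$x
  }
  Ht <- H(marg("t"))
  Ixt <- H(marg("x")) + Ht - H(marg(c("x", "t")))
  Iyt <- H(marg("y")) + Ht - H(marg(c("y", "t")))
  Ixyt <- H(marg(c("x", "y"))) + Ht - H(p$prob)
  pt <- aggregate(p$prob, by = list(t = p$t), sum)
  spec <- function(sv) {
    sapply(pt$t, function(tv) {
      sel <- p$t == tv
      st <- aggregate(p$prob[sel], by = list(s = p[[sv]][sel]), sum)
      ps <- aggregate(p$prob, by = list(s = p[[sv]]), sum)
      ptv <- pt$x[pt$t == tv]
      sum(sapply(seq_len(nrow(st)), function(i) {
        pst <- st$x[i]; psm <- ps$x[ps$s == st$s[i]]
        if (pst <= 0) 0 else (pst / ptv) * log2(pst / (psm * ptv))
      }))
    })
  }
  R <- sum(pt$x * pmin(spec("x"), spec("y")))
  list(synergy = Ixyt - (Ixt - R) - (Iyt - R) - R, redundancy = R,
       joint_mi = Ixyt)
}

# brute-force maximal modularity over all partitions of a small graph
modularity_bruteforce <- function(A) {
  n <- nrow(A)
  m2 <- sum(A)
  deg <- rowSums(A)
  best <- -Inf
  # enumerate set partitions via restricted growth strings
  rgs <- function(prefix, maxv) {
    if (length(prefix) == n) {
      memb <- prefix
      q <- 0
      for (c in unique(memb)) {
        idx <- memb == c
        q <- q + sum(A[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
      }
      best <<- max(best, q)
      return(invisible())
    }
    for (v in seq_len(maxv + 1))
      rgs(c(prefix, v), max(maxv, v))
    invisible()
  }
  rgs(1L, 1L)
  best
}

# memoized desk-scale cohort shared by the acceptance tests
.acc_env <- new.env(parent = emptyenv())
acceptance_cohort <- function(n_plants = 6, seed = 42) {
  key <- paste0("c", n_plants, "_", seed)
  if (is.null(.acc_env[[key]])) {
    recs <- simulate_cohort(n_plants = n_plants, seed = seed)
    .acc_env[[key]] <- lapply(recs, function(r)
      compute_pts(r, pts_config_test_scale(tau = 2)))
  }
  .acc_env[[key]]
}
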