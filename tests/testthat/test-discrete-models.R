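test_that("oriented percolation: trivial laws and one-generation probabilities", {
  real0 <- simulate_op(k11(), p = 0, n_max = 4, seed = 1)
  expect_true(all(vapply(real0$generations[-1], nrow, 1L) == 0L))

  # d = 1, L = 1, p = 1: two independent Bernoulli(1/2) bonds out of the root
  set.seed(2)
  empty1 <- 0L
  reps <- 2e4
  sizes1 <- integer(reps)
  for (r in seq_len(reps)) {
    real <- simulate_op(k11(), p = 1, n_max = 1)
    sizes1[r] <- nrow(real$generations[[2]])
  }
  p_empty <- mean(sizes1 == 0L)
  expect_lt(abs(p_empty - 0.25), 3 * sqrt(0.25 * 0.75 / reps))
  expect_lt(abs(mean(sizes1) - 1), 3 * sd(sizes1) / sqrt(reps))  # E|T_1| = p

  # E|T_1| = p for a non-trivial p and the d = 2 kernel
  set.seed(3)
  s <- vapply(seq_len(5000), function(i)
    nrow(simulate_op(k21(), p = 0.8, n_max = 1)$generations[[2]]), 1L)
  expect_lt(abs(mean(s) - 0.8), 3 * sd(s) / sqrt(5000))
})

test_that("oriented percolation: conditional mean bond growth is p|T_n| (regression through origin)", {
  # E[occupied bonds out of T_n | T_n] = p |T_n| exactly (site counts lose
  # mass to coinciding targets, so the identity is tested on bond counts)
  set.seed(4)
  xs <- ys <- numeric(0)
  for (r in 1:800) {
    real <- simulate_op(k11(), p = 0.9, n_max = 6)
    sz <- vapply(real$generations, nrow, 1L)
    nb <- vapply(real$bonds, nrow, 1L)
    xs <- c(xs, sz[1:6])
    ys <- c(ys, nb[1:6])
  }
  keep <- xs > 0
  fit <- stats::lm(ys[keep] ~ 0 + xs[keep])
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf[1, 1] - 0.9), 3 * cf[1, 2])
  # and the collapsed site counts cannot exceed the bond counts
  expect_true(all(ys <= pmax(2 * xs, 0) + 1e-9))
})

test_that("oriented percolation reachability equals brute-force path enumeration", {
  op <- make_fixture("op_three_gen")
  sys <- op_ancestral_system(op)
  for (m in 0:3) for (n in m:3) {
    om <- op$generations[[m + 1]]; on <- op$generations[[n + 1]]
    for (i in seq_len(nrow(om))) for (j in seq_len(nrow(on)))
      expect_identical(sys$query(m, n, om[i, ], on[j, ]),
                       op_reach_bruteforce(op, m, om[i, ], n, on[j, ]))
  }
  # random realizations against the oracle
  set.seed(5)
  for (r in 1:10) {
    real <- simulate_op(k11(), p = 0.95, n_max = 4)
    s <- op_ancestral_system(real)
    for (m in 0:3) for (n in m:4) {
      om <- real$generations[[m + 1]]; on <- real$generations[[n + 1]]
      if (!nrow(om) || !nrow(on)) next
      i <- sample.int(nrow(om), 1); j <- sample.int(nrow(on), 1)
      expect_identical(s$query(m, n, om[i, ], on[j, ]),
                       op_reach_bruteforce(real, m, om[i, ], n, on[j, ]))
    }
  }
})

test_that("branching random walk: delta_1 law is a single walk; critical mass is a martingale", {
  real <- simulate_brw(offspring_delta(1), k11(), 10, seed = 6)
  expect_true(all(vapply(real$positions, nrow, 1L) == 1L))

  # generation-n position variance of the single walk is n * sigma2_D
  set.seed(7)
  n <- 15
  pos <- vapply(seq_len(4000), function(i)
    simulate_brw(offspring_delta(1), k21(), n)$positions[[n + 1]][1, 1], 0L)
  v <- mean(pos^2)
  expect_lt(abs(v - n * 0.75), 4 * sd(pos^2) / sqrt(4000))

  # critical binary: particle count at generation 20 has mean 1
  set.seed(8)
  cnt <- vapply(seq_len(10000), function(i) {
    ps <- simulate_brw(offspring_binary(), k11(), 20)$positions
    if (length(ps) >= 21) nrow(ps[[21]]) else 0L
  }, 1L)
  expect_lt(abs(mean(cnt) - 1), 3 * sd(cnt) / sqrt(10000))
})

test_that("Galton-Watson survival matches the generating-function recursion", {
  law <- offspring_binary()
  expect_equal(gw_survival_experiment(offspring_delta(0), 1, 100, seed = 1)$value, 0)
  for (n in c(25, 100, 200)) {
    est <- gw_survival_experiment(law, n, 5e4, seed = 10 + n)
    expect_lt(abs(est$value - n * gw_survival_exact(law, n)), 3 * est$se)
  }
})

test_that("Yaglom law: exponential rate, variance-2 law, and KS distributional check", {
  law <- offspring_binary()
  n <- 100
  yg <- gw_yaglom_experiment(law, n, min_survivors = 3000, seed = 11)
  exact <- n * gw_survival_exact(law, n)   # the estimator targets n P(Z_n>0)
  expect_lt(abs(yg$value - exact), 4 * yg$se)
  expect_lt(abs(yg$value - 2), 0.2)        # near the limiting rate 2/gamma

  l2 <- law_var2()
  expect_equal(l2$mean, 1)
  expect_equal(l2$variance, 2)
  yg2 <- gw_yaglom_experiment(l2, n, min_survivors = 3000, seed = 12)
  expect_lt(abs(yg2$value - 1), 0.1)       # 2/gamma with gamma = 2

  # distributional check of the conditional sample.  Independent oracle:
  # the exact law of Z_n is recovered by iterating the offspring pgf on the
  # unit circle and inverting with an FFT.
  K <- 8192
  z <- exp(2i * pi * (0:(K - 1)) / K)
  for (g in seq_len(n)) z <- (1 + z^2) / 2
  pmf <- Re(stats::fft(z)) / K
  expect_lt(abs(sum(pmf) - 1), 1e-9)
  p_surv <- 1 - pmf[1]
  expect_equal(p_surv, gw_survival_exact(law, n), tolerance = 1e-9)
  cond_cdf <- cumsum(pmf[-1]) / p_surv          # P(Z_n <= k | Z_n > 0)
  # empirical sample vs the exact conditional law: sampling error only
  x <- yg$extra$sample
  ks_vals <- sort(unique(x))
  Fhat <- stats::ecdf(x)(ks_vals)
  Fex <- cond_cdf[pmin(round(ks_vals * n), K - 1)]
  expect_lt(max(abs(Fhat - Fex)), 1.63 / sqrt(length(x)))
  # the exact conditional law is already close to the fitted exponential
  # (midpoint-corrected for the even-integer lattice of the binary law)
  Fexp <- stats::pexp(ks_vals + 1 / n, rate = yg$value)
  expect_lt(max(abs(Fex - Fexp)), 0.05)
})

test_that("integrated-mass Laplace functional: exact endpoints, monotonicity, closed form", {
  law <- offspring_binary()
  pars <- sbm_params(gamma = 1)
  lp0 <- gw_laplace_experiment(law, 0, 50, 2000, seed = 13)
  expect_equal(lp0$value, 1)
  vals <- vapply(c(0.5, 1, 2, 4), function(l)
    gw_laplace_experiment(law, l, 50, 20000, seed = 14)$value, 0)
  expect_true(all(diff(vals) < 0))
  lp <- gw_laplace_experiment(law, 1, 100, 1e5, seed = 15)
  cf <- laplace_integrated_mass(pars, 1)
  expect_lt(abs(lp$value - cf), 3 * lp$se + 0.1 * cf)
})

test_that("critical-scale probe for oriented percolation is reproducible and sane", {
  pc <- estimate_p_c(k11(), c(0.5, 2), n_probe = 12, reps = 300, seed = 16,
                     n_iter = 4)
  expect_true(pc$bracket[1] < pc$bracket[2])
  expect_true(all(pc$bracket >= 0.5 & pc$bracket <= 2))
  pc2 <- estimate_p_c(k11(), c(0.5, 2), n_probe = 12, reps = 300, seed = 16,
                      n_iter = 4)
  expect_identical(pc$bracket, pc2$bracket)
})
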