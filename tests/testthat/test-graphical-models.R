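test_that("degenerate horizons and hand fixtures trace correctly", {
  sim <- simulate_voter(k11(), t_max = 0, seed = 1)
  expect_equal(sim$trajectory$final_set, matrix(0L, 1, 1))
  expect_equal(sim$trajectory$n_events, 0)
  expect_identical(sim$trajectory$status, "alive")

  # single arrow at 0.3 from the origin to +1: the +1 site adopts opinion 1
  fx <- make_fixture("voter_single_arrow")
  occ <- occupied_at(fx, 1)
  expect_setequal(occ[, 1], c(0L, 1L))
  expect_equal(radius(range_of(fx)), 1)

  # contact fixture: arrow 0.4 (origin infects +1), recovery 0.9 at origin
  cp <- make_fixture("cp_recovery_arrow")
  expect_setequal(occupied_at(cp, 0.5)[, 1], c(0L, 1L))
  expect_equal(occupied_at(cp, 1.0)[, 1], 1L)
})

test_that("dual walks reproduce the backward trace, cocycle and coalescence", {
  fx <- make_fixture("voter_two_arrow")
  pw <- dual_walk(fx, 1, 0)
  expect_equal(pw$jump_times, 0.3)          # jumps to +1 at backward time 0.7
  expect_equal(as.integer(pw$sites), 1L)
  expect_equal(dual_position(pw, 0.5), 0L)
  expect_equal(dual_position(pw, 0.7), 0L)  # holds the old site at the jump
  expect_equal(dual_position(pw, 0.71), 1L)
  expect_equal(dual_position(pw, 1.5), 0L)  # (t - s)^+ convention

  # a site with no arrows into it has a constant dual
  pw2 <- dual_walk(fx, 1, 5)
  expect_equal(length(pw2$jump_times), 0L)
  expect_equal(dual_position(pw2, 0.9), 5L)

  # cocycle W^{t,x}_{t-u} = W^{s, W^{t,x}_{t-s}}_{s-u} on simulated records
  set.seed(33)
  sim <- simulate_voter(k11(), 3)
  for (x in c(0L, 1L, -1L)) {
    t <- 3
    pw <- dual_walk(sim$record, t, x)
    for (s in c(2.5, 1.5, 0.7)) for (u in c(0.5, 0.2)) {
      mid <- dual_position(pw, t - s)
      inner <- dual_walk(sim$record, s, mid)
      expect_identical(dual_position(pw, t - u),
                       dual_position(inner, s - u))
    }
  }

  # two duals that meet stay together afterwards (backwards)
  set.seed(51)
  sim2 <- simulate_voter(k21(), 4)
  occ <- occupied_at(sim2$record, 4)
  if (nrow(occ) >= 2) {
    p1 <- dual_walk(sim2$record, 4, occ[1, ])
    p2 <- dual_walk(sim2$record, 4, occ[2, ])
    met <- FALSE
    for (s in seq(0, 4, by = 0.05)) {
      a <- dual_position(p1, 4 - s); b <- dual_position(p2, 4 - s)
      if (met) expect_identical(a, b)
      if (identical(a, b)) met <- TRUE
    }
  }
  succeed()
})

test_that("voter mass is a martingale and emptiness is absorbing", {
  mm <- estimate_mean_mass(model_spec("voter", k21()), 2, 5000, seed = 4)
  expect_lt(abs(mm$value - 1), 3 * mm$se)

  set.seed(5)
  for (i in 1:20) {
    sim <- simulate_voter(k11(), 6)
    sz <- sim$trajectory$sizes
    if (any(sz == 0L))
      expect_true(all(sz[seq.int(which(sz == 0L)[1], length(sz))] == 0L))
    if (identical(sim$trajectory$status, "extinct"))
      expect_equal(sz[length(sz)], 0L)
  }
})

test_that("contact process: exponential death at lambda = 0 and monotone thinning coupling", {
  # lambda = 0: the origin dies at its first recovery mark, S ~ Exp(1)
  set.seed(6)
  b <- sbmlattice:::.spec_batch(model_spec("contact", k11(), lambda = 0),
                                Inf, NULL, 2e4, sim_caps())
  expect_true(all(b$status == 1L))
  expect_lt(abs(mean(b$survival_time) - 1), 3 / sqrt(2e4))

  # thinning coupling: drop arrows of a lambda2 record independently with
  # probability 1 - lambda1/lambda2 -> a valid lambda1 realization whose
  # infected set is contained in the lambda2 one at every time
  set.seed(61)
  for (rep in 1:10) {
    sim2 <- simulate_contact(k11(), lambda = 2, t_max = 3)
    rec2 <- sim2$record
    keep <- stats::runif(nrow(rec2$arrows)) < 1.2 / 2
    rec1 <- graphical_record("contact", d = 1, t_max = 3,
                             arrows = rec2$arrows[keep, , drop = FALSE],
                             recoveries = rec2$recoveries)
    for (t in c(0.5, 1.5, 2.8)) {
      s1 <- occupied_at(rec1, t)
      s2 <- occupied_at(rec2, t)
      if (nrow(s1))
        expect_true(all(s1[, 1] %in% s2[, 1]))
    }
  }
})

test_that("resource caps censor explicitly instead of truncating silently", {
  sim <- simulate_contact(k11(), lambda = 4, t_max = 50, seed = 9,
                          caps = sim_caps(max_events = 40, max_sites = 1e6))
  expect_identical(sim$trajectory$status, "censored")
  expect_true(sim$trajectory$censored)
})

test_that("critical-rate probe returns a sane, reproducible bracket", {
  lc <- estimate_lambda_c(k11(), c(0.5, 4), t_probe = 10, reps = 400,
                          seed = 12, n_iter = 5)
  expect_true(all(lc$bracket > 1))    # certain extinction at lambda <= 1
  # supercritical end survives at least as often as the subcritical end
  expect_gte(lc$probe_upper["theta_t"], lc$probe_lower["theta_t"])
  lc2 <- estimate_lambda_c(k11(), c(0.5, 4), t_probe = 10, reps = 400,
                           seed = 12, n_iter = 5)
  expect_identical(lc$bracket, lc2$bracket)
})

test_that("voter two-point function matches the single dual walk (duality)", {
  # P(x in T_t) equals the probability that a rate-one D-walk started at x
  # is at the origin at time t
  K <- k21(); t <- 2; reps <- 20000
  set.seed(77)
  hits <- matrix(0, 3, 3)
  for (r in seq_len(reps)) {
    occ <- simulate_voter(K, t, record = FALSE)$trajectory$final_set
    for (i in seq_len(nrow(occ))) {
      x <- occ[i, ]
      if (all(abs(x) <= 1)) hits[x[1] + 2, x[2] + 2] <- hits[x[1] + 2, x[2] + 2] + 1
    }
  }
  phat <- hits / reps
  set.seed(78)
  W <- walk_positions(K, t, reps)
  for (x1 in -1:1) for (x2 in -1:1) {
    pw <- mean(W[, 1] == x1 & W[, 2] == x2)
    se <- sqrt(pw * (1 - pw) / reps + phat[x1 + 2, x2 + 2] / reps)
    expect_lt(abs(phat[x1 + 2, x2 + 2] - pw), 4 * se + 1e-4)
  }
})
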