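test_that("survival times follow the documented conventions", {
  # OP with p = 0: first empty generation is 1 (infimum convention)
  st <- survival_time(simulate_op(k11(), 0, 3, seed = 31))
  expect_equal(st$time, 1)
  expect_false(st$censored)

  # a record with no events is censored at the horizon
  sim <- simulate_voter(k11(), 0, seed = 32)
  st2 <- survival_time(sim$trajectory)
  expect_true(st2$censored)
  expect_equal(st2$time, 0)

  # theta(0) = 1 and contact theta(t) = exp(-t) at lambda = 0
  spc <- model_spec("contact", k11(), lambda = 0)
  expect_equal(estimate_survival_prob(spc, 0, 500, seed = 33)$value, 1)
  th <- estimate_survival_prob(spc, 1, 2e4, seed = 34)
  expect_lt(abs(th$value - exp(-1)), 3 * th$se)
})

test_that("range and radius use the Euclidean norm with the documented conventions", {
  expect_equal(radius(matrix(0, 1, 2)), 0)
  expect_equal(radius(matrix(c(3, 4), 1, 2)), 5)
  expect_error(radius(matrix(numeric(0), 0, 2)), "empty")
  fx <- make_fixture("voter_single_arrow")
  expect_equal(radius(range_of(fx)), 1)
})

test_that("the capped Hausdorff metric follows the paper conventions and metric axioms", {
  expect_equal(hausdorff(NULL, NULL), 0)            # both empty
  expect_equal(hausdorff(NULL, matrix(0, 1, 1)), 1) # empty vs nonempty
  expect_equal(hausdorff(matrix(0, 1, 1), NULL), 1)
  K <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(hausdorff(K, K), 0)
  # d = 1: {0} vs {0.3}: both directed deviations 0.3, sum 0.6 < 1
  expect_equal(hausdorff(matrix(0, 1, 1), matrix(0.3, 1, 1)), 0.6)
  # far sets cap at 1
  expect_equal(hausdorff(matrix(0, 1, 1), matrix(10, 1, 1)), 1)

  # metric axioms on random small point sets (uncapped regime: the sum
  # metric d_1 itself must satisfy the triangle inequality)
  set.seed(35)
  for (i in 1:40) {
    A <- matrix(runif(6, 0, 0.2), ncol = 2)
    B <- matrix(runif(8, 0, 0.2), ncol = 2)
    C <- matrix(runif(4, 0, 0.2), ncol = 2)
    expect_equal(hausdorff(A, B), hausdorff(B, A))
    expect_lte(hausdorff(A, C), hausdorff(A, B) + hausdorff(B, C) + 1e-12)
    expect_equal(hausdorff(A, A), 0)
  }
  # capped version still satisfies the triangle inequality for far sets
  A <- matrix(0, 1, 1); B <- matrix(5, 1, 1); C <- matrix(100, 1, 1)
  expect_lte(hausdorff(A, C), hausdorff(A, B) + hausdorff(B, C))
})

test_that("one-arm estimates are pathwise monotone in r under a common realization set", {
  sp <- model_spec("voter", k21())
  set.seed(36)
  b <- sbmlattice:::.spec_batch(sp, Inf, 8, 4000, sim_caps())
  # a run resolved at exit radius 8 determines exit for every r <= 8
  etas <- vapply(c(2, 4, 6, 8), function(r) mean(b$max_radius2 > r^2), 0)
  expect_true(all(diff(etas) <= 0))
  expect_true(all(b$status %in% c(1L, 2L)))  # extinct or exited, no horizon
  # the one_arm() estimator agrees with the derived value at the probe radius
  oa <- one_arm(sp, 8, 4000, seed = 36)
  expect_equal(oa$value, etas[4])
  # r = 0 for the single-site death process: the range never leaves {o}
  oa0 <- one_arm(model_spec("contact", k11(), lambda = 0), 0, 300, seed = 37)
  expect_equal(oa0$value, 0)
})

test_that("modulus statistic: zero window, monotonicity, exhaustive small-instance oracle", {
  set.seed(38)
  real <- simulate_brw(offspring_binary(), k11(), 4)
  while (nrow(real$positions[[length(real$positions)]]) == 0)
    real <- simulate_brw(offspring_binary(), k11(), 4)
  sys <- brw_ancestral_system(real)
  m0 <- modulus_stat(sys, 0)
  expect_equal(m0$value, 0)            # equal-time related pairs coincide
  m1 <- modulus_stat(sys, 1)
  m3 <- modulus_stat(sys, 3)
  expect_lte(m1$value, m3$value)
  expect_true(m3$exhaustive)
  # a generous budget reproduces the exhaustive value
  m3b <- modulus_stat(sys, 3, pair_budget = 1e6, seed = 39)
  expect_equal(m3b$value, m3$value)
})

test_that("spatial moments: zero at t = 0, voter duality value, single-walk reduction", {
  sp <- model_spec("voter", k21())
  expect_equal(spatial_moment(sp, 0, 2, 200, seed = 40)$value, 0)
  sm <- spatial_moment(sp, 4, 2, 3e4, seed = 41)
  expect_lt(abs(sm$value - 4 * 2 * 0.75), 3 * sm$se)   # t d sigma2_D
  # BRW with delta_1 offspring: moment of a single discrete walk
  spb <- model_spec("brw", k11(), offspring = offspring_delta(1))
  smb <- spatial_moment(spb, 9, 2, 4000, seed = 42)
  expect_lt(abs(smb$value - 9 * 1), 4 * smb$se)
})

test_that("ancestral increment moments reduce to walk moments for the voter model", {
  sp <- model_spec("voter", k21())
  expect_equal(ancestral_increment_moment(sp, 2, 0, 2, 200, seed = 43)$value, 0)
  ai <- ancestral_increment_moment(sp, 4, 3, 2, 4000, seed = 44)
  expect_lt(abs(ai$value - 3 * 2 * 0.75), 3 * ai$se)
  # OP near its critical scale: ratio to (s v 1)^{p/2} stays bounded
  spo <- model_spec("op", k11(), p = 1)
  ratios <- vapply(c(1, 2, 4), function(s) {
    est <- ancestral_increment_moment(spo, 6, s, 2, 400, seed = 45 + s)
    est$value / max(s, 1)
  }, 0)
  expect_true(all(is.finite(ratios)))
  expect_lt(max(ratios), 25)
})

test_that("local jump probe: exact zero beyond the finite range, decaying voter tail", {
  spo <- model_spec("op", k11(), p = 0.9)
  pr <- local_jump_probe(spo, c(0, 2, 2 * sqrt(1) * 1 + 0.5), 400, seed = 46)
  expect_equal(pr$p_hat[1], 1)            # N = 0 always reached
  expect_equal(pr$p_hat[3], 0)            # beyond 2 sqrt(d) L: impossible
  sp <- model_spec("voter", k21())
  pv <- local_jump_probe(sp, 1:5, 2e4, seed = 47)
  pos <- pv$p_hat > 0
  fit <- stats::lm(log(pv$p_hat[pos]) ~ pv$N[pos])
  expect_lt(coef(fit)[2], 0)              # at least exponential-looking decay
})

test_that("integrated mass is the exact piecewise-constant integral", {
  immortal <- structure(list(model = "voter", d = 1, t_max = 2,
                             times = numeric(0), sizes = integer(0),
                             status = "alive", censored = FALSE,
                             survival_time = NA, exit_time = NA,
                             stop_time = 2, max_radius = 0,
                             final_set = matrix(0L, 1, 1), n_events = 0),
                        class = "occupied_trajectory")
  expect_equal(integrated_mass(immortal, 0, 1, n = 2, m_value = 5), 0.2)
  expect_error(integrated_mass(immortal, 0, 3, n = 1, m_value = 1),
               "beyond the simulated horizon")

  twojump <- structure(list(model = "voter", d = 1, t_max = 5,
                            times = c(0.5, 1.5), sizes = c(2L, 0L),
                            status = "extinct", censored = FALSE,
                            survival_time = 1.5, exit_time = NA,
                            stop_time = 1.5, max_radius = 1,
                            final_set = matrix(integer(0), 0, 1),
                            n_events = 2),
                       class = "occupied_trajectory")
  # 1 * 0.5 + 2 * 1.0 + 0 = 2.5 on [0, 2]
  expect_equal(integrated_mass(twojump, 0, 2, n = 1, m_value = 1), 2.5)
  expect_equal(integrated_mass(twojump, 2, 4, n = 1, m_value = 1), 0)
})

test_that("mass normalizations m(t) match the stated branches", {
  expect_equal(m_function("voter", 0.5, d = 3), 1)
  expect_equal(m_function("voter", 7, d = 3), 7)
  expect_equal(m_function("voter", exp(1), d = 2), exp(1))
  expect_equal(m_function("voter", 1, d = 2), exp(1))  # t v e branch
  expect_equal(m_function("op", 7, constants = list(A = 1, V = 1)), 7)
  expect_equal(m_function("op", 0.2, constants = list(A = 2, V = 3)), 12)
  expect_error(m_function("op", 1), "A and V")
})

test_that("t * theta(t) is flat across a dyadic grid for the voter model in d = 3", {
  sp <- model_spec("voter", k31())
  grid <- c(8, 16, 32)
  vals <- ses <- numeric(3)
  for (i in seq_along(grid)) {
    th <- estimate_survival_prob(sp, grid[i], 3e4, seed = 50 + i)
    vals[i] <- grid[i] * th$value
    ses[i] <- grid[i] * th$se
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(vals[i] - vals[j]), 3 * (ses[i] + ses[j]) + 0.1)
})
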