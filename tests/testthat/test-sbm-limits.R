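test_that("blow-up solver: scaling invariance, first-integral residual, quadrature oracle", {
  tol <- 1e-6
  for (d in c(1, 2, 3, 4)) {
    sols <- lapply(c(0.5, 1, 2), function(a) solve_vd0(d, tol = tol, a = a))
    v <- vapply(sols, function(s) s$vd0, 0)
    # v_d(0) = a R(a)^2 is an exact symmetry of the equation
    expect_lt(max(v) - min(v), 2 * tol + 2 * max(vapply(sols, function(s) s$vd0_err, 0)))
    expect_true(all(v > 0))
  }

  # d = 1: exact first integral v'^2 = (2/3)(v^3 - a^3) holds along the grid
  s1 <- solve_vd0(1, tol = tol)
  g <- s1$grid
  keep <- g$v < 1e4
  res <- abs(g$w[keep]^2 - (2 / 3) * (g$v[keep]^3 - 1)) /
    pmax(1, (2 / 3) * g$v[keep]^3)
  expect_lt(max(res), 10 * tol)

  # independent quadrature oracle for d = 1
  expect_lt(abs(s1$vd0 - vd0_quadrature_d1()), 2 * tol)
  expect_lt(abs(solve_vd0(1, tol = tol, a = 2)$vd0 - vd0_quadrature_d1(2)),
            4 * tol)

  # finite-difference residual of the radial equation away from blow-up
  s3 <- solve_vd0(3, tol = tol)
  g3 <- s3$grid
  i <- which(g3$v > 1.5 & g3$v < 100)
  i <- i[i > 1 & i < length(g3$r)]
  dw <- (g3$w[i + 1] - g3$w[i - 1]) / (g3$r[i + 1] - g3$r[i - 1])
  rhs <- g3$v[i]^2 - 2 / g3$r[i] * g3$w[i]
  expect_lt(stats::median(abs(dw - rhs) / pmax(1, g3$v[i]^2)), 1e-3)

  # honest error bound: doubling the resolution moves the value less than
  # the reported bound
  a <- solve_vd0(2, tol = 1e-5)
  b <- solve_vd0(2, tol = 1e-7)
  expect_lt(abs(a$vd0 - b$vd0), a$vd0_err + b$vd0_err)
})

test_that("escape probability: exact d = 2 value, cross-method d = 3, monotone in L", {
  expect_equal(escape_probability(k21()), 2 * pi * 0.75)
  K22 <- uniform_box_kernel(2, 2)
  expect_equal(kernel_variance(K22), 50 / 24)   # sum x1^2 over the box / 24
  expect_equal(escape_probability(K22), 2 * pi * 50 / 24)
  expect_error(escape_probability(k11()), "d >= 2")

  four <- escape_probability(k31(), "fourier")
  mc <- escape_probability(k31(), "monte_carlo", seed = 55, walkers = 8000,
                           n_max = 2000)
  expect_lt(abs(four - mc$value), 3 * mc$se + mc$extra$tail_bound)
  expect_gt(four, 0.5)
  expect_lt(four, 1)

  # spreading the kernel out raises the escape probability toward 1
  b1 <- escape_probability(uniform_box_kernel(3, 1), "fourier")
  b2 <- escape_probability(uniform_box_kernel(3, 2), "fourier")
  b4 <- escape_probability(uniform_box_kernel(3, 4), "fourier")
  expect_true(b1 < b2 && b2 < b4)
  expect_lt(b4, 1)
})

test_that("canonical-measure closed forms take their exact values", {
  p1 <- sbm_params(gamma = 1)
  expect_equal(canonical_survival(p1, 1), 2)
  expect_equal(canonical_survival(sbm_params(gamma = 2), 1), 1)
  s <- c(1, 2, 4, 8)
  expect_true(all(diff(canonical_survival(p1, 1) / s) < 0))
  expect_error(canonical_survival(p1, 0))

  # one-arm tail: exact r^{-2} scaling and the delta_0 exit probability
  t1 <- sbm_one_arm_tail(p1, vd0 = 9, r = 1)
  t2 <- sbm_one_arm_tail(p1, vd0 = 9, r = 2)
  expect_equal(t2$canonical_tail, t1$canonical_tail / 4)
  expect_equal(t1$canonical_tail, 9)
  expect_equal(t1$exit_probability, 1 - exp(-9))

  # Yaglom density: normalization, mean, value at zero
  expect_equal(yaglom_density(p1, 0), 2)
  expect_equal(stats::integrate(function(x) yaglom_density(p1, x), 0, Inf)$value,
               1, tolerance = 1e-6)
  expect_equal(stats::integrate(function(x) x * yaglom_density(p1, x), 0,
                                Inf)$value, yaglom_mean(p1), tolerance = 1e-6)
  expect_equal(yaglom_mean(sbm_params(gamma = 3)), 1.5)
})

test_that("v_t^(lambda) solves its Riccati equation; Laplace limits hold", {
  p <- sbm_params(gamma = 2)
  lam <- 1.3
  for (t in seq(0.1, 2, by = 0.3)) {
    dv <- (v_lambda(p, lam, t + 1e-6) - v_lambda(p, lam, t - 1e-6)) / 2e-6
    rhs <- -p$gamma * v_lambda(p, lam, t)^2 / 2 + lam
    expect_lt(abs(dv - rhs), 1e-5)
  }
  expect_equal(v_lambda(p, 0, 1), 0)
  expect_equal(laplace_integrated_mass(p, 0), 1)
  # lambda -> 0: transform tends to 1; large lambda: ~ sqrt(2/(gamma lambda))
  expect_gt(laplace_integrated_mass(p, 1e-8), 1 - 1e-3)
  lam_big <- 1e6
  expect_equal(laplace_integrated_mass(p, lam_big) *
                 sqrt(p$gamma * lam_big / 2), 1, tolerance = 1e-2)

  sm <- small_mass_asymptotics(p, 0.01)
  expect_lt(sm$asymptotic, sm$upper_bound)
  # the ratio bound/asymptotic is e sqrt(pi) > 1, independent of a and gamma
  r1 <- small_mass_asymptotics(p, 0.01)
  r2 <- small_mass_asymptotics(sbm_params(gamma = 5), 3)
  expect_equal(r1$upper_bound / r1$asymptotic, exp(1) * sqrt(pi))
  expect_equal(r2$upper_bound / r2$asymptotic, exp(1) * sqrt(pi))
})

test_that("predicted constants dispatch per model and stay internally consistent", {
  expect_equal(normal_abs_moment(3, 2), 3)
  expect_equal(normal_abs_moment(2, 0), 1)
  expect_equal(normal_abs_moment(1, 1), sqrt(2 / pi))

  # two-dimensional voter: v_2(0)/(2 pi), independent of the kernel
  c2a <- limit_constants(k21(), "voter", tol = 1e-6)
  c2b <- limit_constants(uniform_box_kernel(2, 2), "voter", tol = 1e-6)
  p2a <- predicted_one_arm_constant(c2a)
  p2b <- predicted_one_arm_constant(c2b)
  expect_equal(as.numeric(p2a), as.numeric(p2b), tolerance = 1e-8)
  expect_equal(attr(p2a, "normalization"), "r^2/log r")
  expect_equal(as.numeric(p2a), c2a$vd0 / (2 * pi), tolerance = 1e-10)

  # d = 3 voter: the general-form consistency assertion runs inside
  c3 <- limit_constants(k31(), "voter", tol = 1e-6)
  p3 <- predicted_one_arm_constant(c3)
  expect_equal(as.numeric(p3), c3$sigma2_D * c3$vd0 / (2 * c3$beta_D),
               tolerance = 1e-10)

  # OP-style models need A, V, v and match sigma2_D v vd0/(A V)
  cop <- limit_constants(k31(), "op", A = 1.1, V = 1.2, v = 1.05)
  pop <- predicted_one_arm_constant(cop)
  expect_equal(as.numeric(pop),
               cop$sigma2_D * 1.05 * cop$vd0 / (1.1 * 1.2), tolerance = 1e-10)
  expect_error(predicted_one_arm_constant(
    limit_constants(k31(), "op")), "A, V and v")

  # spatial moments: voter p = 2 reduces to sigma2_D * d; p = 0 to s_D gamma/2
  expect_equal(predicted_spatial_moment(c3, 2), c3$sigma2_D * 3,
               tolerance = 1e-10)
  expect_equal(predicted_spatial_moment(c3, 0), c3$s_D * c3$gamma / 2,
               tolerance = 1e-10)

  # closed-form operations are pure: bit-identical repeat evaluations
  expect_identical(predicted_spatial_moment(c3, 3),
                   predicted_spatial_moment(c3, 3))
  expect_identical(solve_vd0(2, tol = 1e-6)$vd0, solve_vd0(2, tol = 1e-6)$vd0)
})
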