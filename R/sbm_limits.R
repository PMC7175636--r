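#' Super-Brownian-motion parameters
#'
#' @param gamma branching rate (`> 0`); for a critical offspring law this is
#'   the offspring variance.
#' @param sigma0sq diffusion parameter (`> 0`).
#' @param d dimension.
#' @export
sbm_params <- function(gamma = 1, sigma0sq = 1, d = 1) {
  stopifnot(gamma > 0, sigma0sq > 0, d >= 1)
  structure(list(gamma = gamma, sigma0sq = sigma0sq, d = d),
            class = "sbm_params")
}

# one adaptive RK4 sweep of v'' + (d-1)/r v' = v^2 from r0 with the series
# start v = a + a^2 r^2 / (2d); returns the blow-up radius estimate and the
# trajectory grid.  h_scale controls the step: h = h_scale / (1 + sqrt(v)),
# which shrinks like the distance to blow-up.
.vd_sweep <- function(d, a, h_scale, v_blow = 1e8, r0 = 1e-4,
                      keep_grid = FALSE) {
  deriv <- function(r, v, w) c(w, v * v - (d - 1) / r * w)
  v <- a + a^2 * r0^2 / (2 * d)
  w <- a^2 * r0 / d
  r <- r0
  gr <- if (keep_grid) list(r = r, v = v, w = w)
  repeat {
    h <- h_scale / (1 + sqrt(v))
    k1 <- deriv(r, v, w)
    k2 <- deriv(r + h / 2, v + h / 2 * k1[1], w + h / 2 * k1[2])
    k3 <- deriv(r + h / 2, v + h / 2 * k2[1], w + h / 2 * k2[2])
    k4 <- deriv(r + h, v + h * k3[1], w + h * k3[2])
    v <- v + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    w <- w + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    r <- r + h
    if (keep_grid) {
      gr$r <- c(gr$r, r); gr$v <- c(gr$v, v); gr$w <- c(gr$w, w)
    }
    if (!is.finite(v) || v > v_blow) break
    if (r > 100 / sqrt(a)) stop("no blow-up detected; integration diverged")
  }
  # extrapolate the remaining distance with the near-blow-up asymptotic
  # v ~ 6/x^2 + (6(d-1)/(5R)) / x, x = R - r (leading universal term plus
  # the curvature correction); two fixed-point passes suffice
  x <- sqrt(6 / v)
  for (i in 1:2) {
    c1 <- 6 * (d - 1) / (5 * (r + x))
    x <- (c1 + sqrt(c1^2 + 24 * v)) / (2 * v)
  }
  list(R = r + x, grid = gr)
}

#' Solve the semilinear blow-up problem for the one-arm constant
#'
#' Computes `v_d(0)`, the value at the origin of the unique positive radial
#' solution of `Delta v = v^2` on the unit ball that blows up at the
#' boundary.  The radial ODE `v'' + (d-1)/r v' = v^2` is integrated from a
#' series start at the origin with initial value `a`; blow-up is detected at
#' a large threshold and the remaining distance recovered from the universal
#' asymptotic `v ~ 6 / (R - r)^2`.  By the scaling symmetry (if `v` solves
#' the equation so does `lambda^2 v(lambda .)`), `v_d(0) = a * R(a)^2` where
#' `R(a)` is the blow-up radius — independent of `a`, which the validity
#' tests exploit.  The error bound comes from step-halving (Richardson).
#'
#' @param d dimension (`>= 1`).
#' @param tol requested absolute tolerance on `v_d(0)`.
#' @param a initial value at the origin (any positive number; the result is
#'   invariant).
#' @return an `ode_solution`: `vd0`, `vd0_err`, `blowup_radius`, the
#'   dimension and a coarse `grid` (`r`, `v`, `w = v'`) for residual checks.
#' @export
solve_vd0 <- function(d, tol = 1e-6, a = 1) {
  stopifnot(d >= 1, tol > 0, a > 0)
  h <- 0.02
  sw <- .vd_sweep(d, a, h, keep_grid = TRUE)
  for (iter in 1:12) {
    sw2 <- .vd_sweep(d, a, h / 2)
    err <- abs(sw2$R - sw$R) / 15      # RK4 Richardson factor
    R <- (16 * sw2$R - sw$R) / 15
    vd0_err <- a * abs(R + sw2$R) * err  # d(aR^2) = 2 a R dR, padded
    if (vd0_err < tol) {
      return(structure(list(d = d, a = a, vd0 = a * R^2, vd0_err = vd0_err,
                            blowup_radius = R, blowup_err = err,
                            grid = sw$grid, h = h),
                       class = "ode_solution"))
    }
    h <- h / 2
    sw <- list(R = sw2$R, grid = sw$grid)
  }
  stop("solve_vd0 did not reach the requested tolerance; diagnostics: ",
       sprintf("h = %.3g, last error %.3g", h, err))
}

#' @export
print.ode_solution <- function(x, ...) {
  cat(sprintf("radial blow-up solution, d = %d: v_d(0) = %.8g (err <= %.2g),\n",
              x$d, x$vd0, x$vd0_err))
  cat(sprintf("  blow-up radius %.8g for initial value a = %g\n",
              x$blowup_radius, x$a))
  invisible(x)
}

#' Independent quadrature oracle for `v_1(0)`
#'
#' In one dimension the equation `v'' = v^2` with `v(0) = a`, `v'(0) = 0`
#' has the first integral `v'^2 = (2/3)(v^3 - a^3)`, so the blow-up radius
#' is the convergent integral `R(a) = int_a^Inf dw / sqrt((2/3)(w^3 - a^3))`
#' and `v_1(0) = a R(a)^2`.  Used only as a cross-check of the ODE solver.
#'
#' @param a initial value.
#' @export
vd0_quadrature_d1 <- function(a = 1) {
  f <- function(w) 1 / sqrt((2 / 3) * (w^3 - a^3))
  R <- stats::integrate(f, a, Inf, rel.tol = 1e-10)$value
  a * R^2
}

#' Escape (no-return) probability of the kernel walk
#'
#' For `d > 2`, the probability that the discrete-time `D`-walk from the
#' origin never returns: via the Green-function identity `beta = 1/G` with
#' `G = (2 pi)^{-d} int_{[-pi,pi]^d} (1 - D_hat(k))^{-1} dk` (method
#' `"fourier"`; the integrable singularity at `k = 0` is handled by
#' geometrically refined composite Gauss panels), or by direct simulation of
#' no return within `n_max` steps with a local-CLT tail-correction bound
#' (method `"monte_carlo"`).  For `d = 2` the walk is recurrent and the
#' value `2 pi sigma2_D` is returned by definition (the normalization the
#' two-dimensional limit theory uses).
#'
#' @param kernel a [step_kernel()].
#' @param method `"fourier"` or `"monte_carlo"`.
#' @param n_nodes Gauss nodes per panel (fourier).
#' @param n_panels geometric panels per dimension (fourier).
#' @param walkers,n_max simulation size (monte_carlo).
#' @param seed optional seed (monte_carlo).
#' @return for `"fourier"` and `d = 2`, a number; for `"monte_carlo"`, an
#'   [mc_estimate()] whose `extra$tail_bound` bounds the unobserved
#'   late-return probability and whose bracket accounts for it.
#' @export
escape_probability <- function(kernel, method = c("fourier", "monte_carlo"),
                               n_nodes = 8, n_panels = 8, walkers = 10000,
                               n_max = 4000, seed = NULL) {
  method <- match.arg(method)
  d <- kernel$d
  if (d < 2) stop("escape probability is used only for d >= 2")
  if (d == 2) return(2 * pi * kernel_variance(kernel))
  if (method == "fourier") {
    gauss <- .gauss_legendre(n_nodes)
    edges <- c(0, pi * 2^-(rev(seq_len(n_panels) - 1)), pi)
    edges <- sort(unique(edges))
    nodes1 <- wts1 <- numeric(0)
    for (i in seq_len(length(edges) - 1)) {
      aa <- edges[i]; bb <- edges[i + 1]
      nodes1 <- c(nodes1, (bb - aa) / 2 * gauss$x + (aa + bb) / 2)
      wts1 <- c(wts1, (bb - aa) / 2 * gauss$w)
    }
    grids <- rep(list(seq_along(nodes1)), d)
    idx <- as.matrix(do.call(expand.grid, grids))
    G <- 0
    # keep the cos() work matrix (points x offsets) around ~2e7 entries
    chunk <- max(2000L, as.integer(2e7 / nrow(kernel$offsets)))
    for (start in seq(1L, nrow(idx), by = chunk)) {
      rows <- start:min(start + chunk - 1L, nrow(idx))
      kmat <- matrix(nodes1[idx[rows, ]], nrow = length(rows))
      wvec <- apply(matrix(wts1[idx[rows, ]], nrow = length(rows)), 1, prod)
      Dhat <- characteristic_function(kernel, kmat)
      G <- G + sum(wvec / (1 - Dhat))
    }
    G <- G * (2^d) / (2 * pi)^d        # even symmetry: 2^d copies of [0,pi]^d
    return(1 / G)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(kernel$offsets)
  returned <- rep(FALSE, walkers)
  pos <- matrix(0L, walkers, d)
  active <- seq_len(walkers)
  for (s in seq_len(n_max)) {
    stp <- kernel$offsets[sample.int(m, length(active), replace = TRUE,
                                     prob = kernel$probs), , drop = FALSE]
    pos[active, ] <- pos[active, , drop = FALSE] + stp
    back <- rowSums(pos[active, , drop = FALSE] != 0L) == 0L
    if (any(back)) {
      returned[active[back]] <- TRUE
      active <- active[!back]
      if (!length(active)) break
    }
  }
  ph <- mean(!returned)
  se <- sqrt(ph * (1 - ph) / walkers)
  # expected number of visits to the origin after n_max (local CLT scale)
  s2 <- kernel_variance(kernel)
  tail <- (d / (2 * pi * s2))^(d / 2) * n_max^(1 - d / 2) / (d / 2 - 1)
  mc_estimate(ph, se, walkers, lower = ph - tail, upper = ph,
              extra = list(tail_bound = tail, n_max = n_max))
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Canonical-measure survival tail
#'
#' `N_o(S > s) = 2 / (gamma s)`: the sigma-finite canonical measure of
#' super-Brownian motion gives mass `2/(gamma s)` to survival beyond `s`.
#'
#' @param params an [sbm_params()].
#' @param s time (`> 0`).
#' @export
canonical_survival <- function(params, s) {
  stopifnot(s > 0)
  2 / (params$gamma * s)
}

#' One-arm tail of super-Brownian motion
#'
#' Canonical-measure tail `N_o(r_0(R) > r) = v_d(0) sigma0^2 / (gamma r^2)`
#' and the corresponding exit probability from a unit point mass,
#' `1 - exp(-tail)`.
#'
#' @param params an [sbm_params()].
#' @param vd0 the constant `v_d(0)` from [solve_vd0()].
#' @param r radius (`> 0`).
#' @return list with `canonical_tail` and `exit_probability`.
#' @export
sbm_one_arm_tail <- function(params, vd0, r) {
  stopifnot(r > 0, vd0 > 0)
  tail <- vd0 * params$sigma0sq / params$gamma * r^-2
  list(canonical_tail = tail, exit_probability = 1 - exp(-tail))
}

#' Yaglom exponential density of the rescaled mass
#'
#' Conditioned on survival beyond time 1, the canonical-measure mass at
#' time 1 is exponential with density `(2/gamma) exp(-(2/gamma) x)`; its
#' mean is `gamma / 2`.
#'
#' @param params an [sbm_params()].
#' @param x evaluation points (`>= 0`).
#' @export
yaglom_density <- function(params, x) {
  rate <- 2 / params$gamma
  ifelse(x < 0, 0, rate * exp(-rate * x))
}

#' @rdname yaglom_density
#' @export
yaglom_mean <- function(params) params$gamma / 2

#' Exponential-duality solution `v_t^(lambda)`
#'
#' The unique solution of `dv/dt = -gamma v^2 / 2 + lambda`, `v(0) = 0`:
#' `v_t = sqrt(2 lambda / gamma) (e^{t sqrt(2 gamma lambda)} - 1) /
#' (e^{t sqrt(2 gamma lambda)} + 1)`.
#'
#' @param params an [sbm_params()].
#' @param lambda Laplace argument (`>= 0`).
#' @param t time.
#' @export
v_lambda <- function(params, lambda, t) {
  stopifnot(lambda >= 0, t >= 0)
  if (lambda == 0) return(0)
  g <- params$gamma
  # (e^x - 1)/(e^x + 1) = tanh(x/2): overflow-safe for large arguments
  sqrt(2 * lambda / g) * tanh(t * sqrt(2 * g * lambda) / 2)
}

#' Laplace transform of the integrated mass over `[1, 2]`
#'
#' Closed form for the conditional Laplace functional
#' `N_o^1[exp(-lambda int_1^2 X_s(1) ds)] = 2 / (2 + gamma v_1^(lambda))`.
#'
#' @inheritParams v_lambda
#' @export
laplace_integrated_mass <- function(params, lambda) {
  2 / (2 + params$gamma * v_lambda(params, lambda, 1))
}

#' Small-mass asymptotics of the integrated mass
#'
#' As `a` tends to 0, `N_o^1(int_1^2 X_s(1) ds <= a)` behaves as
#' `4 sqrt(a) / sqrt(2 pi gamma)`, with the uniform upper bound
#' `2 e sqrt(2 a / gamma)`.
#'
#' @param params an [sbm_params()].
#' @param a mass level (`> 0`).
#' @return list with `asymptotic` and `upper_bound` (asymptotic <= bound for
#'   every `a`).
#' @export
small_mass_asymptotics <- function(params, a) {
  stopifnot(a > 0)
  g <- params$gamma
  asym <- 4 / sqrt(2 * pi * g) * sqrt(a)
  bound <- 2 * exp(1) * sqrt(2 * a / g)
  stopifnot(asym <= bound)
  list(asymptotic = asym, upper_bound = bound)
}

#' Absolute moment of a d-dimensional standard normal
#'
#' `E|Z|^p = 2^{p/2} Gamma((d + p)/2) / Gamma(d/2)` (chi-distribution
#' moment).
#'
#' @param d dimension.
#' @param p moment order (`>= 0`).
#' @export
normal_abs_moment <- function(d, p) {
  2^(p / 2) * exp(lgamma((d + p) / 2) - lgamma(d / 2))
}

#' Constants feeding the model-specific limit predictions
#'
#' Collects `v_d(0)` and the walk escape probability `beta_D` (both
#' computed), the survival normalization `s_D`, and the lace-expansion
#' constants `A` (asymptotic mean mass), `V` (vertex factor) and `v`
#' (diffusion correction), which are *inputs*: the theory defines them only
#' as lace-expansion limits, so they must be supplied by the user or
#' estimated, and their provenance is recorded.
#'
#' @param kernel a [step_kernel()].
#' @param model `"voter"`, `"op"`, `"contact"` or `"lattice_tree"`.
#' @param A,V,v user-supplied constants (models other than the voter).
#' @param tol tolerance for [solve_vd0()].
#' @param provenance character tag for `A`, `V`, `v` (e.g. `"user"`,
#'   `"estimated"`).
#' @export
limit_constants <- function(kernel, model = c("voter", "op", "contact",
                                              "lattice_tree"),
                            A = NA, V = NA, v = NA, tol = 1e-6,
                            provenance = "user") {
  model <- match.arg(model)
  d <- kernel$d
  s2 <- kernel_variance(kernel)
  vd0 <- solve_vd0(d, tol = tol)
  beta_D <- if (d >= 2) escape_probability(kernel, "fourier") else NA_real_
  s_D <- switch(model,
                voter = 1 / beta_D,
                op = , contact = , lattice_tree = 2 * A)
  gamma <- switch(model, voter = 2 * beta_D, 1)
  sigma0sq <- switch(model, voter = s2, s2 * v)
  structure(list(model = model, d = d, sigma2_D = s2,
                 vd0 = vd0$vd0, vd0_err = vd0$vd0_err,
                 beta_D = beta_D, s_D = s_D, gamma = gamma,
                 sigma0sq = sigma0sq, A = A, V = V, v = v,
                 provenance = provenance),
            class = "limit_constants")
}

#' @export
print.limit_constants <- function(x, ...) {
  cat(sprintf("limit constants (%s, d = %d): v_d(0) = %.6g, beta_D = %.6g\n",
              x$model, x$d, x$vd0, x$beta_D))
  cat(sprintf("  gamma = %.6g, sigma0^2 = %.6g, s_D = %.6g", x$gamma,
              x$sigma0sq, x$s_D))
  if (!is.na(x$A))
    cat(sprintf("; A = %.4g, V = %.4g, v = %.4g (%s)", x$A, x$V, x$v,
                x$provenance))
  cat("\n")
  invisible(x)
}

#' Predicted one-arm constant per model
#'
#' The limit of `r^2 P(r_0(R) > r)` (or `r^2 / log r` times the probability
#' for the two-dimensional voter model): `sigma2_D v_d(0) / (2 beta_D)` for
#' the voter model in `d > 2`, `v_2(0) / (2 pi)` in `d = 2` (independent of
#' the kernel), and `sigma2_D v v_d(0) / (A V)` for oriented percolation,
#' the contact process and lattice trees.  Internally cross-checked against
#' the general form `sigma0^2 s_D v_d(0) / 2` divided by the model's mass
#' normalization slope.
#'
#' @param constants a [limit_constants()].
#' @return the predicted constant; attribute `"normalization"` names the
#'   radial normalization (`r^2` or `r^2/log r`).
#' @export
predicted_one_arm_constant <- function(constants) {
  x <- constants
  if (x$model == "voter" && x$d == 2) {
    out <- x$vd0 / (2 * pi)
    attr(out, "normalization") <- "r^2/log r"
    return(out)
  }
  if (x$model == "voter") {
    out <- x$sigma2_D * x$vd0 / (2 * x$beta_D)
    general <- (x$sigma0sq / 2) * x$s_D * x$vd0 / 1   # m(t) = t v 1: slope 1
    stopifnot(abs(out - general) < 1e-10 * max(1, abs(out)))
  } else {
    if (anyNA(c(x$A, x$V, x$v)))
      stop("this model needs the constants A, V and v")
    out <- x$sigma2_D * x$v * x$vd0 / (x$A * x$V)
    general <- (x$sigma0sq / 2) * x$s_D * x$vd0 / (x$A^2 * x$V)
    stopifnot(abs(out - general) < 1e-10 * max(1, abs(out)))
  }
  attr(out, "normalization") <- "r^2"
  out
}

#' Predicted spatial moment constant
#'
#' The limit of `t^{-p/2} E[sum_{x in T_t} |x|^p]`:
#' `s_D gamma sigma0^p E|Z|^p / 2` with the model's parameterization (for
#' the voter model in `d > 2` and `p = 2` this is exactly `sigma2_D d`).
#'
#' @param constants a [limit_constants()].
#' @param p moment order.
#' @export
predicted_spatial_moment <- function(constants, p) {
  x <- constants
  x$s_D * x$gamma * x$sigma0sq^(p / 2) / 2 * normal_abs_moment(x$d, p)
}

#' Heuristic estimate of the mean-mass constant `A`
#'
#' `A` is the large-time limit of `E|T_n|` for the near-critical discrete
#' models; this estimates it from the plateau of the empirical means over a
#' generation grid.  Clearly labelled heuristic: it depends on the supplied
#' (approximate) critical parameter.
#'
#' @param spec a [model_spec()] (`"op"` or `"brw"`).
#' @param n_grid generations over which to average.
#' @param reps replicates.
#' @param seed optional seed.
#' @export
estimate_A <- function(spec, n_grid, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(n_grid, function(n)
    estimate_mean_mass(spec, n, reps)$value, 0)
  mc_estimate(mean(means), stats::sd(means) / sqrt(length(means)),
              reps * length(n_grid),
              extra = list(grid = n_grid, means = means,
                           provenance = "heuristic plateau estimate"))
}
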