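#' Model specifications for Monte-Carlo experiments
#'
#' A light container naming one of the four lattice models with its
#' parameters; the experiment functions dispatch on it.
#'
#' @param model `"voter"`, `"contact"`, `"op"` or `"brw"`.
#' @param kernel a [step_kernel()].
#' @param lambda infection rate (contact process).
#' @param p bond probability scale (oriented percolation).
#' @param offspring an [offspring_law()] (branching random walk).
#' @export
model_spec <- function(model = c("voter", "contact", "op", "brw"), kernel,
                       lambda = NULL, p = NULL, offspring = NULL) {
  model <- match.arg(model)
  validate_step_kernel(kernel)
  if (model == "contact" && is.null(lambda)) stop("contact process needs lambda")
  if (model == "op" && is.null(p)) stop("oriented percolation needs p")
  if (model == "brw" && is.null(offspring)) stop("branching random walk needs an offspring law")
  structure(list(model = model, kernel = kernel, lambda = lambda, p = p,
                 offspring = offspring),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  extra <- switch(x$model,
                  contact = sprintf(", lambda = %.4g", x$lambda),
                  op = sprintf(", p = %.4g", x$p),
                  brw = sprintf(", offspring variance %.4g", x$offspring$variance),
                  "")
  cat(sprintf("model spec: %s on Z^%d (L = %d)%s\n", x$model, x$kernel$d,
              x$kernel$L, extra))
  invisible(x)
}

.is_continuous <- function(spec) spec$model %in% c("voter", "contact")

.spec_batch <- function(spec, t_max, exit_radius, reps, caps, moment_p = -1) {
  cpp_particle_batch(spec$model, spec$kernel$offsets, .kernel_cum(spec$kernel),
                     spec$lambda %||% 0, t_max,
                     if (is.null(exit_radius)) -1 else exit_radius,
                     caps$max_events, as.integer(caps$max_sites),
                     as.integer(reps), moment_p)
}

# simulate one discrete realization for the given spec
.spec_discrete_run <- function(spec, n_max, caps) {
  if (spec$model == "op") simulate_op(spec$kernel, spec$p, n_max, caps = caps)
  else simulate_brw(spec$offspring, spec$kernel, n_max, caps = caps)
}

.discrete_sizes <- function(real) {
  vapply(if (real$model == "op") real$generations else real$positions, nrow, 1L)
}

#' Extinction time of a trajectory or realization
#'
#' The first time the occupied set is empty (by the infimum convention, the
#' first empty generation in discrete time).  Returns a list with `time` and
#' a `censored` flag: a trajectory still alive at its horizon is censored at
#' that horizon.
#'
#' @param x an `occupied_trajectory`, `op_realization` or `brw_realization`.
#' @export
survival_time <- function(x) UseMethod("survival_time")

#' @export
survival_time.occupied_trajectory <- function(x) {
  if (identical(x$status, "extinct"))
    list(time = x$survival_time, censored = FALSE)
  else list(time = x$stop_time, censored = TRUE)
}

#' @export
survival_time.op_realization <- function(x) {
  sizes <- .discrete_sizes(x)
  empty <- which(sizes == 0L)
  if (length(empty)) list(time = empty[1] - 1L, censored = FALSE)
  else list(time = length(sizes) - 1L, censored = TRUE)
}

#' @export
survival_time.brw_realization <- survival_time.op_realization

#' Estimate the survival probability `theta(t)`
#'
#' Fraction of replicates whose occupied set is nonempty strictly after `t`.
#' Censored replicates (resource caps) are bracketed both ways.
#'
#' @param spec a [model_spec()].
#' @param t time (continuous models) or generation (discrete models).
#' @param reps replicates.
#' @param seed optional seed.
#' @param caps see [sim_caps()].
#' @return an [mc_estimate()] of `theta(t)`.
#' @export
estimate_survival_prob <- function(spec, t, reps, seed = NULL,
                                   caps = sim_caps()) {
  if (!is.null(seed)) set.seed(seed)
  if (.is_continuous(spec)) {
    b <- .spec_batch(spec, t, NULL, reps, caps)
    alive <- sum(b$status == 0L)
    cens <- sum(b$status == 3L)
  } else {
    alive <- cens <- 0L
    for (r in seq_len(reps)) {
      real <- .spec_discrete_run(spec, ceiling(t), caps)
      sizes <- .discrete_sizes(real)
      if (real$censored) cens <- cens + 1L
      else if (length(sizes) > t && sizes[floor(t) + 1L] > 0L)
        alive <- alive + 1L
    }
  }
  ph <- alive / reps
  mc_estimate(ph, sqrt(ph * (1 - ph) / reps), reps,
              censored_frac = cens / reps,
              lower = alive / reps, upper = (alive + cens) / reps)
}

#' Mean occupied mass at a fixed time
#'
#' Monte-Carlo estimate of `E|T_t|` (for the voter model this is exactly 1
#' at every `t`: the mass is a martingale).
#'
#' @inheritParams estimate_survival_prob
#' @export
estimate_mean_mass <- function(spec, t, reps, seed = NULL, caps = sim_caps()) {
  if (!is.null(seed)) set.seed(seed)
  if (.is_continuous(spec)) {
    b <- .spec_batch(spec, t, NULL, reps, caps)
    sizes <- b$final_size
    cens <- mean(b$status == 3L)
  } else {
    sizes <- numeric(reps)
    cens <- 0
    for (r in seq_len(reps)) {
      real <- .spec_discrete_run(spec, ceiling(t), caps)
      sz <- .discrete_sizes(real)
      sizes[r] <- if (length(sz) > t) sz[floor(t) + 1L] else 0L
      cens <- cens + real$censored / reps
    }
  }
  mc_estimate(mean(sizes), sd(sizes) / sqrt(reps), reps, censored_frac = cens)
}

#' Set of ever-occupied sites (the range)
#'
#' @param x a `graphical_record` (replayed), `op_realization` or
#'   `brw_realization`.
#' @return a `range_set`: matrix of points and a scale tag.
#' @export
range_of <- function(x) UseMethod("range_of")

#' @export
range_of.graphical_record <- function(x) {
  d <- x$d
  ev <- .record_events(x)
  occ <- new.env(parent = emptyenv())
  ever <- new.env(parent = emptyenv())
  o <- rep(0L, d)
  occ[[.site_key(o)]] <- o
  ever[[.site_key(o)]] <- o
  voter <- identical(x$model, "voter")
  for (i in seq_len(nrow(ev))) {
    if (ev[i, 2] == 1) {
      row <- x$arrows[ev[i, 3], ]
      xx <- as.integer(row[2:(d + 1)])
      yy <- as.integer(row[(d + 2):(2 * d + 1)])
      xk <- .site_key(xx)
      if (!is.null(occ[[.site_key(yy)]])) {
        occ[[xk]] <- xx
        ever[[xk]] <- xx
      } else if (voter && !is.null(occ[[xk]])) rm(list = xk, envir = occ)
    } else {
      row <- x$recoveries[ev[i, 3], ]
      xk <- .site_key(as.integer(row[2:(d + 1)]))
      if (!is.null(occ[[xk]])) rm(list = xk, envir = occ)
    }
  }
  keys <- ls(ever)
  pts <- do.call(rbind, mget(keys, envir = ever))
  dimnames(pts) <- NULL
  structure(list(points = pts, scale = 1), class = "range_set")
}

#' @export
range_of.op_realization <- function(x) {
  pts <- do.call(rbind, x$generations)
  pts <- pts[!duplicated(.site_keys(pts)), , drop = FALSE]
  structure(list(points = pts, scale = 1), class = "range_set")
}

#' @export
range_of.brw_realization <- function(x) {
  pts <- do.call(rbind, x$positions)
  pts <- pts[!duplicated(.site_keys(pts)), , drop = FALSE]
  structure(list(points = pts, scale = 1), class = "range_set")
}

#' @export
print.range_set <- function(x, ...) {
  cat(sprintf("range set: %d points (scale %g), radius %.4g\n",
              nrow(x$points), x$scale, radius(x)))
  invisible(x)
}

#' Euclidean radius of a point set
#'
#' `r_0(K) = sup_x |x|` in the Euclidean norm (the kernel range `L` is a
#' sup-norm bound; radii are always Euclidean).
#'
#' @param R a `range_set` or a matrix of points.
#' @export
radius <- function(R) {
  pts <- if (inherits(R, "range_set")) R$points else as.matrix(R)
  if (nrow(pts) == 0) stop("radius of an empty set is undefined")
  sqrt(max(rowSums(pts^2)))
}

#' One-arm probability: the range exits a ball
#'
#' Estimates `eta_r`, the probability that the set of ever-occupied sites
#' leaves the closed Euclidean ball of radius `r` around the origin.  Each
#' replicate stops the moment a site with `|x| > r` appears (exact: ranges
#' only grow) or at extinction; replicates whose caps were hit while still
#' inside the ball are censored and bracketed.
#'
#' @param spec a [model_spec()].
#' @param r ball radius.
#' @param reps replicates.
#' @param seed optional seed.
#' @param caps see [sim_caps()].
#' @export
one_arm <- function(spec, r, reps, seed = NULL, caps = sim_caps()) {
  if (!is.null(seed)) set.seed(seed)
  if (.is_continuous(spec)) {
    b <- .spec_batch(spec, Inf, r, reps, caps)
    exited <- sum(b$status == 2L)
    cens <- sum(b$status == 3L)
  } else {
    exited <- cens <- 0L
    n_guess <- max(16L, ceiling(4 * (r + 1)^2))
    for (i in seq_len(reps)) {
      real <- .spec_discrete_run(spec, n_guess, caps)
      rng <- range_of(real)
      if (radius(rng) > r) exited <- exited + 1L
      else {
        sizes <- .discrete_sizes(real)
        if (real$censored || sizes[length(sizes)] > 0L) cens <- cens + 1L
      }
    }
  }
  ph <- exited / reps
  mc_estimate(ph, sqrt(ph * (1 - ph) / reps), reps,
              censored_frac = cens / reps,
              lower = ph, upper = (exited + cens) / reps)
}

#' Hausdorff-type metric on finite point sets
#'
#' The capped two-sided Hausdorff metric used for range convergence:
#' `d_1(K, K') = Delta_1(K, K') + Delta_1(K', K)` (the *sum* of the two
#' directed deviations, not their maximum), `d_0 = min(d_1, 1)`, with the
#' conventions `d_0(empty, K) = 1` for nonempty `K` and
#' `d_0(empty, empty) = 0` (forced by the metric axioms; the definition
#' leaves it unstated).
#'
#' @param K,Kp numeric matrices of points (zero rows = empty set), or
#'   `range_set`s.
#' @return a value in `[0, 1]`.
#' @export
hausdorff <- function(K, Kp) {
  pts <- function(z) {
    if (inherits(z, "range_set")) z <- z$points
    if (is.null(z) || length(z) == 0) return(matrix(numeric(0), 0, 1))
    if (!is.matrix(z)) z <- matrix(z, 1)
    z
  }
  A <- pts(K); B <- pts(Kp)
  if (nrow(A) == 0 && nrow(B) == 0) return(0)
  if (nrow(A) == 0 || nrow(B) == 0) return(1)
  cross <- function(P, Q) {
    # max over rows p of min over rows q of |p - q|
    d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
      outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
    max(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  min(cross(A, B) + cross(B, A), 1)
}

#' Modulus-of-continuity statistic of an ancestral system
#'
#' `Delta(rho)`: the largest spatial distance `|y2 - y1|` over ancestrally
#' related pairs `(s1, y1) -> (s2, y2)` with `|s2 - s1| <= rho`, evaluated
#' on the jump skeleton.  With a finite `pair_budget` the time-pair grid is
#' subsampled and the value is a lower bound on the skeleton supremum;
#' exact (on the skeleton) when the budget covers all pairs.
#'
#' @param sys an `ancestral_system` (possibly rescaled).
#' @param rho time-window width (in the system's own time units).
#' @param pair_budget cap on the number of time pairs examined.
#' @param seed optional seed for the subsampling.
#' @return list with `value`, `pairs_examined`, `exhaustive` flag.
#' @export
modulus_stat <- function(sys, rho, pair_budget = Inf, seed = NULL) {
  stopifnot(inherits(sys, "ancestral_system"), rho >= 0)
  if (!is.null(seed)) set.seed(seed)
  tg <- sort(unique(sys$skeleton))
  prs <- which(outer(tg, tg, function(a, b) b - a) >= 0 &
               outer(tg, tg, function(a, b) b - a) <= rho, arr.ind = TRUE)
  prs <- prs[tg[prs[, 2]] >= tg[prs[, 1]], , drop = FALSE]
  exhaustive <- TRUE
  if (nrow(prs) > pair_budget) {
    prs <- prs[sample.int(nrow(prs), pair_budget), , drop = FALSE]
    exhaustive <- FALSE
  }
  best <- 0
  n_ex <- 0L
  for (k in seq_len(nrow(prs))) {
    s1 <- tg[prs[k, 1]]; s2 <- tg[prs[k, 2]]
    o2 <- sys$occupied(s2)
    if (!nrow(o2)) next
    o1 <- sys$occupied(s1)
    if (!nrow(o1)) next
    cc <- sys$coord_cols
    for (i in seq_len(nrow(o2))) for (j in seq_len(nrow(o1))) {
      if (sys$query(s1, s2, o1[j, ], o2[i, ])) {
        disp <- sqrt(sum((o2[i, cc] - o1[j, cc])^2))
        if (disp > best) best <- disp
      }
    }
    n_ex <- n_ex + 1L
  }
  list(value = best, pairs_examined = n_ex, exhaustive = exhaustive)
}

# fast voter-specific modulus profile: trace the dual of each sampled
# anchor once and take windowed displacement maxima for all rho at once.
# A lower bound on the skeleton supremum: anchors are the occupied sites at
# a budgeted sample of event times, and long duals are thinned to a
# breakpoint budget.
.voter_modulus_profile <- function(record, rho_grid_base,
                                   max_anchor_times = 12,
                                   max_anchor_sites = 8,
                                   max_breakpoints = 256) {
  times <- sort(unique(record$arrows[, 1]))
  if (length(times) > max_anchor_times)
    times <- times[sort(sample.int(length(times), max_anchor_times))]
  times <- unique(c(times, record$t_max))
  snaps <- occupied_at_multi(record, times)
  best <- numeric(length(rho_grid_base))
  for (k in seq_along(times)) {
    t <- times[k]
    occ <- snaps[[k]]
    if (nrow(occ) > max_anchor_sites)
      occ <- occ[sample.int(nrow(occ), max_anchor_sites), , drop = FALSE]
    for (i in seq_len(nrow(occ))) {
      x <- occ[i, ]
      pw <- dual_walk(record, t, x)
      if (!length(pw$jump_times)) next
      sites <- rbind(matrix(as.numeric(x), 1), pw$sites)
      bw <- c(0, t - pw$jump_times)          # backward times, increasing
      if (length(bw) > max_breakpoints) {
        keep <- sort(sample.int(length(bw), max_breakpoints))
        bw <- bw[keep]
        sites <- sites[keep, , drop = FALSE]
      }
      prof <- cpp_window_max_disp(bw, sites, rho_grid_base)
      best <- pmax(best, prof)
    }
  }
  best
}

#' Occupied sets of a record at several times in one replay
#'
#' Equivalent to calling [occupied_at()] for each time, but replays the
#' event record only once.
#'
#' @param record a `graphical_record`.
#' @param times increasing times in `[0, t_max]`.
#' @return list of site matrices, one per time.
#' @export
occupied_at_multi <- function(record, times) {
  stopifnot(all(times >= 0), all(times <= record$t_max))
  ord <- order(times)
  st <- times[ord]
  d <- record$d
  ev <- .record_events(record)
  occ <- new.env(parent = emptyenv())
  assign(.site_key(integer(d)), rep(0L, d), envir = occ)
  voter <- identical(record$model, "voter")
  snap <- function() {
    keys <- ls(occ)
    if (!length(keys)) return(matrix(integer(0), 0, d))
    out <- do.call(rbind, mget(keys, envir = occ))
    dimnames(out) <- NULL
    out
  }
  res <- vector("list", length(st))
  nxt <- 1L
  i <- 1L
  n_ev <- nrow(ev)
  while (nxt <= length(st)) {
    while (i <= n_ev && ev[i, 1] <= st[nxt]) {
      if (ev[i, 2] == 1) {
        row <- record$arrows[ev[i, 3], ]
        x <- as.integer(row[2:(d + 1)])
        y <- as.integer(row[(d + 2):(2 * d + 1)])
        xk <- .site_key(x)
        if (!is.null(occ[[.site_key(y)]])) occ[[xk]] <- x
        else if (voter && !is.null(occ[[xk]])) rm(list = xk, envir = occ)
      } else {
        row <- record$recoveries[ev[i, 3], ]
        xk <- .site_key(as.integer(row[2:(d + 1)]))
        if (!is.null(occ[[xk]])) rm(list = xk, envir = occ)
      }
      i <- i + 1L
    }
    res[[nxt]] <- snap()
    nxt <- nxt + 1L
  }
  out <- vector("list", length(st))
  out[ord] <- res
  out
}

#' Tail experiment for the ancestral modulus of continuity
#'
#' For each scale `n` in the grid, simulates voter-model realizations,
#' computes the rescaled modulus `Delta(rho)` on the jump skeleton, and
#' tabulates `m(n) * P(Delta(rho) > C (rho^alpha + n^-alpha))` over the
#' `rho` grid, together with a log-log slope diagnostic against the tail
#' exponent `beta`.
#'
#' @param spec a voter [model_spec()].
#' @param n_grid integer vector of diffusive scales.
#' @param rho_grid rescaled time-window widths in `(0, 1]`.
#' @param cfg a [modulus_config()].
#' @param C threshold constant.
#' @param reps replicates per scale.
#' @param seed optional seed.
#' @param caps see [sim_caps()].
#' @return list with a tidy `table` (one row per `(n, rho)`) and the fitted
#'   `slopes` per scale with standard errors.
#' @export
modulus_tail_experiment <- function(spec, n_grid, rho_grid, cfg = modulus_config(),
                                    C = 1, reps = 200, seed = NULL,
                                    caps = sim_caps()) {
  stopifnot(spec$model == "voter")
  if (!is.null(seed)) set.seed(seed)
  rows <- NULL
  slopes <- NULL
  for (n in n_grid) {
    thresh <- C * (rho_grid^cfg$alpha + n^(-cfg$alpha))
    exceed <- matrix(0, reps, length(rho_grid))
    for (r in seq_len(reps)) {
      sim <- simulate_voter(spec$kernel, t_max = 4 * n, caps = caps,
                            record = TRUE)
      prof <- .voter_modulus_profile(sim$record, rho_grid * n)
      exceed[r, ] <- (prof / sqrt(n)) > thresh
    }
    phat <- colMeans(exceed)
    se <- sqrt(phat * (1 - phat) / reps)
    mn <- m_function("voter", n, d = spec$kernel$d)
    rows <- rbind(rows, data.frame(n = n, rho = rho_grid, threshold = thresh,
                                   p_exceed = phat, se = se,
                                   scaled_tail = mn * phat,
                                   scaled_se = mn * se))
    pos <- phat > 0 & phat < 1
    if (sum(pos) >= 2) {
      fit <- stats::lm(log(phat[pos]) ~ log(rho_grid[pos]))
      cf <- summary(fit)$coefficients
      slopes <- rbind(slopes, data.frame(
        n = n, slope = cf[2, 1],
        slope_se = if (nrow(cf) > 1) cf[2, 2] else NA_real_))
    }
  }
  list(table = rows, slopes = slopes, cfg = cfg, C = C, reps = reps)
}

#' Exponent configuration for the modulus statistics
#'
#' Holds the exponents of the modulus tail bound: a spatial Hoelder exponent
#' `alpha` in `(0, 1/2)`, a tail exponent `beta` in `(0, 1]`, the spatial
#' moment order `p` and the local-jump exponent `kappa`, subject to
#' `(1 - 2 alpha) / (1 + beta) >= 4 / p` and `alpha < 1/2 - 2/kappa`.  The
#' derived exponent `q = min(kappa (1/2 - alpha)/... , 1)` of the scale
#' correction is also reported.
#'
#' @param alpha spatial exponent.
#' @param beta tail exponent.
#' @param p moment order (`> 4`).
#' @param kappa jump-tail order (`> 4`).
#' @export
modulus_config <- function(alpha = 0.1, beta = 1, p = 12, kappa = 40) {
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must lie in (0, 1/2)")
  if (!(beta > 0 && beta <= 1)) stop("beta must lie in (0, 1]")
  if ((1 - 2 * alpha) / (1 + beta) < 4 / p - 1e-12)
    stop("exponents violate (1 - 2 alpha)/(1 + beta) >= 4/p")
  if (!(alpha < 0.5 - 2 / kappa))
    stop("exponents violate alpha < 1/2 - 2/kappa")
  q <- min((kappa * (0.5 - alpha) - 2) / 2, 1)
  structure(list(alpha = alpha, beta = beta, p = p, kappa = kappa, q = q),
            class = "modulus_config")
}

#' Spatial moment experiment
#'
#' Estimates `E[sum_{x in T_t} |x|^p]` and its diffusive normalization by
#' `t^{p/2}`.  For the voter model the second moment is exactly
#' `t * d * sigma2_D` at every `t` by duality with a single random walk.
#'
#' @inheritParams estimate_survival_prob
#' @param p moment order.
#' @export
spatial_moment <- function(spec, t, p, reps, seed = NULL, caps = sim_caps()) {
  if (!is.null(seed)) set.seed(seed)
  if (.is_continuous(spec)) {
    b <- .spec_batch(spec, t, NULL, reps, caps, moment_p = p)
    v <- b$moment_sum
    cens <- mean(b$status == 3L)
  } else {
    v <- numeric(reps)
    cens <- 0
    for (r in seq_len(reps)) {
      real <- .spec_discrete_run(spec, floor(t), caps)
      sz <- .discrete_sizes(real)
      g <- floor(t) + 1L
      if (length(sz) >= g && sz[g] > 0L) {
        pts <- if (real$model == "op") real$generations[[g]] else {
          P <- real$positions[[g]]
          P[!duplicated(.site_keys(P)), , drop = FALSE]
        }
        v[r] <- sum(rowSums(pts^2)^(p / 2))
      }
      cens <- cens + real$censored / reps
    }
  }
  est <- mean(v)
  se <- sd(v) / sqrt(reps)
  mc_estimate(est, se, reps, censored_frac = cens,
              extra = list(normalized = est / t^(p / 2),
                           normalized_se = se / t^(p / 2)))
}

#' Ancestral-increment moment experiment
#'
#' Estimates `E[sum_{x in T_t} sum_y 1((t - s, y) -> (t, x)) |x - y|^p]`,
#' the `p`-th moment of displacements along the ancestral relation over a
#' backward window of length `s`.  For the voter model this reduces by
#' duality to the moment of a single rate-one walk: exactly
#' `s * d * sigma2_D` when `p = 2`.
#'
#' @inheritParams estimate_survival_prob
#' @param s backward window length (`0 <= s <= t`).
#' @param p moment order.
#' @export
ancestral_increment_moment <- function(spec, t, s, p, reps, seed = NULL,
                                       caps = sim_caps()) {
  stopifnot(s >= 0, s <= t)
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(reps)
  cens <- 0
  for (r in seq_len(reps)) {
    if (spec$model == "voter") {
      sim <- simulate_voter(spec$kernel, t_max = t, caps = caps, record = TRUE)
      cens <- cens + sim$trajectory$censored / reps
      occ <- sim$trajectory$final_set
      tot <- 0
      for (i in seq_len(nrow(occ))) {
        pw <- dual_walk(sim$record, t, occ[i, ])
        y <- dual_position(pw, s)
        tot <- tot + sum((occ[i, ] - y)^2)^(p / 2)
      }
      vals[r] <- tot
    } else if (spec$model == "brw") {
      real <- simulate_brw(spec$offspring, spec$kernel, floor(t), caps = caps)
      cens <- cens + real$censored / reps
      g <- floor(t) + 1L; gm <- floor(t - s) + 1L
      if (length(real$positions) >= g && nrow(real$positions[[g]]) > 0) {
        P <- real$positions[[g]]
        keys <- .site_keys(P)
        tot <- 0
        for (x_key in unique(keys)) {
          idx <- which(keys == x_key)
          x <- P[idx[1], ]
          anc <- unique(vapply(idx, function(i)
            .site_key(.brw_ancestor_site(real, g - 1L, i, gm - 1L)), ""))
          for (yk in anc) {
            y <- as.integer(strsplit(yk, ",", fixed = TRUE)[[1]])
            tot <- tot + sum((x - y)^2)^(p / 2)
          }
        }
        vals[r] <- tot
      }
    } else {
      # generic route through the ancestral system (op / contact)
      sys <- if (spec$model == "op")
        op_ancestral_system(simulate_op(spec$kernel, spec$p, floor(t), caps = caps))
      else {
        sim <- simulate_contact(spec$kernel, spec$lambda, t, caps = caps,
                                record = TRUE)
        contact_ancestral_system(sim$record, sim$trajectory)
      }
      occ_t <- sys$occupied(t)
      occ_s <- sys$occupied(t - s)
      tot <- 0
      for (i in seq_len(nrow(occ_t))) for (j in seq_len(nrow(occ_s)))
        if (sys$query(t - s, t, occ_s[j, ], occ_t[i, ]))
          tot <- tot + sum((occ_t[i, ] - occ_s[j, ])^2)^(p / 2)
      vals[r] <- tot
    }
  }
  mc_estimate(mean(vals), sd(vals) / sqrt(reps), reps, censored_frac = cens)
}

#' Local-jump probe: large ancestral displacements over a short window
#'
#' Estimates, for each `N` in the grid, the probability that some descendant
#' of the root within the time window `[0, 2]` sits at distance at least
#' `N` from the origin.  For finite-range discrete-time models this is
#' identically zero beyond `2 * sqrt(d) * L` (at most two kernel steps).
#'
#' @param spec a [model_spec()].
#' @param N_grid displacement thresholds.
#' @param reps replicates.
#' @param seed optional seed.
#' @param caps see [sim_caps()].
#' @return data frame with columns `N`, `p_hat`, `se`.
#' @export
local_jump_probe <- function(spec, N_grid, reps, seed = NULL,
                             caps = sim_caps()) {
  if (!is.null(seed)) set.seed(seed)
  maxdisp <- numeric(reps)
  if (.is_continuous(spec)) {
    b <- .spec_batch(spec, 2, NULL, reps, caps)
    maxdisp <- sqrt(b$max_radius2)
  } else {
    for (r in seq_len(reps)) {
      real <- .spec_discrete_run(spec, 2L, caps)
      rng <- range_of(real)
      maxdisp[r] <- radius(rng)
    }
  }
  ph <- vapply(N_grid, function(N) mean(maxdisp >= N), 0)
  data.frame(N = N_grid, p_hat = ph, se = sqrt(ph * (1 - ph) / reps))
}

#' Time-integrated rescaled mass of a trajectory
#'
#' Exact piecewise-constant integral of `|T_{n u}| / m(n)` over the
#' rescaled time interval `[t0, t1]`.
#'
#' @param traj an `occupied_trajectory`.
#' @param t0,t1 rescaled time interval.
#' @param n diffusive scale (default 1).
#' @param m_value mass normalization `m(n)` (default `n`, the critical
#'   branching normalization).
#' @export
integrated_mass <- function(traj, t0, t1, n = 1, m_value = n) {
  stopifnot(inherits(traj, "occupied_trajectory"), t0 <= t1, n >= 1)
  a <- n * t0; b <- n * t1
  horizon <- if (identical(traj$status, "extinct")) Inf else traj$stop_time
  if (b > horizon + 1e-12)
    stop("interval extends beyond the simulated horizon")
  brk <- c(0, traj$times)             # |T| constant on [brk[i], brk[i+1])
  sz <- c(1L, traj$sizes)
  total <- 0
  for (i in seq_along(brk)) {
    lo <- max(a, brk[i])
    hi <- min(b, if (i < length(brk)) brk[i + 1] else Inf)
    if (hi > lo) total <- total + sz[i] * (hi - lo)
  }
  total / (n * m_value)
}

#' Mass normalization function `m(t)` per model
#'
#' Voter model: `t v 1` for `d > 2` and `(t v e)/log(t v e)` for `d = 2`.
#' Oriented percolation, contact process and lattice trees: `A^2 V (t v 1)`
#' with the lace-expansion constants `A, V` supplied through `constants`.
#'
#' @param model `"voter"`, `"op"`, `"contact"` or `"lattice_tree"`.
#' @param t time.
#' @param d dimension (voter model only).
#' @param constants a [limit_constants()] (or list with `A`, `V`).
#' @export
m_function <- function(model, t, d = NULL, constants = NULL) {
  if (model == "voter") {
    if (is.null(d)) stop("the voter m(t) needs the dimension d")
    if (d > 2) return(pmax(t, 1))
    if (d == 2) return(pmax(t, exp(1)) / log(pmax(t, exp(1))))
    stop("voter m(t) defined for d >= 2")
  }
  if (is.null(constants) || is.null(constants$A) || is.null(constants$V))
    stop("m(t) for this model needs constants A and V")
  constants$A^2 * constants$V * pmax(t, 1)
}
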