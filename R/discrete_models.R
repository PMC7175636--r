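#' Finitely supported offspring laws
#'
#' @param values nonnegative integer support.
#' @param probs probabilities summing to 1.
#' @return an `offspring_law` with fields `values`, `probs`, `mean`,
#'   `variance` and a `critical` flag (mean exactly 1 within 1e-12).  For a
#'   critical law the variance equals the branching rate `gamma` of the
#'   limiting super-Brownian motion.
#' @export
offspring_law <- function(values, probs) {
  stopifnot(length(values) == length(probs), all(probs >= 0),
            all(values >= 0), all(values == round(values)))
  if (abs(sum(probs) - 1) > 1e-12) stop("offspring probabilities must sum to 1")
  m <- sum(values * probs)
  v <- sum(values^2 * probs) - m^2
  structure(list(values = as.integer(values), probs = probs, mean = m,
                 variance = v, critical = abs(m - 1) < 1e-12),
            class = "offspring_law")
}

#' @rdname offspring_law
#' @details `offspring_binary()` is the critical binary law (0 or 2 children,
#'   probability 1/2 each; variance `gamma = 1`); `offspring_delta(k)` always
#'   produces `k` children.
#' @export
offspring_binary <- function() offspring_law(c(0L, 2L), c(0.5, 0.5))

#' @rdname offspring_law
#' @param k fixed number of children.
#' @export
offspring_delta <- function(k) offspring_law(k, 1)

#' @export
print.offspring_law <- function(x, ...) {
  cat(sprintf("offspring law on {%s}: probs (%s); mean %.4g, variance %.4g%s\n",
              paste(x$values, collapse = ", "),
              paste(signif(x$probs, 4), collapse = ", "),
              x$mean, x$variance, if (x$critical) " [critical]" else ""))
  invisible(x)
}

# total offspring of a vector of population sizes, by sequential binomial
# splitting over the support (vectorized across replicates; doubles to
# avoid overflow on supercritical excursions)
.gw_step <- function(Z, law) {
  rem <- as.numeric(Z)
  pleft <- 1
  tot <- numeric(length(Z))
  for (j in seq_along(law$values)) {
    pj <- law$probs[j]
    nj <- if (pleft - pj < 1e-14) rem else
      rbinom(length(rem), rem, min(1, pj / pleft))
    tot <- tot + law$values[j] * nj
    rem <- rem - nj
    pleft <- pleft - pj
  }
  tot
}

#' Simulate oriented percolation cluster growth
#'
#' Bonds from `(n, x)` to `(n + 1, x + e)` are independently occupied with
#' probability `p * D(e)`; only bonds out of currently occupied sites are
#' generated (sufficient for the cluster of the origin).
#'
#' @param kernel a [step_kernel()].
#' @param p bond probability scale; requires `p * max(D) <= 1`.
#' @param n_max number of generations.
#' @param seed optional seed.
#' @param caps resource limits ([sim_caps()]; `max_sites` bounds a single
#'   generation).
#' @return an `op_realization`: `generations` (list of site matrices,
#'   entry `g + 1` is generation `g`), `bonds` (list of matrices with
#'   `from`/`to` coordinates per generation) and a `censored` flag.
#' @export
simulate_op <- function(kernel, p, n_max, seed = NULL, caps = sim_caps()) {
  validate_step_kernel(kernel)
  if (p < 0 || p * max(kernel$probs) > 1)
    stop("need 0 <= p * max(D) <= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- kernel$d
  m <- nrow(kernel$offsets)
  gens <- vector("list", n_max + 1L)
  bonds <- vector("list", n_max)
  gens[[1L]] <- matrix(0L, 1, d)
  censored <- FALSE
  for (g in seq_len(n_max)) {
    S <- gens[[g]]
    if (nrow(S) == 0L) {
      gens[[g + 1L]] <- matrix(integer(0), 0, d)
      bonds[[g]] <- matrix(integer(0), 0, 2 * d)
      next
    }
    from <- S[rep(seq_len(nrow(S)), each = m), , drop = FALSE]
    to <- from + kernel$offsets[rep(seq_len(m), nrow(S)), , drop = FALSE]
    occ <- rbinom(nrow(from), 1L, rep(p * kernel$probs, nrow(S))) == 1L
    bonds[[g]] <- cbind(from[occ, , drop = FALSE], to[occ, , drop = FALSE])
    tgt <- to[occ, , drop = FALSE]
    gens[[g + 1L]] <- tgt[!duplicated(.site_keys(tgt)), , drop = FALSE]
    if (nrow(gens[[g + 1L]]) > caps$max_sites) {
      censored <- TRUE
      gens <- gens[seq_len(g + 1L)]
      bonds <- bonds[seq_len(g)]
      break
    }
  }
  structure(list(model = "op", kernel = kernel, d = d, p = p,
                 n_max = length(gens) - 1L, generations = gens,
                 bonds = bonds, censored = censored),
            class = "op_realization")
}

#' @export
print.op_realization <- function(x, ...) {
  sizes <- vapply(x$generations, nrow, 1L)
  cat(sprintf("oriented percolation realization (d = %d, p = %.4g): %d generations%s\n",
              x$d, x$p, x$n_max, if (x$censored) " [censored]" else ""))
  cat("  |T_n|:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Simulate branching random walk
#'
#' Each particle independently produces children according to the offspring
#' law, each child displaced by an independent kernel step.  Multi-occupancy
#' is allowed; ancestral relations live on labelled particles and project to
#' occupied sites.
#'
#' @param offspring an [offspring_law()].
#' @param kernel a [step_kernel()].
#' @param n_max generations.
#' @param seed optional seed.
#' @param caps resource limits (`max_sites` bounds particles per generation).
#' @return a `brw_realization`: `positions` (list of particle-position
#'   matrices per generation) and `parents` (list of parent row indices into
#'   the previous generation).
#' @export
simulate_brw <- function(offspring, kernel, n_max, seed = NULL,
                         caps = sim_caps()) {
  stopifnot(inherits(offspring, "offspring_law"))
  validate_step_kernel(kernel)
  if (!is.null(seed)) set.seed(seed)
  d <- kernel$d
  pos <- vector("list", n_max + 1L)
  par <- vector("list", n_max + 1L)
  pos[[1L]] <- matrix(0L, 1, d)
  par[[1L]] <- NA_integer_
  censored <- FALSE
  for (g in seq_len(n_max)) {
    np <- nrow(pos[[g]])
    if (np == 0L) {
      pos[[g + 1L]] <- matrix(integer(0), 0, d)
      par[[g + 1L]] <- integer(0)
      next
    }
    counts <- sample(offspring$values, np, replace = TRUE,
                     prob = offspring$probs)
    parent <- rep.int(seq_len(np), counts)
    tot <- length(parent)
    if (tot > caps$max_sites) {
      censored <- TRUE
      pos <- pos[seq_len(g)]
      par <- par[seq_len(g)]
      break
    }
    pos[[g + 1L]] <- if (tot)
      pos[[g]][parent, , drop = FALSE] + sample_step(kernel, tot)
    else matrix(integer(0), 0, d)
    par[[g + 1L]] <- parent
  }
  structure(list(model = "brw", kernel = kernel, d = d,
                 offspring = offspring, n_max = length(pos) - 1L,
                 positions = pos, parents = par, censored = censored),
            class = "brw_realization")
}

#' @export
print.brw_realization <- function(x, ...) {
  sizes <- vapply(x$positions, nrow, 1L)
  cat(sprintf("branching random walk (d = %d, %s offspring): %d generations%s\n",
              x$d, if (x$offspring$critical) "critical" else "non-critical",
              x$n_max, if (x$censored) " [censored]" else ""))
  cat("  particles per generation:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Export a branching-random-walk genealogy as a data frame
#'
#' Columns: `id`, `parent_id`, `generation`, position coordinates.  Suitable
#' for writing with [utils::write.csv()].
#' @param real a `brw_realization`.
#' @export
brw_genealogy <- function(real) {
  d <- real$d
  out <- NULL
  offset <- 0L
  prev_offset <- 0L
  for (g in seq_along(real$positions)) {
    np <- nrow(real$positions[[g]])
    if (np == 0L) break
    ids <- offset + seq_len(np)
    pid <- if (g == 1L) NA_integer_ else prev_offset + real$parents[[g]]
    blk <- data.frame(id = ids, parent_id = pid, generation = g - 1L)
    posdf <- as.data.frame(real$positions[[g]])
    names(posdf) <- paste0("x", seq_len(d))
    out <- rbind(out, cbind(blk, posdf))
    prev_offset <- offset
    offset <- offset + np
  }
  out
}

#' Exact Galton-Watson survival probability
#'
#' Iterates the probability generating function: with `f(s) = sum p_j s^j`,
#' the extinction-by-generation-`n` probability is the `n`-fold iterate of
#' `f` at 0, and `P(Z_n > 0)` is its complement.  Serves as the independent
#' oracle for the survival experiments.
#'
#' @param offspring an [offspring_law()].
#' @param n generation.
#' @export
gw_survival_exact <- function(offspring, n) {
  q <- 0
  for (i in seq_len(n)) q <- sum(offspring$probs * q^offspring$values)
  1 - q
}

#' Kolmogorov survival experiment for a critical Galton-Watson process
#'
#' Estimates `n * P(Z_n > 0)`, the finite-`n` analogue of the
#' canonical-measure survival constant `2 / gamma` (branching rate `gamma` =
#' offspring variance).
#'
#' @param offspring an [offspring_law()].
#' @param n generation at which survival is assessed.
#' @param reps independent replicates.
#' @param seed optional seed.
#' @return an [mc_estimate()] of `n * P(Z_n > 0)`; `extra$p_hat` holds the
#'   raw survival fraction and `extra$exact` the recursion value.
#' @export
gw_survival_experiment <- function(offspring, n, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- rep.int(1L, reps)
  for (g in seq_len(n)) {
    alive <- Z > 0L
    if (!any(alive)) break
    Z[alive] <- .gw_step(Z[alive], offspring)
  }
  phat <- mean(Z > 0L)
  se <- sqrt(phat * (1 - phat) / reps)
  mc_estimate(n * phat, n * se, reps,
              extra = list(p_hat = phat, exact = gw_survival_exact(offspring, n)))
}

#' Yaglom experiment: conditional exponential law of `Z_n / n`
#'
#' Simulates until at least `min_survivors` replicates survive to generation
#' `n` (or exactly `reps` replicates if given), then estimates the rate of
#' the limiting exponential of `Z_n / n` given survival as the inverse
#' conditional mean.  The limit rate is `2 / gamma`.
#'
#' @param offspring an [offspring_law()].
#' @param n generation.
#' @param reps optional fixed number of replicates.
#' @param min_survivors minimum surviving replicates when `reps` is `NULL`.
#' @param seed optional seed.
#' @param batch batch size for the adaptive mode.
#' @return an [mc_estimate()] of the rate; `extra$sample` holds the surviving
#'   values of `Z_n / n` and `extra$conditional_mean` their mean.
#' @export
gw_yaglom_experiment <- function(offspring, n, reps = NULL,
                                 min_survivors = 1e4, seed = NULL,
                                 batch = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  run_batch <- function(nrep) {
    Z <- rep.int(1L, nrep)
    for (g in seq_len(n)) {
      alive <- Z > 0L
      if (!any(alive)) break
      Z[alive] <- .gw_step(Z[alive], offspring)
    }
    Z[Z > 0L]
  }
  total <- 0
  surv <- integer(0)
  if (!is.null(reps)) {
    surv <- run_batch(reps)
    total <- reps
  } else {
    while (length(surv) < min_survivors) {
      surv <- c(surv, run_batch(batch))
      total <- total + batch
      if (total > 1e8) stop("survivor quota unreachable within 1e8 replicates")
    }
  }
  x <- surv / n
  mbar <- mean(x)
  rate <- 1 / mbar
  se <- sd(x) / (mbar^2 * sqrt(length(x)))   # delta method
  mc_estimate(rate, se, as.integer(total),
              extra = list(sample = x, n_survivors = length(x),
                           conditional_mean = mbar))
}

#' Laplace functional of integrated Galton-Watson mass
#'
#' Monte-Carlo estimate of
#' `E[exp(-lambda * (1/n) * sum_{k=n}^{2n} Z_k / n) | Z_n > 0]`, the
#' discretized conditional Laplace transform of the mass integrated over the
#' rescaled time window `[1, 2]`.  The super-Brownian limit is the closed
#' form [laplace_integrated_mass()].
#'
#' @param offspring an [offspring_law()].
#' @param lambda Laplace argument (nonnegative).
#' @param n generation scale.
#' @param reps replicates.
#' @param seed optional seed.
#' @return an [mc_estimate()]; `extra$n_survivors` counts the conditioning
#'   event.
#' @export
gw_laplace_experiment <- function(offspring, lambda, n, reps, seed = NULL) {
  stopifnot(lambda >= 0)
  if (!is.null(seed)) set.seed(seed)
  Z <- rep.int(1L, reps)
  for (g in seq_len(n)) {
    alive <- Z > 0L
    if (!any(alive)) break
    Z[alive] <- .gw_step(Z[alive], offspring)
  }
  surv <- Z > 0L
  if (!any(surv)) stop("no replicate survived to generation n")
  Zs <- Z[surv]
  S <- as.numeric(Zs)                      # k = n term
  for (g in seq_len(n)) {                  # k = n+1 .. 2n
    alive <- Zs > 0L
    if (any(alive)) Zs[alive] <- .gw_step(Zs[alive], offspring)
    S <- S + Zs
  }
  vals <- exp(-lambda * S / n^2)
  mc_estimate(mean(vals), sd(vals) / sqrt(length(vals)), reps,
              extra = list(n_survivors = sum(surv)))
}

#' Bisection estimate of the critical bond-probability scale
#'
#' Same approximate bisection as [estimate_lambda_c()], for oriented
#' percolation: at a candidate `p` the decay of `n * theta_hat(n)` between
#' `n_probe / 2` and `n_probe` decides the branch.
#'
#' @param kernel a [step_kernel()].
#' @param bracket initial bracket for `p`.
#' @param n_probe probe generation.
#' @param reps replicates per probe.
#' @param seed optional seed.
#' @param n_iter bisection iterations.
#' @param caps see [sim_caps()].
#' @export
estimate_p_c <- function(kernel, bracket, n_probe = 30, reps = 2000,
                         seed = NULL, n_iter = 8, caps = sim_caps()) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (!is.null(seed)) set.seed(seed)
  half <- floor(n_probe / 2)
  probe <- function(p) {
    alive_n <- alive_h <- 0
    for (r in seq_len(reps)) {
      real <- simulate_op(kernel, p, n_probe, caps = caps)
      sizes <- vapply(real$generations, nrow, 1L)
      if (length(sizes) > half && sizes[half + 1L] > 0L)
        alive_h <- alive_h + 1
      if (length(sizes) > n_probe && sizes[n_probe + 1L] > 0L)
        alive_n <- alive_n + 1
    }
    c(theta_n = alive_n / reps, theta_half = alive_h / reps)
  }
  lo <- bracket[1]; hi <- bracket[2]
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    p <- probe(mid)
    decaying <- n_probe * p["theta_n"] < 0.75 * half * p["theta_half"]
    if (decaying) lo <- mid else hi <- mid
  }
  list(bracket = c(lo, hi), estimate = (lo + hi) / 2,
       note = "Monte-Carlo bisection bracket; not the exact critical scale")
}
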