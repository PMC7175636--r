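#' Resource caps for event-driven simulations
#'
#' Critical trajectories have survival times with infinite mean, so every
#' simulator takes explicit caps; hitting a cap flags the realization as
#' censored instead of silently truncating it.
#'
#' @param max_events maximum number of generated Poisson events.
#' @param max_sites maximum number of simultaneously occupied sites.
#' @export
sim_caps <- function(max_events = 1e7, max_sites = 1e6) {
  stopifnot(max_events > 0, max_sites > 0)
  list(max_events = max_events, max_sites = max_sites)
}

.status_labels <- c("alive", "extinct", "exited", "censored")

.new_record <- function(model, kernel, t_max, arrows, recoveries) {
  d <- kernel$d
  colnames(arrows) <- c("time", paste0("target", seq_len(d)),
                        paste0("source", seq_len(d)))
  if (nrow(recoveries) > 0 || model == "contact")
    colnames(recoveries) <- c("time", paste0("site", seq_len(d)))
  structure(list(model = model, kernel = kernel, d = d, t_max = t_max,
                 arrows = arrows, recoveries = recoveries,
                 coverage = "occupied-anchored",
                 cache = new.env(parent = emptyenv())),
            class = "graphical_record")
}

.new_trajectory <- function(model, d, t_max, run) {
  status <- .status_labels[run$status + 1L]
  structure(list(model = model, d = d, t_max = t_max,
                 times = run$jump_times, sizes = run$jump_sizes,
                 status = status, censored = identical(status, "censored"),
                 survival_time = run$survival_time,
                 exit_time = run$exit_time, stop_time = run$stop_time,
                 max_radius = sqrt(run$max_radius2),
                 final_set = run$final_set, n_events = run$n_events),
            class = "occupied_trajectory")
}

#' @export
print.graphical_record <- function(x, ...) {
  cat(sprintf("graphical record (%s, d = %d, horizon %.4g): %d arrows, %d recovery marks\n",
              x$model, x$d, x$t_max, nrow(x$arrows), nrow(x$recoveries)))
  invisible(x)
}

#' @export
print.occupied_trajectory <- function(x, ...) {
  cat(sprintf("occupied trajectory (%s, d = %d): %d jumps on [0, %.4g], status '%s'\n",
              x$model, x$d, length(x$times), x$t_max, x$status))
  if (identical(x$status, "extinct"))
    cat(sprintf("  extinct at t = %.6g\n", x$survival_time))
  cat(sprintf("  |T| at stop: %d; max Euclidean radius of range: %.4g\n",
              nrow(x$final_set), x$max_radius))
  invisible(x)
}

.run_particle <- function(model, kernel, lambda, t_max, exit_radius, caps,
                          record, store_jumps) {
  cpp_particle_run(model, kernel$offsets, .kernel_cum(kernel),
                   lambda, t_max,
                   if (is.null(exit_radius)) -1 else exit_radius,
                   caps$max_events, as.integer(caps$max_sites),
                   record, store_jumps)
}

#' Simulate the voter model from a single 1 at the origin
#'
#' Event-driven graphical construction: arrows from a source voter `y` into a
#' target `x` arrive at rate `D(x - y)` and the target adopts the source's
#' opinion.  Only arrows with an endpoint in the occupied set are
#' materialized, which is exact for the trajectory law and sufficient to
#' trace every dual walk anchored at an occupied space-time point.
#'
#' @param kernel a [step_kernel()].
#' @param t_max simulation horizon (arrows at exactly `t_max` are included).
#' @param seed optional integer passed to [set.seed()].
#' @param caps resource limits, see [sim_caps()].
#' @param record keep the realized arrows (needed for dual walks and
#'   ancestral queries); disable for bulk Monte Carlo.
#' @param exit_radius optional Euclidean radius; the run stops (status
#'   `"exited"`) the moment any occupied site leaves the closed ball.
#' @return a list with components `record` (a `graphical_record`, or `NULL`)
#'   and `trajectory` (an `occupied_trajectory`).
#' @export
simulate_voter <- function(kernel, t_max, seed = NULL, caps = sim_caps(),
                           record = TRUE, exit_radius = NULL) {
  validate_step_kernel(kernel)
  stopifnot(t_max >= 0)
  if (!is.null(seed)) set.seed(seed)
  run <- .run_particle("voter", kernel, 0, t_max, exit_radius, caps,
                       record, TRUE)
  list(record = if (record)
         .new_record("voter", kernel, t_max, run$arrows, run$recoveries)
       else NULL,
       trajectory = .new_trajectory("voter", kernel$d, t_max, run))
}

#' Simulate the contact process from a single infected site at the origin
#'
#' Infected sites recover at rate 1 (a recovery mark) and emit infection
#' arrows at rate `lambda * D(x - y)` towards each site `x`.  A site is
#' infected at time `t` iff an oriented, recovery-free arrow path leads from
#' the origin at time 0 to it.
#'
#' @inheritParams simulate_voter
#' @param lambda infection rate (nonnegative); `lambda = 0` is a pure death
#'   process at the origin.
#' @export
simulate_contact <- function(kernel, lambda, t_max, seed = NULL,
                             caps = sim_caps(), record = TRUE,
                             exit_radius = NULL) {
  validate_step_kernel(kernel)
  stopifnot(lambda >= 0, t_max >= 0)
  if (!is.null(seed)) set.seed(seed)
  run <- .run_particle("contact", kernel, lambda, t_max, exit_radius, caps,
                       record, TRUE)
  list(record = if (record)
         .new_record("contact", kernel, t_max, run$arrows, run$recoveries)
       else NULL,
       trajectory = .new_trajectory("contact", kernel$d, t_max, run))
}

#' Build a graphical record by hand (fixtures, unit tests)
#'
#' @param model `"voter"` or `"contact"`.
#' @param d dimension.
#' @param t_max horizon.
#' @param arrows matrix (or data frame) with columns time, target coords,
#'   source coords; may have zero rows.
#' @param recoveries matrix with columns time, site coords (contact only).
#' @param kernel optional `step_kernel` consistent with the arrows.
#' @export
graphical_record <- function(model = c("voter", "contact"), d, t_max,
                             arrows = NULL, recoveries = NULL, kernel = NULL) {
  model <- match.arg(model)
  if (is.null(kernel)) kernel <- uniform_box_kernel(d, 1)
  a <- if (is.null(arrows)) matrix(numeric(0), 0, 1 + 2 * d) else
    as.matrix(arrows)
  r <- if (is.null(recoveries)) matrix(numeric(0), 0, 1 + d) else
    as.matrix(recoveries)
  if (nrow(a) && (any(a[, 1] <= 0) || any(a[, 1] > t_max)))
    stop("arrow times must lie in (0, t_max]")
  if (nrow(r) && (any(r[, 1] <= 0) || any(r[, 1] > t_max)))
    stop("recovery times must lie in (0, t_max]")
  if (anyDuplicated(c(a[, 1], r[, 1])))
    stop("event times must be distinct")
  .new_record(model, kernel, t_max, a[order(a[, 1]), , drop = FALSE],
              r[order(r[, 1]), , drop = FALSE])
}

.site_key <- function(x) paste(x, collapse = ",")
.site_keys <- function(m) apply(m, 1L, paste, collapse = ",")

# merged, time-ordered event table: time, type (1 arrow / 2 recovery), row
.record_events <- function(record) {
  if (!is.null(record$cache$events)) return(record$cache$events)
  a <- record$arrows; r <- record$recoveries
  ev <- rbind(
    if (nrow(a)) cbind(a[, 1], 1, seq_len(nrow(a))),
    if (nrow(r)) cbind(r[, 1], 2, seq_len(nrow(r))))
  if (is.null(ev)) ev <- matrix(numeric(0), 0, 3)
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  record$cache$events <- ev
  ev
}

#' Occupied set of a record at a given time
#'
#' Replays the recorded events from the initial condition `{o}` up to and
#' including time `s` (right-continuous convention: events at exactly `s`
#' count).
#'
#' @param record a `graphical_record`.
#' @param s time in `[0, t_max]`.
#' @return integer matrix of occupied sites (possibly zero rows).
#' @export
occupied_at <- function(record, s) {
  stopifnot(inherits(record, "graphical_record"), s >= 0)
  if (s > record$t_max) stop("s beyond the record horizon")
  d <- record$d
  ev <- .record_events(record)
  occ <- new.env(parent = emptyenv())
  assign(.site_key(integer(d)), rep(0L, d), envir = occ)
  voter <- identical(record$model, "voter")
  for (i in seq_len(nrow(ev))) {
    if (ev[i, 1] > s) break
    if (ev[i, 2] == 1) {
      row <- record$arrows[ev[i, 3], ]
      x <- as.integer(row[2:(d + 1)]); y <- as.integer(row[(d + 2):(2 * d + 1)])
      xk <- .site_key(x); yk <- .site_key(y)
      y_occ <- !is.null(occ[[yk]])
      if (voter) {
        if (y_occ) occ[[xk]] <- x else if (!is.null(occ[[xk]])) rm(list = xk, envir = occ)
      } else if (y_occ) occ[[xk]] <- x
    } else {
      row <- record$recoveries[ev[i, 3], ]
      xk <- .site_key(as.integer(row[2:(d + 1)]))
      if (!is.null(occ[[xk]])) rm(list = xk, envir = occ)
    }
  }
  keys <- ls(occ)
  if (!length(keys)) return(matrix(integer(0), 0, d))
  out <- do.call(rbind, mget(keys, envir = occ))
  dimnames(out) <- NULL
  out
}

# arrow indices grouped by target key (memoized on the record)
.target_index <- function(record) {
  if (!is.null(record$cache$tindex)) return(record$cache$tindex)
  d <- record$d
  idx <- if (nrow(record$arrows))
    split(seq_len(nrow(record$arrows)),
          .site_keys(record$arrows[, 2:(d + 1), drop = FALSE]))
  else list()
  record$cache$tindex <- idx
  idx
}

#' Dual (coalescing) random walk of the voter model
#'
#' Traces the opinion at site `x` at time `t` backwards: at each arrow into
#' the current site the walk jumps to the arrow's source.  Arrows at exactly
#' time `t` are included; subsequent searches are on strictly earlier times.
#'
#' @param record a voter `graphical_record`.
#' @param t anchor time in `[0, t_max]`.
#' @param x anchor site (integer vector).
#' @return a `dual_walk_path`: anchor, absolute jump times (decreasing) and
#'   the site after each jump.  Query positions with [dual_position()].
#' @export
dual_walk <- function(record, t, x) {
  stopifnot(inherits(record, "graphical_record"),
            identical(record$model, "voter"), t >= 0, t <= record$t_max)
  d <- record$d
  x <- as.integer(x)
  idx <- .target_index(record)
  cur <- x; cur_t <- t; inclusive <- TRUE
  jt_acc <- vector("list", 64); js_acc <- vector("list", 64); nj <- 0L
  repeat {
    cand <- idx[[.site_key(cur)]]
    if (is.null(cand)) break
    tm <- record$arrows[cand, 1]
    ok <- if (inclusive) tm <= cur_t else tm < cur_t
    if (!any(ok)) break
    j <- cand[ok][which.max(tm[ok])]
    u <- record$arrows[j, 1]
    cur <- as.integer(record$arrows[j, (d + 2):(2 * d + 1)])
    nj <- nj + 1L
    if (nj > length(jt_acc)) {
      length(jt_acc) <- 2L * nj
      length(js_acc) <- 2L * nj
    }
    jt_acc[[nj]] <- unname(u); js_acc[[nj]] <- cur
    cur_t <- u; inclusive <- FALSE
  }
  structure(list(anchor_t = t, anchor_x = x,
                 jump_times = unlist(jt_acc[seq_len(nj)]) %||% numeric(0),
                 sites = if (nj) matrix(unlist(js_acc[seq_len(nj)]),
                                        nj, d, byrow = TRUE)
                 else matrix(integer(0), 0, d),
                 d = d),
            class = "dual_walk_path")
}

#' Position of a dual walk at backward time `s`
#'
#' Follows the left-continuous convention: the walk holds its old position at
#' the backward jump time itself.  For `s >= t` the anchor site is returned
#' (the `(t - s)^+` convention of the ancestral relation).
#'
#' @param path a `dual_walk_path`.
#' @param s backward time (time elapsed since the anchor).
#' @export
dual_position <- function(path, s) {
  if (s <= 0) return(path$anchor_x)
  u <- path$anchor_t - s            # absolute time
  if (u < -1e-9 * (1 + abs(path$anchor_t)))
    return(path$anchor_x)           # the (t - s)^+ reindexing of paths
  # jumps at absolute times jt (decreasing); after jump i the walk is at
  # sites[i, ] on absolute times [jt[i+1], jt[i])  (left-cont. in s).  The
  # tolerance keeps a query at exactly a jump time on the pre-jump site
  # even when t - (t - s) is one ulp off.
  eps <- 1e-9 * (1 + abs(path$anchor_t))
  k <- sum(path$jump_times > u + eps)
  if (k == 0) path$anchor_x else as.integer(path$sites[k, ])
}

#' @export
print.dual_walk_path <- function(x, ...) {
  cat(sprintf("dual walk anchored at t = %.4g, x = (%s): %d backward jumps\n",
              x$anchor_t, paste(x$anchor_x, collapse = ","),
              length(x$jump_times)))
  invisible(x)
}

#' Bisection estimate of the critical infection rate
#'
#' The critical rate is only defined implicitly (smallest rate with positive
#' survival probability at all times), and no closed form exists, so this is
#' an explicitly approximate Monte-Carlo bracket: at each candidate rate the
#' decay of `t * theta_hat(t)` between `t_probe / 2` and `t_probe` decides
#' the branch.  Returns the final bracket together with the survival
#' estimates at both ends.
#'
#' @param kernel a [step_kernel()].
#' @param bracket numeric length-2 initial bracket for `lambda`.
#' @param t_probe probe horizon.
#' @param reps Monte-Carlo replicates per probe.
#' @param seed integer seed.
#' @param n_iter bisection iterations.
#' @param caps see [sim_caps()].
#' @export
estimate_lambda_c <- function(kernel, bracket, t_probe = 20, reps = 2000,
                              seed = NULL, n_iter = 8, caps = sim_caps()) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (!is.null(seed)) set.seed(seed)
  probe <- function(lambda) {
    b <- cpp_particle_batch("contact", kernel$offsets, .kernel_cum(kernel),
                            lambda, t_probe, -1, caps$max_events,
                            as.integer(caps$max_sites), as.integer(reps), -1)
    alive_t <- b$status == 0L
    alive_half <- alive_t | (b$status == 1L & b$survival_time > t_probe / 2)
    c(theta_t = mean(alive_t), theta_half = mean(alive_half))
  }
  lo <- bracket[1]; hi <- bracket[2]
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    p <- probe(mid)
    # subcritical: t * theta(t) decays markedly between t/2 and t
    decaying <- t_probe * p["theta_t"] < 0.75 * (t_probe / 2) * p["theta_half"]
    if (decaying) lo <- mid else hi <- mid
  }
  # final probes at the bracket ends use monotone thinning coupling, so the
  # reported survival frequencies are ordered pathwise
  alive_lo_t <- alive_hi_t <- alive_lo_h <- alive_hi_h <- 0L
  probe_reps <- max(100L, reps %/% 4L)
  for (r in seq_len(probe_reps)) {
    sim <- simulate_contact(kernel, hi, t_probe, caps = caps, record = TRUE)
    rec_hi <- sim$record
    keep <- stats::runif(nrow(rec_hi$arrows)) < lo / hi
    rec_lo <- graphical_record("contact", d = kernel$d, t_max = t_probe,
                               arrows = rec_hi$arrows[keep, , drop = FALSE],
                               recoveries = rec_hi$recoveries,
                               kernel = kernel)
    alive_hi_t <- alive_hi_t + (!identical(sim$trajectory$status, "extinct"))
    alive_hi_h <- alive_hi_h +
      (identical(sim$trajectory$status, "alive") ||
         (is.na(sim$trajectory$survival_time) ||
            sim$trajectory$survival_time > t_probe / 2))
    alive_lo_t <- alive_lo_t + (nrow(occupied_at(rec_lo, t_probe)) > 0)
    alive_lo_h <- alive_lo_h + (nrow(occupied_at(rec_lo, t_probe / 2)) > 0)
  }
  list(bracket = c(lo, hi), estimate = (lo + hi) / 2,
       probe_lower = c(theta_t = alive_lo_t / probe_reps,
                       theta_half = alive_lo_h / probe_reps),
       probe_upper = c(theta_t = alive_hi_t / probe_reps,
                       theta_half = alive_hi_h / probe_reps),
       t_probe = t_probe, reps = reps,
       note = "Monte-Carlo bisection bracket; not the exact critical rate")
}
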