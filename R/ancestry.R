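#' Ancestral systems: a uniform query interface over all model back-ends
#'
#' An `ancestral_system` bundles an occupied trajectory with the model's
#' ancestral relation `e_{s,t}(y, x)`, the indicator that the space-time
#' point `(s, y)` is an ancestor of `(t, x)`.  The relation must satisfy the
#' runtime-checkable axioms: reflexivity exactly on occupied sites, occupied
#' endpoints, the root property (every occupied point descends from the
#' origin at time 0), transitivity, and interpolation (a related pair admits
#' an intermediate ancestor at every intermediate time).  Path regularity and
#' measurability are properties of the probabilistic construction, not of
#' realized samples, and are deliberately not part of the runtime report.
#'
#' @name ancestral_system
NULL

.new_ancestral_system <- function(model, time_kind, d, horizon, occupied,
                                  query, skeleton, unique_paths, backend,
                                  root = rep(0, d), coord_cols = seq_len(d)) {
  structure(list(model = model, time_kind = time_kind, d = d,
                 horizon = horizon, occupied = occupied, query = query,
                 skeleton = skeleton, unique_paths = unique_paths,
                 backend = backend, scale = 1, root = root,
                 coord_cols = coord_cols),
            class = "ancestral_system")
}

#' @export
print.ancestral_system <- function(x, ...) {
  cat(sprintf("ancestral system (%s, %s time, d = %d, horizon %.4g, scale n = %g)\n",
              x$model, x$time_kind, x$d, x$horizon, x$scale))
  invisible(x)
}

#' Ancestral system of a simulated voter model
#'
#' The relation is `e_{s,t}(y, x) = 1` iff `x` is occupied at `t` and `y`
#' is the position of the dual walk of `(t, x)` at backward time
#' `(t - s)^+`; ancestral paths are unique.
#'
#' @param record a voter [graphical_record()].
#' @param trajectory the matching `occupied_trajectory` (optional, used for
#'   the jump skeleton).
#' @return an `ancestral_system`.
#' @export
voter_ancestral_system <- function(record, trajectory = NULL) {
  stopifnot(identical(record$model, "voter"))
  cache <- new.env(parent = emptyenv())
  occ_at <- function(t) {
    key <- sprintf("occ%.15g", t)
    if (is.null(cache[[key]])) cache[[key]] <- occupied_at(record, t)
    cache[[key]]
  }
  dual_of <- function(t, x) {
    key <- sprintf("dual%.15g|%s", t, .site_key(x))
    if (is.null(cache[[key]])) cache[[key]] <- dual_walk(record, t, x)
    cache[[key]]
  }
  query <- function(s, t, y, x) {
    if (s > t) return(FALSE)
    occ <- occ_at(t)
    if (!nrow(occ) || !(.site_key(as.integer(x)) %in% .site_keys(occ)))
      return(FALSE)
    identical(as.integer(dual_position(dual_of(t, as.integer(x)), t - s)),
              as.integer(y))
  }
  # every arrow time belongs to the skeleton: duals jump at arrows between
  # two occupied sites even though the occupied set does not change
  skel <- sort(unique(c(0, record$arrows[, 1], record$t_max)))
  .new_ancestral_system("voter", "continuous", record$d, record$t_max,
                        occ_at, query, skel, TRUE,
                        list(record = record, trajectory = trajectory))
}

# delta-free oriented-path reachability (s, y) -> (t, x) on a contact record
.contact_reach <- function(record, s, y, t, x) {
  d <- record$d
  if (s > t) return(FALSE)
  if (s == t) return(identical(as.integer(y), as.integer(x)))
  ev <- .record_events(record)
  A <- new.env(parent = emptyenv())
  y <- as.integer(y)
  assign(.site_key(y), y, envir = A)
  for (i in seq_len(nrow(ev))) {
    u <- ev[i, 1]
    if (u <= s) next
    if (u > t) break
    if (ev[i, 2] == 1) {
      row <- record$arrows[ev[i, 3], ]
      src <- .site_key(as.integer(row[(d + 2):(2 * d + 1)]))
      if (!is.null(A[[src]])) {
        tgt <- as.integer(row[2:(d + 1)])
        A[[.site_key(tgt)]] <- tgt
      }
    } else {
      row <- record$recoveries[ev[i, 3], ]
      k <- .site_key(as.integer(row[2:(d + 1)]))
      if (!is.null(A[[k]])) rm(list = k, envir = A)
    }
  }
  !is.null(A[[.site_key(as.integer(x))]])
}

#' Ancestral system of a simulated contact process
#'
#' `(s, y)` is an ancestor of `(t, x)` iff `y` is infected at `s` and a
#' recovery-free oriented arrow path leads from `(s, y)` to `(t, x)` on the
#' record.  Ancestral paths exist but need not be unique.
#'
#' @inheritParams voter_ancestral_system
#' @export
contact_ancestral_system <- function(record, trajectory = NULL) {
  stopifnot(identical(record$model, "contact"))
  cache <- new.env(parent = emptyenv())
  occ_at <- function(t) {
    key <- sprintf("occ%.15g", t)
    if (is.null(cache[[key]])) cache[[key]] <- occupied_at(record, t)
    cache[[key]]
  }
  query <- function(s, t, y, x) {
    if (s > t) return(FALSE)
    occ <- occ_at(s)
    if (!nrow(occ) || !(.site_key(as.integer(y)) %in% .site_keys(occ)))
      return(FALSE)
    .contact_reach(record, s, y, t, x)
  }
  skel <- sort(unique(c(0, record$arrows[, 1], record$recoveries[, 1],
                        record$t_max)))
  .new_ancestral_system("contact", "continuous", record$d, record$t_max,
                        occ_at, query, skel, FALSE,
                        list(record = record, trajectory = trajectory))
}

# forward reachable set of (m, y) at generation n over the stored bonds
.op_reach_set <- function(real, m, y, n) {
  d <- real$d
  A <- matrix(as.integer(y), 1, d)
  if (m == n) return(A)
  for (g in seq.int(m + 1L, n)) {
    B <- real$bonds[[g]]
    if (is.null(B) || nrow(B) == 0L) return(matrix(integer(0), 0, d))
    keep <- .site_keys(B[, seq_len(d), drop = FALSE]) %in% .site_keys(A)
    tgt <- B[keep, d + seq_len(d), drop = FALSE]
    if (nrow(tgt) == 0L) return(matrix(integer(0), 0, d))
    A <- tgt[!duplicated(.site_keys(tgt)), , drop = FALSE]
  }
  A
}

#' Ancestral system of an oriented-percolation realization
#'
#' `(m, y)` is an ancestor of `(n, x)` iff `y` lies in the cluster of the
#' origin and an occupied bond path leads from `(m, y)` to `(n, x)`.  Real
#' times are mapped to generations by the floor convention.
#'
#' @param real an `op_realization` from [simulate_op()].
#' @export
op_ancestral_system <- function(real) {
  stopifnot(inherits(real, "op_realization"))
  gens <- real$generations
  occ_at <- function(t) {
    g <- floor(t)
    if (g < 0 || g + 1L > length(gens)) return(matrix(integer(0), 0, real$d))
    gens[[g + 1L]]
  }
  query <- function(s, t, y, x) {
    m <- floor(s); n <- floor(t)
    if (m > n) return(FALSE)
    occ <- occ_at(m)
    if (!nrow(occ) || !(.site_key(as.integer(y)) %in% .site_keys(occ)))
      return(FALSE)
    if (m == n) return(identical(as.integer(y), as.integer(x)))
    R <- .op_reach_set(real, m, as.integer(y), n)
    nrow(R) > 0 && .site_key(as.integer(x)) %in% .site_keys(R)
  }
  .new_ancestral_system("op", "discrete", real$d, real$n_max, occ_at, query,
                        seq.int(0L, real$n_max), FALSE, list(real = real))
}

# site of the generation-m ancestor of particle i of generation n
.brw_ancestor_site <- function(real, n, i, m) {
  g <- n
  while (g > m) {
    i <- real$parents[[g + 1L]][i]
    g <- g - 1L
  }
  real$positions[[m + 1L]][i, ]
}

#' Ancestral system of a branching random walk
#'
#' Branching random walk allows several particles per site, and the
#' ancestral relation lives on *labelled particles*: the site projection of
#' genealogical descent is not transitive in general (two particles at the
#' same site can have different ancestors), so the relational axioms only
#' hold at the particle level.  With `labelled = TRUE` (the default) a
#' "site" of this system is a row `(position..., particle index)` and the
#' relation is genealogical descent of the labelled particle — a tree, so
#' every axiom holds and ancestral paths are unique.  With
#' `labelled = FALSE` the site projection is returned (useful for
#' range/one-arm statistics); its queries answer "some particle at `x` has
#' an ancestor at `y`", which need not be transitive.
#'
#' @param real a `brw_realization` from [simulate_brw()].
#' @param labelled logical; see above.
#' @export
brw_ancestral_system <- function(real, labelled = TRUE) {
  stopifnot(inherits(real, "brw_realization"))
  pos <- real$positions
  d <- real$d
  if (labelled) {
    occ_at <- function(t) {
      g <- floor(t)
      if (g < 0 || g + 1L > length(pos)) return(matrix(integer(0), 0, d + 1L))
      P <- pos[[g + 1L]]
      cbind(P, seq_len(nrow(P)))
    }
    query <- function(s, t, y, x) {
      m <- floor(s); n <- floor(t)
      if (m > n || n + 1L > length(pos)) return(FALSE)
      P <- pos[[n + 1L]]
      id <- as.integer(x[d + 1L])
      if (id < 1L || id > nrow(P) ||
          !identical(as.integer(P[id, ]), as.integer(x[seq_len(d)])))
        return(FALSE)
      aid <- id
      g <- n
      while (g > m) {
        aid <- real$parents[[g + 1L]][aid]
        g <- g - 1L
      }
      identical(as.integer(y[d + 1L]), aid) &&
        identical(as.integer(pos[[m + 1L]][aid, ]),
                  as.integer(y[seq_len(d)]))
    }
    return(.new_ancestral_system("brw", "discrete", d, real$n_max, occ_at,
                                 query, seq.int(0L, real$n_max), TRUE,
                                 list(real = real),
                                 root = c(rep(0L, d), 1L),
                                 coord_cols = seq_len(d)))
  }
  occ_at <- function(t) {
    g <- floor(t)
    if (g < 0 || g + 1L > length(pos)) return(matrix(integer(0), 0, d))
    P <- pos[[g + 1L]]
    P[!duplicated(.site_keys(P)), , drop = FALSE]
  }
  query <- function(s, t, y, x) {
    m <- floor(s); n <- floor(t)
    if (m > n || n + 1L > length(pos)) return(FALSE)
    P <- pos[[n + 1L]]
    if (nrow(P) == 0L) return(FALSE)
    at_x <- which(.site_keys(P) == .site_key(as.integer(x)))
    for (i in at_x) {
      anc <- .brw_ancestor_site(real, n, i, m)
      if (identical(as.integer(anc), as.integer(y))) return(TRUE)
    }
    FALSE
  }
  .new_ancestral_system("brw", "discrete", d, real$n_max, occ_at, query,
                        seq.int(0L, real$n_max), FALSE, list(real = real))
}

#' Check the ancestral-relation axioms on a realized system
#'
#' Exhaustively checks reflexivity (`e_{s,s}(y,x) = 1` iff `x = y` occupied),
#' occupied endpoints, and the root property on the time grid; checks
#' transitivity and interpolation on sampled ordered time triples with all
#' occupied-site combinations (capped per triple).  Violations are returned
#' as witnesses, never raised as errors.
#'
#' @param sys an `ancestral_system`.
#' @param time_grid times to check on; defaults to (a thinning of) the jump
#'   skeleton.
#' @param n_triples number of sampled time triples for the two relational
#'   axioms.
#' @param max_sites cap on occupied sites considered per time point.
#' @param seed optional seed for the triple sampling.
#' @return a report list: per-axiom `pass`, `n_checked` and `witnesses`,
#'   plus an overall `ok` flag; serializable with [jsonlite::toJSON()].
#' @export
check_ar_axioms <- function(sys, time_grid = NULL, n_triples = 50,
                            max_sites = 25, seed = NULL) {
  stopifnot(inherits(sys, "ancestral_system"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(time_grid)) {
    time_grid <- sys$skeleton
    if (length(time_grid) > 12)
      time_grid <- sort(unique(c(0, sample(time_grid, 10), max(time_grid))))
  }
  time_grid <- sort(unique(time_grid))
  d <- sys$d
  origin <- sys$root
  rep0 <- function() list(pass = TRUE, n_checked = 0L, witnesses = list())
  rep_list <- list(reflexivity = rep0(), endpoints = rep0(), root = rep0(),
                   transitivity = rep0(), interpolation = rep0())
  note <- function(which, witness) {
    rep_list[[which]]$pass <<- FALSE
    if (length(rep_list[[which]]$witnesses) < 5)
      rep_list[[which]]$witnesses <<-
        c(rep_list[[which]]$witnesses, list(witness))
  }
  tick <- function(which, k = 1L)
    rep_list[[which]]$n_checked <<- rep_list[[which]]$n_checked + k
  occ_cap <- function(t) {
    m <- sys$occupied(t)
    if (nrow(m) > max_sites) m[seq_len(max_sites), , drop = FALSE] else m
  }

  for (s in time_grid) {
    occ <- occ_cap(s)
    if (nrow(occ) == 0) next
    outsider <- occ[1, ]
    outsider[1] <- max(occ[, 1]) + 1000
    for (i in seq_len(nrow(occ))) {
      x <- occ[i, ]
      if (!sys$query(s, s, x, x)) note("reflexivity", list(s = s, x = x, kind = "missing self-relation"))
      j <- if (i < nrow(occ)) i + 1L else if (i > 1) 1L else NA
      if (!is.na(j) && sys$query(s, s, occ[j, ], x))
        note("reflexivity", list(s = s, x = x, y = occ[j, ], kind = "distinct sites self-related"))
      tick("reflexivity")
      # root property
      if (!sys$query(0, s, origin, x))
        note("root", list(t = s, x = x, kind = "occupied point not descending from origin"))
      tick("root")
    }
    if (sys$query(s, s, outsider, outsider))
      note("reflexivity", list(s = s, x = outsider, kind = "unoccupied site self-related"))
  }

  grid_pairs_checked <- 0L
  for (k in seq_len(n_triples)) {
    st <- sort(sample(time_grid, 3, replace = TRUE))
    o1 <- occ_cap(st[1]); o2 <- occ_cap(st[2]); o3 <- occ_cap(st[3])
    if (!nrow(o1) || !nrow(o2) || !nrow(o3)) next
    y1 <- o1[sample.int(nrow(o1), 1), ]
    y3 <- o3[sample.int(nrow(o3), 1), ]
    # transitivity over all middle candidates
    for (j in seq_len(nrow(o2))) {
      y2 <- o2[j, ]
      if (sys$query(st[1], st[2], y1, y2) && sys$query(st[2], st[3], y2, y3)) {
        tick("transitivity")
        if (!sys$query(st[1], st[3], y1, y3))
          note("transitivity", list(times = st, y1 = y1, y2 = y2, y3 = y3))
        # endpoint occupancy for a known related pair
        tick("endpoints")
        if (!(.site_key(round(y1)) %in% .site_keys(o1)))
          note("endpoints", list(s = st[1], y = y1))
      }
    }
    # interpolation: related endpoints must admit an intermediate ancestor
    if (sys$query(st[1], st[3], y1, y3)) {
      tick("interpolation")
      o2full <- sys$occupied(st[2])
      found <- FALSE
      for (j in seq_len(nrow(o2full))) {
        y2 <- o2full[j, ]
        if (sys$query(st[1], st[2], y1, y2) &&
            sys$query(st[2], st[3], y2, y3)) { found <- TRUE; break }
      }
      if (!found) note("interpolation", list(times = st, y1 = y1, y3 = y3))
    }
    grid_pairs_checked <- grid_pairs_checked + 1L
  }
  rep_list$ok <- all(vapply(rep_list[names(rep_list) != "ok"],
                            function(r) isTRUE(r$pass), TRUE))
  rep_list
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract an ancestral path to an occupied space-time point
#'
#' Returns a cadlag step path `w` with `w_t = x`, every sampled pair of
#' points on it ancestrally related, and `w_0 = o`.  For systems with unique
#' paths (voter, branching random walk) this is the path; otherwise one
#' valid path is chosen deterministically, taking the lexicographically
#' smallest intermediate site at every step of the interpolation.
#'
#' @param sys an `ancestral_system`.
#' @param t terminal time.
#' @param x terminal site, occupied at `t`.
#' @return an `ancestral_path`: breakpoint `times` (increasing, starting at
#'   0) and `sites` (one row per breakpoint); `w_s` is the site of the last
#'   breakpoint at or before `s`, and `w_s = x` for `s >= t`.
#' @export
extract_ancestral_path <- function(sys, t, x) {
  stopifnot(inherits(sys, "ancestral_system"))
  x <- if (sys$scale == 1) as.integer(x) else as.numeric(x)
  occ <- sys$occupied(t)
  if (!nrow(occ) || !(.site_key(x) %in% .site_keys(occ)))
    stop("(t, x) is not an occupied space-time point")
  times <- sys$skeleton[sys$skeleton < t]
  times <- sort(unique(c(0, times)))
  sites <- matrix(sys$root, 1)        # w_0 = the root (root property)
  prev_t <- 0
  prev_y <- sys$root
  if (length(times) > 1) for (s in times[-1]) {
    occ_s <- sys$occupied(s)
    cand <- NULL
    for (j in do.call(order, as.data.frame(occ_s))) {
      y <- occ_s[j, ]
      if (sys$query(prev_t, s, prev_y, y) && sys$query(s, t, y, x)) {
        cand <- y
        break
      }
    }
    if (is.null(cand))
      stop("interpolation failed while extracting the path (axiom violation?)")
    sites <- rbind(sites, cand)
    prev_t <- s
    prev_y <- cand
  }
  sites <- rbind(sites, x)
  dimnames(sites) <- NULL
  structure(list(times = c(times, t), sites = sites, terminal_t = t,
                 terminal_x = x, d = sys$d),
            class = "ancestral_path")
}

#' Position of an ancestral path at time `s`
#' @param path an `ancestral_path`.
#' @param s time.
#' @export
path_position <- function(path, s) {
  if (s >= path$terminal_t) return(path$terminal_x)
  k <- max(which(path$times <= s))
  path$sites[k, ]
}

#' @export
print.ancestral_path <- function(x, ...) {
  cat(sprintf("ancestral path to (t = %.4g, x = (%s)): %d breakpoints\n",
              x$terminal_t, paste(x$terminal_x, collapse = ","),
              length(x$times)))
  invisible(x)
}

#' Rescale an ancestral system (diffusive scaling)
#'
#' Pure reindexing, no resampling: the rescaled occupied set at time `t` is
#' `T_{nt} / sqrt(n)` and `(s, y)` relates to `(t, x)` in the rescaled
#' system iff `(ns, sqrt(n) y)` relates to `(nt, sqrt(n) x)` in the base
#' system.  Rescaling a rescaled system multiplies the scales.
#'
#' @param sys an `ancestral_system`.
#' @param n scale, real `>= 1`.
#' @export
rescale_system <- function(sys, n) {
  stopifnot(inherits(sys, "ancestral_system"), n >= 1)
  if (sys$scale != 1) return(rescale_system(sys$backend$base, sys$scale * n))
  if (n == 1) return(sys)
  base <- sys
  rt <- sqrt(n)
  cc <- base$coord_cols
  to_lattice <- function(y) {
    z <- y
    z[cc] <- y[cc] * rt
    zi <- round(z)
    if (max(abs(z - zi)) > 1e-8) NULL else as.integer(zi)
  }
  occ <- function(t) {
    m <- base$occupied(n * t)
    m[, cc] <- m[, cc] / rt
    m
  }
  query <- function(s, t, y, x) {
    yi <- to_lattice(y); xi <- to_lattice(x)
    if (is.null(yi) || is.null(xi)) return(FALSE)
    base$query(n * s, n * t, yi, xi)
  }
  out <- .new_ancestral_system(base$model, base$time_kind, base$d,
                               base$horizon / n, occ, query,
                               base$skeleton / n, base$unique_paths,
                               list(base = base), root = {
                                 r <- base$root
                                 r[cc] <- r[cc] / rt
                                 r
                               }, coord_cols = cc)
  out$scale <- n
  out
}

#' Intermediate ancestors along a chain of times
#'
#' Given related endpoints `(s_0, y_0)` and `(s_M, y_M)` and intermediate
#' times, returns intermediate sites `y_1, ..., y_{M-1}` with every
#' consecutive pair ancestrally related (lexicographic tie-break).
#'
#' @param sys an `ancestral_system`.
#' @param times increasing vector `s_0 < ... < s_M`.
#' @param y0 site at `times[1]`.
#' @param yM site at `times[length(times)]`.
#' @return matrix of intermediate sites (zero rows when `M = 1`).
#' @export
interpolation_chain <- function(sys, times, y0, yM) {
  stopifnot(length(times) >= 2, !is.unsorted(times, strictly = TRUE))
  if (!sys$query(times[1], times[length(times)], y0, yM))
    stop("endpoints are not ancestrally related")
  M <- length(times) - 1L
  out <- matrix(numeric(0), 0, sys$d)
  prev <- y0
  tM <- times[length(times)]
  if (M >= 2) for (i in 2:M) {
    occ <- sys$occupied(times[i])
    chosen <- NULL
    for (j in do.call(order, as.data.frame(occ))) {
      y <- occ[j, ]
      if (sys$query(times[i - 1L], times[i], prev, y) &&
          sys$query(times[i], tM, y, yM)) { chosen <- y; break }
    }
    if (is.null(chosen))
      stop("interpolation failed: no intermediate ancestor found")
    out <- rbind(out, chosen)
    prev <- chosen
  }
  dimnames(out) <- NULL
  out
}
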