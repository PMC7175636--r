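#' Experiment configurations
#'
#' A config names one experiment, the model it runs on, its parameter
#' grids, replicate count and master seed.  `validate_experiment_config()`
#' checks the schema and errors naming the offending field; every run
#' embeds the fully resolved config in its output metadata.
#'
#' @param experiment one of `"survival"`, `"one_arm"`, `"modulus"`,
#'   `"yaglom"`, `"gw_survival"`, `"laplace"`, `"spatial_moment"`,
#'   `"ar_axioms"`, `"vd0"`, `"escape"`, `"mean_mass"`.
#' @param model list describing the model: `model` (name), `d`, `L`, and
#'   `lambda` / `p` / `offspring` (list with `values`, `probs`) as needed;
#'   ignored by the purely numerical experiments.
#' @param params named list of experiment parameters (grids such as `t`,
#'   `r`, `n`, `rho`, `lambda`, `p` — see the per-experiment functions).
#' @param reps replicate count.
#' @param seed master seed (integer).
#' @param caps optional [sim_caps()] override.
#' @export
experiment_config <- function(experiment, model = NULL, params = list(),
                              reps = 1000, seed = 1, caps = sim_caps()) {
  cfg <- structure(list(experiment = experiment, model = model,
                        params = params, reps = reps, seed = seed,
                        caps = caps),
                   class = "experiment_config")
  validate_experiment_config(cfg)
  cfg
}

.experiment_names <- c("survival", "one_arm", "modulus", "yaglom",
                       "gw_survival", "laplace", "spatial_moment",
                       "ar_axioms", "vd0", "escape", "mean_mass")

#' @rdname experiment_config
#' @param cfg an `experiment_config` (or plain list, e.g. parsed from YAML).
#' @export
validate_experiment_config <- function(cfg) {
  if (is.null(cfg$experiment) || !cfg$experiment %in% .experiment_names)
    stop("field 'experiment' must be one of: ",
         paste(.experiment_names, collapse = ", "))
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("field 'seed' must be a finite integer")
  if (is.null(cfg$reps) || cfg$reps < 1)
    stop("field 'reps' must be a positive integer")
  needs_model <- cfg$experiment %in% c("survival", "one_arm", "modulus",
                                       "spatial_moment", "ar_axioms",
                                       "mean_mass")
  if (needs_model) {
    if (is.null(cfg$model) || is.null(cfg$model$model))
      stop("field 'model$model' is required for experiment '",
           cfg$experiment, "'")
    if (is.null(cfg$model$d) || is.null(cfg$model$L))
      stop("fields 'model$d' and 'model$L' are required")
  }
  invisible(cfg)
}

#' Read an experiment config from YAML or JSON
#' @param path file path (extension decides the parser).
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- structure(raw, class = "experiment_config")
  if (is.null(cfg$params)) cfg$params <- list()
  if (is.null(cfg$reps)) cfg$reps <- 1000
  if (is.null(cfg$caps)) cfg$caps <- sim_caps()
  validate_experiment_config(cfg)
  cfg
}

.cfg_spec <- function(cfg) {
  m <- cfg$model
  kernel <- uniform_box_kernel(m$d, m$L)
  offspring <- if (!is.null(m$offspring))
    offspring_law(m$offspring$values, m$offspring$probs)
  model_spec(m$model, kernel, lambda = m$lambda, p = m$p,
             offspring = offspring)
}

# reproducible per-grid-point seed derivation from the master seed
.derive_seed <- function(master, name, i) {
  h <- sum(utf8ToInt(name)) %% 1009L
  as.integer((as.numeric(master) * 31 + h * 131 + i * 7) %% 2147483629)
}

#' Run a configured experiment
#'
#' Deterministic given the config's seed: grid point `i` of experiment
#' `name` runs with the derived seed `(master, name, i)` so that any single
#' grid point can be reproduced in isolation.  Returns a tidy data frame
#' (one row per grid point, with estimate, standard error and censoring
#' bracket) plus run metadata; when `out` is given, writes `<out>.csv` and
#' `<out>.json`.
#'
#' @param cfg an [experiment_config()].
#' @param out optional output path prefix.
#' @return list with `rows` (data frame) and `meta`.
#' @export
run_experiment <- function(cfg, out = NULL) {
  validate_experiment_config(cfg)
  t_start <- Sys.time()
  ex <- cfg$experiment
  ds <- function(i) .derive_seed(cfg$seed, ex, i)
  rows <- switch(ex,
    survival = {
      grid <- cfg$params$t
      do.call(rbind, lapply(seq_along(grid), function(i) {
        est <- estimate_survival_prob(.cfg_spec(cfg), grid[i], cfg$reps,
                                      seed = ds(i), caps = cfg$caps)
        data.frame(t = grid[i], estimate = est$value, se = est$se,
                   censored_lo = est$lower, censored_hi = est$upper,
                   censored_frac = est$censored_frac)
      }))
    },
    mean_mass = {
      grid <- cfg$params$t
      do.call(rbind, lapply(seq_along(grid), function(i) {
        est <- estimate_mean_mass(.cfg_spec(cfg), grid[i], cfg$reps,
                                  seed = ds(i), caps = cfg$caps)
        data.frame(t = grid[i], estimate = est$value, se = est$se,
                   censored_frac = est$censored_frac)
      }))
    },
    one_arm = {
      grid <- cfg$params$r
      do.call(rbind, lapply(seq_along(grid), function(i) {
        est <- one_arm(.cfg_spec(cfg), grid[i], cfg$reps, seed = ds(i),
                       caps = cfg$caps)
        data.frame(r = grid[i], estimate = est$value, se = est$se,
                   censored_lo = est$lower, censored_hi = est$upper,
                   censored_frac = est$censored_frac,
                   r2_eta = grid[i]^2 * est$value)
      }))
    },
    spatial_moment = {
      grid <- cfg$params$t
      p <- cfg$params$p %||% 2
      do.call(rbind, lapply(seq_along(grid), function(i) {
        est <- spatial_moment(.cfg_spec(cfg), grid[i], p, cfg$reps,
                              seed = ds(i), caps = cfg$caps)
        data.frame(t = grid[i], p = p, estimate = est$value, se = est$se,
                   normalized = est$extra$normalized,
                   censored_frac = est$censored_frac)
      }))
    },
    gw_survival = {
      law <- offspring_law(cfg$params$offspring$values,
                           cfg$params$offspring$probs)
      n <- cfg$params$n %||% 100
      est <- gw_survival_experiment(law, n, cfg$reps, seed = ds(1))
      data.frame(n = n, estimate = est$value, se = est$se,
                 exact_recursion = n * est$extra$exact)
    },
    yaglom = {
      law <- offspring_law(cfg$params$offspring$values,
                           cfg$params$offspring$probs)
      n <- cfg$params$n %||% 100
      est <- gw_yaglom_experiment(law, n,
                                  min_survivors = cfg$params$min_survivors %||% 1e4,
                                  seed = ds(1))
      data.frame(n = n, rate = est$value, se = est$se,
                 n_survivors = est$extra$n_survivors,
                 limit_rate = 2 / law$variance)
    },
    laplace = {
      law <- offspring_law(cfg$params$offspring$values,
                           cfg$params$offspring$probs)
      n <- cfg$params$n %||% 100
      grid <- cfg$params$lambda %||% 1
      pars <- sbm_params(gamma = law$variance, sigma0sq = 1, d = 1)
      do.call(rbind, lapply(seq_along(grid), function(i) {
        est <- gw_laplace_experiment(law, grid[i], n, cfg$reps, seed = ds(i))
        data.frame(lambda = grid[i], n = n, estimate = est$value,
                   se = est$se,
                   closed_form = laplace_integrated_mass(pars, grid[i]))
      }))
    },
    modulus = {
      res <- modulus_tail_experiment(
        .cfg_spec(cfg), cfg$params$n, cfg$params$rho,
        cfg = do.call(modulus_config, cfg$params$cfg %||% list()),
        C = cfg$params$C %||% 1, reps = cfg$reps, seed = ds(1),
        caps = cfg$caps)
      res$table
    },
    ar_axioms = {
      spec <- .cfg_spec(cfg)
      n_real <- cfg$params$n_realizations %||% 20
      ok <- 0L
      for (i in seq_len(n_real)) {
        set.seed(ds(i))
        sys <- switch(spec$model,
          voter = {
            sim <- simulate_voter(spec$kernel, cfg$params$t_max %||% 3,
                                  caps = cfg$caps)
            voter_ancestral_system(sim$record, sim$trajectory)
          },
          contact = {
            sim <- simulate_contact(spec$kernel, spec$lambda,
                                    cfg$params$t_max %||% 3, caps = cfg$caps)
            contact_ancestral_system(sim$record, sim$trajectory)
          },
          op = op_ancestral_system(
            simulate_op(spec$kernel, spec$p, cfg$params$n_max %||% 6,
                        caps = cfg$caps)),
          brw = brw_ancestral_system(
            simulate_brw(spec$offspring, spec$kernel,
                         cfg$params$n_max %||% 6, caps = cfg$caps)))
        rep_i <- check_ar_axioms(sys, n_triples = cfg$params$n_triples %||% 30)
        ok <- ok + rep_i$ok
      }
      data.frame(realizations = n_real, all_axioms_passed = ok,
                 fraction_passed = ok / n_real)
    },
    vd0 = {
      dgrid <- cfg$params$d %||% c(1, 2, 3)
      do.call(rbind, lapply(dgrid, function(dd) {
        sol <- solve_vd0(dd, tol = cfg$params$tol %||% 1e-6)
        data.frame(d = dd, vd0 = sol$vd0, err = sol$vd0_err,
                   blowup_radius = sol$blowup_radius)
      }))
    },
    escape = {
      m <- cfg$model
      kernel <- uniform_box_kernel(m$d, m$L)
      four <- escape_probability(kernel, "fourier")
      mcp <- escape_probability(kernel, "monte_carlo", seed = ds(1),
                                walkers = cfg$reps)
      data.frame(d = m$d, L = m$L, fourier = four, monte_carlo = mcp$value,
                 mc_se = mcp$se, mc_tail_bound = mcp$extra$tail_bound)
    })
  meta <- list(config = unclass(cfg), package_version =
                 as.character(utils::packageVersion("sbmlattice")),
               wall_time_sec = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs")))
  if (!is.null(out)) {
    utils::write.csv(rows, paste0(out, ".csv"), row.names = FALSE)
    jsonlite::write_json(meta, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  list(rows = rows, meta = meta)
}

# hand-build an oriented-percolation realization from a bond list
.op_from_bonds <- function(bond_list, d, kernel = NULL) {
  if (is.null(kernel)) kernel <- uniform_box_kernel(d, 1)
  n_max <- length(bond_list)
  gens <- vector("list", n_max + 1L)
  gens[[1L]] <- matrix(0L, 1, d)
  bonds <- vector("list", n_max)
  for (g in seq_len(n_max)) {
    B <- bond_list[[g]]
    B <- matrix(as.integer(B), ncol = 2 * d)
    keep <- .site_keys(B[, seq_len(d), drop = FALSE]) %in%
      .site_keys(gens[[g]])
    if (!all(keep)) stop("bond out of a non-occupied site in fixture")
    bonds[[g]] <- B
    tgt <- B[, d + seq_len(d), drop = FALSE]
    gens[[g + 1L]] <- tgt[!duplicated(.site_keys(tgt)), , drop = FALSE]
  }
  structure(list(model = "op", kernel = kernel, d = d, p = NA_real_,
                 n_max = n_max, generations = gens, bonds = bonds,
                 censored = FALSE),
            class = "op_realization")
}

#' Hand-traceable fixtures used across the unit tests
#'
#' * `"voter_single_arrow"`: d = 1, horizon 1, one arrow at time 0.3 from
#'   the origin to +1 (the +1 site adopts the origin's opinion, so
#'   `T_1 = {0, +1}`).
#' * `"voter_two_arrow"`: arrows at 0.3 (into the origin from +1) and 0.7
#'   (into +1 from +2); the dual of `(1, 0)` jumps to +1 at backward time
#'   0.7 and stays there.
#' * `"cp_recovery_arrow"`: contact record with an infection arrow at 0.4
#'   (origin infects +1) and a recovery at 0.9 at the origin, so
#'   `T_0.5 = {0, +1}` and `T_1 = {+1}`.
#' * `"op_three_gen"`: three-generation bond fixture with two distinct
#'   occupied paths from the origin to `(3, 1)`.
#'
#' @param name fixture name.
#' @param path optional file path: the fixture is also written as JSON.
#' @return a `graphical_record` or `op_realization`.
#' @export
make_fixture <- function(name, path = NULL) {
  fx <- switch(name,
    voter_single_arrow = graphical_record(
      "voter", d = 1, t_max = 1,
      arrows = matrix(c(0.3, 1, 0), 1, 3)),
    voter_two_arrow = graphical_record(
      "voter", d = 1, t_max = 1,
      arrows = rbind(c(0.3, 0, 1), c(0.7, 1, 2))),
    cp_recovery_arrow = graphical_record(
      "contact", d = 1, t_max = 1,
      arrows = matrix(c(0.4, 1, 0), 1, 3),
      recoveries = matrix(c(0.9, 0), 1, 2)),
    op_three_gen = .op_from_bonds(list(
      rbind(c(0, -1), c(0, 1)),
      rbind(c(-1, 0), c(1, 0), c(1, 2)),
      rbind(c(0, 1), c(2, 1))), d = 1),
    stop("unknown fixture name: ", name))
  if (!is.null(path)) {
    rows_of <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    obj <- if (inherits(fx, "graphical_record"))
      list(model = fx$model, t_max = fx$t_max,
           arrows = rows_of(fx$arrows),
           recoveries = rows_of(fx$recoveries))
    else list(model = "op", d = fx$d,
              bonds = lapply(seq_along(fx$bonds), function(g)
                unname(cbind(g, fx$bonds[[g]]))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  fx
}

#' Run the built-in verification suites
#'
#' `"quick"`: the exact Hausdorff convention, the voter mass martingale at
#' reduced replicates, ancestral-axiom checks on a few realizations of every
#' model, the blow-up solver's scaling/residual identities and the closed
#' forms.  `"full"` adds the full-scale Galton-Watson survival and Yaglom
#' experiments, the Laplace-transform comparison and the scaled-down
#' one-arm bracket table.
#'
#' @param level `"quick"` or `"full"`.
#' @param seed master seed.
#' @return summary list, one entry per check with `pass` and the numbers.
#' @export
verify_all <- function(level = c("quick", "full"), seed = 1) {
  level <- match.arg(level)
  out <- list()
  K2 <- uniform_box_kernel(2, 1)

  out$hausdorff_empty <- list(value = hausdorff(NULL, matrix(0, 1, 2)),
                              pass = hausdorff(NULL, matrix(0, 1, 2)) == 1)

  reps <- if (level == "quick") 5000 else 20000
  mm <- estimate_mean_mass(model_spec("voter", K2), 5, reps,
                           seed = .derive_seed(seed, "mass", 1))
  out$voter_mass_martingale <- list(value = mm$value, se = mm$se,
                                    pass = abs(mm$value - 1) < 3 * mm$se)

  sol <- solve_vd0(2, tol = 1e-6)
  sol_b <- solve_vd0(2, tol = 1e-6, a = 2)
  out$vd0_scaling <- list(vd0 = sol$vd0, alt = sol_b$vd0,
                          pass = abs(sol$vd0 - sol_b$vd0) <
                            2e-6 + sol$vd0_err + sol_b$vd0_err)

  pars <- sbm_params(gamma = 1)
  out$closed_forms <- list(
    canonical = canonical_survival(pars, 1),
    laplace0 = laplace_integrated_mass(pars, 0),
    pass = canonical_survival(pars, 1) == 2 &&
      laplace_integrated_mass(pars, 0) == 1)

  n_ax <- if (level == "quick") 5 else 25
  ax_pass <- TRUE
  for (i in seq_len(n_ax)) {
    set.seed(.derive_seed(seed, "axioms", i))
    sim <- simulate_voter(uniform_box_kernel(1, 1), 2)
    sys <- voter_ancestral_system(sim$record, sim$trajectory)
    ax_pass <- ax_pass && check_ar_axioms(sys, n_triples = 15)$ok
  }
  out$ar_axioms_voter <- list(realizations = n_ax, pass = ax_pass)

  if (level == "full") {
    law <- offspring_binary()
    gs <- gw_survival_experiment(law, 100, 5e5,
                                 seed = .derive_seed(seed, "gw", 1))
    out$gw_survival <- list(value = gs$value, se = gs$se,
                            exact = 100 * gs$extra$exact,
                            pass = abs(gs$value - 2) < 3 * gs$se + 0.08)
    yg <- gw_yaglom_experiment(law, 100, min_survivors = 1e4,
                               seed = .derive_seed(seed, "yaglom", 1))
    out$yaglom <- list(rate = yg$value, pass = abs(yg$value - 2) < 0.1)
    lp <- gw_laplace_experiment(law, 1, 100, 2e5,
                                seed = .derive_seed(seed, "laplace", 1))
    cf <- laplace_integrated_mass(sbm_params(gamma = 1), 1)
    out$laplace <- list(estimate = lp$value, closed_form = cf,
                        pass = abs(lp$value - cf) < 3 * lp$se + 0.1 * cf)
    K3 <- uniform_box_kernel(3, 1)
    cst <- limit_constants(K3, "voter")
    pred <- predicted_one_arm_constant(cst)
    rows <- NULL
    for (i in seq_along(c(10, 15, 20))) {
      r <- c(10, 15, 20)[i]
      oa <- one_arm(model_spec("voter", K3), r, 30000,
                    seed = .derive_seed(seed, "onearm", i))
      rows <- rbind(rows, data.frame(r = r, eta = oa$value, se = oa$se,
                                     r2_eta = r^2 * oa$value,
                                     predicted = pred))
    }
    out$one_arm_bracket <- list(table = rows,
                                pass = all(abs(rows$r2_eta - pred) <
                                             0.25 * pred + 3 * rows$r^2 * rows$se))
  }
  out$all_pass <- all(vapply(out[names(out) != "all_pass"], function(x)
    isTRUE(x$pass) || is.null(x$pass), TRUE))
  out
}
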