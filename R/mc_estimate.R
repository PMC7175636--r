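#' Monte-Carlo estimate with standard error and censoring bracket
#'
#' Every simulation-based estimator in the package returns one of these.
#' When some replicates were censored (resource caps hit before the outcome
#' resolved), `lower` and `upper` bracket the estimand by resolving the
#' censored replicates both ways; silent truncation would bias exactly the
#' heavy-tailed quantities the scaling theory is about.
#'
#' @param value point estimate.
#' @param se Monte-Carlo standard error.
#' @param reps number of replicates.
#' @param censored_frac fraction of censored replicates, in `[0, 1]`.
#' @param lower,upper censoring bracket (default the point value).
#' @param extra optional named list of auxiliary results.
#' @export
mc_estimate <- function(value, se, reps, censored_frac = 0,
                        lower = value, upper = value, extra = list()) {
  stopifnot(se >= 0, censored_frac >= 0, censored_frac <= 1)
  structure(list(value = value, se = se, reps = reps,
                 censored_frac = censored_frac,
                 lower = lower, upper = upper, extra = extra),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo estimate: %.6g (se %.3g, %d replicates", x$value,
              x$se, x$reps))
  if (x$censored_frac > 0)
    cat(sprintf(", %.2f%% censored, bracket [%.6g, %.6g]",
                100 * x$censored_frac, x$lower, x$upper))
  cat(")\n")
  invisible(x)
}
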