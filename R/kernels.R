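#' Finite-range symmetric step kernels on the integer lattice
#'
#' A `step_kernel` stores an explicit table of integer offsets `x` (rows of a
#' matrix, sup-norm at most `L`) together with probabilities `D(x)`.  The
#' kernel drives every model in the package: voter-model resampling, contact
#' infection attempts, oriented-percolation bonds and branching-random-walk
#' displacements.  Validity requires `D` to be a probability distribution with
#' `D(o) = 0`, symmetric under `x -> -x`, and with an isotropic coordinate
#' covariance matrix `sigma2_D * I` (checked to 1e-12); the common
#' per-coordinate variance `sigma2_D` is precomputed and stored.
#'
#' Norm conventions used throughout: the kernel range `L` bounds offsets in
#' the sup-norm, whereas all radii (range radius, one-arm radius) use the
#' Euclidean norm.
#'
#' @param offsets integer matrix, one offset per row, `d` columns.
#' @param probs numeric vector of probabilities, one per row of `offsets`.
#' @param L optional declared range; defaults to the sup-norm of the support.
#' @return an object of class `step_kernel` with fields `d`, `L`, `offsets`,
#'   `probs`, `sigma2` (per-coordinate variance `sigma2_D`).
#' @export
step_kernel <- function(offsets, probs, L = NULL) {
  offsets <- as.matrix(offsets)
  storage.mode(offsets) <- "integer"
  d <- ncol(offsets)
  if (d < 1L || nrow(offsets) < 1L)
    stop("kernel support must be a non-empty matrix of integer offsets")
  if (length(probs) != nrow(offsets))
    stop("probs must have one entry per offset")
  if (any(probs < 0)) stop("kernel probabilities must be nonnegative")
  sup <- max(abs(offsets))
  if (is.null(L)) L <- sup
  if (sup > L) stop("offset outside the declared sup-norm range L")
  K <- structure(
    list(d = d, L = as.integer(L), offsets = offsets, probs = as.numeric(probs),
         sigma2 = NA_real_),
    class = "step_kernel")
  K$sigma2 <- .kernel_isotropic_variance(K)
  validate_step_kernel(K)
  K
}

# covariance matrix of the kernel; errors if not sigma2 * I within tol
.kernel_isotropic_variance <- function(K, tol = 1e-12) {
  X <- K$offsets
  cov <- crossprod(X * sqrt(K$probs))   # sum_x probs * x x^T
  s2 <- mean(diag(cov))
  if (max(abs(cov - diag(s2, K$d))) > tol * max(1, s2))
    stop("anisotropic kernel: coordinate covariance is not sigma2 * identity")
  s2
}

#' Validate a step kernel against its invariants
#'
#' Checks normalization (to 1e-12), absence of the origin, symmetry
#' `D(-x) = D(x)`, sup-norm range and isotropy of the coordinate covariance.
#' Called by the constructor; exported so user-built kernels can be re-checked.
#'
#' @param K a `step_kernel`.
#' @return `K`, invisibly; errors describe the violated invariant.
#' @export
validate_step_kernel <- function(K) {
  stopifnot(inherits(K, "step_kernel"))
  if (abs(sum(K$probs) - 1) > 1e-12)
    stop("kernel probabilities do not sum to 1")
  if (any(rowSums(K$offsets != 0L) == 0L))
    stop("kernel must put no mass on the origin")
  if (max(abs(K$offsets)) > K$L)
    stop("offset outside the declared sup-norm range L")
  key <- apply(K$offsets, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) stop("duplicate offsets in kernel support")
  neg <- apply(-K$offsets, 1L, paste, collapse = ",")
  m <- match(neg, key)
  if (anyNA(m)) stop("kernel support is not symmetric under x -> -x")
  if (max(abs(K$probs - K$probs[m])) > 1e-12)
    stop("kernel probabilities are not symmetric: D(-x) != D(x)")
  .kernel_isotropic_variance(K)
  invisible(K)
}

#' Uniform kernel on a centred box
#'
#' The spread-out kernel: uniform on the nonzero integer offsets of the box
#' `[-L, L]^d`, each with probability `1 / ((2L+1)^d - 1)`.
#'
#' @param d dimension (positive integer).
#' @param L sup-norm range (positive integer).
#' @return a `step_kernel`.
#' @examples
#' uniform_box_kernel(2, 1)  # the 8 neighbours of the origin, prob 1/8 each
#' @export
uniform_box_kernel <- function(d, L) {
  if (length(d) != 1L || d < 1 || d != round(d)) stop("d must be a positive integer")
  if (length(L) != 1L || L < 1 || L != round(L)) stop("L must be a positive integer")
  g <- do.call(expand.grid, rep(list(seq.int(-L, L)), d))
  g <- as.matrix(g[rowSums(g != 0) > 0, , drop = FALSE])
  dimnames(g) <- NULL
  step_kernel(g, rep(1 / nrow(g), nrow(g)), L = L)
}

#' Per-coordinate variance of a step kernel
#'
#' Returns `sigma2_D = sum_x x_1^2 D(x)`, the common diagonal entry of the
#' (isotropic) coordinate covariance matrix.  The total variance is
#' `sigma2 = d * sigma2_D`.
#'
#' @param K a `step_kernel`.
#' @export
kernel_variance <- function(K) {
  validate_step_kernel(K)
  K$sigma2
}

#' Characteristic function of a step kernel
#'
#' `D_hat(k) = sum_x cos(k . x) D(x)`, real by symmetry, with values in
#' `[-1, 1]`.  Used by the Fourier route to the walk escape probability.
#'
#' @param K a `step_kernel`.
#' @param k numeric vector of length `d` (a frequency), or a matrix with `d`
#'   columns for vectorized evaluation.
#' @return numeric vector of values of `D_hat`.
#' @export
characteristic_function <- function(K, k) {
  if (is.matrix(k)) {
    if (ncol(k) != K$d) stop("k must have d columns")
    return(as.numeric(cos(k %*% t(K$offsets)) %*% K$probs))
  }
  if (length(k) != K$d) stop("k must have length d")
  sum(cos(K$offsets %*% k) * K$probs)
}

#' Draw random steps from a kernel
#'
#' Samples offsets from `D` using R's global random stream, so `set.seed`
#' makes draws reproducible.
#'
#' @param K a `step_kernel`.
#' @param n number of draws.
#' @return an `n` by `d` integer matrix of offsets.
#' @export
sample_step <- function(K, n = 1L) {
  idx <- sample.int(nrow(K$offsets), n, replace = TRUE, prob = K$probs)
  K$offsets[idx, , drop = FALSE]
}

#' Serialize / deserialize a kernel as JSON
#'
#' Format: `{"d": int, "L": int, "entries": [[offset..., prob], ...]}`.
#'
#' @param K a `step_kernel`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
kernel_to_json <- function(K, path = NULL) {
  entries <- cbind(K$offsets, K$probs)
  obj <- list(d = K$d, L = K$L,
              entries = lapply(seq_len(nrow(entries)), function(i) unname(entries[i, ])))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname kernel_to_json
#' @param json a JSON string or file path produced by [kernel_to_json()].
#' @export
kernel_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  entries <- obj$entries
  if (is.list(entries)) entries <- do.call(rbind, entries)
  d <- obj$d
  step_kernel(entries[, seq_len(d), drop = FALSE], entries[, d + 1L], L = obj$L)
}

#' @export
print.step_kernel <- function(x, ...) {
  cat(sprintf("step kernel on Z^%d, range L = %d (sup-norm), %d offsets\n",
              x$d, x$L, nrow(x$offsets)))
  cat(sprintf("  per-coordinate variance sigma2_D = %.6g\n", x$sigma2))
  invisible(x)
}

# internal: cumulative probabilities for the C++ samplers
.kernel_cum <- function(K) cumsum(K$probs)
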