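# shared fixtures and small oracles for the test suite

k11 <- function() uniform_box_kernel(1, 1)
k21 <- function() uniform_box_kernel(2, 1)
k31 <- function() uniform_box_kernel(3, 1)

# mean-1, variance-2 offspring law (0 w.p. 5/8, 2 w.p. 1/4, 4 w.p. 1/8)
law_var2 <- function() offspring_law(c(0L, 2L, 4L), c(5, 2, 1) / 8)

# brute-force per-coordinate variance of a kernel by direct enumeration
enum_variance <- function(K) sum(K$offsets[, 1]^2 * K$probs)

# brute-force oriented-percolation reachability by path enumeration
op_reach_bruteforce <- function(real, m, y, n, x) {
  if (m > n) return(FALSE)
  if (m == n) return(identical(as.integer(y), as.integer(x)))
  B <- real$bonds[[m + 1L]]
  if (is.null(B) || nrow(B) == 0) return(FALSE)
  d <- real$d
  for (i in seq_len(nrow(B))) {
    if (identical(as.integer(B[i, seq_len(d)]), as.integer(y)) &&
        op_reach_bruteforce(real, m + 1L, B[i, d + seq_len(d)], n, x))
      return(TRUE)
  }
  FALSE
}

# positions of a single continuous-time rate-one kernel walk at time t
walk_positions <- function(K, t, reps) {
  n_steps <- stats::rpois(reps, t)
  out <- matrix(0L, reps, K$d)
  for (i in seq_len(reps)) {
    if (n_steps[i] > 0)
      out[i, ] <- colSums(sample_step(K, n_steps[i]))
  }
  out
}
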