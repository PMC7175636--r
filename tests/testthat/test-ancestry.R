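test_that("ancestral-relation axioms hold on realized systems of all four models", {
  set.seed(21)
  n_real <- 8
  make_sys <- list(
    voter = function() {
      sim <- simulate_voter(k11(), 2.5)
      voter_ancestral_system(sim$record, sim$trajectory)
    },
    contact = function() {
      sim <- simulate_contact(k11(), 1.3, 2.5)
      contact_ancestral_system(sim$record, sim$trajectory)
    },
    op = function() op_ancestral_system(simulate_op(k11(), 0.9, 5)),
    brw = function() brw_ancestral_system(
      simulate_brw(offspring_binary(), k11(), 5)))
  for (nm in names(make_sys)) {
    for (i in seq_len(n_real)) {
      rep <- check_ar_axioms(make_sys[[nm]](), n_triples = 20)
      expect_true(rep$ok, info = sprintf("model %s realization %d", nm, i))
    }
  }
})

test_that("a corrupted relation is reported with an interpolation witness", {
  op <- make_fixture("op_three_gen")
  sys <- op_ancestral_system(op)
  base_query <- sys$query
  # drop every relation out of generation 1 into generation 3
  sys$query <- function(s, t, y, x) {
    if (floor(s) == 1 && floor(t) == 3) return(FALSE)
    base_query(s, t, y, x)
  }
  rep <- check_ar_axioms(sys, time_grid = c(0, 1, 3), n_triples = 60,
                         seed = 22)
  expect_false(rep$interpolation$pass)
  expect_gt(length(rep$interpolation$witnesses), 0)
})

test_that("extracted ancestral paths are valid, deterministic, and match the voter dual", {
  set.seed(23)
  for (i in 1:5) {
    sim <- simulate_voter(k11(), 2)
    sys <- voter_ancestral_system(sim$record, sim$trajectory)
    occ <- sys$occupied(2)
    if (!nrow(occ)) next
    x <- occ[1, ]
    p1 <- extract_ancestral_path(sys, 2, x)
    p2 <- extract_ancestral_path(sys, 2, x)
    expect_identical(p1$sites, p2$sites)     # deterministic / idempotent
    pw <- dual_walk(sim$record, 2, x)
    for (s in c(0, 0.4, 1.1, 1.9, 2))
      expect_identical(as.integer(path_position(p1, s)),
                       as.integer(dual_position(pw, 2 - s)))
  }

  # trivial root path
  sim <- simulate_voter(k11(), 0, seed = 24)
  sys <- voter_ancestral_system(sim$record, sim$trajectory)
  p <- extract_ancestral_path(sys, 0, 0L)
  expect_equal(as.integer(path_position(p, 0)), 0L)

  # unoccupied endpoint errors
  expect_error(extract_ancestral_path(sys, 0, 7L), "not an occupied")

  # OP fixture: the path to (3, 1) is one of the enumerated valid paths
  op <- make_fixture("op_three_gen")
  osys <- op_ancestral_system(op)
  path <- extract_ancestral_path(osys, 3, 1L)
  sites <- as.integer(vapply(0:3, function(g) path_position(path, g)[1], 0))
  valid <- list(c(0L, -1L, 0L, 1L), c(0L, 1L, 0L, 1L), c(0L, 1L, 2L, 1L))
  expect_true(any(vapply(valid, identical, TRUE, y = sites)))
  # every consecutive pair along the path is related
  for (g in 0:2)
    expect_true(osys$query(g, g + 1, sites[g + 1], sites[g + 2]))
})

test_that("diffusive rescaling is a pure reindexing and round-trips", {
  op <- make_fixture("op_three_gen")
  sys <- op_ancestral_system(op)
  expect_identical(rescale_system(sys, 1), sys)

  rs <- rescale_system(sys, 4)
  expect_equal(rs$scale, 4)
  # occupied sets: T^{(n)}_t = T_{nt} / sqrt(n)
  expect_equal(rs$occupied(0.5) * 2, sys$occupied(2) + 0)
  # e^{(n)}_{s,t}(y,x) = e_{ns,nt}(sqrt(n) y, sqrt(n) x)
  expect_true(rs$query(0, 3 / 4, 0, 0.5))
  expect_identical(rs$query(1 / 4, 3 / 4, -0.5, 0.5),
                   sys$query(1, 3, -1L, 1L))
  # non-lattice rescaled points are never related
  expect_false(rs$query(0, 3 / 4, 0, 0.3))

  # round trip: rescaling a rescaled system multiplies scales on the base
  rt <- rescale_system(rs, 1)
  expect_identical(rt$query(1 / 4, 3 / 4, -0.5, 0.5),
                   rs$query(1 / 4, 3 / 4, -0.5, 0.5))
})

test_that("interpolation chains produce pairwise-related intermediates", {
  op <- make_fixture("op_three_gen")
  sys <- op_ancestral_system(op)
  # M = 1: empty chain
  expect_equal(nrow(interpolation_chain(sys, c(0, 3), 0L, 1L)), 0L)
  ch <- interpolation_chain(sys, c(0, 1, 2, 3), 0L, 1L)
  expect_equal(nrow(ch), 2L)
  pts <- rbind(0L, ch, 1L)
  for (i in 1:3)
    expect_true(sys$query(i - 1, i, pts[i, ], pts[i + 1, ]))
  expect_error(interpolation_chain(sys, c(0, 3), 5L, 1L), "not ancestrally")

  # voter: the chain equals the dual walk sampled at the given times
  set.seed(25)
  sim <- simulate_voter(k11(), 2)
  vs <- voter_ancestral_system(sim$record, sim$trajectory)
  occ <- vs$occupied(2)
  if (nrow(occ)) {
    x <- occ[1, ]
    times <- c(0, 0.7, 1.4, 2)
    ch <- interpolation_chain(vs, times, 0L, x)
    pw <- dual_walk(sim$record, 2, x)
    for (k in 2:3)
      expect_identical(as.integer(ch[k - 1, ]),
                       as.integer(dual_position(pw, 2 - times[k])))
  }
  succeed()
})
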