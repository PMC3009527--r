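test_that("identical genomes give k_hat = 0 with zero objective", {
  set.seed(61)
  G <- seed_duplications(make_ancestor(60, 0, 1), 3, 4)
  est <- estimate_k(G, G, event_params(0.2, 0.6, 4), k_max = 120, C = 10)
  expect_identical(est$k_hat, 0L)
  expect_identical(est$objective, 0)
  expect_identical(unname(est$per_type), c(0, 0, 0))

  grid_est <- estimate_k_unknown_params(G, G, L_max = 4, k_max = 40,
                                        resolution = 0.2)
  expect_identical(grid_est$k_hat, 0L)
})

test_that("k_hat is invariant under chromosome reordering of F", {
  set.seed(62)
  G <- seed_duplications(make_ancestor(50, 2, 1), 3, 4)
  params <- event_params(0.2, 0.5, 4)
  F1 <- evolve(G, 30, params, log = FALSE)$genome
  e1 <- estimate_k(G, F1, params, k_max = 200)
  F2 <- F1
  o <- rev(seq_along(F2$chrs))
  F2$chrs <- F2$chrs[o]
  F2$circular <- F2$circular[o]
  e2 <- estimate_k(G, F2, params, k_max = 200)
  expect_identical(e1$k_hat, e2$k_hat)
  expect_equal(e1$objective, e2$objective)
})

test_that("simulated distances are recovered near the truth", {
  set.seed(63)
  G <- seed_duplications(make_ancestor(300, 0, 1), 5, 5)
  ref <- genome_ref(G)
  params <- event_params(0.2, 0.6, 5)
  traj <- expected_trajectory(ref, 600, params, 10)
  kh <- numeric(12)
  for (r in seq_along(kh)) {
    F <- evolve(G, 150, params, log = FALSE)$genome
    vF <- quiet_cap(genome_vector(ref, F, 10))
    kh[r] <- truedist:::.estimate_from_trajectory(vF, traj)$k_hat
  }
  # genomes this small (300 genes) sit at the edge of the recursion's
  # O(C^2/N) approximations; the headline fixtures (>= 1000 genes) are
  # checked tightly in the acceptance suite
  expect_lt(abs(mean(kh) - 150), 40)
  expect_lt(sd(kh), 45)
})

test_that("ties break toward the smallest k", {
  # a flat trajectory region: force by comparing against an exact-hit row
  set.seed(64)
  G <- seed_duplications(make_ancestor(40, 0, 1), 2, 3)
  ref <- genome_ref(G)
  traj <- expected_trajectory(ref, 50, event_params(0.2, 0.6, 3), 10)
  v0 <- quiet_cap(genome_vector(ref, G, 10))
  est <- truedist:::.estimate_from_trajectory(v0, traj)
  expect_identical(est$k_hat, 0L)
})

test_that("the constrained parameter grid has the predicted size", {
  for (res in c(0.1, 0.05)) {
    grid <- parameter_grid(res)
    vals <- seq(0, 1, by = res)
    n_manual <- sum(outer(vals, vals,
                          function(pd, pl) pd < 4 * pl & pd + pl <= 1 + 1e-9))
    expect_identical(nrow(grid), n_manual)
    expect_true(all(grid$p_d < 4 * grid$p_l))
    expect_true(all(grid$p_d + grid$p_l <= 1 + 1e-9))
  }
  expect_error(estimate_k_unknown_params(
    toy_genome(), toy_genome(), grid = parameter_grid(0.01)[0, ]), "empty")
})

test_that("grid estimation with a trajectory cache matches the direct call", {
  set.seed(66)
  G <- seed_duplications(make_ancestor(40, 0, 1), 2, 3)
  ref <- genome_ref(G)
  F <- evolve(G, 20, event_params(0.2, 0.5, 3), log = FALSE)$genome
  grid <- parameter_grid(0.2)
  cache <- grid_trajectories(ref, grid, 80, C = 10, L_max = 3)
  direct <- estimate_k_unknown_params(G, F, L_max = 3, k_max = 80,
                                      resolution = 0.2)
  cached <- estimate_k_unknown_params(ref, F, L_max = 3, k_max = 80,
                                      grid = grid, trajectories = cache)
  expect_identical(direct$k_hat, cached$k_hat)
  expect_identical(direct$p_d_hat, cached$p_d_hat)
  expect_identical(direct$p_l_hat, cached$p_l_hat)
})

test_that("decompose_events rounds by largest remainder and sums to k_hat", {
  e <- truedist:::.new_estimate(1000L, 0.2, 0.6, 0, 4000L, 10L)
  expect_identical(decompose_events(e),
                   c(rearrangement = 200L, duplication = 200L, loss = 600L))
  e0 <- truedist:::.new_estimate(0L, 0.2, 0.6, 0, 4000L, 10L)
  expect_identical(sum(decompose_events(e0)), 0L)
  set.seed(67)
  for (i in 1:20) {
    k <- sample.int(500, 1)
    pd <- runif(1, 0, 0.5); pl <- runif(1, 0, 0.5)
    ei <- truedist:::.new_estimate(k, pd, pl, 0, 2000L, 10L)
    parts <- decompose_events(ei)
    expect_identical(sum(parts), k)
    expect_true(all(abs(parts - ei$per_type) < 1))
  }
})
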