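# The one-step operators are checked against brute-force enumeration of
# every possible event on small genomes.  Enumeration is exact, so the
# tolerances below reflect only the operators' documented approximations:
# the neglected O(C^2/N) re-creation of reference adjacencies, the
# assumption that no two duplicates share one segment, and the frozen
# telomeres of the loss step.  Each bound is a small multiple of C^2/N.

test_that("one-step rearrangement expectation matches exhaustive enumeration", {
  fx <- small_pair(seed = 99, n = 12, n_linear = 1, n_circular = 1,
                   seed_dups = 2, L_max = 3, k = 6, p_d = 0.2, p_l = 0.3)
  C <- 6
  vH <- quiet_cap(genome_vector(fx$ref, fx$H, C))
  exact <- enumerate_rearrangements(fx$ref, fx$H, C)
  ana <- vec_coords(expected_after_rearrangement(vH, C))
  # genes exactly unchanged; adjacency/telomere flows within the
  # re-creation bound (~ C^2/N with N = 12)
  expect_identical(ana[1:C], vec_coords(vH)[1:C])
  expect_lt(max(abs(ana - exact)), 0.1)
  expect_lt(sum(abs(ana - exact)), 0.25)
})

test_that("one-step duplication expectation matches exhaustive enumeration", {
  # circular-only fixture: no segment truncation; duplicates spread out
  fx <- small_pair(seed = 5, n = 14, n_linear = 0, n_circular = 1,
                   seed_dups = 2, L_max = 2, k = 5, p_d = 0.3, p_l = 0.3)
  C <- 6
  L_max <- 3
  vH <- quiet_cap(genome_vector(fx$ref, fx$H, C))
  exact <- enumerate_duplications(fx$ref, fx$H, L_max, C)
  ana <- vec_coords(expected_after_duplication(vH, L_max, C))
  expect_lt(max(abs(ana - exact)), 0.3)
  # expected gene gain is the mean segment length
  N_exact <- sum(exact[1:C])
  expect_equal(sum(ana[1:C]), N_exact, tolerance = 0.05)
})

test_that("L_max = 1 duplications add exactly one gene and no internal copies", {
  fx <- small_pair(seed = 5, n = 14, n_linear = 0, n_circular = 1,
                   seed_dups = 2, L_max = 2, k = 0)
  C <- 6
  vH <- quiet_cap(genome_vector(fx$ref, fx$G, C))
  ana <- expected_after_duplication(vH, L_max = 1, C)
  expect_equal(ana$N, vH$N + 1)
  exact <- enumerate_duplications(fx$ref, fx$G, 1L, C)
  expect_lt(max(abs(vec_coords(ana) - exact)), 0.3)
})

test_that("one-step loss expectation matches exhaustive enumeration", {
  for (seed in c(5, 29)) {
    fx <- small_pair(seed = seed, n = 14, n_linear = 0, n_circular = 1,
                     seed_dups = 2, L_max = 2, k = 5)
    C <- 6
    vH <- quiet_cap(genome_vector(fx$ref, fx$H, C))
    exact <- enumerate_losses(fx$ref, fx$H, C)
    aux <- loss_aux(fx$ref, fx$H, L_max = 2)
    ana <- vec_coords(expected_after_loss(vH, aux, C)$vector)
    # gene flows are exact; adjacency flows use the flank bound and the
    # exactly initialised recovery counts
    expect_equal(ana[1:C], exact[1:C], tolerance = 1e-9)
    expect_lt(max(abs(ana - exact)), 0.35)
  }
})

test_that("every-family-duplicated loss moves one family from class 2 to 1", {
  g <- genome(list(c("+a", "+b", "+a", "+b")), circular = TRUE)
  ref <- genome_ref(g)
  v <- genome_vector(ref, g, C = 4)
  out <- expected_after_loss(v, loss_aux(ref, g, L_max = 2), C = 4)
  expect_equal(out$vector$SG[2], v$SG[2] - 2)
  expect_equal(out$vector$SG[1], v$SG[1] + 1)
  expect_equal(out$vector$N, v$N - 1)
})

test_that("the loss step freezes telomeres", {
  fx <- small_pair(seed = 7, n = 16, n_linear = 2, n_circular = 0,
                   seed_dups = 2, L_max = 3, k = 4)
  C <- 6
  vH <- quiet_cap(genome_vector(fx$ref, fx$H, C))
  out <- expected_after_loss(vH, loss_aux(fx$ref, fx$H, 3), C)
  expect_identical(out$vector$ST, vH$ST)
  expect_identical(out$vector$DT, vH$DT)
})

test_that("expected_step reduces to the single operators at degenerate params", {
  fx <- small_pair()
  C <- 6
  vH <- as_expected_vector(quiet_cap(genome_vector(fx$ref, fx$H, C)))
  aux <- loss_aux(fx$ref, fx$H, 4)
  st_r <- expected_step(vH, aux, event_params(0, 0, 4), C)
  expect_equal(vec_coords(st_r$vector),
               vec_coords(expected_after_rearrangement(vH, C)))
  st_d <- expected_step(vH, aux, event_params(1, 0, 4), C)
  expect_equal(vec_coords(st_d$vector),
               vec_coords(expected_after_duplication(vH, 4, C)))
  st_l <- expected_step(vH, aux, event_params(0, 1, 4), C)
  expect_equal(vec_coords(st_l$vector),
               vec_coords(expected_after_loss(vH, aux, C)$vector))
})

test_that("expected_step renormalises when no gene is deletable", {
  g <- make_ancestor(20, 0, 1)
  ref <- genome_ref(g)
  v <- genome_vector(ref, g, C = 5)
  aux <- loss_aux(ref, L_max = 3)
  st <- expected_step(v, aux, event_params(p_d = 0.5, p_l = 0.5, 3), C = 5)
  expect_equal(vec_coords(st$vector),
               vec_coords(expected_after_duplication(v, 3, 5)))
})

test_that("trajectories start at v0, are deterministic, and conserve gene mass", {
  set.seed(55)
  G <- seed_duplications(make_ancestor(100, 0, 1), 5, 5)
  ref <- genome_ref(G)
  v0 <- genome_vector(ref, G, 10)
  tr <- expected_trajectory(ref, 150, event_params(0.2, 0.6, 5), 10)
  expect_equal(tr$coords[1, ], vec_coords(v0))
  tr2 <- expected_trajectory(ref, 150, event_params(0.2, 0.6, 5), 10)
  expect_identical(tr$coords, tr2$coords)

  # pure rearrangement: gene coordinates constant, damage monotone
  trr <- expected_trajectory(ref, 200, event_params(0, 0, 5), 10)
  expect_true(all(abs(sweep(trr$coords[, 1:10], 2, trr$coords[1, 1:10])) < 1e-9))
  expect_true(all(diff(trr$coords[, "DA"]) >= -1e-9))
  expect_true(all(diff(trr$coords[, "SA1"]) <= 1e-9))
})

test_that("trajectory cost grows linearly in k (constant per-step work)", {
  set.seed(57)
  G <- seed_duplications(make_ancestor(150, 0, 1), 5, 5)
  ref <- genome_ref(G)
  params <- event_params(0.2, 0.6, 5)
  t1 <- system.time(expected_trajectory(ref, 1000, params, 10))["elapsed"]
  t4 <- system.time(expected_trajectory(ref, 4000, params, 10))["elapsed"]
  # 4x the steps: linear cost predicts ~4x the time, quadratic ~16x
  expect_lt(t4, 10 * max(t1, 0.05))
})

test_that("extremity mass stays consistent along a mixed trajectory", {
  set.seed(56)
  G <- seed_duplications(make_ancestor(200, 1, 1), 5, 5)
  ref <- genome_ref(G)
  tr <- expected_trajectory(ref, 400, event_params(0.2, 0.6, 5), 10)
  mass <- rowSums(tr$coords[, 11:23])             # SA + DA + ST + DT
  lk <- (tr$coords[, "ST"] + tr$coords[, "DT"]) / 2
  gap <- abs(mass - (tr$N + lk))
  # grows at most like C^2 k / N
  expect_lt(max(gap), 100 * 400 / 200 * 0.5)
  expect_lt(gap[2], 1)
})
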