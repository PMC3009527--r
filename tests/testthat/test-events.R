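# site indexing reminder: for a linear chromosome of n genes the global
# offsets cover positions 0..n (0 and n are telomeres); circular
# chromosomes contribute n adjacency sites.

test_that("rearrangement cases dispatch and transform as derived by hand", {
  # case 1: inversion of the enclosed segment
  g <- genome(list(c("+a", "+b", "+c")))
  r <- apply_rearrangement(g, 2L, 3L)
  expect_identical(r$record$kind, "inversion")
  expect_identical(r$genome$chrs[[1]], c(1L, -2L, 3L))

  # case 1 with a telomere: end-segment inversion
  r2 <- apply_rearrangement(g, 1L, 3L)   # left telomere + adjacency {b,c}
  expect_identical(r2$record$kind, "inversion")
  expect_identical(r2$genome$chrs[[1]], c(-2L, -1L, 3L))

  # case 3: same adjacency twice splits a linear chromosome
  h <- genome(list(c("+a", "+b")))
  r3 <- apply_rearrangement(h, 2L, 2L)
  expect_identical(r3$record$kind, "fission")
  expect_identical(lengths(r3$genome$chrs), c(1L, 1L))

  # case 3 on a circular chromosome linearises it
  cg <- genome(list(c("+a", "+b", "+c")), circular = TRUE)
  r4 <- apply_rearrangement(cg, 1L, 1L)
  expect_identical(r4$record$kind, "linearization")
  expect_false(any(r4$genome$circular))
  expect_identical(r4$genome$chrs[[1]], c(2L, 3L, 1L))

  # case 4: both telomeres of one chromosome circularise it
  r5 <- apply_rearrangement(h, 1L, 3L)
  expect_identical(r5$record$kind, "circularization")
  expect_true(all(r5$genome$circular))
  # selecting one telomere twice is assimilated to both telomeres
  r6 <- apply_rearrangement(h, 1L, 1L)
  expect_identical(r6$record$kind, "circularization")

  # case 4 on two chromosomes: fusion joining the selected ends
  two <- genome(list(c("+a", "+b"), c("+c", "+d")))
  r7 <- apply_rearrangement(two, 3L, 4L)  # right telomere of 1, left of 2
  expect_identical(r7$record$kind, "fusion")
  expect_identical(r7$genome$chrs[[1]], c(1L, 2L, 3L, 4L))
  # joining two left ends reverses one partner
  r8 <- apply_rearrangement(two, 1L, 4L)
  expect_identical(r8$genome$chrs[[1]], c(-2L, -1L, 3L, 4L))

  # case 2: translocation has the two stated outcomes
  r9 <- apply_rearrangement(two, 2L, 5L, u = 0.25)  # {a,b} with {c,d}
  expect_identical(r9$record$kind, "translocation")
  expect_identical(r9$genome$chrs, list(c(1L, 4L), c(3L, 2L)))
  r10 <- apply_rearrangement(two, 2L, 5L, u = 0.75)
  expect_identical(r10$genome$chrs, list(c(1L, -3L), c(-4L, 2L)))

  # case 2 with a circular partner is a fusion
  mix <- genome(list(c("+a", "+b"), c("+c", "+d")),
                circular = c(FALSE, TRUE))
  r11 <- apply_rearrangement(mix, 2L, 4L, u = 0.75)
  expect_identical(r11$record$kind, "fusion")
  expect_identical(length(r11$genome$chrs), 1L)
  expect_identical(n_genes(r11$genome), 4L)
})

test_that("rearrangements preserve the gene multiset and conservation", {
  set.seed(11)
  g <- seed_duplications(make_ancestor(30, 2, 1), 3, 4)
  genes <- sort(abs(unlist(g$chrs)))
  for (i in 1:200) {
    Tn <- n_genes(g) + n_linear(g)
    r <- apply_rearrangement(g, sample.int(Tn, 1), sample.int(Tn, 1))
    g <- r$genome
    expect_identical(sort(abs(unlist(g$chrs))), genes)
    expect_conserved(g)
  }
})

test_that("duplication splices copies as derived by hand", {
  h <- genome(list(c("+a", "+b")))
  # duplicate +b (gene position 2), length 1, into the left telomere site
  r <- apply_duplication(h, 2L, 1L, 1L)
  expect_identical(r$genome$chrs[[1]], c(2L, 1L, 2L))

  # length runs past a linear end: truncated
  r2 <- apply_duplication(h, 2L, 5L, 2L)
  expect_identical(r2$record$details$length, 1L)

  # circular wrap, capped at chromosome size
  cg <- genome(list(c("+a", "+b", "+c")), circular = TRUE)
  r3 <- apply_duplication(cg, 3L, 9L, 2L)
  expect_identical(r3$record$details$length, 3L)
  expect_identical(n_genes(r3$genome), 6L)

  # conservation and gene-count bookkeeping across random duplications
  set.seed(4)
  g <- seed_duplications(make_ancestor(25, 1, 1), 2, 3)
  for (i in 1:100) {
    N <- n_genes(g)
    r <- apply_duplication(g, sample.int(N, 1), sample.int(5, 1),
                           sample.int(N + n_linear(g), 1))
    expect_identical(n_genes(r$genome), N + r$record$details$length)
    expect_conserved(r$genome)
    g <- r$genome
  }
})

test_that("loss removes one gene and rejoins the flanks", {
  g <- genome(list(c("+a", "+b", "+a")))
  r <- apply_loss(g, 1L)
  expect_identical(r$genome$chrs[[1]], c(2L, 1L))
  em <- extremity_multiset(r$genome)
  expect_identical(em$adjacencies, "a^t|b^h")

  # circular (+a,+a): forced outcome is circular (+a)
  ca <- genome(list(c("+a", "+a")), circular = TRUE)
  r2 <- apply_loss(ca, 2L)
  expect_identical(r2$genome$chrs[[1]], 1L)
  expect_true(r2$genome$circular)

  # deleting a single-gene chromosome removes the chromosome
  g2 <- genome(list(c("+a", "+b"), "+a"))
  r3 <- apply_loss(g2, 3L)
  expect_identical(length(r3$genome$chrs), 1L)

  # single-copy families are not deletable
  expect_error(apply_loss(g, 2L), "fewer than two")
})

test_that("event categories are drawn with the model probabilities", {
  set.seed(21)
  g <- seed_duplications(make_ancestor(40, 0, 1), 3, 3)
  expect_identical(draw_event(g, event_params(1, 0))$category, "duplication")
  expect_identical(draw_event(g, event_params(0, 0))$category, "rearrangement")

  n <- 20000
  cats <- character(n)
  params <- event_params(0.2, 0.6)
  for (i in seq_len(n)) cats[i] <- draw_event(g, params)$category
  p_hat <- table(factor(cats, c("rearrangement", "duplication", "loss"))) / n
  se <- sqrt(c(0.2, 0.2, 0.6) * c(0.8, 0.8, 0.4) / n)
  expect_true(all(abs(p_hat - c(0.2, 0.2, 0.6)) < 4 * se))
})

test_that("infeasible loss renormalises onto the feasible categories", {
  g <- make_ancestor(20, 0, 1)          # duplicate-free: no legal loss
  set.seed(3)
  cats <- replicate(400, draw_event(g, event_params(p_d = 0.5, p_l = 0.5))$category)
  expect_true(all(cats == "duplication"))
  expect_error(draw_event(g, event_params(p_d = 0, p_l = 1)),
               "no gene is deletable")
})

test_that("evolve applies k events, keeps counts honest, and replays", {
  set.seed(8)
  g <- seed_duplications(make_ancestor(60, 1, 1), 4, 4)
  out0 <- evolve(g, 0, event_params(0.2, 0.6))
  expect_identical(out0$genome$chrs, g$chrs)
  expect_identical(nrow(out0$log), 0L)

  set.seed(99)
  out <- evolve(g, 300, event_params(0.2, 0.6))
  expect_identical(sum(out$counts), 300L)
  expect_identical(nrow(out$log), 300L)
  expect_identical(as.vector(table(factor(out$log$category,
                                          names(out$counts)))),
                   as.vector(out$counts))
  expect_conserved(out$genome)

  set.seed(99)
  out2 <- evolve(g, 300, event_params(0.2, 0.6))
  expect_identical(out2$genome$chrs, out$genome$chrs)
  expect_identical(out2$log, out$log)
})
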