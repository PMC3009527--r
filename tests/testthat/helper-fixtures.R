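# Shared fixtures and independent oracles.
#
# The enumeration oracles apply every possible single event by brute force
# through the simulator and average the resulting summary vectors; they are
# the ground truth the analytic one-step operators are compared against.

# the worked toy genome: one linear chromosome (+a +b -c +a +b -d +a) and
# one circular chromosome (+e -f)
toy_genome <- function() {
  genome(list(c("+a", "+b", "-c", "+a", "+b", "-d", "+a"),
              c("+e", "-f")),
         circular = c(FALSE, TRUE), name = "G")
}

vec_coords <- function(v) truedist:::.vec_coords(v)
quiet_cap <- function(expr) truedist:::.quiet_cap(expr)

# a small reference with duplicates plus a mildly evolved descendant
small_pair <- function(seed = 5, n = 14, n_linear = 0, n_circular = 1,
                       seed_dups = 2, L_max = 2, k = 5,
                       p_d = 0.3, p_l = 0.3) {
  set.seed(seed)
  G <- seed_duplications(make_ancestor(n, n_linear, n_circular),
                        seed_dups, L_max)
  H <- evolve(G, k, event_params(p_d, p_l, L_max), log = FALSE)$genome
  list(G = G, ref = genome_ref(G), H = H)
}

# exact one-step mean vector over all ordered rearrangement site pairs,
# averaging the two-outcome cases over both auxiliary coin values
enumerate_rearrangements <- function(ref, H, C) {
  Tn <- n_genes(H) + n_linear(H)
  acc <- 0
  cnt <- 0L
  for (s1 in seq_len(Tn)) for (s2 in seq_len(Tn)) for (u in c(0.25, 0.75)) {
    g2 <- apply_rearrangement(H, s1, s2, u)$genome
    acc <- acc + vec_coords(quiet_cap(genome_vector(ref, g2, C)))
    cnt <- cnt + 1L
  }
  acc / cnt
}

# exact one-step mean over all (length, start, insertion site) duplications
enumerate_duplications <- function(ref, H, L_max, C) {
  N <- n_genes(H)
  Tn <- N + n_linear(H)
  acc <- 0
  cnt <- 0L
  for (len in seq_len(L_max)) for (st in seq_len(N)) for (si in seq_len(Tn)) {
    g2 <- apply_duplication(H, st, len, si)$genome
    acc <- acc + vec_coords(quiet_cap(genome_vector(ref, g2, C)))
    cnt <- cnt + 1L
  }
  acc / cnt
}

# exact one-step mean over all legal deletions
enumerate_losses <- function(ref, H, C) {
  fc <- truedist:::.family_counts(H)
  allv <- abs(unlist(H$chrs))
  cand <- which(fc[allv] >= 2L)
  acc <- 0
  for (tg in cand)
    acc <- acc + vec_coords(quiet_cap(genome_vector(ref, apply_loss(H, tg)$genome, C)))
  acc / length(cand)
}

# Monte-Carlo mean and standard error of the one-step vector for one event
# category, drawn through the simulator
mc_one_step <- function(ref, H, category, n_draws, C, L_max = 10) {
  params <- switch(category,
    rearrangement = event_params(0, 0, L_max),
    duplication   = event_params(1, 0, L_max),
    loss          = event_params(0, 1, L_max))
  p <- 2L * C + 3L
  s <- numeric(p)
  s2 <- numeric(p)
  for (i in seq_len(n_draws)) {
    g2 <- apply_event(H, draw_event(H, params))$genome
    x <- vec_coords(quiet_cap(genome_vector(ref, g2, C)))
    s <- s + x
    s2 <- s2 + x * x
  }
  m <- s / n_draws
  se <- sqrt(pmax(s2 / n_draws - m^2, 0) / (n_draws - 1))
  list(mean = m, se = se)
}

# conservation identity |adjacencies| + |telomeres| = N + l, telomeres = 2l
expect_conserved <- function(g) {
  em <- extremity_multiset(g)
  expect_identical(length(em$adjacencies) + length(em$telomeres),
                   n_genes(g) + n_linear(g))
  expect_identical(length(em$telomeres), 2L * n_linear(g))
}
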