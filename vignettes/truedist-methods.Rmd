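---
title: "Estimating true evolutionary distances from gene orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating true evolutionary distances from gene orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truedist)
```

## The problem

Two genomes described as signed gene orders differ by an unknown number of
evolutionary events: rearrangements that shuffle the order, and gene
duplications and losses that change the content.  Edit distances — the
*smallest* number of events that could explain the difference — are well
studied but systematically underestimate the *true* distance, because
independent events often cancel or overwrite one another.  `truedist`
implements a model-based correction: it simulates (and analytically
predicts) how a summary of the genome decays under random events, and
reads the true event count off the predicted decay curve.

The model treats a genome as chromosomes that are either linear or
circular, which matters biologically: most prokaryotic genomes are one
circular chromosome, most eukaryotic nuclear genomes several linear ones.
Events are drawn from three categories with fixed probabilities: a
duplication with probability $p_d$, a loss with probability $p_l$, and a
rearrangement otherwise ($p_r = 1 - p_d - p_l$).

## Genome representation

Every gene copy has a tail ($g^t$) and a head ($g^h$); `+g` reads tail to
head.  Consecutive genes define an *adjacency* (an unordered pair of
extremities); each end of a linear chromosome is a *telomere* (a singleton
extremity).  A genome with $N$ genes and $l$ linear chromosomes therefore
has exactly $N + l$ adjacency-or-telomere instances, $2l$ of them
telomeres — an identity the simulator asserts after every event.  The
multiset view is not injective: genomes with duplicated genes can share
all multisets, which is why the package never attempts to reconstruct a
genome from its summary.

```{r}
g <- parse_genomes(">G\n+a +b -c +a +b -d +a $\n+e -f @\n")[[1]]
extremity_multiset(g)
```

## The event model

A rearrangement selects two adjacency/telomere instances uniformly *with
replacement* and dispatches on four cases: two sites in one chromosome
invert the enclosed segment; sites in two chromosomes cause a
translocation (two outcomes, equally likely) or, with a circular partner,
a fusion; the same adjacency twice causes a fission (linear) or
linearization (circular); two telomeres fuse two linear chromosomes or
circularize one (one telomere selected twice counts as both telomeres of
its chromosome).  Unlike the classical double-cut-and-join operation,
this repertoire never spontaneously excises circular chromosomes from
linear ones, so simulated genomes keep their prokaryotic or eukaryotic
character.

A duplication copies a segment of $U\{1..L_{\max}\}$ consecutive genes
(start uniform over gene positions) and splices the copy at a uniformly
chosen instance; at a linear chromosome end the segment is truncated, on
a circular chromosome it wraps, capped at the chromosome length.  A loss
deletes one uniformly chosen gene whose family has at least two copies —
losses are conditioned on duplicated content, so single-copy genes are
never destroyed.  When no gene is deletable, the category is redrawn from
the feasible ones with renormalised weights; silently skipping the event
would corrupt event counts.

Each event's draws happen in a fixed order (category, sites, auxiliary
coins), so a run is exactly reproducible from its seed.

## The summary vector and its expected decay

Relative to a reference genome $G$, any genome $G^*$ is summarised by
$V_G(G^*) = (SG_1..SG_C,\ SA_1..SA_C,\ DA,\ ST,\ DT)$: gene copies whose
family has exactly $i$ copies, adjacency instances of multiplicity $i$
whose type occurs in $G$, adjacency instances absent from $G$, and
telomeres shared with / absent from $G$.  Counting is by instance, so
$\sum_i SG_i = N^*$ and $\sum_i SA_i + DA + ST + DT = N^* + l^*$.
Multiplicities above the cap $C$ (10 in all experiments) are accumulated
in class $C$.

The package's analytic core is a one-step recursion: given the expected
vector after $k$ events, it returns the expected vector after one more
event of each category, and `expected_step()` mixes the three with
weights $(p_r, p_d, p_l)$.  Iterating from $V_G(G)$ costs $O(kC)$ total.
The class flows follow instance counting — destroying one instance of a
multiplicity-$i$ type removes $i$ instances from class $i$ and adds
$i-1$ to class $i-1$ — with the exact with-replacement selection
probabilities for rearrangements, segment-composition expectations for
duplications ($L = (L_{\max}+1)/2$ genes, $L-1$ internal adjacencies),
and flank-counting bounds for losses.

Three places deserve comment because they are approximations, not exact
expectations:

* **Re-created reference adjacencies.** A rearrangement or duplication
  occasionally recreates an adjacency of $G$ by chance; the probability is
  $O(C^2/N)$ per event and the recursion books new adjacencies as
  distinct.  The error this induces is visible on genomes of a few
  hundred genes and negligible at the study scales (1,000+ genes).
* **Truncation at linear chromosome ends.** The simulator truncates
  segments that overrun a linear chromosome, so the recursion uses the
  expected realised length $L - l(L_{\max}^2-1)/(6N)$; the correction is
  exact for the overshoot expectation and vanishes as $N$ grows.
* **Loss-step auxiliaries.** Two quantities needed by the loss update are
  not functions of the vector: `g1`, the number of deletable genes
  flanking multiplicity-1 shared adjacencies, and the recoverable-context
  counts `R[j]` — insertion sites whose duplicated segment has $j$
  surviving copy genes, whose final erosion re-creates the broken shared
  adjacency (deleting a freshly inserted duplicate restores the adjacency
  its insertion broke).  Both start from exact enumeration on the
  reference and then evolve by mean-field bookkeeping: proportional decay
  with $SA_1$, demotion inflows from class 2 (with one surely-deletable
  flank plus a second when the hit family had three or more copies), and
  an aging chain for the contexts.  The coefficients were validated
  against exact recomputation of the auxiliaries on simulated
  intermediate genomes, not against the estimator's end metrics.

## The distance estimator

`estimate_k()` computes $V_G(F)$, iterates the recursion to
$k_{\max} = 4N$ (the search bound used throughout), and returns the
smallest $k$ minimising the 1-norm distance between prediction and
observation.  Ties break toward smaller $k$ — a parsimony-flavoured,
deterministic rule.  With unknown parameters,
`estimate_k_unknown_params()` enumerates $(p_d, p_l)$ on a grid (1%
resolution by default, constrained to $p_d < 4p_l$, $p_d + p_l \le 1$)
and minimises jointly over $(k, p_d, p_l)$, breaking ties toward smaller
$k$, then $p_d$, then $p_l$.  Because every trajectory depends only on
the reference, `grid_trajectories()` caches them once per reference and
reuses them across many final genomes.

Per-type counts are reported as $\hat{k}$ times the category
probabilities (`decompose_events()` rounds by largest remainder so the
parts sum to $\hat{k}$).  In simulation studies the estimate co-varies
with the run's realised duplication count — more duplications leave a
stronger gene-content signature — which is why duplication errors can
fall below the binomial noise floor of the category counts.

## What the synthetic generator does and does not emulate

`make_ancestor()` builds a duplicate-free genome: distinct families,
uniform random orientations, near-equal chromosome sizes (the studies
describe only "various sizes"; near-equal is the symmetric choice).
`seed_duplications()` then applies 10 random duplications
($L_{\max} = 10$) so the reference carries initial duplicated genes.
This emulates the copy-number structure the model reasons about, but not
features of real genomes such as gene-family size distributions, hotspots
of rearrangement, tandem-biased duplication, or selection; passing tests
therefore demonstrate internal consistency of estimator and model, not
that real genome pairs evolve by this process.

## Validation strategy and known limitations

* Hand-derived examples and brute-force enumeration oracles check the
  simulator and the one-step operators on small genomes (every ordered
  site pair, every duplication triple, every legal deletion).
* Monte-Carlo one-step checks at 200 genes: the rearrangement operator
  matches the empirical mean of $10^5$ draws within noise; the
  duplication operator shows per-coordinate biases up to ~0.16 events on
  copy-number classes, the signature of its stated assumption that no
  two duplicates share one segment (violated once seed duplications
  cluster copies); the loss operator matches except on telomere
  coordinates, which the recursion freezes by design while real
  end-of-chromosome deletions move ~0.014 telomeres per event.  These
  residuals shrink like $1/N$ and do not register at the study scales.
* Trajectory-versus-sample-mean and estimator-accuracy experiments at the
  published scales (1,000 genes / 1 circular chromosome with
  $p_d{=}0.2, p_l{=}0.6$; 10,000 genes / 5 linear chromosomes with
  $p_d{=}0.1, p_l{=}0.2$) are run by the acceptance suite at 500-1000
  replicates (reduced from the published 10,000) with true distances up
  to twice the gene count; `scripts/acceptance.R` recomputes the
  per-type relative errors from scratch.
* Below roughly 500 genes the estimator inherits visible bias from the
  $O(C^2/N)$ terms (about +10% at 300 genes, $k = N/2$); the method is
  intended for genome-scale gene orders.
* Estimates assume both genomes are gene orders over the same family
  universe; families absent from the reference only ever contribute
  distinct adjacencies (a warning is raised when there is no overlap at
  all).

## Problem sizes used in the packaged studies

The acceptance suite uses 500 replicates for the 1,000-gene fixture at
$k \in \{250, 500, 1000, 2000\}$, 30 replicates for the 10,000-gene
fixture at $k = 10{,}000$, and 40 replicates for the hidden-parameter
study with a 5%-resolution search grid; `scripts/acceptance.R` uses 1,000
and 100 replicates for the two fixtures.  These sizes give Monte-Carlo
standard errors a few times smaller than the effects being measured while
keeping a desk-scale runtime.

## A worked example

```{r}
set.seed(7)
G <- seed_duplications(make_ancestor(500, n_circular = 1), 10, 10)
params <- event_params(p_d = 0.2, p_l = 0.6, L_max = 10)
run <- evolve(G, 400, params)
run$counts
est <- estimate_k(G, run$genome, params)
est
decompose_events(est)
```
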