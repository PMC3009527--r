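#' Event model parameters
#'
#' The stochastic model draws each event category independently: a gene
#' duplication with probability `p_d`, a gene loss with probability `p_l`,
#' and a rearrangement with the remaining probability
#' `p_r = 1 - p_d - p_l`.  `L_max` caps the length (in genes) of a
#' duplicated segment; the realised length is uniform on `1..L_max`.
#'
#' @param p_d Probability of a duplication event, in `[0, 1]`.
#' @param p_l Probability of a loss event, in `[0, 1]`; `p_d + p_l <= 1`.
#' @param L_max Maximum duplicated-segment length (positive integer).
#' @return An object of class `event_params`.
#' @export
event_params <- function(p_d, p_l, L_max = 10L) {
  stopifnot(p_d >= 0, p_l >= 0, p_d + p_l <= 1 + 1e-12, L_max >= 1)
  structure(list(p_d = p_d, p_l = p_l, p_r = max(0, 1 - p_d - p_l),
                 L_max = as.integer(L_max)),
            class = "event_params")
}

#' @export
print.event_params <- function(x, ...) {
  cat(sprintf("<event_params: p_r=%.3f p_d=%.3f p_l=%.3f L_max=%d>\n",
              x$p_r, x$p_d, x$p_l, x$L_max))
  invisible(x)
}

# ---- site/gene indexing ----------------------------------------------------
#
# Rearrangement and insertion sites are the N + l adjacency/telomere
# instances, indexed 1..N+l chromosome by chromosome.  Within a linear
# chromosome of n genes the local positions are 0..n: 0 is the left
# telomere, n the right telomere, and p in 1..n-1 the adjacency between
# genes p and p+1.  Within a circular chromosome the local positions are
# 1..n, p being the adjacency between gene p and gene (p mod n) + 1.

.site_counts <- function(g) lengths(g$chrs) + !g$circular
.n_sites <- function(g) n_genes(g) + n_linear(g)

.locate_site <- function(g, idx) {
  cl <- cumsum(.site_counts(g))
  chr <- findInterval(idx - 0.5, cl) + 1L
  off <- idx - (if (chr > 1L) cl[chr - 1L] else 0L)
  # local position: linear -> off - 1 (0..n), circular -> off (1..n)
  pos <- if (g$circular[chr]) off else off - 1L
  list(chr = chr, pos = pos)
}

.locate_gene <- function(g, idx) {
  cl <- cumsum(lengths(g$chrs))
  chr <- findInterval(idx - 0.5, cl) + 1L
  list(chr = chr, pos = idx - (if (chr > 1L) cl[chr - 1L] else 0L))
}

.is_telomere <- function(g, loc) {
  !g$circular[loc$chr] &&
    (loc$pos == 0L || loc$pos == length(g$chrs[[loc$chr]]))
}

.family_counts <- function(g) {
  tabulate(abs(unlist(g$chrs, use.names = FALSE)), length(g$families))
}

# cut a circular chromosome at local adjacency position p, returning the
# linear gene order that starts just after the cut
.open_circular <- function(v, p) {
  n <- length(v)
  start <- p %% n + 1L
  if (start == 1L) v else v[c(start:n, seq_len(start - 1L))]
}

.drop_empty_chrs <- function(chrs, circular) {
  keep <- lengths(chrs) > 0L
  list(chrs = chrs[keep], circular = circular[keep])
}

# ---- rearrangement ---------------------------------------------------------

#' Apply one rearrangement event
#'
#' Two adjacency/telomere instances are the operation's sites (drawn with
#' replacement, uniformly over the `N + l` instances, by [draw_event()]).
#' The outcome dispatches on four cases: two sites in the same chromosome
#' cause an inversion of the enclosed segment; sites in two different
#' chromosomes cause a translocation (two possible outcomes, chosen
#' equiprobably via `u`) or, when at least one chromosome is circular, a
#' fusion; the same adjacency selected twice causes a fission (linear) or a
#' linearization (circular); two telomeres cause a fusion of two linear
#' chromosomes or a circularization when both belong to one chromosome
#' (selecting one telomere twice counts as selecting both telomeres of its
#' chromosome).  Rearrangements never change the gene content.
#'
#' @param g A `genome`.
#' @param site1,site2 Global site indices in `1..N+l`.
#' @param u Auxiliary uniform deviate deciding between the two translocation
#'   outcomes (or the two orientations of a fusion involving a circular
#'   chromosome).
#' @return A list with elements `genome` and `record`.
#' @examples
#' g <- genome(list(c("+a", "+b", "+c")))
#' # invert gene b: sites are the two interior adjacencies (indices 2 and 3)
#' apply_rearrangement(g, 2L, 3L)$genome$chrs[[1]]
#' @export
apply_rearrangement <- function(g, site1, site2, u = stats::runif(1)) {
  T <- .n_sites(g)
  if (site1 < 1L || site1 > T || site2 < 1L || site2 > T)
    stop("site index out of range")
  a <- .locate_site(g, site1)
  b <- .locate_site(g, site2)
  chrs <- g$chrs
  circ <- g$circular
  kind <- NULL

  if (a$chr == b$chr) {
    cc <- a$chr
    v <- chrs[[cc]]
    n <- length(v)
    p <- min(a$pos, b$pos)
    q <- max(a$pos, b$pos)
    tel_p <- !circ[cc] && (p == 0L)
    tel_q <- !circ[cc] && (q == n)
    if (p == q) {
      if (.is_telomere(g, a)) {
        # one telomere twice ~ both telomeres of the chromosome
        circ[cc] <- TRUE
        kind <- "circularization"
      } else if (circ[cc]) {
        chrs[[cc]] <- .open_circular(v, p)
        circ[cc] <- FALSE
        kind <- "linearization"
      } else {
        chrs[[cc]] <- v[seq_len(p)]
        chrs[[length(chrs) + 1L]] <- v[(p + 1L):n]
        circ <- c(circ, FALSE)
        kind <- "fission"
      }
    } else if (tel_p && tel_q) {
      circ[cc] <- TRUE
      kind <- "circularization"
    } else {
      seg <- (p + 1L):q
      v[seg] <- -rev(v[seg])
      chrs[[cc]] <- v
      kind <- "inversion"
    }
  } else {
    v1 <- chrs[[a$chr]]; v2 <- chrs[[b$chr]]
    tel1 <- .is_telomere(g, a); tel2 <- .is_telomere(g, b)
    if (tel1 && tel2) {
      # fusion of two linear chromosomes, joining the selected ends
      s1 <- if (a$pos == 0L) -rev(v1) else v1     # selected end becomes the right end
      s2 <- if (b$pos == 0L) v2 else -rev(v2)     # selected end becomes the left end
      chrs[[a$chr]] <- c(s1, s2)
      chrs[[b$chr]] <- integer()
      kind <- "fusion"
    } else if (circ[a$chr] || circ[b$chr]) {
      # open a circular chromosome at its selected adjacency and merge it
      # into the other chromosome at the other selected site
      if (circ[a$chr]) { src <- a; dst <- b } else { src <- b; dst <- a }
      s <- .open_circular(chrs[[src$chr]], src$pos)
      if (u < 0.5) s <- -rev(s)
      w <- chrs[[dst$chr]]
      chrs[[dst$chr]] <- append(w, s, after = dst$pos)
      chrs[[src$chr]] <- integer()
      kind <- "fusion"
    } else {
      # translocation between two linear chromosomes; two outcomes
      p <- a$pos; q <- b$pos
      L1 <- v1[seq_len(p)]; R1 <- if (p < length(v1)) v1[(p + 1L):length(v1)] else integer()
      L2 <- v2[seq_len(q)]; R2 <- if (q < length(v2)) v2[(q + 1L):length(v2)] else integer()
      if (u < 0.5) {
        chrs[[a$chr]] <- c(L1, R2)
        chrs[[b$chr]] <- c(L2, R1)
      } else {
        chrs[[a$chr]] <- c(L1, -rev(L2))
        chrs[[b$chr]] <- c(-rev(R2), R1)
      }
      kind <- "translocation"
    }
  }
  res <- .drop_empty_chrs(chrs, circ)
  g2 <- new_genome(res$chrs, res$circular, g$families, g$name)
  if (isTRUE(getOption("truedist.check"))) validate_genome(g2)
  list(genome = g2,
       record = list(category = "rearrangement", kind = kind,
                     sites = c(site1, site2)))
}

# ---- duplication -----------------------------------------------------------

#' Apply one segmental duplication
#'
#' The segment of `length` consecutive genes starting at gene position
#' `start` is copied (preserving order and orientation) and spliced into the
#' genome at the adjacency/telomere instance `insert_site` of the
#' pre-duplication genome.  At a linear chromosome end the segment is
#' truncated to the available genes; on a circular chromosome it wraps
#' around, capped at the chromosome length.  Splicing into an adjacency
#' removes that adjacency and adds `L + 1` new ones; splicing at a telomere
#' consumes it, creates a new telomere, and adds `L` adjacencies.
#'
#' @param g A `genome`.
#' @param start Global gene position in `1..N` where the copied segment
#'   begins.
#' @param len Segment length drawn from `1..L_max`.
#' @param insert_site Global site index in `1..N+l` receiving the copy.
#' @return A list with elements `genome` and `record` (the record's
#'   `details$families` holds the family ids of the copied genes).
#' @export
apply_duplication <- function(g, start, len, insert_site) {
  N <- n_genes(g)
  if (start < 1L || start > N) stop("start position out of range")
  if (len < 1L) stop("segment length must be positive")
  src <- .locate_gene(g, start)
  v <- g$chrs[[src$chr]]
  n <- length(v)
  if (g$circular[src$chr]) {
    len <- min(len, n)                          # wrap, capped at chromosome size
    idx <- (src$pos - 1L + seq_len(len) - 1L) %% n + 1L
  } else {
    len <- min(len, n - src$pos + 1L)           # truncate at the right end
    idx <- src$pos + seq_len(len) - 1L
  }
  seg <- v[idx]
  dst <- .locate_site(g, insert_site)
  chrs <- g$chrs
  chrs[[dst$chr]] <- append(chrs[[dst$chr]], seg, after = dst$pos)
  g2 <- new_genome(chrs, g$circular, g$families, g$name)
  if (isTRUE(getOption("truedist.check"))) validate_genome(g2)
  list(genome = g2,
       record = list(category = "duplication", kind = "duplication",
                     sites = insert_site,
                     details = list(start = start, length = len,
                                    families = abs(seg))))
}

# one fully random duplication; shared by seed_duplications() and the
# event-drawing machinery
.random_duplication <- function(g, L_max) {
  len <- sample.int(L_max, 1L)
  start <- sample.int(n_genes(g), 1L)
  site <- sample.int(.n_sites(g), 1L)
  apply_duplication(g, start, len, site)
}

# ---- loss ------------------------------------------------------------------

#' Apply one gene loss
#'
#' Deletes the gene instance at global position `target`.  Losses are
#' restricted to genes whose family has at least two copies in the genome;
#' the two sites flanking the deleted gene are replaced by one (an
#' adjacency, a telomere, or -- when the gene was alone on its chromosome --
#' nothing, the chromosome being removed).
#'
#' @param g A `genome`.
#' @param target Global gene position in `1..N`; its family must have >= 2
#'   copies.
#' @return A list with elements `genome` and `record` (the record's
#'   `details$family` holds the deleted family id).
#' @export
apply_loss <- function(g, target) {
  loc <- .locate_gene(g, target)
  fam <- abs(g$chrs[[loc$chr]][loc$pos])
  fc <- .family_counts(g)
  if (fc[fam] < 2L)
    stop("gene family '", g$families[fam], "' has fewer than two copies")
  chrs <- g$chrs
  chrs[[loc$chr]] <- chrs[[loc$chr]][-loc$pos]
  res <- .drop_empty_chrs(chrs, g$circular)
  if (length(res$chrs) == 0L) stop("loss would leave an empty genome")
  g2 <- new_genome(res$chrs, res$circular, g$families, g$name)
  if (isTRUE(getOption("truedist.check"))) validate_genome(g2)
  list(genome = g2,
       record = list(category = "loss", kind = "loss", sites = target,
                     details = list(family = fam)))
}

# ---- drawing and applying random events ------------------------------------

#' Draw one random event
#'
#' Samples the event category with probabilities `(p_r, p_d, p_l)` and then
#' the category's sites: a rearrangement draws two adjacency/telomere
#' instances with replacement, uniformly over the `N + l` instances (plus an
#' auxiliary uniform deviate for two-outcome cases); a duplication draws a
#' segment length uniform on `1..L_max`, a start gene position uniform on
#' `1..N`, and an insertion site uniform over the `N + l` instances; a loss
#' draws a target uniformly from all gene instances whose family has at
#' least two copies.  When no gene is deletable the loss weight is
#' renormalised onto the feasible categories, so event counts are never
#' corrupted by silent no-ops.
#'
#' The per-event draw order is fixed (category, then sites, then auxiliary
#' choices), so a run is exactly replayable from its seed.
#'
#' @param g A `genome`.
#' @param params An [event_params()] object.
#' @param fc Optional precomputed family-count vector (an optimisation used
#'   by [evolve()]).
#' @return An (unapplied) event description for [apply_event()].
#' @export
draw_event <- function(g, params, fc = NULL) {
  if (is.null(fc)) fc <- .family_counts(g)
  p_d <- params$p_d; p_l <- params$p_l
  if (p_l > 0) {
    if (!any(fc >= 2L)) {
      tot <- params$p_r + p_d
      if (tot <= 0) stop("loss is the only enabled category but no gene is deletable")
      p_d <- p_d / tot
      p_l <- 0
    }
  }
  r <- stats::runif(1)
  if (r < 1 - p_d - p_l) {
    T <- .n_sites(g)
    sites <- sample.int(T, 2L, replace = TRUE)
    list(category = "rearrangement", sites = sites, u = stats::runif(1))
  } else if (r < 1 - p_l) {
    list(category = "duplication",
         length = sample.int(params$L_max, 1L),
         start = sample.int(n_genes(g), 1L),
         site = sample.int(.n_sites(g), 1L))
  } else {
    allv <- abs(unlist(g$chrs, use.names = FALSE))
    cand <- which(fc[allv] >= 2L)
    list(category = "loss", target = cand[sample.int(length(cand), 1L)])
  }
}

#' Apply a drawn event
#'
#' @param g A `genome`.
#' @param ev An event drawn by [draw_event()].
#' @return A list with elements `genome` and `record`.
#' @export
apply_event <- function(g, ev) {
  switch(ev$category,
    rearrangement = apply_rearrangement(g, ev$sites[1L], ev$sites[2L], ev$u),
    duplication   = apply_duplication(g, ev$start, ev$length, ev$site),
    loss          = apply_loss(g, ev$target),
    stop("unknown event category: ", ev$category))
}

#' Evolve a genome for k random events
#'
#' Draws and applies `k` events sequentially under the model parameters.
#' Randomness comes from R's global RNG; `set.seed()` beforehand makes the
#' run exactly reproducible (final genome and log alike).
#'
#' @param g The starting `genome`.
#' @param k Number of events (non-negative integer).
#' @param params An [event_params()] object.
#' @param log Keep the full per-event log (set `FALSE` to save memory in
#'   large batch runs; category counts are always returned).
#' @return A list with `genome` (the evolved genome), `counts` (named vector
#'   of events applied per category, summing to `k`) and, when `log = TRUE`,
#'   `log`, a data frame with columns `step`, `category`, `kind`.
#' @examples
#' set.seed(42)
#' anc <- make_ancestor(50, n_circular = 1)
#' out <- evolve(anc, 20, event_params(p_d = 0.2, p_l = 0.6))
#' out$counts
#' @export
evolve <- function(g, k, params, log = TRUE) {
  validate_genome(g)
  stopifnot(k >= 0)
  fc <- .family_counts(g)
  counts <- c(rearrangement = 0L, duplication = 0L, loss = 0L)
  cats <- kinds <- if (log) character(k) else NULL
  for (step in seq_len(k)) {
    ev <- draw_event(g, params, fc = fc)
    res <- apply_event(g, ev)
    g <- res$genome
    rec <- res$record
    if (rec$category == "duplication") {
      fc <- fc + tabulate(rec$details$families, length(fc))
    } else if (rec$category == "loss") {
      fc[rec$details$family] <- fc[rec$details$family] - 1L
    }
    counts[rec$category] <- counts[rec$category] + 1L
    if (log) { cats[step] <- rec$category; kinds[step] <- rec$kind }
  }
  out <- list(genome = g, counts = counts)
  if (log)
    out$log <- data.frame(step = seq_len(k), category = cats, kind = kinds)
  out
}
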