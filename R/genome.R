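#' Construct a genome from signed gene orders
#'
#' A genome is an ordered collection of chromosomes, each a sequence of
#' oriented genes drawn from named gene families.  Chromosomes are either
#' linear (they contribute two telomeres) or circular (they contribute none).
#' Gene families may occur in several copies anywhere in the genome.
#'
#' @param chromosomes A list of character vectors.  Each vector is one
#'   chromosome; each element is a gene name with an optional `+`/`-`
#'   orientation prefix (no prefix means `+`).
#' @param circular Logical vector, one entry per chromosome (recycled if
#'   length 1).  Default: all linear.
#' @param name Genome identifier used when serialising.
#' @return An object of class `genome`.
#' @examples
#' g <- genome(list(c("+a", "+b", "-c", "+a", "+b", "-d", "+a"),
#'                  c("+e", "-f")),
#'             circular = c(FALSE, TRUE), name = "G")
#' g
#' @seealso [parse_genomes()], [extremity_multiset()], [make_ancestor()]
#' @export
genome <- function(chromosomes, circular = FALSE, name = "genome") {
  stopifnot(is.list(chromosomes), length(chromosomes) >= 1L)
  circular <- rep_len(as.logical(circular), length(chromosomes))
  toks <- unlist(chromosomes, use.names = FALSE)
  if (length(toks) == 0L) stop("genome must contain at least one gene")
  sgn <- ifelse(startsWith(toks, "-"), -1L, 1L)
  fam <- sub("^[+-]", "", toks)
  if (any(!nzchar(fam))) stop("empty gene family name")
  families <- unique(fam)
  ids <- match(fam, families) * sgn
  chrs <- split(ids, rep.int(seq_along(chromosomes), lengths(chromosomes)))
  chrs <- lapply(unname(chrs), as.integer)
  new_genome(chrs, circular, families, name)
}

# low-level constructor: chrs is a list of signed integer vectors, sign =
# orientation, abs() = index into `families`
new_genome <- function(chrs, circular, families, name = "genome") {
  structure(list(chrs = chrs, circular = as.logical(circular),
                 families = families, name = name),
            class = "genome")
}

#' Validate genome invariants
#'
#' Checks that every chromosome holds at least one gene, that family indices
#' are in range, and that chromosome/topology bookkeeping is consistent.
#' Called internally after every simulated event when `options(truedist.check
#' = TRUE)`.
#'
#' @param g A `genome`.
#' @return `g`, invisibly; stops on violation.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "genome"))
  if (length(g$chrs) < 1L) stop("genome must have at least one chromosome")
  if (length(g$circular) != length(g$chrs))
    stop("topology flags do not match chromosome count")
  for (v in g$chrs) {
    if (length(v) == 0L) stop("empty chromosome")
    if (any(v == 0L) || any(abs(v) > length(g$families)))
      stop("gene family index out of range")
  }
  invisible(g)
}

#' Gene count of a genome
#' @param g A `genome`.
#' @return Total number of gene copies `N`.
#' @export
n_genes <- function(g) sum(lengths(g$chrs))

#' Number of linear chromosomes
#' @param g A `genome`.
#' @return The count `l` of linear chromosomes.
#' @export
n_linear <- function(g) sum(!g$circular)

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome '%s': %d genes, %d chromosomes (%d linear, %d circular), %d families>\n",
              x$name, n_genes(x), length(x$chrs), n_linear(x),
              sum(x$circular), length(x$families)))
  invisible(x)
}

# ---- extremity coding ------------------------------------------------------
#
# Extremity of family f: tail -> 2f, head -> 2f + 1 (numeric, exact well past
# any realistic family count).  An adjacency is the unordered pair of the
# right extremity of one gene and the left extremity of the next; it is
# stored canonically as lo * B + hi with B = 2 * n_families + 2, so multiset
# equality reduces to equality of numeric keys.

.ext_base <- function(n_families) 2 * n_families + 2

# per-chromosome left/right extremity codes
.chr_exts <- function(v) {
  f <- abs(v)
  neg <- v < 0L
  list(left = 2 * f + as.numeric(neg), right = 2 * f + as.numeric(!neg))
}

# numeric adjacency keys and telomere codes of a genome
.site_keys <- function(g) {
  B <- .ext_base(length(g$families))
  adj <- vector("list", length(g$chrs))
  tel <- vector("list", length(g$chrs))
  for (i in seq_along(g$chrs)) {
    v <- g$chrs[[i]]
    e <- .chr_exts(v)
    n <- length(v)
    if (g$circular[i]) {
      a <- e$right
      b <- e$left[c(seq_len(n)[-1L], 1L)]
    } else {
      a <- e$right[-n]
      b <- e$left[-1L]
      tel[[i]] <- c(e$left[1L], e$right[n])
    }
    adj[[i]] <- pmin(a, b) * B + pmax(a, b)
  }
  list(adj = unlist(adj, use.names = FALSE),
       tel = unlist(tel, use.names = FALSE))
}

.ext_label <- function(code, families) {
  if (length(code) == 0L) return(character(0))
  fam <- families[code %/% 2]
  side <- ifelse(code %% 2 == 1, "h", "t")
  paste0(fam, "^", side)
}

#' Adjacency/telomere multiset of a genome
#'
#' Converts a genome to its multiset representation: every pair of
#' consecutive genes contributes one adjacency (an unordered pair of gene
#' extremities, tail `g^t` or head `g^h`), and each end of a linear
#' chromosome contributes one telomere.  A linear chromosome of `n` genes
#' yields `n - 1` adjacencies and 2 telomeres; a circular one yields `n`
#' adjacencies.  The representation is not injective: distinct genomes with
#' duplicated genes can share all multisets.
#'
#' @param g A `genome`.
#' @return A list of class `extremity_multiset` with character vectors
#'   `adjacencies` (elements like `"a^h|b^t"`, extremities in a fixed
#'   canonical order) and `telomeres` (elements like `"a^t"`), each sorted.
#' @examples
#' g <- genome(list(c("+a", "+b")), name = "toy")
#' extremity_multiset(g)
#' @export
extremity_multiset <- function(g) {
  validate_genome(g)
  k <- .site_keys(g)
  B <- .ext_base(length(g$families))
  lo <- k$adj %/% B
  hi <- k$adj %% B
  adj <- paste0(.ext_label(lo, g$families), "|", .ext_label(hi, g$families))
  tel <- .ext_label(k$tel, g$families)
  structure(list(adjacencies = sort(adj), telomeres = sort(tel)),
            class = "extremity_multiset")
}

#' @export
print.extremity_multiset <- function(x, ...) {
  cat(sprintf("<extremity multiset: %d adjacencies, %d telomeres>\n",
              length(x$adjacencies), length(x$telomeres)))
  if (length(x$adjacencies))
    cat(" adjacencies:", paste(x$adjacencies, collapse = " "), "\n")
  if (length(x$telomeres))
    cat(" telomeres:  ", paste(x$telomeres, collapse = " "), "\n")
  invisible(x)
}

# ---- GRIMM-style IO --------------------------------------------------------

#' Parse genomes from a GRIMM-style gene-order document
#'
#' The dialect: a record starts with `>name`; each following non-empty line
#' is one chromosome given as whitespace-separated signed gene names and
#' terminated by `$` (linear) or `@` (circular).  Lines starting with `#`
#' are comments.
#'
#' @param text A character scalar holding the document, a character vector of
#'   lines, or a file path (when `is_file = TRUE`).
#' @param is_file Read `text` as a file path instead of document content.
#' @return A list of `genome` objects.
#' @examples
#' gs <- parse_genomes(">G\n+a +b -c +a +b -d +a $\n+e -f @\n")
#' gs[[1]]
#' @export
parse_genomes <- function(text, is_file = FALSE) {
  lines <- if (is_file) readLines(text, warn = FALSE)
           else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  genomes <- list()
  cur_name <- NULL
  cur_chrs <- list()
  cur_circ <- logical()
  flush <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_chrs) == 0L)
      stop("record '", cur_name, "' has no chromosomes")
    genomes[[length(genomes) + 1L]] <<-
      genome(cur_chrs, cur_circ, name = cur_name)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- trimws(substring(ln, 2L))
      cur_chrs <- list()
      cur_circ <- logical()
      next
    }
    if (is.null(cur_name))
      stop("line ", i, ": chromosome line before any '>' record header")
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    term <- toks[length(toks)]
    if (!term %in% c("$", "@"))
      stop("line ", i, ": chromosome line must end in '$' or '@'")
    toks <- toks[-length(toks)]
    if (length(toks) == 0L)
      stop("line ", i, ": empty chromosome")
    if (any(toks %in% c("$", "@")))
      stop("line ", i, ": terminator in mid-line")
    cur_chrs[[length(cur_chrs) + 1L]] <- toks
    cur_circ <- c(cur_circ, term == "@")
  }
  flush()
  genomes
}

#' Serialise genomes to the GRIMM-style gene-order format
#'
#' Canonical inverse of [parse_genomes()]: every gene carries an explicit
#' `+`/`-` sign and chromosomes end in `$` (linear) or `@` (circular).
#'
#' @param genomes A `genome` or list of `genome` objects.
#' @param file Optional path; when given the document is written there.
#' @return The document as a single character scalar (invisibly when `file`
#'   is given).
#' @export
write_genomes <- function(genomes, file = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  out <- character()
  for (g in genomes) {
    validate_genome(g)
    out <- c(out, paste0(">", g$name))
    for (i in seq_along(g$chrs)) {
      v <- g$chrs[[i]]
      toks <- paste0(ifelse(v < 0L, "-", "+"), g$families[abs(v)])
      out <- c(out, paste(c(toks, if (g$circular[i]) "@" else "$"),
                          collapse = " "))
    }
  }
  doc <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(sub("\n$", "", doc), file)
    return(invisible(doc))
  }
  doc
}

# ---- synthetic ancestors ---------------------------------------------------

#' Generate a duplicate-free ancestor genome
#'
#' Creates a genome of `n_genes` distinct gene families with uniform random
#' orientations, partitioned into `n_linear + n_circular` chromosomes of
#' near-equal sizes.  This is the starting point of simulation studies: a
#' genome with no duplicated genes whose structure mimics either a
#' prokaryotic genome (one circular chromosome) or a eukaryotic one (several
#' linear chromosomes).
#'
#' Randomness is drawn from R's global RNG; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param n_genes Number of gene families (each in one copy).
#' @param n_linear,n_circular Chromosome counts; at least one chromosome in
#'   total and `n_genes >= n_linear + n_circular`.
#' @param name Genome identifier.
#' @return A `genome` with `n_genes` genes and no duplicated families.
#' @examples
#' set.seed(1)
#' make_ancestor(12, n_linear = 2, n_circular = 1)
#' @export
make_ancestor <- function(n_genes, n_linear = 0L, n_circular = 1L,
                          name = "ancestor") {
  n_chr <- n_linear + n_circular
  if (n_chr < 1L) stop("need at least one chromosome")
  if (n_genes < n_chr) stop("fewer genes than chromosomes: partition infeasible")
  families <- paste0("g", seq_len(n_genes))
  signs <- sample(c(-1L, 1L), n_genes, replace = TRUE)
  ids <- sample.int(n_genes) * signs
  # near-equal block sizes, deterministic given the draw order
  bounds <- round(seq(0, n_genes, length.out = n_chr + 1L))
  chrs <- lapply(seq_len(n_chr),
                 function(i) ids[(bounds[i] + 1L):bounds[i + 1L]])
  circular <- c(rep(FALSE, n_linear), rep(TRUE, n_circular))
  validate_genome(new_genome(chrs, circular, families, name))
}

#' Apply seed duplication events to create a reference with duplicates
#'
#' Applies `n_events` random segmental duplications (segment length uniform
#' on `1..L_max`, start position and insertion site uniform over the genome)
#' to `g`.  Used to turn a duplicate-free ancestor into the reference genome
#' `G` carrying some initially duplicated genes.
#'
#' @param g A `genome`.
#' @param n_events Number of duplication events (default 10).
#' @param L_max Maximum duplicated-segment length (default 10).
#' @return The duplicated `genome`.
#' @export
seed_duplications <- function(g, n_events = 10L, L_max = 10L) {
  validate_genome(g)
  for (i in seq_len(n_events)) g <- .random_duplication(g, L_max)$genome
  g
}

# ---- reference summary -----------------------------------------------------

#' Precompute the reference-genome summary used by [genome_vector()]
#'
#' Stores the set of adjacency types and telomere types of the reference
#' genome `G` (as canonical numeric keys) together with its family table, so
#' that vectors of many evolved genomes can be computed against `G` without
#' re-deriving its multisets.
#'
#' @param g The reference `genome` `G`.
#' @return An object of class `genome_ref`.
#' @export
genome_ref <- function(g) {
  validate_genome(g)
  k <- .site_keys(g)
  structure(list(genome = g,
                 families = g$families,
                 adj_types = sort(unique(k$adj)),
                 tel_types = sort(unique(k$tel))),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref '%s': %d adjacency types, %d telomere types>\n",
              x$genome$name, length(x$adj_types), length(x$tel_types)))
  invisible(x)
}
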