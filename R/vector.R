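# map a genome's family ids into a shared family universe and compute its
# adjacency/telomere keys there
.keys_in_universe <- function(g, universe) {
  map <- match(g$families, universe)
  if (anyNA(map)) stop("family missing from universe")
  g2 <- g
  g2$families <- universe
  g2$chrs <- lapply(g$chrs, function(v) sign(v) * map[abs(v)])
  .site_keys(g2)
}

#' Summary vector of a genome relative to a reference
#'
#' Computes `V_G(G*)`, the copy-number summary of genome `G*` with respect
#' to the reference genome `G`:
#' \describe{
#'   \item{`SG[i]`}{number of gene copies whose family has exactly `i`
#'     copies in `G*` (instance counting: a family with `i` copies
#'     contributes `i`), for `i = 1..C`;}
#'   \item{`SA[i]`}{number of adjacency instances whose adjacency type has
#'     exactly `i` copies in `G*` and also occurs in `G`;}
#'   \item{`DA`}{number of adjacency instances in `G*` whose type does not
#'     occur in `G`;}
#'   \item{`ST`, `DT`}{number of telomere instances in `G*` whose type
#'     does / does not occur in `G`.}
#' }
#' Multiplicities above the copy-number cap `C` are accumulated in class
#' `C` (a condition of class `truedist_cap_warning` is signalled).  The
#' identities `sum(SG) = N*` and `sum(SA) + DA + ST + DT = N* + l*` always
#' hold.
#'
#' @param ref A [genome_ref()] (or a `genome`, coerced on the fly).
#' @param g_star The genome to summarise.
#' @param C Copy-number cap (default 10).
#' @return An object of class `genome_vector` with fields `SG`, `SA`
#'   (length-`C` numeric vectors), `DA`, `ST`, `DT`, `N`, `l`, `C`.
#' @examples
#' g <- genome(list(c("+a", "+b", "-c", "+a", "+b", "-d", "+a"),
#'                  c("+e", "-f")),
#'             circular = c(FALSE, TRUE), name = "G")
#' genome_vector(genome_ref(g), g, C = 10)
#' @export
genome_vector <- function(ref, g_star, C = 10L) {
  if (inherits(ref, "genome")) ref <- genome_ref(ref)
  stopifnot(inherits(ref, "genome_ref"), C >= 1L)
  validate_genome(g_star)
  C <- as.integer(C)

  if (identical(g_star$families, ref$families)) {
    ks <- .site_keys(g_star)
    ref_adj <- ref$adj_types
    ref_tel <- ref$tel_types
    fam_ids <- abs(unlist(g_star$chrs, use.names = FALSE))
    n_universe <- length(ref$families)
  } else {
    universe <- union(ref$families, g_star$families)
    ks <- .keys_in_universe(g_star, universe)
    rk <- .keys_in_universe(ref$genome, universe)
    ref_adj <- sort(unique(rk$adj))
    ref_tel <- sort(unique(rk$tel))
    if (!any(g_star$families %in% ref$families))
      warning("genomes share no gene family; every adjacency is distinct",
              call. = FALSE)
    fam_ids <- match(g_star$families, universe)[
      abs(unlist(g_star$chrs, use.names = FALSE))]
    n_universe <- length(universe)
  }

  # adjacency copy-number classes (instance counting)
  uks <- unique(ks$adj)
  m <- match(ks$adj, uks)
  type_count <- tabulate(m, length(uks))
  inst_count <- type_count[m]
  shared_type <- uks %in% ref_adj
  shared_inst <- shared_type[m]
  capped <- FALSE
  if (any(inst_count > C)) capped <- TRUE
  cls <- pmin(inst_count, C)
  SA <- tabulate(cls[shared_inst], C)
  DA <- sum(!shared_inst)

  ST <- sum(ks$tel %in% ref_tel)
  DT <- length(ks$tel) - ST

  fc <- tabulate(fam_ids, n_universe)
  fc <- fc[fc > 0L]
  if (any(fc > C)) capped <- TRUE
  gcls <- pmin(fc, C)
  SG <- vapply(seq_len(C), function(i) sum(fc[gcls == i]), numeric(1))

  if (capped)
    warning(warningCondition(
      sprintf("copy numbers above C = %d accumulated in class C", C),
      class = "truedist_cap_warning"))

  structure(list(SG = as.numeric(SG), SA = as.numeric(SA),
                 DA = as.numeric(DA), ST = as.numeric(ST),
                 DT = as.numeric(DT),
                 N = n_genes(g_star), l = n_linear(g_star), C = C),
            class = "genome_vector")
}

# flat coordinate vector (SG_1..SG_C, SA_1..SA_C, DA, ST, DT)
.vec_coords <- function(v) {
  c(stats::setNames(v$SG, paste0("SG", seq_along(v$SG))),
    stats::setNames(v$SA, paste0("SA", seq_along(v$SA))),
    DA = v$DA, ST = v$ST, DT = v$DT)
}

#' @export
print.genome_vector <- function(x, ...) {
  cat(sprintf("<genome_vector: N*=%g l*=%g C=%d>\n", x$N, x$l, x$C))
  print(.vec_coords(x))
  invisible(x)
}

#' 1-norm distance between two summary vectors
#'
#' Sum of absolute coordinate differences over
#' `(SG_1..SG_C, SA_1..SA_C, DA, ST, DT)`.  This is the objective the
#' distance estimator minimises over the expected-vector trajectory.
#'
#' @param u,v `genome_vector` or `expected_vector` objects with the same
#'   cap `C`.
#' @return Non-negative numeric scalar.
#' @export
l1_distance <- function(u, v) {
  if (u$C != v$C) stop("vectors have different copy-number caps")
  sum(abs(.vec_coords(u) - .vec_coords(v)))
}

#' Coerce a genome vector to a (real-valued) expected vector
#'
#' @param v A `genome_vector` (or `expected_vector`, returned unchanged).
#' @return An `expected_vector` carrying the same coordinates plus the real
#'   gene count `N` and linear-chromosome count `l`.
#' @export
as_expected_vector <- function(v) {
  if (inherits(v, "expected_vector")) return(v)
  stopifnot(inherits(v, "genome_vector"))
  structure(list(SG = as.numeric(v$SG), SA = as.numeric(v$SA),
                 DA = as.numeric(v$DA), ST = as.numeric(v$ST),
                 DT = as.numeric(v$DT),
                 N = as.numeric(v$N), l = as.numeric(v$l), C = v$C),
            class = "expected_vector")
}

#' @export
print.expected_vector <- function(x, ...) {
  cat(sprintf("<expected_vector: N=%0.2f l=%0.2f C=%d>\n", x$N, x$l, x$C))
  print(round(.vec_coords(x), 3))
  invisible(x)
}
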