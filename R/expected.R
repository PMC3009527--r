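# ---------------------------------------------------------------------------
# One-step expectation recursions for the summary vector.
#
# Each operator takes the current expected vector, identifies it with the
# actual vector of the current genome, and returns the expected vector after
# one event of its category.  The class flows follow instance counting:
# destroying one instance of an adjacency (or gene family) type with exactly
# i copies moves all i instances out of class i and i-1 instances into class
# i-1.  Newly created adjacencies and telomeres are booked as distinct
# (absent from the reference); the expected incidental re-creation of
# reference types is O(C^2/N) per rearrangement or duplication and is
# deliberately omitted, while the loss step carries an explicit recoverable
# shared-adjacency correction (RSA below), because deleting a recently
# duplicated copy frequently restores the very adjacency its insertion
# broke.
# ---------------------------------------------------------------------------

#' Auxiliary state of the loss recursion
#'
#' The loss update needs two quantities that are not functions of the
#' summary vector alone and are therefore carried as auxiliary running
#' state:
#' \describe{
#'   \item{`g1`}{the number of deletable gene instances (family copy number
#'     >= 2) flanking shared adjacencies of multiplicity 1, counted with
#'     incidence multiplicity (each adjacency has two flank slots);}
#'   \item{`R_lo`, `R_hi`}{aging chains over remaining-copy length
#'     `j = 1..L_max`: `R_lo[j] + R_hi[j]` approximates the number of
#'     insertion contexts -- a duplicated segment spliced into a shared
#'     adjacency -- with exactly `j` copy genes left.  Deleting the last
#'     remaining gene of such a context re-creates the broken shared
#'     adjacency, so `R_lo[1] + R_hi[1]` is the count of gene instances
#'     whose deletion recovers a shared adjacency right now.  The `hi`
#'     chain holds contexts whose broken type still has a surviving copy,
#'     so recovery promotes the type from class 1 to class 2 instead of
#'     re-entering class 1.}
#' }
#' At a concrete genome the immediately recoverable count (`R[1]`, split
#' into `lo`/`hi`) is computed exactly by enumerating deletable genes and
#' testing the adjacency their deletion would join; longer contexts start
#' at zero and are populated by the mean-field dynamics inside
#' [expected_step()].
#'
#' @param ref A [genome_ref()].
#' @param g The genome to measure; defaults to the reference genome itself
#'   (the trajectory's starting point).
#' @param L_max Maximum duplicated-segment length (chain length).
#' @return An object of class `loss_aux` with fields `g1`, `R_lo`, `R_hi`.
#' @export
loss_aux <- function(ref, g = ref$genome, L_max = 10L) {
  stopifnot(inherits(ref, "genome_ref"))
  same <- identical(g$families, ref$families)
  if (same) {
    keyfun <- .site_keys
    adj_types <- ref$adj_types
  } else {
    universe <- union(ref$families, g$families)
    keyfun <- function(x) .keys_in_universe(x, universe)
    adj_types <- sort(unique(.keys_in_universe(ref$genome, universe)$adj))
    g <- local({
      map <- match(g$families, universe)
      new_genome(lapply(g$chrs, function(v) sign(v) * map[abs(v)]),
                 g$circular, universe, g$name)
    })
  }
  fc <- .family_counts(g)
  ks <- .site_keys(g)
  uks <- unique(ks$adj)
  m <- match(ks$adj, uks)
  type_mult <- tabulate(m, length(uks))
  mult <- type_mult[m]
  shared <- (uks %in% adj_types)[m]

  B <- .ext_base(length(g$families))
  g1 <- 0
  RSA <- 0
  RSA_hi <- 0
  pos0 <- 0L
  for (ci in seq_along(g$chrs)) {
    v <- g$chrs[[ci]]
    n <- length(v)
    f <- abs(v)
    e <- .chr_exts(v)
    n_adj <- if (g$circular[ci]) n else n - 1L
    sel <- if (n_adj > 0L) pos0 + seq_len(n_adj) else integer()
    pos0 <- pos0 + n_adj

    # flanking families of this chromosome's adjacency instances, in the
    # same order .site_keys emits them
    if (n_adj > 0L) {
      if (g$circular[ci]) {
        lf <- f
        rf <- f[c(seq_len(n)[-1L], 1L)]
      } else {
        lf <- f[-n]
        rf <- f[-1L]
      }
      hit <- mult[sel] == 1L & shared[sel]
      if (any(hit))
        g1 <- g1 + sum(fc[lf[hit]] >= 2L) + sum(fc[rf[hit]] >= 2L)
    }

    # recoverable deletions: the adjacency joining the deleted gene's
    # neighbours, with its flanking adjacency keys (NA at telomeres)
    del_ok <- fc[f] >= 2L
    if (!any(del_ok) || n_adj == 0L) next
    kadj <- ks$adj[sel]
    join <- flank_l <- flank_r <- rep(NA_real_, n)
    if (g$circular[ci]) {
      prev <- c(n, seq_len(n - 1L))
      flank_l <- kadj[prev]
      flank_r <- kadj
      if (n == 2L) {
        # deleting one gene leaves a one-gene circle with its self-adjacency
        join[1L] <- pmin(e$left[2L], e$right[2L]) * B + pmax(e$left[2L], e$right[2L])
        join[2L] <- pmin(e$left[1L], e$right[1L]) * B + pmax(e$left[1L], e$right[1L])
      } else {
        nxt <- c(seq_len(n)[-1L], 1L)
        a <- e$right[prev]; b <- e$left[nxt]
        join <- pmin(a, b) * B + pmax(a, b)
      }
    } else {
      if (n >= 2L) {
        flank_l[2:n] <- kadj
        flank_r[seq_len(n - 1L)] <- kadj
      }
      if (n >= 3L) {
        mid <- 2:(n - 1L)
        a <- e$right[mid - 1L]; b <- e$left[mid + 1L]
        join[mid] <- pmin(a, b) * B + pmax(a, b)
      }
    }
    ok <- which(del_ok & !is.na(join) & join %in% adj_types)
    if (length(ok)) {
      RSA <- RSA + length(ok)
      # surviving copies of the joined type, discounting the two flanking
      # instances this very deletion destroys (the tandem case)
      jt <- match(join[ok], uks)
      m_cur <- ifelse(is.na(jt), 0, type_mult[jt])
      m_eff <- m_cur -
        (!is.na(flank_l[ok]) & flank_l[ok] == join[ok]) -
        (!is.na(flank_r[ok]) & flank_r[ok] == join[ok])
      RSA_hi <- RSA_hi + sum(m_eff >= 1)
    }
  }
  R_lo <- R_hi <- numeric(L_max)
  R_lo[1L] <- RSA - RSA_hi
  R_hi[1L] <- RSA_hi
  structure(list(g1 = as.numeric(g1), R_lo = R_lo, R_hi = R_hi),
            class = "loss_aux")
}

#' @export
print.loss_aux <- function(x, ...) {
  cat(sprintf("<loss_aux: g1=%.3f recoverable now=%.3f (hi %.3f), in erosion=%.3f>\n",
              x$g1, x$R_lo[1L] + x$R_hi[1L], x$R_hi[1L],
              sum(x$R_lo[-1L]) + sum(x$R_hi[-1L])))
  invisible(x)
}

.new_expected <- function(SG, SA, DA, ST, DT, N, l, C) {
  structure(list(SG = SG, SA = SA, DA = DA, ST = ST, DT = DT,
                 N = N, l = l, C = C),
            class = "expected_vector")
}

#' Expected vector after one rearrangement
#'
#' Two sites are drawn with replacement, uniformly over the `N + l`
#' adjacency/telomere instances, and replaced by new ones.  Gene
#' coordinates are exactly unchanged.  For each shared-adjacency class
#' `i`, a single destroyed instance moves `i` instances out of class `i`
#' and `i - 1` into class `i - 1`; two instances of the same type move the
#' type to class `i - 2`; two instances of different class-`i` types
#' double the single-type flow.  Newly created adjacencies/telomeres are
#' booked as distinct, which neglects an `O(C^2/N)` re-creation term.
#'
#' @param v An `expected_vector` (or `genome_vector`, coerced).
#' @param C Copy-number cap; defaults to `v$C`.
#' @return The expected vector after one rearrangement.
#' @export
expected_after_rearrangement <- function(v, C = v$C) {
  v <- as_expected_vector(v)
  SA <- v$SA
  A <- sum(SA) + v$DA
  TL <- v$ST + v$DT
  T <- v$N + v$l
  if (T <= 0) return(v)
  i <- seq_len(C)
  T2 <- T * T
  h1 <- (2 * SA * (T - SA) + SA) / T2          # one instance of a class-i type destroyed
  h2d <- pmax(SA * (SA - i), 0) / T2           # two different class-i types destroyed
  h2s <- SA * (i - 1) / T2                     # two instances of one class-i type destroyed
  up1 <- c(h1[-1L] + 2 * h2d[-1L], 0)          # inflow from class i+1
  up2 <- if (C >= 3L) c(h2s[-(1:2)], 0, 0) else rep(0, C)  # inflow from class i+2
  SA_new <- SA - i * (h1 + h2s + 2 * h2d) + i * up1 + i * up2
  DA_new <- v$DA - (2 * v$DA / T - v$DA / T2) +
    (2 * (A * A - A) + 2 * A * TL + TL * TL) / T2
  ST_new <- v$ST * (1 - 2 / T)
  DT_new <- v$DT * (1 - 2 / T) + (2 * A + 2 * A * TL) / T2
  .new_expected(v$SG, SA_new, DA_new, ST_new, DT_new,
                v$N, (ST_new + DT_new) / 2, C)
}

#' Expected vector after one duplication
#'
#' With `L = (L_max + 1) / 2` the expected segment length, the expected
#' number of class-`i` gene instances inside the duplicated segment is
#' `L * SG_i / N` and of class-`i` internal shared adjacencies
#' `(L - 1) * SA_i / (N - l)`; each copied instance promotes its family or
#' adjacency type from class `i` to `i + 1` (class `C` absorbs overflow).
#' The insertion breaks one uniformly chosen adjacency/telomere instance
#' (probability `1/(N + l)` per site) and adds distinct boundary
#' adjacencies; the expected gene count increases by `L`.  This assumes no
#' two duplicate genes or adjacencies lie within one segment and again
#' neglects the `O(C^2/N)` re-creation term.
#'
#' @param v An `expected_vector` (or `genome_vector`, coerced).
#' @param L_max Maximum duplicated-segment length.
#' @param C Copy-number cap; defaults to `v$C`.
#' @return The expected vector after one duplication.
#' @export
expected_after_duplication <- function(v, L_max, C = v$C) {
  v <- as_expected_vector(v)
  T <- v$N + v$l
  if (T <= 0 || v$N <= 0) return(v)
  # expected realised segment length: the drawn length, minus the expected
  # truncation when the start falls within L_max - 1 genes of a linear
  # chromosome end (start uniform over N, overshoot summed in closed form)
  L <- (L_max + 1) / 2 - v$l * (L_max^2 - 1) / (6 * v$N)
  A <- sum(v$SA) + v$DA
  TL <- v$ST + v$DT
  i <- seq_len(C)

  # segment-internal gene promotions
  gp <- L * v$SG / v$N
  SG_new <- v$SG - i * gp + i * c(0, gp[-C])
  SG_new[C] <- v$SG[C] + C * (if (C >= 2L) gp[C - 1L] else 0) + gp[C]

  # segment-internal adjacency promotions
  ap <- if (A > 0) (L - 1) * v$SA / A else rep(0, C)
  SA_new <- v$SA - i * ap + i * c(0, ap[-C])
  SA_new[C] <- v$SA[C] + C * (if (C >= 2L) ap[C - 1L] else 0) + ap[C]

  # insertion breaks one uniformly chosen site
  br_out <- i * v$SA / T
  br_in <- i * c(v$SA[-1L] / T, 0)
  SA_new <- SA_new - br_out + br_in

  DA_new <- v$DA + (if (A > 0) (L - 1) * v$DA / A else 0) -
    v$DA / T + (2 * A + TL) / T
  ST_new <- v$ST * (1 - 1 / T)
  DT_new <- v$DT * (1 - 1 / T) + TL / T
  .new_expected(SG_new, SA_new, DA_new, ST_new, DT_new,
                v$N + L, (ST_new + DT_new) / 2, C)
}

#' Expected vector after one gene loss
#'
#' One gene whose family has at least two copies is uniformly selected and
#' deleted, out of `D = N - SG_1` candidates.  A class-`i` family is hit
#' with probability `SG_i / D`, moving `i` instances out of class `i` and
#' `i - 1` into class `i - 1`.  For shared adjacencies of class `i >= 2`
#' the expected number of instances destroyed per deletion is approximated
#' by the flank bound `2 SA_i / D` (each such adjacency flanks two
#' deletable genes); class 1 uses the running flank count `aux$g1`.
#' Telomeres are frozen.  The adjacency joining the deleted gene's
#' neighbours re-creates a shared adjacency with probability `RSA / D`
#' (credited to class 1) and is otherwise distinct.
#'
#' @param v An `expected_vector` (or `genome_vector`, coerced).
#' @param aux A [loss_aux()] state.
#' @param C Copy-number cap; defaults to `v$C`.
#' @return A list with the updated `vector` and `aux`.
#' @export
expected_after_loss <- function(v, aux, C = v$C) {
  v <- as_expected_vector(v)
  D <- v$N - v$SG[1L]
  if (D < 1) stop("no deletable gene mass: loss step infeasible")
  i <- seq_len(C)

  ghit <- v$SG / D
  ghit[1L] <- 0
  SG_new <- v$SG - i * ghit + i * c(ghit[-1L], 0)

  ahit <- 2 * v$SA / D
  ahit[1L] <- min(aux$g1, 2 * v$SA[1L]) / D
  s_hit <- sum(ahit)
  if (s_hit > 2) ahit <- ahit * (2 / s_hit)    # at most two flanks per deletion
  SA_new <- v$SA - i * ahit + i * c(ahit[-1L], 0)

  # re-created shared adjacency: class-1 re-entry, or a 1 -> 2 promotion
  # when the re-created type still has a surviving copy
  r_tot <- min((aux$R_lo[1L] + aux$R_hi[1L]) / D, 1)
  r_hi <- min(aux$R_hi[1L] / D, r_tot)
  SA_new[1L] <- SA_new[1L] + (r_tot - r_hi) - r_hi
  if (C >= 2L) SA_new[2L] <- SA_new[2L] + 2 * r_hi
  DA_new <- v$DA - max(0, 2 - sum(ahit)) + (1 - r_tot)

  out <- .new_expected(SG_new, SA_new, DA_new, v$ST, v$DT,
                       v$N - 1, v$l, C)
  aux_new <- .aux_after_loss(v, out, aux)
  list(vector = out, aux = aux_new)
}

# ---- mean-field evolution of the auxiliary state ---------------------------
#
# g1 incidences scale with the surviving class-1 shared adjacencies; new
# incidences appear when previously single-copy genes flanking class-1
# shared adjacencies gain a copy (duplication) and disappear when a
# two-copy family drops to one (loss).  The recoverable-context chains
# age as follows.  A duplication creates one context of length
# `j ~ U{1..L_max}` when its insertion breaks a shared adjacency
# (probability SA_tot / T per event, split lo/hi by the broken class);
# it also destroys existing contexts it splices into.  A loss erodes a
# length-j context with probability ~ j/D per context (one of its j copy
# genes is deleted), moving it to length j - 1; eroding a length-1
# context is the recovery itself, consuming it.  A rearrangement whose
# cut lands among the j + 1 spanning adjacencies of a context separates
# the flanks and destroys it.

.scale_g1 <- function(aux_g1, SA1_old, SA1_new) {
  if (SA1_old <= 0) 0 else aux_g1 * (SA1_new / SA1_old)
}

.clamp_aux <- function(g1, R_lo, R_hi, SA1, D) {
  R_lo <- pmax(R_lo, 0)
  R_hi <- pmax(R_hi, 0)
  tot1 <- R_lo[1L] + R_hi[1L]
  if (tot1 > max(D, 0) && tot1 > 0) {
    sc <- max(D, 0) / tot1
    R_lo[1L] <- R_lo[1L] * sc
    R_hi[1L] <- R_hi[1L] * sc
  }
  structure(list(g1 = min(max(g1, 0), 2 * SA1), R_lo = R_lo, R_hi = R_hi),
            class = "loss_aux")
}

# deletable-flank incidences arriving with class-2 -> class-1 type
# demotions: the surviving instance keeps one deletable flank for sure
# and a second when the hit family had three or more copies
.g1_demotion_gain <- function(v_old, rate_inst) {
  D <- v_old$N - v_old$SG[1L]
  if (D < 1 || v_old$C < 2L) return(0)
  w <- max(0, 1 - v_old$SG[2L] / D)
  rate_inst * (1 + w)
}

.aux_after_rearrangement <- function(v_old, v_new, aux) {
  T <- v_old$N + v_old$l
  g1 <- .scale_g1(aux$g1, v_old$SA[1L], v_new$SA[1L])
  if (v_old$C >= 2L && T > 0) {
    SA2 <- v_old$SA[2L]
    SA3 <- if (v_old$C >= 3L) v_old$SA[3L] else 0
    rate <- ((2 * SA2 * (T - SA2) + SA2) + 2 * max(SA2^2 - 2 * SA2, 0) +
               2 * SA3) / T^2
    g1 <- g1 + .g1_demotion_gain(v_old, rate)
  }
  j <- seq_along(aux$R_lo)
  dec <- pmax(0, 1 - 2 * (j + 1) / T)
  .clamp_aux(g1, aux$R_lo * dec, aux$R_hi * dec,
             v_new$SA[1L], v_new$N - v_new$SG[1L])
}

.aux_after_duplication <- function(v_old, v_new, aux, L_max) {
  T <- v_old$N + v_old$l
  A <- sum(v_old$SA) + v_old$DA
  L <- (L_max + 1) / 2
  g1 <- .scale_g1(aux$g1, v_old$SA[1L], v_new$SA[1L])
  # only the two segment-boundary genes gain a countable flank: interior
  # source genes have their flanking adjacencies duplicated along with
  # them, promoting those types out of the multiplicity-1 class
  if (v_old$N > 0 && A > 0)
    g1 <- g1 + 2 * (v_old$SG[1L] / v_old$N) * (v_old$SA[1L] / A)
  if (v_old$C >= 2L && T > 0)
    g1 <- g1 + .g1_demotion_gain(v_old, v_old$SA[2L] / T)
  j <- seq_along(aux$R_lo)
  dec <- pmax(0, 1 - (j + 1) / T)
  gain_lo <- (1 / L_max) * (v_old$SA[1L] / T)
  gain_hi <- (1 / L_max) * ((sum(v_old$SA) - v_old$SA[1L]) / T)
  .clamp_aux(g1,
             aux$R_lo * dec + gain_lo,
             aux$R_hi * dec + gain_hi,
             v_new$SA[1L], v_new$N - v_new$SG[1L])
}

.aux_after_loss <- function(v_old, v_new, aux) {
  D <- v_old$N - v_old$SG[1L]
  A <- sum(v_old$SA) + v_old$DA
  SA1 <- v_old$SA[1L]
  g1 <- aux$g1
  if (D >= 1) {
    # incidence bookkeeping for one deletion: a class-1 shared adjacency
    # destroyed through its deletable flank (rate g1/D) takes that flank
    # plus, with probability ~ g1/(2 SA1), a second deletable one; a
    # class-2 type dropping to class 1 (rate 2 SA2/D) contributes its
    # surviving instance's still-deletable flank; a family falling from
    # two copies to one (rate SG2/D) retires the survivor's average share
    # g1/D of slots
    q <- if (SA1 > 0) min(g1 / (2 * SA1), 1) else 0
    g1 <- g1 - (aux$g1 / D) * (1 + q)
    if (v_old$C >= 2L) {
      # the surviving instance keeps one deletable flank for sure and a
      # second one when the hit family had three or more copies
      w <- max(0, 1 - v_old$SG[2L] / D)
      g1 <- g1 + (2 * v_old$SA[2L] / D) * (1 + w) -
        (v_old$SG[2L] / D) * (aux$g1 / D)
    }
  }
  R_lo <- aux$R_lo; R_hi <- aux$R_hi
  if (D >= 1) {
    j <- seq_along(R_lo)
    out_lo <- pmin(j * R_lo / D, R_lo)
    out_hi <- pmin(j * R_hi / D, R_hi)
    R_lo <- R_lo - out_lo + c(out_lo[-1L], 0)
    R_hi <- R_hi - out_hi + c(out_hi[-1L], 0)
  }
  .clamp_aux(g1, R_lo, R_hi, v_new$SA[1L], v_new$N - v_new$SG[1L])
}

#' One step of the expectation recursion
#'
#' Convex combination, with weights `(p_r, p_d, p_l)`, of the three one-step
#' operators applied to the same input vector.  When the expected number of
#' deletable genes is below one the loss weight is renormalised onto the
#' feasible categories, mirroring the simulator's redraw rule.  Coordinates
#' are clamped at zero afterwards (the approximations can undershoot near
#' saturation).
#'
#' @param v An `expected_vector` (or `genome_vector`, coerced).
#' @param aux A [loss_aux()] state.
#' @param params An [event_params()] object.
#' @param C Copy-number cap; defaults to `v$C`.
#' @return A list with the updated `vector` and `aux`.
#' @export
expected_step <- function(v, aux, params, C = v$C) {
  v <- as_expected_vector(v)
  p_r <- params$p_r; p_d <- params$p_d; p_l <- params$p_l
  D <- v$N - v$SG[1L]
  if (p_l > 0 && D < 1) {
    tot <- p_r + p_d
    if (tot <= 0) {
      # loss-only model with nothing left to delete: no event can occur,
      # so the expected vector is absorbed at its current state
      return(list(vector = v, aux = aux))
    }
    p_r <- p_r / tot; p_d <- p_d / tot; p_l <- 0
  }
  parts_v <- list(); parts_a <- list(); w <- numeric()
  if (p_r > 0) {
    vr <- expected_after_rearrangement(v, C)
    parts_v <- c(parts_v, list(vr))
    parts_a <- c(parts_a, list(.aux_after_rearrangement(v, vr, aux)))
    w <- c(w, p_r)
  }
  if (p_d > 0) {
    vd <- expected_after_duplication(v, params$L_max, C)
    parts_v <- c(parts_v, list(vd))
    parts_a <- c(parts_a, list(.aux_after_duplication(v, vd, aux, params$L_max)))
    w <- c(w, p_d)
  }
  if (p_l > 0) {
    lo <- expected_after_loss(v, aux, C)
    parts_v <- c(parts_v, list(lo$vector))
    parts_a <- c(parts_a, list(lo$aux))
    w <- c(w, p_l)
  }
  mix <- function(field, idx = NULL) {
    s <- 0
    for (j in seq_along(w))
      s <- s + w[j] * (if (is.null(idx)) parts_v[[j]][[field]]
                       else parts_v[[j]][[field]])
    s
  }
  SG <- pmax(mix("SG"), 0)
  SA <- pmax(mix("SA"), 0)
  DA <- max(mix("DA"), 0)
  ST <- max(mix("ST"), 0)
  DT <- max(mix("DT"), 0)
  N <- mix("N")
  g1 <- 0; R_lo <- 0 * aux$R_lo; R_hi <- R_lo
  for (j in seq_along(w)) {
    g1 <- g1 + w[j] * parts_a[[j]]$g1
    R_lo <- R_lo + w[j] * parts_a[[j]]$R_lo
    R_hi <- R_hi + w[j] * parts_a[[j]]$R_hi
  }
  list(vector = .new_expected(SG, SA, DA, ST, DT, N, (ST + DT) / 2, C),
       aux = structure(list(g1 = g1, R_lo = R_lo, R_hi = R_hi),
                       class = "loss_aux"))
}

#' Expected-vector trajectory
#'
#' Iterates [expected_step()] `k_max` times from the reference's
#' self-vector `V_G(G)`, identifying at every step the expectation with the
#' running vector.  The cost is `O(k_max * C)`: each step touches only the
#' `2C + 3` coordinates.
#'
#' @param ref A [genome_ref()] (the auxiliary loss state is then initialised
#'   exactly from the reference genome), or a `genome_vector`/
#'   `expected_vector` start point combined with an explicit `aux`.
#' @param k_max Number of steps.
#' @param params An [event_params()] object.
#' @param C Copy-number cap (default 10).
#' @param aux Optional [loss_aux()] start state (required when `ref` is a
#'   bare vector).
#' @return An object of class `expected_trajectory`: a list with `coords`
#'   (a `(k_max + 1) x (2C + 3)` matrix, row `k + 1` holding the expected
#'   coordinates after `k` events), `N` (expected gene counts), `params`
#'   and `C`.
#' @examples
#' set.seed(7)
#' G <- seed_duplications(make_ancestor(60), n_events = 3, L_max = 5)
#' tr <- expected_trajectory(genome_ref(G), 50, event_params(0.2, 0.6))
#' tr$coords[c(1, 51), ]
#' @export
expected_trajectory <- function(ref, k_max, params, C = 10L, aux = NULL) {
  if (inherits(ref, "genome_ref")) {
    v <- as_expected_vector(genome_vector(ref, ref$genome, C))
    if (is.null(aux)) aux <- loss_aux(ref, L_max = params$L_max)
  } else {
    v <- as_expected_vector(ref)
    C <- v$C
    if (is.null(aux))
      stop("supply `aux` (a loss_aux state) when starting from a bare vector")
  }
  coords <- matrix(0, nrow = k_max + 1L, ncol = 2L * C + 3L)
  colnames(coords) <- names(.vec_coords(v))
  Ns <- numeric(k_max + 1L)
  coords[1L, ] <- .vec_coords(v)
  Ns[1L] <- v$N
  for (k in seq_len(k_max)) {
    st <- expected_step(v, aux, params, C)
    v <- st$vector
    aux <- st$aux
    coords[k + 1L, ] <- .vec_coords(v)
    Ns[k + 1L] <- v$N
  }
  structure(list(coords = coords, N = Ns, params = params, C = C),
            class = "expected_trajectory")
}

#' @export
print.expected_trajectory <- function(x, ...) {
  cat(sprintf("<expected_trajectory: %d steps, C=%d, p_r=%.2f p_d=%.2f p_l=%.2f>\n",
              nrow(x$coords) - 1L, x$C, x$params$p_r, x$params$p_d,
              x$params$p_l))
  invisible(x)
}
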