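# distances from an observed vector to every row of a trajectory
.traj_distances <- function(vF, traj) {
  obs <- .vec_coords(vF)
  rowSums(abs(sweep(traj$coords, 2L, obs)))
}

.new_estimate <- function(k_hat, p_d, p_l, objective, k_max, C) {
  p_r <- max(0, 1 - p_d - p_l)
  structure(list(k_hat = as.integer(k_hat), p_d_hat = p_d, p_l_hat = p_l,
                 objective = objective,
                 per_type = c(rearrangement = k_hat * p_r,
                              duplication = k_hat * p_d,
                              loss = k_hat * p_l),
                 k_max = k_max, C = C),
            class = "truedist_estimate")
}

#' @export
print.truedist_estimate <- function(x, ...) {
  cat(sprintf("<estimate: k_hat=%d (p_d=%.3f, p_l=%.3f), objective=%.3f>\n",
              x$k_hat, x$p_d_hat, x$p_l_hat, x$objective))
  cat(sprintf("  expected per type: %.1f rearrangements, %.1f duplications, %.1f losses\n",
              x$per_type[1L], x$per_type[2L], x$per_type[3L]))
  invisible(x)
}

# estimate against a precomputed trajectory (the cache used by experiments)
.estimate_from_trajectory <- function(vF, traj) {
  d <- .traj_distances(vF, traj)
  k_hat <- which.min(d) - 1L
  .new_estimate(k_hat, traj$params$p_d, traj$params$p_l, d[k_hat + 1L],
                nrow(traj$coords) - 1L, traj$C)
}

#' Estimate the true number of evolutionary events (known parameters)
#'
#' Computes the summary vector `V_G(F)` of the final genome relative to the
#' reference `G`, iterates the expectation recursion from `V_G(G)` for
#' `k_max` steps under the given parameters, and returns the smallest `k`
#' whose predicted expected vector minimises the 1-norm distance to
#' `V_G(F)`.  The estimate counts actual events -- the true evolutionary
#' distance -- not the (smaller) edit distance.
#'
#' @param G The reference `genome` (or a [genome_ref()]).
#' @param F The final `genome`.
#' @param params An [event_params()] object (the true or assumed
#'   `p_d`, `p_l`, `L_max`).
#' @param k_max Search bound on the event count; defaults to 4 times the
#'   gene count of `G`.
#' @param C Copy-number cap (default 10).
#' @return An object of class `truedist_estimate` with fields `k_hat`,
#'   `p_d_hat`, `p_l_hat`, `objective` (the minimised 1-norm), `per_type`
#'   (expected event counts per category, `k_hat` times the category
#'   probabilities) and the search settings.
#' @examples
#' set.seed(11)
#' G <- seed_duplications(make_ancestor(100), n_events = 4, L_max = 5)
#' F <- evolve(G, 40, event_params(0.2, 0.6), log = FALSE)$genome
#' estimate_k(G, F, event_params(0.2, 0.6))
#' @export
estimate_k <- function(G, F, params, k_max = NULL, C = 10L) {
  ref <- if (inherits(G, "genome_ref")) G else genome_ref(G)
  if (is.null(k_max)) k_max <- 4L * n_genes(ref$genome)
  traj <- expected_trajectory(ref, k_max, params, C)
  vF <- genome_vector(ref, F, C)
  .estimate_from_trajectory(vF, traj)
}

#' Parameter grid satisfying the robustness-mode constraints
#'
#' All `(p_d, p_l)` pairs on a regular grid of the given resolution with
#' `p_d < 4 * p_l` and `p_d + p_l <= 1`.
#'
#' @param resolution Grid step (default 0.01).
#' @return A data frame with columns `p_d` and `p_l`.
#' @export
parameter_grid <- function(resolution = 0.01) {
  stopifnot(resolution > 0, resolution <= 1)
  vals <- seq(0, 1, by = resolution)
  grid <- expand.grid(p_d = vals, p_l = vals, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$p_d < 4 * grid$p_l & grid$p_d + grid$p_l <= 1 + 1e-9, ]
  grid <- grid[order(grid$p_d, grid$p_l), ]
  rownames(grid) <- NULL
  grid
}

#' Precompute expected-vector trajectories over a parameter grid
#'
#' One trajectory per `(p_d, p_l)` pair, all from the same reference.  The
#' cache lets many final genomes be scored against one reference without
#' re-iterating the recursion.
#'
#' @param ref A [genome_ref()] (or `genome`).
#' @param grid A data frame as returned by [parameter_grid()].
#' @param k_max Trajectory length.
#' @param C Copy-number cap.
#' @param L_max Maximum duplicated-segment length.
#' @return A list of `expected_trajectory` objects, one per grid row.
#' @export
grid_trajectories <- function(ref, grid, k_max, C = 10L, L_max = 10L) {
  if (inherits(ref, "genome")) ref <- genome_ref(ref)
  aux0 <- loss_aux(ref, L_max = L_max)
  v0 <- as_expected_vector(genome_vector(ref, ref$genome, C))
  lapply(seq_len(nrow(grid)), function(j) {
    expected_trajectory(v0, k_max,
                        event_params(grid$p_d[j], grid$p_l[j], L_max),
                        C = C, aux = aux0)
  })
}

#' Estimate the true number of events with unknown model parameters
#'
#' Enumerates `(p_d, p_l)` pairs on a grid (default 1% resolution,
#' constrained to `p_d < 4 p_l` and `p_d + p_l <= 1`), computes the
#' expected-vector trajectory for each pair, and minimises the 1-norm
#' distance jointly over `(k, p_d, p_l)`.  Ties are broken toward smaller
#' `k`, then smaller `p_d`, then smaller `p_l`.
#'
#' @param G The reference `genome` (or [genome_ref()]).
#' @param F The final `genome`.
#' @param L_max Maximum duplicated-segment length (default 10).
#' @param k_max Search bound; defaults to 4 times the gene count of `G`.
#' @param C Copy-number cap (default 10).
#' @param resolution Grid step (default 0.01).
#' @param trajectories Optional precomputed [grid_trajectories()] cache
#'   (must match `grid`).
#' @param grid Optional explicit parameter grid.
#' @return A `truedist_estimate` (see [estimate_k()]) whose `p_d_hat`,
#'   `p_l_hat` are the selected grid point.
#' @export
estimate_k_unknown_params <- function(G, F, L_max = 10L, k_max = NULL,
                                      C = 10L, resolution = 0.01,
                                      trajectories = NULL, grid = NULL) {
  ref <- if (inherits(G, "genome_ref")) G else genome_ref(G)
  if (is.null(k_max)) k_max <- 4L * n_genes(ref$genome)
  if (is.null(grid)) grid <- parameter_grid(resolution)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  if (is.null(trajectories))
    trajectories <- grid_trajectories(ref, grid, k_max, C, L_max)
  vF <- genome_vector(ref, F, C)
  best <- NULL
  for (j in seq_len(nrow(grid))) {
    d <- .traj_distances(vF, trajectories[[j]])
    k <- which.min(d) - 1L
    obj <- d[k + 1L]
    cand <- c(obj, k, grid$p_d[j], grid$p_l[j])
    if (is.null(best) || obj < best[1L] - 1e-12 ||
        (abs(obj - best[1L]) <= 1e-12 &&
         (k < best[2L] ||
          (k == best[2L] && (cand[3L] < best[3L] ||
                             (cand[3L] == best[3L] && cand[4L] < best[4L])))))) {
      best <- cand
    }
  }
  .new_estimate(best[2L], best[3L], best[4L], best[1L], k_max, C)
}

#' Integer per-category decomposition of an estimate
#'
#' Splits `k_hat` into rearrangement/duplication/loss counts by multiplying
#' with the category probabilities and rounding by largest remainder, so
#' the parts always sum to `k_hat`.
#'
#' @param result A `truedist_estimate`.
#' @return Named integer vector `(rearrangement, duplication, loss)`.
#' @export
decompose_events <- function(result) {
  stopifnot(inherits(result, "truedist_estimate"))
  raw <- result$per_type
  base <- floor(raw)
  deficit <- result$k_hat - sum(base)
  if (deficit > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(deficit)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(raw))
}
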