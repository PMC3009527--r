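# run `expr` with copy-number cap warnings muffled (expected in long
# simulations: class C absorbs the overflow by design)
.quiet_cap <- function(expr) {
  withCallingHandlers(expr,
    truedist_cap_warning = function(w) invokeRestart("muffleWarning"))
}

#' Configuration of a simulation experiment
#'
#' Bundles the generating conditions of one experiment: the ancestor's
#' size and chromosome structure, the seed duplications that create the
#' reference genome `G`, the event-model parameters, the true event counts
#' to probe, and the replicate budget.
#'
#' @param n_genes Ancestor gene count.
#' @param n_linear,n_circular Ancestor chromosome counts.
#' @param seed_dups Number of seed duplication events forming `G`
#'   (default 10).
#' @param L_max Maximum duplicated-segment length (default 10).
#' @param p_d,p_l Duplication and loss probabilities.
#' @param k_values True event counts to probe (default `0` to
#'   `2 * n_genes` in four steps).
#' @param replicates Number of independent evolution runs per experiment.
#' @param C Copy-number cap (default 10).
#' @param k_max_multiplier Search bound multiplier: the estimator scans
#'   `k` up to this multiple of the reference gene count (default 4).
#' @param seed RNG seed for the whole experiment.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_genes, n_linear = 0L, n_circular = 1L,
                              seed_dups = 10L, L_max = 10L,
                              p_d, p_l,
                              k_values = round(seq(0, 2 * n_genes,
                                                   length.out = 5L))[-1L],
                              replicates = 100L, C = 10L,
                              k_max_multiplier = 4L, seed = 1L) {
  stopifnot(replicates >= 1L, all(k_values >= 0))
  structure(list(n_genes = n_genes, n_linear = n_linear,
                 n_circular = n_circular, seed_dups = seed_dups,
                 L_max = L_max, p_d = p_d, p_l = p_l,
                 k_values = sort(unique(as.integer(k_values))),
                 replicates = as.integer(replicates), C = as.integer(C),
                 k_max_multiplier = k_max_multiplier,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config: %d genes (%dL+%dC), p_d=%.2f p_l=%.2f, k in {%s}, %d replicates, seed %d>\n",
              x$n_genes, x$n_linear, x$n_circular, x$p_d, x$p_l,
              paste(x$k_values, collapse = ", "), x$replicates, x$seed))
  invisible(x)
}

# build the reference genome G of a config (consumes RNG draws)
.build_reference <- function(cfg) {
  anc <- make_ancestor(cfg$n_genes, cfg$n_linear, cfg$n_circular)
  seed_duplications(anc, cfg$seed_dups, cfg$L_max)
}

#' Trajectory accuracy experiment
#'
#' Compares the analytic expected-vector trajectory with the Monte-Carlo
#' sample mean of `V_G(G^k)` over independent simulated runs, at each
#' probed `k`.
#'
#' @param cfg An [experiment_config()].
#' @return A data frame with one row per `(k, coordinate)`: the predicted
#'   expectation, the sample mean, their gap, and the Monte-Carlo standard
#'   error of the mean.  The configuration is attached as
#'   `attr(, "config")`.
#' @export
run_trajectory_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  G <- .build_reference(cfg)
  ref <- genome_ref(G)
  params <- event_params(cfg$p_d, cfg$p_l, cfg$L_max)
  ks <- cfg$k_values
  kmx <- max(ks)
  traj <- expected_trajectory(ref, kmx, params, cfg$C)
  nc <- 2L * cfg$C + 3L
  sums <- matrix(0, length(ks), nc)
  sq <- matrix(0, length(ks), nc)
  for (r in seq_len(cfg$replicates)) {
    g <- G
    prev <- 0L
    for (j in seq_along(ks)) {
      g <- evolve(g, ks[j] - prev, params, log = FALSE)$genome
      prev <- ks[j]
      x <- .quiet_cap(.vec_coords(genome_vector(ref, g, cfg$C)))
      sums[j, ] <- sums[j, ] + x
      sq[j, ] <- sq[j, ] + x * x
    }
  }
  mean_v <- sums / cfg$replicates
  se_v <- sqrt(pmax(sq / cfg$replicates - mean_v^2, 0) /
                 max(cfg$replicates - 1L, 1L))
  coord <- colnames(traj$coords)
  out <- data.frame(
    k = rep(ks, each = nc),
    coordinate = rep(coord, times = length(ks)),
    predicted = as.vector(t(traj$coords[ks + 1L, , drop = FALSE])),
    sample_mean = as.vector(t(mean_v)),
    mc_se = as.vector(t(se_v)))
  out$gap <- out$predicted - out$sample_mean
  attr(out, "config") <- cfg
  out
}

#' Estimator accuracy experiment
#'
#' Simulates `replicates` independent evolutions of the reference genome
#' and, at each probed true event count `k`, estimates the event count from
#' the evolved genome.  In `known` mode the generating `(p_d, p_l)` are
#' given to the estimator; in `grid` mode each run draws its generating
#' parameters uniformly from the 1%-resolution grid with `p_d < 4 p_l` and
#' the estimator searches a parameter grid of `estimation_resolution`
#' jointly with `k`.  Per-type estimates are `k_hat` times the (assumed or
#' selected) category probabilities; actual per-type counts come from the
#' simulator's event log.
#'
#' @param cfg An [experiment_config()].
#' @param mode `"known"` or `"grid"`.
#' @param estimation_resolution Grid step used by the estimator in `grid`
#'   mode (default 0.01; coarser values trade accuracy for speed).
#' @return A data frame with one row per `k`: mean and SD of `k_hat`, the
#'   per-type mean absolute differences `mad_*`, the per-type relative
#'   errors `rel_*` (mean absolute difference divided by the mean actual
#'   count, in percent), and the mean actual counts.  The configuration is
#'   attached as `attr(, "config")`.
#' @export
run_estimation_experiment <- function(cfg, mode = c("known", "grid"),
                                      estimation_resolution = 0.01) {
  stopifnot(inherits(cfg, "experiment_config"))
  mode <- match.arg(mode)
  set.seed(cfg$seed)
  G <- .build_reference(cfg)
  ref <- genome_ref(G)
  k_max <- as.integer(round(cfg$k_max_multiplier * n_genes(G)))
  ks <- cfg$k_values
  nk <- length(ks)

  if (mode == "known") {
    params <- event_params(cfg$p_d, cfg$p_l, cfg$L_max)
    traj <- expected_trajectory(ref, k_max, params, cfg$C)
  } else {
    gen_grid <- parameter_grid(0.01)
    est_grid <- parameter_grid(estimation_resolution)
    cache <- grid_trajectories(ref, est_grid, k_max, cfg$C, cfg$L_max)
  }

  k_hat <- matrix(0, cfg$replicates, nk)
  est_types <- array(0, c(cfg$replicates, nk, 3L))
  act_types <- array(0, c(cfg$replicates, nk, 3L))
  for (r in seq_len(cfg$replicates)) {
    if (mode == "grid") {
      pick <- gen_grid[sample.int(nrow(gen_grid), 1L), ]
      params <- event_params(pick$p_d, pick$p_l, cfg$L_max)
    }
    g <- G
    prev <- 0L
    counts <- c(rearrangement = 0L, duplication = 0L, loss = 0L)
    for (j in seq_len(nk)) {
      res <- evolve(g, ks[j] - prev, params, log = FALSE)
      g <- res$genome
      prev <- ks[j]
      counts <- counts + res$counts
      vF <- .quiet_cap(genome_vector(ref, g, cfg$C))
      est <- if (mode == "known") {
        .estimate_from_trajectory(vF, traj)
      } else {
        .quiet_cap(estimate_k_unknown_params(
          ref, g, L_max = cfg$L_max, k_max = k_max,
          C = cfg$C, grid = est_grid, trajectories = cache))
      }
      k_hat[r, j] <- est$k_hat
      est_types[r, j, ] <- est$per_type
      act_types[r, j, ] <- counts
    }
  }

  type_names <- c("rearrangement", "duplication", "loss")
  out <- data.frame(k = ks,
                    mean_k_hat = colMeans(k_hat),
                    sd_k_hat = apply(k_hat, 2L, stats::sd))
  for (t in 1:3) {
    e <- matrix(est_types[, , t], cfg$replicates, nk)
    a <- matrix(act_types[, , t], cfg$replicates, nk)
    mad <- colMeans(abs(e - a))
    act <- colMeans(a)
    out[[paste0("mad_", type_names[t])]] <- mad
    out[[paste0("mean_actual_", type_names[t])]] <- act
    out[[paste0("rel_", type_names[t])]] <- 100 * mad / ifelse(act > 0, act, NA)
  }
  attr(out, "config") <- cfg
  attr(out, "mode") <- mode
  out
}
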