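#' Simulation configuration
#'
#' Run-time parameters of the event-driven binary-network simulation.
#' Time is measured in ms with \eqn{\tau_E} defaulting to 10 ms (the value
#' is purely a choice of unit: the dynamics depend only on
#' \eqn{\tau_I/\tau_E}). Per-population update probabilities scale as
#' \eqn{P_{UE}/P_{UI} = \tau_I/\tau_E}.
#'
#' @param duration Simulation duration (ms).
#' @param bin_ms Bin width for rate estimation (ms).
#' @param discard_ms Initial transient excluded from statistics (ms).
#' @param init_p Probability for each unit to start in the up state.
#' @param seed Integer seed.
#' @param n_trials Trials per network realization (sweep driver).
#' @param n_realizations Connectivity draws per parameter value (sweep
#'   driver).
#' @param record_updates Keep the full update log (every update event, not
#'   only state flips); memory-hungry, for diagnostics.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(duration = 1000, bin_ms = 10,
                              discard_ms = 100, init_p = 0.5, seed = 1L,
                              n_trials = 5L, n_realizations = 5L,
                              record_updates = FALSE) {
  stopifnot(duration > 0, bin_ms > 0, discard_ms >= 0,
            init_p >= 0, init_p <= 1)
  structure(list(duration = duration, bin_ms = bin_ms,
                 discard_ms = discard_ms, init_p = init_p,
                 seed = as.integer(seed), n_trials = as.integer(n_trials),
                 n_realizations = as.integer(n_realizations),
                 record_updates = record_updates),
            class = "simulation_config")
}

#' Simulate a binary network
#'
#' Event-driven asynchronous dynamics: every unit carries an independent
#' exponential update clock with mean interval \eqn{\tau_\alpha}; at an
#' update the unit's state becomes
#' \eqn{\Theta(\sum_j J_{ij}\sigma_j - \theta_i + J_{\alpha X} m_X)} with
#' the external drive entering as a constant. A spike is a 0-to-1
#' transition. Only state flips are recorded (with the initial state they
#' determine the whole trajectory); exact time-averaged population rates
#' over \code{[discard_ms, duration]} are accumulated during the run.
#' Fully reproducible given the seed.
#'
#' @param wm A \code{\link{build_matrix}} result.
#' @param config A \code{\link{simulation_config}}.
#' @param seed Overrides \code{config$seed} when given.
#' @return An object of class \code{"binary_sim"}: list with \code{flips}
#'   (data frame \code{t}, \code{unit}, \code{state}), \code{sigma0},
#'   \code{mean_m_E}, \code{mean_m_I}, \code{n_updates}, \code{n_flips},
#'   \code{duration}, the cluster assignments, and (optionally)
#'   \code{updates}.
#' @export
simulate_network <- function(wm, config = simulation_config(),
                             seed = config$seed) {
  stopifnot(inherits(wm, "weight_matrix"),
            inherits(config, "simulation_config"))
  spec <- wm$spec
  J <- wm$J
  if (!methods::is(J, "dgCMatrix")) J <- methods::as(J, "CsparseMatrix")
  set.seed(seed)
  sigma0 <- stats::runif(spec$N) < config$init_p
  res <- simulate_binary_cpp(
    spec$N_E, spec$N_I, J@p, J@i, J@x,
    spec$theta_E, spec$theta_I, spec$J_EX, spec$J_IX, spec$m_X,
    spec$tau_E, spec$tau_I, config$duration, sigma0,
    config$discard_ms, config$record_updates)
  out <- list(flips = data.frame(t = res$flip_t, unit = res$flip_unit,
                                 state = res$flip_state),
              sigma0 = as.integer(sigma0),
              mean_m_E = res$mean_m_E, mean_m_I = res$mean_m_I,
              n_updates = res$n_updates, n_flips = res$n_flips,
              duration = config$duration, config = config, seed = seed,
              N_E = spec$N_E, N_I = spec$N_I,
              assignment_E = wm$cluster$assignment_E,
              assignment_I = wm$cluster$assignment_I)
  if (config$record_updates)
    out$updates <- data.frame(t = res$update_t, unit = res$update_unit,
                              state = res$update_state)
  class(out) <- "binary_sim"
  out
}

#' @export
print.binary_sim <- function(x, ...) {
  cat(sprintf(
    "<binary_sim> %d units, %.0f ms, %.0f updates, %.0f flips, m_E=%.4f\n",
    x$N_E + x$N_I, x$duration, x$n_updates, x$n_flips, x$mean_m_E))
  invisible(x)
}

#' Spike times (0-to-1 transitions)
#'
#' @param sim A \code{\link{simulate_network}} result.
#' @return Data frame with \code{time_ms} and 0-based \code{unit_id}
#'   (E units first).
#' @export
spike_times <- function(sim) {
  up <- sim$flips[sim$flips$state == 1L, ]
  data.frame(time_ms = up$t, unit_id = up$unit - 1L)
}

#' Per-cluster activity rate time series
#'
#' Pools the states of the units in each cluster and reports the fraction
#' of up units at the end of each bin (the instantaneous mean cluster
#' activity rate, sampled at bin ends).
#'
#' @param sim A \code{\link{simulate_network}} result.
#' @param membership Integer vector over all \eqn{N} units mapping each
#'   unit to a group id (\code{NA} = excluded). Defaults to the excitatory
#'   cluster assignment stored with the simulation.
#' @param bin_ms Bin width in ms.
#' @return An object of class \code{"cluster_rate_series"}: list with
#'   \code{t} (bin-end times) and \code{rates} (bins x clusters matrix).
#' @export
cluster_rates <- function(sim, membership = NULL,
                          bin_ms = sim$config$bin_ms) {
  stopifnot(inherits(sim, "binary_sim"))
  N <- sim$N_E + sim$N_I
  if (is.null(membership)) {
    membership <- rep(NA_integer_, N)
    membership[seq_len(sim$N_E)] <- sim$assignment_E
  }
  stopifnot(length(membership) == N)
  groups <- sort(unique(membership[!is.na(membership)]))
  if (length(groups) == 0) stop("cluster_rates: no units assigned")
  tend <- seq(bin_ms, sim$duration, by = bin_ms)
  rates <- matrix(NA_real_, length(tend), length(groups),
                  dimnames = list(NULL, paste0("c", groups)))
  for (gi in seq_along(groups)) {
    units <- which(membership == groups[gi])
    if (length(units) == 0) stop("cluster_rates: empty cluster ", groups[gi])
    n0 <- sum(sim$sigma0[units])
    sel <- sim$flips$unit %in% units
    ft <- sim$flips$t[sel]
    dlt <- ifelse(sim$flips$state[sel] == 1L, 1L, -1L)
    counts <- c(n0, n0 + cumsum(dlt))          # count after k-th flip
    idx <- findInterval(tend, ft)              # flips up to each bin end
    rates[, gi] <- counts[idx + 1] / length(units)
  }
  structure(list(t = tend, rates = rates, bin_ms = bin_ms,
                 group_sizes = vapply(groups, function(g)
                   sum(membership == g, na.rm = TRUE), integer(1))),
            class = "cluster_rate_series")
}

#' Mean time variance of cluster activity rates
#'
#' The winnerless-competition statistic: after discarding the initial
#' transient, the variance over time of each cluster's activity rate is
#' computed and averaged over clusters. Elevated values indicate
#' coordinated switching of whole clusters between activity states.
#'
#' @param series A \code{\link{cluster_rates}} result.
#' @param discard_ms Initial transient to drop.
#' @return Scalar \eqn{\sigma^2_m}.
#' @export
sigma2_m <- function(series, discard_ms = 100) {
  stopifnot(inherits(series, "cluster_rate_series"))
  keep <- series$t > discard_ms
  if (!any(keep)) stop("sigma2_m: series shorter than the discard window")
  r <- series$rates[keep, , drop = FALSE]
  v <- apply(r, 2, stats::var)
  v[is.na(v)] <- 0  # single-bin series: no variance
  mean(v)
}

#' Sweep clustering strength and measure rate variance in simulations
#'
#' For each value of \eqn{J_{E+}}: draws \code{n_realizations} connectivity
#' matrices, runs \code{n_trials} simulations on each, computes
#' \eqn{\sigma^2_m} per trial, and reports mean and standard deviation.
#'
#' @param spec A \code{\link{network_spec}}.
#' @param mode \code{"E_weights"} or \code{"EI_weights"}.
#' @param R_J Inhibitory clustering ratio (EI mode).
#' @param grid Values of \eqn{J_{E+}}.
#' @param config A \code{\link{simulation_config}} (supplies trial counts,
#'   duration, binning and base seed).
#' @param verbose Print progress lines.
#' @return Data frame with \code{sweep_value}, \code{mean_sigma2_m},
#'   \code{sd_sigma2_m}, \code{n}.
#' @export
variance_sweep <- function(spec, mode = c("E_weights", "EI_weights"),
                           R_J = spec$R_J, grid,
                           config = simulation_config(), verbose = FALSE) {
  mode <- match.arg(mode)
  out <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    sp <- spec
    sp$clustering_mode <- mode
    sp$J_Eplus <- grid[k]
    sp$R_J <- R_J
    vals <- numeric(0)
    for (r in seq_len(config$n_realizations)) {
      wm <- build_matrix(sp, seed = config$seed + 131L * k + 7L * r)
      for (tr in seq_len(config$n_trials)) {
        sim <- simulate_network(wm, config,
                                seed = config$seed + 131L * k + 7L * r + tr)
        s2 <- sigma2_m(cluster_rates(sim), discard_ms = config$discard_ms)
        vals <- c(vals, s2)
      }
    }
    out[[k]] <- data.frame(sweep_value = grid[k],
                           mean_sigma2_m = mean(vals),
                           sd_sigma2_m = stats::sd(vals),
                           n = length(vals))
    if (verbose)
      message(sprintf("J_Eplus=%.2f  sigma2_m=%.5f", grid[k], mean(vals)))
  }
  do.call(rbind, out)
}
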