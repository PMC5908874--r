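#' Complementary Gaussian tail (population gain function)
#'
#' \eqn{H(z) = \int_z^\infty e^{-x^2/2}/\sqrt{2\pi}\, dx}, the upper tail of
#' the standard normal. This is the single-unit gain: the probability that a
#' Gaussian input exceeds the threshold. Strictly decreasing, with
#' \eqn{H(-\infty) = 1}, \eqn{H(0) = 1/2}, \eqn{H(\infty) = 0}; computed via
#' \code{pnorm(..., lower.tail = FALSE)} so it is accurate far into the tail.
#'
#' @param z Numeric vector (may contain \code{Inf}/\code{-Inf}).
#' @return Probabilities in \[0, 1\].
#' @export
gain_H <- function(z) {
  if (any(is.nan(z))) stop("gain_H: NaN input")
  stats::pnorm(z, lower.tail = FALSE)
}

#' Reduce a network architecture to a population rate system
#'
#' Builds the population-level description used by the mean-field rate
#' dynamics: per-population mean input weights
#' \eqn{\bar J_{\alpha\beta} = j_{\alpha\beta} p_{\alpha\beta} n_\beta \sqrt N}
#' and weight variances
#' \eqn{\bar J^{(2)}_{\alpha\beta} = p_{\alpha\beta}(1 - p_{\alpha\beta})
#' j^2_{\alpha\beta} n_\beta}, with cluster multipliers folded in
#' (\eqn{J_\pm} on \eqn{\bar J}, \eqn{J_\pm^2} on \eqn{\bar J^{(2)}}).
#' The number of populations depends on the architecture: 2 (unclustered),
#' \eqn{Q + 1} (excitatory clusters + I), \eqn{2Q} (EI clusters),
#' \eqn{Q + 2} (clusters + background + I).
#'
#' @param spec A \code{\link{network_spec}}; its \code{clustering_mode},
#'   \code{Q}, \code{J_Eplus}, \code{R_J}, \code{background_fraction} and
#'   \code{R_EE} select and parameterize the architecture.
#' @param weights Optional \code{\link{derive_weights}} result.
#' @param prob_weight_factor Within-cluster weight multiplier used only in
#'   probability-clustering mode (the companion of the probability increase;
#'   not part of the weight-clustering architectures).
#' @return An object of class \code{"population_system"}: list with
#'   \code{P}, \code{sizes}, \code{n} (fractions), \code{Jbar}, \code{Jbar2},
#'   \code{theta}, \code{Jx}, \code{m_X}, \code{tau} (in units of
#'   \eqn{\tau_E}), \code{labels}, \code{pop_type} ("E"/"I") and
#'   \code{cluster_id}.
#' @export
reduce_network <- function(spec, weights = derive_weights(spec),
                           prob_weight_factor = 1.9) {
  stopifnot(inherits(spec, "network_spec"))
  mode <- spec$clustering_mode
  w <- weights
  sN <- sqrt(spec$N)
  tauI <- spec$tau_I / spec$tau_E
  # unclustered 2x2 building blocks
  jmat <- matrix(c(w$j_EE, w$j_EI, w$j_IE, w$j_II), 2, 2, byrow = TRUE)
  pmat <- matrix(c(spec$p_EE, spec$p_EI, spec$p_IE, spec$p_II),
                 2, 2, byrow = TRUE)
  nvec <- c(w$n_E, w$n_I)

  if (mode == "none") {
    Jbar <- jmat * pmat * rep(nvec, each = 2) * sN
    Jbar2 <- pmat * (1 - pmat) * jmat^2 * rep(nvec, each = 2)
    return(.new_population_system(
      sizes = c(spec$N_E, spec$N_I), Jbar = Jbar, Jbar2 = Jbar2,
      theta = c(spec$theta_E, spec$theta_I),
      Jx = c(spec$J_EX, spec$J_IX), m_X = spec$m_X,
      tau = c(1, tauI), labels = c("E", "I"),
      pop_type = c("E", "I"), cluster_id = c(NA_integer_, NA_integer_),
      spec = spec))
  }

  Q <- spec$Q
  if (mode %in% c("E_weights", "EI_weights", "E_probability")) {
    if (spec$N_E %% Q != 0)
      stop("N_E must be divisible by Q")
  }

  if (mode == "E_weights" || mode == "EI_weights") {
    Jp <- spec$J_Eplus
    Jm <- cluster_scaling(Q, Jp)
    if (mode == "E_weights") {
      P <- Q + 1
      n_c <- w$n_E / Q
      EE <- matrix(Jm, Q, Q); diag(EE) <- Jp
      Jbar <- rbind(cbind(EE * w$j_EE * spec$p_EE * n_c * sN,
                          w$j_EI * spec$p_EI * w$n_I * sN),
                    cbind(matrix(w$j_IE * spec$p_IE * n_c * sN, 1, Q),
                          w$j_II * spec$p_II * w$n_I * sN))
      EE2 <- matrix(Jm^2, Q, Q); diag(EE2) <- Jp^2
      Jbar2 <- rbind(cbind(EE2 * spec$p_EE * (1 - spec$p_EE) * w$j_EE^2 * n_c,
                           spec$p_EI * (1 - spec$p_EI) * w$j_EI^2 * w$n_I),
                     cbind(matrix(spec$p_IE * (1 - spec$p_IE) * w$j_IE^2 * n_c,
                                  1, Q),
                           spec$p_II * (1 - spec$p_II) * w$j_II^2 * w$n_I))
      return(.new_population_system(
        sizes = c(rep(spec$N_E / Q, Q), spec$N_I), Jbar = Jbar, Jbar2 = Jbar2,
        theta = c(rep(spec$theta_E, Q), spec$theta_I),
        Jx = c(rep(spec$J_EX, Q), spec$J_IX), m_X = spec$m_X,
        tau = c(rep(1, Q), tauI),
        labels = c(paste0("E", seq_len(Q)), "I"),
        pop_type = c(rep("E", Q), "I"),
        cluster_id = c(seq_len(Q), NA_integer_), spec = spec))
    }
    # EI_weights: 2Q populations, inhibitory clustering via J_I+/J_I-
    if (spec$N_I %% Q != 0)
      stop("N_I must be divisible by Q in EI mode")
    JIp <- 1 + spec$R_J * (Jp - 1)
    JIm <- cluster_scaling(Q, JIp)
    n_cE <- w$n_E / Q
    n_cI <- w$n_I / Q
    Emult <- matrix(Jm, Q, Q); diag(Emult) <- Jp
    Imult <- matrix(JIm, Q, Q); diag(Imult) <- JIp
    blk <- function(mult, j, p, n) mult * j * p * n * sN
    blk2 <- function(mult, j, p, n) mult^2 * p * (1 - p) * j^2 * n
    Jbar <- rbind(
      cbind(blk(Emult, w$j_EE, spec$p_EE, n_cE),
            blk(Imult, w$j_EI, spec$p_EI, n_cI)),
      cbind(blk(Imult, w$j_IE, spec$p_IE, n_cE),
            blk(Imult, w$j_II, spec$p_II, n_cI)))
    Jbar2 <- rbind(
      cbind(blk2(Emult, w$j_EE, spec$p_EE, n_cE),
            blk2(Imult, w$j_EI, spec$p_EI, n_cI)),
      cbind(blk2(Imult, w$j_IE, spec$p_IE, n_cE),
            blk2(Imult, w$j_II, spec$p_II, n_cI)))
    return(.new_population_system(
      sizes = c(rep(spec$N_E / Q, Q), rep(spec$N_I / Q, Q)),
      Jbar = Jbar, Jbar2 = Jbar2,
      theta = c(rep(spec$theta_E, Q), rep(spec$theta_I, Q)),
      Jx = c(rep(spec$J_EX, Q), rep(spec$J_IX, Q)), m_X = spec$m_X,
      tau = c(rep(1, Q), rep(tauI, Q)),
      labels = c(paste0("E", seq_len(Q)), paste0("I", seq_len(Q))),
      pop_type = c(rep("E", Q), rep("I", Q)),
      cluster_id = c(seq_len(Q), seq_len(Q)), spec = spec))
  }

  if (mode == "E_weights_background") {
    f <- spec$background_fraction
    N_bg <- round(f * spec$N_E)
    N_cl <- spec$N_E - N_bg
    if (N_cl %% Q != 0)
      stop("clustered E units (N_E minus background) must be divisible by Q")
    Jp <- spec$J_Eplus
    Jm <- cluster_scaling(Q, Jp)
    n_c <- (N_cl / Q) / spec$N
    n_bg <- N_bg / spec$N
    # multipliers: Eq-style renormalization among clustered units only;
    # anything involving the background keeps the unmodified weight
    EE <- matrix(Jm, Q, Q); diag(EE) <- Jp
    P <- Q + 2
    Jbar <- matrix(0, P, P)
    Jbar2 <- matrix(0, P, P)
    idx_cl <- seq_len(Q); idx_bg <- Q + 1; idx_I <- Q + 2
    Jbar[idx_cl, idx_cl] <- EE * w$j_EE * spec$p_EE * n_c * sN
    Jbar[idx_cl, idx_bg] <- w$j_EE * spec$p_EE * n_bg * sN
    Jbar[idx_bg, idx_cl] <- w$j_EE * spec$p_EE * n_c * sN
    Jbar[idx_bg, idx_bg] <- w$j_EE * spec$p_EE * n_bg * sN
    Jbar[c(idx_cl, idx_bg), idx_I] <- w$j_EI * spec$p_EI * w$n_I * sN
    Jbar[idx_I, idx_cl] <- w$j_IE * spec$p_IE * n_c * sN
    Jbar[idx_I, idx_bg] <- w$j_IE * spec$p_IE * n_bg * sN
    Jbar[idx_I, idx_I] <- w$j_II * spec$p_II * w$n_I * sN
    EE2 <- matrix(Jm^2, Q, Q); diag(EE2) <- Jp^2
    Jbar2[idx_cl, idx_cl] <- EE2 * spec$p_EE * (1 - spec$p_EE) * w$j_EE^2 * n_c
    Jbar2[idx_cl, idx_bg] <- spec$p_EE * (1 - spec$p_EE) * w$j_EE^2 * n_bg
    Jbar2[idx_bg, idx_cl] <- spec$p_EE * (1 - spec$p_EE) * w$j_EE^2 * n_c
    Jbar2[idx_bg, idx_bg] <- spec$p_EE * (1 - spec$p_EE) * w$j_EE^2 * n_bg
    Jbar2[c(idx_cl, idx_bg), idx_I] <-
      spec$p_EI * (1 - spec$p_EI) * w$j_EI^2 * w$n_I
    Jbar2[idx_I, idx_cl] <- spec$p_IE * (1 - spec$p_IE) * w$j_IE^2 * n_c
    Jbar2[idx_I, idx_bg] <- spec$p_IE * (1 - spec$p_IE) * w$j_IE^2 * n_bg
    Jbar2[idx_I, idx_I] <- spec$p_II * (1 - spec$p_II) * w$j_II^2 * w$n_I
    return(.new_population_system(
      sizes = c(rep(N_cl / Q, Q), N_bg, spec$N_I), Jbar = Jbar, Jbar2 = Jbar2,
      theta = c(rep(spec$theta_E, Q + 1), spec$theta_I),
      Jx = c(rep(spec$J_EX, Q + 1), spec$J_IX), m_X = spec$m_X,
      tau = c(rep(1, Q + 1), tauI),
      labels = c(paste0("E", seq_len(Q)), "Ebg", "I"),
      pop_type = c(rep("E", Q + 1), "I"),
      cluster_id = c(seq_len(Q), NA_integer_, NA_integer_), spec = spec))
  }

  if (mode == "E_probability") {
    pp <- .probability_cluster_probs(spec$p_EE, Q, spec$R_EE)
    wf <- prob_weight_factor
    n_c <- w$n_E / Q
    P <- Q + 1
    EEp <- matrix(pp$p_out, Q, Q); diag(EEp) <- pp$p_in
    EEw <- matrix(1, Q, Q); diag(EEw) <- wf
    Jbar <- rbind(cbind(EEw * w$j_EE * EEp * n_c * sN,
                        w$j_EI * spec$p_EI * w$n_I * sN),
                  cbind(matrix(w$j_IE * spec$p_IE * n_c * sN, 1, Q),
                        w$j_II * spec$p_II * w$n_I * sN))
    Jbar2 <- rbind(cbind(EEp * (1 - EEp) * (EEw * w$j_EE)^2 * n_c,
                         spec$p_EI * (1 - spec$p_EI) * w$j_EI^2 * w$n_I),
                   cbind(matrix(spec$p_IE * (1 - spec$p_IE) * w$j_IE^2 * n_c,
                                1, Q),
                         spec$p_II * (1 - spec$p_II) * w$j_II^2 * w$n_I))
    return(.new_population_system(
      sizes = c(rep(spec$N_E / Q, Q), spec$N_I), Jbar = Jbar, Jbar2 = Jbar2,
      theta = c(rep(spec$theta_E, Q), spec$theta_I),
      Jx = c(rep(spec$J_EX, Q), spec$J_IX), m_X = spec$m_X,
      tau = c(rep(1, Q), tauI),
      labels = c(paste0("E", seq_len(Q)), "I"),
      pop_type = c(rep("E", Q), "I"),
      cluster_id = c(seq_len(Q), NA_integer_), spec = spec))
  }
  stop("unknown clustering_mode: ", mode)
}

.new_population_system <- function(sizes, Jbar, Jbar2, theta, Jx, m_X, tau,
                                   labels, pop_type, cluster_id, spec = NULL) {
  P <- length(sizes)
  stopifnot(nrow(Jbar) == P, ncol(Jbar) == P,
            nrow(Jbar2) == P, ncol(Jbar2) == P,
            length(theta) == P, length(Jx) == P, length(tau) == P)
  dimnames(Jbar) <- dimnames(Jbar2) <- list(labels, labels)
  sys <- list(P = P, sizes = sizes, n = sizes / sum(sizes),
              Jbar = Jbar, Jbar2 = Jbar2, theta = theta, Jx = Jx,
              m_X = m_X, tau = tau, labels = labels, pop_type = pop_type,
              cluster_id = cluster_id, spec = spec)
  class(sys) <- "population_system"
  sys
}

#' @export
print.population_system <- function(x, ...) {
  cat(sprintf("<population_system> P=%d (%d E pops, %d I pops), m_X=%.3g\n",
              x$P, sum(x$pop_type == "E"), sum(x$pop_type == "I"), x$m_X))
  invisible(x)
}

#' Mean and variance of the population inputs
#'
#' \eqn{\mu_\alpha = \sum_\beta \bar J_{\alpha\beta} m_\beta +
#' J_{\alpha X} m_X - \theta_\alpha} and
#' \eqn{s^2_\alpha = \sum_\beta \bar J^{(2)}_{\alpha\beta} m_\beta}.
#' The variance comes from the Bernoulli randomness of the connectivity;
#' input correlations are neglected.
#'
#' @param sys A \code{\link{reduce_network}} result.
#' @param m Rate vector of length \code{sys$P}.
#' @return List with \code{mu} and \code{s2}.
#' @export
input_moments <- function(sys, m) {
  stopifnot(inherits(sys, "population_system"))
  if (length(m) != sys$P) stop("input_moments: rate vector has length ",
                               length(m), ", expected ", sys$P)
  list(mu = drop(sys$Jbar %*% m) + sys$Jx * sys$m_X - sys$theta,
       s2 = drop(sys$Jbar2 %*% m))
}

#' Time derivative of the population rates
#'
#' \eqn{\tau_\alpha \dot m_\alpha = -m_\alpha + H(-\mu_\alpha/s_\alpha)}.
#' When \eqn{s_\alpha = 0} the gain degenerates to a step in the mean input
#' (target 1 if \eqn{\mu > 0}, 0 if \eqn{\mu < 0}, 1/2 at 0), the limit of
#' the Gaussian form.
#'
#' @inheritParams input_moments
#' @return Length-P derivative vector (time in units of \eqn{\tau_E}).
#' @export
rate_derivative <- function(sys, m) {
  (mf_gain(sys, m) - m) / sys$tau
}

#' Steady-state gain of each population
#'
#' \eqn{H(-\mu_\alpha/s_\alpha)} at the given rates; fixed points satisfy
#' \code{mf_gain(sys, m) == m}.
#'
#' @inheritParams input_moments
#' @return Length-P vector in \[0, 1\].
#' @export
mf_gain <- function(sys, m) {
  io <- input_moments(sys, m)
  s <- sqrt(pmax(io$s2, 0))
  out <- numeric(sys$P)
  pos <- s > 0
  out[pos] <- gain_H(-io$mu[pos] / s[pos])
  if (any(!pos))
    out[!pos] <- ifelse(io$mu[!pos] > 0, 1, ifelse(io$mu[!pos] < 0, 0, 0.5))
  out
}

#' Maximum fixed-point residual
#'
#' @inheritParams input_moments
#' @return \eqn{\max_\alpha |m_\alpha - H(-\mu_\alpha/s_\alpha)|}.
#' @export
mf_residual <- function(sys, m) max(abs(m - mf_gain(sys, m)))

#' Integrate the population rate dynamics
#'
#' Explicit Euler integration of the rate equations. The dynamics are
#' self-limiting (the gain lies in \[0, 1\]) so trajectories remain in the
#' unit cube for any step obeying the precondition.
#'
#' @inheritParams input_moments
#' @param m0 Initial rates.
#' @param T Duration in units of \eqn{\tau_E}.
#' @param dt Step size; must be at most \code{0.1 * min(sys$tau)}.
#' @param record_every Store every k-th step in the trajectory (0 = final
#'   state only).
#' @param fixed Optional logical mask of populations clamped at their
#'   initial rate (used by the effective-response machinery).
#' @return List with \code{t} (times), \code{m} (matrix, one row per stored
#'   time), \code{final}, and \code{residual} (fixed-point residual at the
#'   final state).
#' @export
integrate_rates <- function(sys, m0, T, dt = 0.05 * min(sys$tau),
                            record_every = 1L, fixed = NULL) {
  stopifnot(inherits(sys, "population_system"), length(m0) == sys$P)
  if (any(!is.finite(m0))) stop("integrate_rates: non-finite initial state")
  if (dt > 0.1 * min(sys$tau) + 1e-15)
    stop("integrate_rates: dt must be <= 0.1 * min(tau)")
  if (is.null(fixed)) fixed <- rep(FALSE, sys$P)
  nsteps <- if (T <= 0) 0L else as.integer(ceiling(T / dt))
  res <- mf_euler_cpp(sys$Jbar, sys$Jbar2, sys$theta, sys$Jx, sys$m_X,
                      sys$tau, as.numeric(m0), dt, nsteps, fixed,
                      as.integer(record_every))
  if (any(!is.finite(res$final)))
    stop("integrate_rates: trajectory became non-finite")
  list(t = res$t, m = res$m, final = drop(res$final),
       residual = mf_residual(sys, drop(res$final)))
}
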