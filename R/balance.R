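#' Derive balanced-state synaptic weights
#'
#' Computes the size-scaled weight constants \eqn{j_{\alpha\beta}} (and the
#' per-synapse weights \eqn{J_{\alpha\beta} = j_{\alpha\beta}/\sqrt{N}}) that
#' put the network in the balanced regime. Two requirements pin the weights
#' down: \eqn{\sqrt{K}} excitatory inputs within one time constant must reach
#' threshold, \eqn{\sqrt{p_{\alpha E} N_E}\, J_{\alpha E} = \theta_\alpha},
#' and excitation and inhibition must cancel on average at equal population
#' rates, with the inhibitory weight onto E carrying an extra factor
#' \eqn{g} controlling the dominance of inhibition:
#' \deqn{j_{EE} = \theta_E / \sqrt{p_{EE} n_E}, \quad
#'       j_{EI} = -g\, j_{EE}\, p_{EE} n_E / (p_{EI} n_I),}
#' \deqn{j_{IE} = \theta_I / \sqrt{p_{IE} n_E}, \quad
#'       j_{II} = -j_{IE}\, p_{IE} n_E / (p_{II} n_I),}
#' where \eqn{n_\alpha = N_\alpha / N} is the population fraction. (Some
#' accounts print \eqn{n_E = N/N_E}; that form is inconsistent with the
#' threshold condition above and we treat it as a typo — with fractions the
#' four expressions satisfy both balance identities exactly.)
#'
#' @param spec A \code{\link{network_spec}} with all probabilities in (0, 1\]
#'   and positive population sizes.
#' @return An object of class \code{"balance_weights"}: list with
#'   \code{j_EE}, \code{j_EI}, \code{j_IE}, \code{j_II} (size-scaled
#'   constants), \code{J_EE}, \code{J_EI}, \code{J_IE}, \code{J_II}
#'   (per-synapse weights), and fractions \code{n_E}, \code{n_I}.
#' @export
#' @examples
#' w <- derive_weights(network_spec())
#' w$j_EE  # 2.5
derive_weights <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  for (p in c("p_EE", "p_EI", "p_IE", "p_II"))
    if (spec[[p]] <= 0) stop("derive_weights: ", p, " must be > 0")
  for (n in c("N_E", "N_I"))
    if (spec[[n]] <= 0) stop("derive_weights: ", n, " must be > 0")
  if (spec$g <= 0) stop("derive_weights: g must be > 0")
  n_E <- spec$N_E / spec$N
  n_I <- spec$N_I / spec$N
  j_EE <- spec$theta_E / sqrt(spec$p_EE * n_E)
  j_EI <- -spec$g * j_EE * spec$p_EE * n_E / (spec$p_EI * n_I)
  j_IE <- spec$theta_I / sqrt(spec$p_IE * n_E)
  j_II <- -j_IE * spec$p_IE * n_E / (spec$p_II * n_I)
  sN <- sqrt(spec$N)
  out <- list(j_EE = j_EE, j_EI = j_EI, j_IE = j_IE, j_II = j_II,
              J_EE = j_EE / sN, J_EI = j_EI / sN,
              J_IE = j_IE / sN, J_II = j_II / sN,
              n_E = n_E, n_I = n_I)
  class(out) <- "balance_weights"
  out
}

#' @export
print.balance_weights <- function(x, ...) {
  cat(sprintf("<balance_weights> j_EE=%.4g j_EI=%.4g j_IE=%.4g j_II=%.4g\n",
              x$j_EE, x$j_EI, x$j_IE, x$j_II))
  invisible(x)
}

#' Check the balance conditions for positive finite rates
#'
#' The closed-form balanced rates are positive and finite only if either
#' \eqn{g < 1} with \eqn{J_{EX}/J_{IX} < g\sqrt{p_{EE}/p_{IE}}}, or
#' \eqn{g > 1} with \eqn{J_{EX}/J_{IX} > g\sqrt{p_{EE}/p_{IE}}}
#' (assuming \eqn{\theta_E = \theta_I}). Exactly one branch can hold;
#' at \eqn{g = 1} the rates diverge and neither does.
#'
#' @param spec A \code{\link{network_spec}}.
#' @return A list with \code{applicable} (FALSE when
#'   \eqn{\theta_E \ne \theta_I}), \code{satisfied}, and \code{branch}
#'   (\code{"g<1"}, \code{"g>1"}, or \code{NA}).
#' @export
check_balance_conditions <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$theta_E != spec$theta_I)
    return(list(applicable = FALSE, satisfied = NA, branch = NA_character_))
  ratio <- spec$J_EX / spec$J_IX
  bound <- spec$g * sqrt(spec$p_EE / spec$p_IE)
  if (spec$g < 1 && ratio < bound)
    return(list(applicable = TRUE, satisfied = TRUE, branch = "g<1"))
  if (spec$g > 1 && ratio > bound)
    return(list(applicable = TRUE, satisfied = TRUE, branch = "g>1"))
  list(applicable = TRUE, satisfied = FALSE, branch = NA_character_)
}

#' Closed-form balanced population rates
#'
#' In the large-\eqn{N} limit the mean excitatory and inhibitory inputs to
#' each unit are of order \eqn{\sqrt{N}\theta} and must cancel, which pins
#' the population rates to
#' \deqn{m_E = \frac{m_X}{\sqrt{N_E}(g-1)}
#'   \left(\frac{J_{EX}}{\theta_E\sqrt{p_{EE}}} -
#'         g\frac{J_{IX}}{\theta_I\sqrt{p_{IE}}}\right), \quad
#'       m_I = \frac{m_X}{\sqrt{N_E}(g-1)}
#'   \left(\frac{J_{EX}}{\theta_E\sqrt{p_{EE}}} -
#'         \frac{J_{IX}}{\theta_I\sqrt{p_{IE}}}\right).}
#' Both rates scale linearly with the external drive \eqn{m_X}.
#'
#' @param spec A \code{\link{network_spec}} with \code{g != 1}.
#' @return Named numeric vector \code{c(m_E=, m_I=)}.
#' @export
#' @examples
#' balanced_rates(network_spec())  # about c(0.0589, 0.0741)
balanced_rates <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$g == 1)
    stop("balanced_rates: g = 1 is singular (rates diverge)")
  pref <- spec$m_X / (sqrt(spec$N_E) * (spec$g - 1))
  eterm <- spec$J_EX / (spec$theta_E * sqrt(spec$p_EE))
  iterm <- spec$J_IX / (spec$theta_I * sqrt(spec$p_IE))
  c(m_E = pref * (eterm - spec$g * iterm),
    m_I = pref * (eterm - iterm))
}
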