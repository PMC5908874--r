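#' Network parameter specification
#'
#' Collects all scalar parameters of a balanced binary-neuron network in a
#' single validated object. Defaults are the standard parameter set used
#' throughout the package: \eqn{N_E = 4000}, \eqn{N_I = 1000},
#' \eqn{p_{EE} = 0.2}, \eqn{p_{EI} = p_{IE} = p_{II} = 0.5}, relative
#' inhibition \eqn{g = 1.2}, thresholds \eqn{\theta = 1}, external weights
#' \eqn{J_{EX} = \sqrt{p_{EE} N_E}} and \eqn{J_{IX} = 0.8\sqrt{p_{EE} N_E}},
#' external drive \eqn{m_X = 0.03} and \eqn{\tau_I = 0.5\,\tau_E}.
#'
#' @param N_E,N_I Positive integer population sizes.
#' @param Q Number of clusters (used by clustered modes).
#' @param p_EE,p_EI,p_IE,p_II Connection probabilities in \[0, 1\]. Indices are
#'   (postsynaptic, presynaptic).
#' @param g Relative strength of inhibition; \code{g > 1} means inhibition
#'   dominates.
#' @param theta_E,theta_I Firing thresholds.
#' @param J_EX_factor,J_IX_factor External weights expressed as multiples of
#'   \eqn{\sqrt{p_{EE} N_E}}; the realized \code{J_EX}, \code{J_IX} are stored
#'   on the returned object.
#' @param m_X External drive rate in \[0, 1\], modelled as a constant.
#' @param tau_E,tau_I Population time constants in ms.
#' @param clustering_mode One of \code{"none"}, \code{"E_weights"},
#'   \code{"EI_weights"}, \code{"E_weights_background"},
#'   \code{"E_probability"}.
#' @param J_Eplus Within-cluster excitatory weight multiplier \eqn{J_{E+} \ge 1}.
#' @param R_J Inhibitory-to-excitatory clustering ratio in \[0, 1\]
#'   (EI mode; \eqn{J_{I+} = 1 + R_J (J_{E+} - 1)}).
#' @param background_fraction Fraction of E units kept as unstructured
#'   background (background mode only).
#' @param R_EE Within/across connection-probability ratio
#'   \eqn{p_{in}/p_{out} \ge 1} (probability-clustering mode).
#' @param seed Integer seed stored with the spec for reproducible
#'   connectivity realizations.
#'
#' @return An object of class \code{"network_spec"}: a named list of the
#'   validated parameters plus derived \code{N}, \code{J_EX}, \code{J_IX} and
#'   in-degrees \code{K} (matrix \eqn{K_{\alpha\beta} = p_{\alpha\beta} N_\beta}).
#' @export
#' @examples
#' spec <- network_spec()
#' spec$J_EX / sqrt(spec$p_EE * spec$N_E)  # 1
network_spec <- function(N_E = 4000L, N_I = 1000L, Q = 20L,
                         p_EE = 0.2, p_EI = 0.5, p_IE = 0.5, p_II = 0.5,
                         g = 1.2, theta_E = 1, theta_I = 1,
                         J_EX_factor = 1, J_IX_factor = 0.8, m_X = 0.03,
                         tau_E = 10, tau_I = 0.5 * tau_E,
                         clustering_mode = c("none", "E_weights", "EI_weights",
                                             "E_weights_background",
                                             "E_probability"),
                         J_Eplus = 1, R_J = 0, background_fraction = 0,
                         R_EE = 1, seed = 1L) {
  clustering_mode <- match.arg(clustering_mode)
  stopifnot(N_E > 0, N_I > 0, Q >= 1, g > 0, m_X >= 0, m_X <= 1,
            tau_E > 0, tau_I > 0, J_Eplus >= 1, R_J >= 0, R_J <= 1,
            background_fraction >= 0, background_fraction < 1, R_EE >= 1)
  probs <- c(p_EE = p_EE, p_EI = p_EI, p_IE = p_IE, p_II = p_II)
  if (any(probs < 0 | probs > 1))
    stop("connection probabilities must lie in [0, 1]")
  N <- N_E + N_I
  spec <- list(
    N_E = as.integer(N_E), N_I = as.integer(N_I), N = as.integer(N),
    Q = as.integer(Q),
    p_EE = p_EE, p_EI = p_EI, p_IE = p_IE, p_II = p_II,
    g = g, theta_E = theta_E, theta_I = theta_I,
    J_EX_factor = J_EX_factor, J_IX_factor = J_IX_factor,
    J_EX = J_EX_factor * sqrt(p_EE * N_E),
    J_IX = J_IX_factor * sqrt(p_EE * N_E),
    m_X = m_X, tau_E = tau_E, tau_I = tau_I,
    clustering_mode = clustering_mode,
    J_Eplus = J_Eplus, R_J = R_J,
    background_fraction = background_fraction, R_EE = R_EE,
    seed = as.integer(seed))
  spec$K <- matrix(c(p_EE * N_E, p_EI * N_I,
                     p_IE * N_E, p_II * N_I),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("E", "I"), c("E", "I")))
  class(spec) <- "network_spec"
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> N_E=%d N_I=%d g=%.3g m_X=%.3g mode=%s",
              x$N_E, x$N_I, x$g, x$m_X, x$clustering_mode))
  if (x$clustering_mode != "none")
    cat(sprintf(" Q=%d J_Eplus=%.3g R_J=%.3g", x$Q, x$J_Eplus, x$R_J))
  cat("\n")
  invisible(x)
}

.spec_yaml_keys <- c("N_E", "N_I", "Q", "theta", "theta_E", "theta_I",
                     "tau_E", "tau_I_over_tau_E",
                     "p_EE", "p_EI", "p_IE", "p_II", "g",
                     "J_EX_factor", "J_IX_factor", "m_X",
                     "clustering_mode", "J_Eplus", "R_J",
                     "background_fraction", "R_EE", "seed")

#' Serialize a network spec to a flat YAML/JSON-friendly list
#'
#' Keys follow the conventional parameter symbols (\code{theta},
#' \code{tau_I_over_tau_E}, \code{p_EE}, \code{g}, \code{J_EX_factor},
#' \code{J_IX_factor}, \code{m_X}, ...). \code{spec_from_list} rejects
#' unknown keys.
#'
#' @param spec A \code{network_spec}.
#' @return \code{spec_to_list}: a flat named list; \code{spec_to_yaml}: a
#'   YAML string.
#' @export
spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  out <- list(N_E = spec$N_E, N_I = spec$N_I, Q = spec$Q,
              tau_E = spec$tau_E,
              tau_I_over_tau_E = spec$tau_I / spec$tau_E,
              p_EE = spec$p_EE, p_EI = spec$p_EI, p_IE = spec$p_IE,
              p_II = spec$p_II, g = spec$g,
              J_EX_factor = spec$J_EX_factor, J_IX_factor = spec$J_IX_factor,
              m_X = spec$m_X, clustering_mode = spec$clustering_mode,
              J_Eplus = spec$J_Eplus, R_J = spec$R_J,
              background_fraction = spec$background_fraction,
              R_EE = spec$R_EE, seed = spec$seed)
  if (spec$theta_E == spec$theta_I) {
    out$theta <- spec$theta_E
  } else {
    out$theta_E <- spec$theta_E
    out$theta_I <- spec$theta_I
  }
  out
}

#' @rdname spec_to_list
#' @export
spec_to_yaml <- function(spec) yaml::as.yaml(spec_to_list(spec))

#' Rebuild a network spec from a flat list or YAML string/file
#'
#' @param x A flat named list (\code{spec_from_list}) or YAML text or file
#'   path (\code{spec_from_yaml}).
#' @return A \code{network_spec}.
#' @export
spec_from_list <- function(x) {
  unknown <- setdiff(names(x), .spec_yaml_keys)
  if (length(unknown))
    stop("unknown network_spec keys: ", paste(unknown, collapse = ", "))
  theta_E <- if (!is.null(x$theta)) x$theta else x$theta_E
  theta_I <- if (!is.null(x$theta)) x$theta else x$theta_I
  args <- x[setdiff(names(x), c("theta", "theta_E", "theta_I",
                                "tau_I_over_tau_E"))]
  if (!is.null(theta_E)) args$theta_E <- theta_E
  if (!is.null(theta_I)) args$theta_I <- theta_I
  if (!is.null(x$tau_I_over_tau_E)) {
    tau_E <- if (!is.null(x$tau_E)) x$tau_E else 10
    args$tau_E <- tau_E
    args$tau_I <- x$tau_I_over_tau_E * tau_E
  }
  do.call(network_spec, args)
}

#' @rdname spec_from_list
#' @export
spec_from_yaml <- function(x) {
  parsed <- if (length(x) == 1 && file.exists(x)) yaml::read_yaml(x)
            else yaml::yaml.load(x)
  spec_from_list(parsed)
}
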