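#' Jacobian of the rate dynamics
#'
#' Partial derivatives of \eqn{\dot m_\alpha} with respect to \eqn{m_\beta}:
#' \deqn{\frac{\partial \dot m_\alpha}{\partial m_\beta} =
#'  -\frac{1}{\tau_\alpha}\left(\delta_{\alpha\beta} +
#'  H'\!\left(-\frac{\mu_\alpha}{s_\alpha}\right)
#'  \frac{\bar J_{\alpha\beta} s_\alpha -
#'        \frac{1}{2}\mu_\alpha \bar J^{(2)}_{\alpha\beta} / s_\alpha}
#'       {s^2_\alpha}\right)}
#' with \eqn{H'(x) = -e^{-x^2/2}/\sqrt{2\pi}}. The second term in the
#' numerator is the variance path: a rate change also moves the input
#' variance, which shifts the effective threshold.
#'
#' @inheritParams input_moments
#' @param m0 Evaluation point (usually a fixed point).
#' @return P x P matrix (time unit \eqn{\tau_E}).
#' @export
mf_jacobian <- function(sys, m0) {
  stopifnot(inherits(sys, "population_system"), length(m0) == sys$P)
  io <- input_moments(sys, m0)
  if (any(io$s2 <= 0))
    stop("mf_jacobian: input variance is zero for some population; ",
         "the Gaussian gain is degenerate there (all-off states cannot be ",
         "classified by linearization)")
  s <- sqrt(io$s2)
  x <- -io$mu / s
  Hp <- -exp(-x^2 / 2) / sqrt(2 * pi)
  num <- sys$Jbar * s - 0.5 * io$mu * sys$Jbar2 / s
  jac <- -(diag(sys$P) + Hp * num / io$s2) / sys$tau
  dimnames(jac) <- dimnames(sys$Jbar)
  jac
}

#' Classify a fixed point of the rate dynamics
#'
#' Computes the Jacobian eigenvalues at \code{m0} and labels the point
#' \code{"stable node"} (all eigenvalues real and negative),
#' \code{"stable spiral"} (complex with negative real parts),
#' \code{"marginal"} (some \eqn{|Re \lambda|} below tolerance) or
#' \code{"unstable"}. For two-population systems the report additionally
#' carries the trace \eqn{T_S}, determinant \eqn{\delta_S}, the
#' \eqn{\tau}-scaled partials \eqn{f'_{\alpha\beta}} (convention
#' \eqn{\tau_E = 1}) and the critical time-constant ratios
#' \eqn{r_1, r_2, r_3} from \code{\link{critical_ratios}}.
#'
#' @inheritParams mf_jacobian
#' @param tol_marginal Real parts smaller than this in magnitude are treated
#'   as marginal.
#' @return An object of class \code{"stability_report"}.
#' @export
classify_fixed_point <- function(sys, m0, tol_marginal = 1e-8) {
  jac <- mf_jacobian(sys, m0)
  ev <- eigen(jac, only.values = TRUE)$values
  re <- Re(ev)
  is_real <- abs(Im(ev)) < 1e-10 * max(1, abs(ev))
  classification <-
    if (any(abs(re) < tol_marginal)) "marginal"
    else if (all(re < 0) && all(is_real)) "stable node"
    else if (all(re < 0)) "stable spiral"
    else "unstable"
  rep <- list(eigenvalues = ev, stable = all(re < 0),
              max_re = max(re), classification = classification,
              P = sys$P)
  if (sys$P == 2) {
    rep$T_S <- sum(diag(jac))
    rep$delta_S <- jac[1, 1] * jac[2, 2] - jac[1, 2] * jac[2, 1]
    fp <- jac * sys$tau          # tau-scaled partials, tau_E = 1
    rep$fprime_EE <- fp[1, 1]; rep$fprime_EI <- fp[1, 2]
    rep$fprime_IE <- fp[2, 1]; rep$fprime_II <- fp[2, 2]
    cr <- critical_ratios(fp[1, 1], fp[1, 2], fp[2, 1], fp[2, 2])
    rep[c("A", "B", "r1", "r2", "r3")] <- cr[c("A", "B", "r1", "r2", "r3")]
  }
  class(rep) <- "stability_report"
  rep
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s (max Re lambda = %.3g, P = %d)\n",
              x$classification, x$max_re, x$P))
  invisible(x)
}

#' Critical inhibitory-to-excitatory time-constant ratios
#'
#' For a two-population system with \eqn{\tau_E = 1}, the trace and
#' determinant of the stability matrix are
#' \eqn{T_S = f'_{EE} + f'_{II}/\tau_I} and
#' \eqn{\delta_S = (f'_{EE} f'_{II} - f'_{EI} f'_{IE})/\tau_I}. Substituting
#' into the discriminant and trace conditions yields three bifurcation
#' ratios
#' \deqn{r_1 = A - \sqrt{A^2 - B^2},\; r_2 = -B,\; r_3 = A + \sqrt{A^2 - B^2}}
#' with \eqn{A = (f'_{EE} f'_{II} - 2 f'_{EI} f'_{IE})/(f'_{EE})^2} and
#' \eqn{B = f'_{II}/f'_{EE}}. Below \eqn{r_1} the fixed point is a stable
#' node, between \eqn{r_1} and \eqn{r_2} a stable spiral, and above
#' \eqn{r_2} it is unstable (a large-amplitude limit cycle takes over).
#'
#' @param fprime_EE,fprime_EI,fprime_IE,fprime_II The \eqn{\tau}-scaled
#'   partial derivatives at the fixed point; \code{fprime_EE} must be
#'   nonzero.
#' @return List with \code{A}, \code{B}, \code{r1}, \code{r2}, \code{r3};
#'   \code{r1}/\code{r3} are \code{NA} when \eqn{A^2 < B^2} (complex).
#' @export
critical_ratios <- function(fprime_EE, fprime_EI, fprime_IE, fprime_II) {
  if (fprime_EE == 0)
    stop("critical_ratios: fprime_EE must be nonzero")
  A <- (fprime_EE * fprime_II - 2 * fprime_EI * fprime_IE) / fprime_EE^2
  B <- fprime_II / fprime_EE
  disc <- A^2 - B^2
  if (disc >= 0) {
    r1 <- A - sqrt(disc)
    r3 <- A + sqrt(disc)
  } else {
    r1 <- NA_real_
    r3 <- NA_real_
  }
  list(A = A, B = B, r1 = r1, r2 = -B, r3 = r3)
}

#' Sweep the time-constant ratio and classify the balanced fixed point
#'
#' Helper for locating the oscillatory instability: for each ratio
#' \eqn{\tau_I/\tau_E} the balanced fixed point of the two-population
#' system is solved and its leading eigenvalue recorded.
#'
#' @param spec A \code{\link{network_spec}} (clustering mode ignored; the
#'   two-population reduction is used).
#' @param ratios Numeric vector of \eqn{\tau_I/\tau_E} values.
#' @return Data frame with \code{ratio}, \code{max_re} and
#'   \code{classification}.
#' @export
stability_sweep <- function(spec, ratios) {
  out <- lapply(ratios, function(r) {
    sp <- spec
    sp$tau_I <- r * sp$tau_E
    sys <- reduce_network(.with_mode(sp, "none"))
    fp <- solve_homogeneous(sys)
    rep <- classify_fixed_point(sys, fp$m)
    data.frame(ratio = r, max_re = rep$max_re,
               classification = rep$classification)
  })
  do.call(rbind, out)
}

.with_mode <- function(spec, mode) {
  spec$clustering_mode <- mode
  spec
}
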