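# Shared fixtures and independent oracles for the test suite.

# The standard parameter set at full size.
default_spec <- function(...) network_spec(...)

# A small network with the same probabilities and g, cheap to realize.
small_spec <- function(...) {
  network_spec(N_E = 400L, N_I = 100L, Q = 20L, ...)
}

# Independent construction of the two-population mean weights
# Jbar_ab = N_b * p_ab * J_ab, straight from the definition (no reuse of
# reduce_network internals).
oracle_jbar2pop <- function(spec, w) {
  matrix(c(spec$N_E * spec$p_EE * w$J_EE, spec$N_I * spec$p_EI * w$J_EI,
           spec$N_E * spec$p_IE * w$J_IE, spec$N_I * spec$p_II * w$J_II),
         2, 2, byrow = TRUE)
}

# Balanced rates by solving the input-cancellation linear system
# Jbar m = -Jx mX directly.
oracle_balanced_rates <- function(spec) {
  w <- derive_weights(spec)
  Jbar <- oracle_jbar2pop(spec, w)
  drop(solve(Jbar, -c(spec$J_EX, spec$J_IX) * spec$m_X))
}

# Central finite differences of the rate derivative.
oracle_fd_jacobian <- function(sys, m0, eps = 1e-6) {
  P <- sys$P
  out <- matrix(0, P, P)
  for (b in seq_len(P)) {
    up <- m0; up[b] <- up[b] + eps
    dn <- m0; dn[b] <- dn[b] - eps
    out[, b] <- (rate_derivative(sys, up) - rate_derivative(sys, dn)) /
      (2 * eps)
  }
  out
}

# Empirical density of a matrix block.
block_density <- function(J, rows, cols) {
  length(J[rows, cols, drop = FALSE]@x) / (length(rows) * length(cols))
}
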