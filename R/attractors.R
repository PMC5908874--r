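#' Newton refinement of a rate fixed point
#'
#' Damped Newton iteration on \eqn{G(m) = H(-\mu/s) - m}, using the
#' analytic Jacobian of the dynamics. Iterates are clamped to the unit
#' cube (outside it the input variance can turn negative). A subset of
#' coordinates can be held fixed, in which case the root is sought in the
#' complementary subspace.
#'
#' @inheritParams input_moments
#' @param m0 Starting point.
#' @param fixed Optional logical mask of clamped populations.
#' @param tol Convergence tolerance on the maximum residual.
#' @param maxit Maximum Newton steps.
#' @return List with \code{m}, \code{residual}, \code{converged}.
#' @export
mf_newton <- function(sys, m0, fixed = NULL, tol = 1e-12, maxit = 60L) {
  P <- sys$P
  if (is.null(fixed)) fixed <- rep(FALSE, P)
  free <- which(!fixed)
  m <- pmin(pmax(as.numeric(m0), 0), 1)
  G <- mf_gain(sys, m) - m
  rn <- max(abs(G[free]))
  for (it in seq_len(maxit)) {
    if (rn < tol) break
    io <- input_moments(sys, m)
    if (any(io$s2[free] <= 0)) return(list(m = m, residual = rn,
                                           converged = FALSE))
    JG <- (mf_jacobian(sys, m) * sys$tau)[free, free, drop = FALSE]
    step <- tryCatch(solve(JG, G[free]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(m = m, residual = rn, converged = FALSE))
    lam <- 1
    repeat {
      m_new <- m
      m_new[free] <- pmin(pmax(m[free] - lam * step, 0), 1)
      G_new <- mf_gain(sys, m_new) - m_new
      rn_new <- max(abs(G_new[free]))
      if (rn_new < rn || lam < 1 / 64) break
      lam <- lam / 2
    }
    if (rn_new >= rn) return(list(m = m, residual = rn, converged = rn < tol))
    m <- m_new; G <- G_new; rn <- rn_new
  }
  list(m = m, residual = rn, converged = rn < tol)
}

# Lump populations with identical dynamics into groups. Exact when rows of
# Jbar/Jbar2 are identical within each group and the group shares a rate.
.lump_system <- function(sys, groups) {
  G <- max(groups)
  reps <- vapply(seq_len(G), function(g) which(groups == g)[1], integer(1))
  agg <- function(M) {
    out <- matrix(0, G, G)
    for (g in seq_len(G))
      for (h in seq_len(G))
        out[g, h] <- sum(M[reps[g], groups == h])
    out
  }
  sizes <- vapply(seq_len(G), function(g) sum(sys$sizes[groups == g]),
                  numeric(1))
  lab <- vapply(seq_len(G), function(g)
    paste0(sys$labels[reps[g]], if (sum(groups == g) > 1) "*" else ""),
    character(1))
  red <- .new_population_system(
    sizes = sizes, Jbar = agg(sys$Jbar), Jbar2 = agg(sys$Jbar2),
    theta = sys$theta[reps], Jx = sys$Jx[reps], m_X = sys$m_X,
    tau = sys$tau[reps], labels = lab, pop_type = sys$pop_type[reps],
    cluster_id = sys$cluster_id[reps], spec = sys$spec)
  list(sys = red, groups = groups, reps = reps)
}

# Default grouping for the homogeneous (all clusters equal) state:
# one group per distinct row structure (E clusters / background / I ...).
.homogeneous_groups <- function(sys) {
  key <- paste(sys$pop_type, is.na(sys$cluster_id),
               sys$labels == "Ebg")
  as.integer(factor(key, levels = unique(key)))
}

#' Solve the homogeneous fixed point of a clustered system
#'
#' All E clusters share one rate (and all I clusters share one rate in EI
#' mode), so the system reduces exactly to one equation per population
#' class. The reduced fixed point is found by relaxation plus Newton
#' polish, lifted back to the full system, and re-verified there.
#'
#' @inheritParams input_moments
#' @param tol Residual tolerance required of the solution.
#' @return List with \code{m} (full-length rate vector), \code{residual},
#'   \code{converged}.
#' @export
solve_homogeneous <- function(sys, tol = 1e-10) {
  lump <- .lump_system(sys, .homogeneous_groups(sys))
  red <- lump$sys
  m0 <- rep(0.1, red$P)
  if (!is.null(sys$spec) && sys$spec$g != 1) {
    br <- balanced_rates(sys$spec)
    m0 <- ifelse(red$pop_type == "E", br["m_E"], br["m_I"])
  }
  # Fixed-point locations do not depend on the time constants (only their
  # stability does), so relax under tau = 1 where the balanced point
  # attracts, then polish; this also reaches points that are unstable at
  # the requested tau ratio.
  red1 <- red
  red1$tau <- rep(1, red$P)
  relax <- integrate_rates(red1, m0, T = 50, record_every = 0L)
  pol <- mf_newton(red, relax$final, tol = 1e-13)
  degenerate <- function(p)
    !p$converged || any(input_moments(red, p$m)$s2 <= 0)
  if (degenerate(pol)) pol <- mf_newton(red, m0, tol = 1e-13)
  if (degenerate(pol)) pol <- mf_newton(red, m0 / 2, tol = 1e-13)
  m_full <- pol$m[lump$groups]
  list(m = m_full, residual = mf_residual(sys, m_full),
       converged = pol$converged && mf_residual(sys, m_full) < tol)
}

#' Canonical signature of a fixed point
#'
#' Cluster permutation symmetry makes states equivalent up to relabelling.
#' The signature is the multiset of E-cluster rates rounded to 1e-4 and
#' sorted descending, plus the count of "active" clusters: clusters whose
#' rate exceeds the midpoint between the largest and smallest E-cluster
#' rate (0 for homogeneous states). In EI mode, inhibitory partners are
#' carried through the same permutation.
#'
#' @inheritParams input_moments
#' @param m Rate vector.
#' @param digits Rounding used for the signature key.
#' @return List with \code{key} (string), \code{n_active}, \code{m_up}
#'   (largest E rate), \code{m_canonical} (permuted rate vector).
#' @export
fp_signature <- function(sys, m, digits = 4L) {
  eidx <- which(sys$pop_type == "E" & !is.na(sys$cluster_id))
  if (length(eidx) == 0) eidx <- which(sys$pop_type == "E")
  me <- m[eidx]
  ord <- order(me, decreasing = TRUE)
  m_can <- m
  m_can[eidx] <- me[ord]
  iidx <- which(sys$pop_type == "I" & !is.na(sys$cluster_id))
  if (length(iidx) == length(eidx) && length(iidx) > 0)
    m_can[iidx] <- m[iidx][ord]
  rng <- diff(range(me))
  n_active <- if (rng < 1e-6) 0L
              else sum(me > (max(me) + min(me)) / 2)
  key <- paste0("a", n_active, "|",
                paste(sprintf("%.*f", digits, sort(round(me, digits),
                                                   decreasing = TRUE)),
                      collapse = ","))
  list(key = key, n_active = n_active, m_up = max(me), m_canonical = m_can)
}

.make_fixed_point <- function(sys, m, residual_tol = 1e-9) {
  res <- mf_residual(sys, m)
  if (res >= residual_tol) return(NULL)
  io <- input_moments(sys, m)
  if (any(io$s2 <= 0)) return(NULL)  # all-off style degenerate state
  rep <- classify_fixed_point(sys, m)
  sig <- fp_signature(sys, m)
  structure(list(m = m, residual = res, report = rep,
                 signature = sig$key, n_active = sig$n_active,
                 m_up = sig$m_up, m_canonical = sig$m_canonical,
                 stable = rep$stable),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> %s, n_active=%d, m_up=%.4f, residual=%.2e\n",
              x$report$classification, x$n_active, x$m_up, x$residual))
  invisible(x)
}

#' Random-restart sampling of stable fixed points
#'
#' Rates are initialised uniformly in \[0, 1\], integrated for a number of
#' time constants so that trajectories settle near an attractor, then
#' refined to a root of the steady-state equations and verified
#' (residual below \code{residual_tol}). Points are deduplicated by their
#' permutation-invariant signature. Because the pre-integration follows
#' the flow, the procedure discovers stable states; unstable refinements
#' are discarded unless \code{keep_unstable}.
#'
#' @inheritParams input_moments
#' @param n_restarts Number of random initial conditions.
#' @param seed Integer seed.
#' @param T_relax Pre-integration duration in units of \eqn{\tau_E}.
#' @param residual_tol Acceptance tolerance on the fixed-point residual.
#' @param keep_unstable Keep points classified unstable (off by default).
#' @return List of \code{fixed_point} objects (unique signatures).
#' @export
sample_fixed_points <- function(sys, n_restarts = 200L, seed = 1L,
                                T_relax = 50, residual_tol = 1e-9,
                                keep_unstable = FALSE) {
  stopifnot(n_restarts >= 1)
  set.seed(seed)
  found <- list()
  n_fail <- 0L
  for (r in seq_len(n_restarts)) {
    m0 <- stats::runif(sys$P)
    relax <- integrate_rates(sys, m0, T = T_relax, record_every = 0L)
    pol <- mf_newton(sys, relax$final)
    fp <- if (pol$converged) .make_fixed_point(sys, pol$m, residual_tol)
          else NULL
    if (is.null(fp)) { n_fail <- n_fail + 1L; next }
    if (!fp$stable && !keep_unstable) next
    if (is.null(found[[fp$signature]])) found[[fp$signature]] <- fp
  }
  if (length(found) == 0)
    stop("sample_fixed_points: no fixed point found in ", n_restarts,
         " restarts (", n_fail, " failures)")
  unname(found)
}

# Grouping for n_active constrained solving.
.constrained_groups <- function(sys, n_active) {
  Q <- max(sys$cluster_id, na.rm = TRUE)
  stopifnot(n_active >= 1, n_active < Q)
  g <- integer(sys$P)
  is_ecl <- sys$pop_type == "E" & !is.na(sys$cluster_id)
  is_icl <- sys$pop_type == "I" & !is.na(sys$cluster_id)
  g[is_ecl & sys$cluster_id <= n_active] <- 1L
  g[is_ecl & sys$cluster_id > n_active] <- 2L
  nxt <- 3L
  if (any(is_icl)) {
    g[is_icl & sys$cluster_id <= n_active] <- nxt
    g[is_icl & sys$cluster_id > n_active] <- nxt + 1L
    nxt <- nxt + 2L
  }
  rest <- which(g == 0L)
  for (k in seq_along(rest)) { g[rest[k]] <- nxt; nxt <- nxt + 1L }
  g
}

#' Fixed points with a prescribed number of active clusters
#'
#' Constrains all but \code{n_active} clusters to share a rate, which
#' reduces the steady-state system to one equation per group: (active
#' clusters, remaining clusters, I) for excitatory clustering — three
#' equations — or (active E, other E, partner I, other I) in EI mode —
#' four equations. The reduced system is solved from a grid of starting
#' points by Newton iteration; every solution (stable or not) is lifted
#' back to the full system, re-verified there and re-classified with the
#' full Jacobian. An empty result is a valid outcome (no such state
#' exists at these parameters).
#'
#' @inheritParams input_moments
#' @param n_active Number of simultaneously active clusters (1 to Q-1).
#' @param residual_tol Acceptance tolerance on the full-system residual.
#' @param focus_grid Starting rates for the active group.
#' @return List of \code{fixed_point} objects, sorted by \code{m_up}.
#' @export
solve_constrained <- function(sys, n_active = 1L, residual_tol = 1e-9,
                              focus_grid = seq(0.02, 0.99, length.out = 21)) {
  lump <- .lump_system(sys, .constrained_groups(sys, n_active))
  red <- lump$sys
  base <- solve_homogeneous(sys)
  base_red <- vapply(seq_len(red$P), function(g)
    mean(base$m[lump$groups == g]), numeric(1))
  sols <- list()
  add_sol <- function(m_red) {
    m_full <- m_red[lump$groups]
    pol <- mf_newton(sys, m_full)  # polish in the full system
    if (!pol$converged) return(invisible(NULL))
    fp <- .make_fixed_point(sys, pol$m, residual_tol)
    if (!is.null(fp) && is.null(sols[[fp$signature]]))
      sols[[fp$signature]] <<- fp
    invisible(NULL)
  }
  # start Newton from states whose slave coordinates are relaxed given the
  # imposed focus rate (under tau = 1, where relaxation is well behaved)
  red1 <- red
  red1$tau <- rep(1, red$P)
  clamp <- c(TRUE, rep(FALSE, red$P - 1))
  for (f in focus_grid) {
    m0 <- base_red
    m0[1] <- f
    relax <- integrate_rates(red1, m0, T = 30, fixed = clamp,
                             record_every = 0L)
    pol <- mf_newton(red, relax$final)
    if (pol$converged) add_sol(pol$m)
  }
  # plus the unconstrained homogeneous start
  pol <- mf_newton(red, base_red)
  if (pol$converged) add_sol(pol$m)
  sols <- unname(sols)
  sols[order(vapply(sols, `[[`, numeric(1), "m_up"))]
}

#' Effective response function of a focus population
#'
#' The rate of one focus population is treated as a parameter
#' \eqn{\bar m_1}; all remaining (slave) populations are relaxed to their
#' steady state given \eqn{\bar m_1}, and the implied output of the focus
#' population \eqn{\Phi_{eff}(\bar m_1) = H(-\mu_1/s_1)} evaluated at the
#' slave solution is recorded. Intersections with the diagonal are fixed
#' points of the full system; a slope above unity at the crossing marks it
#' unstable along the focus direction. Because the one-dimensional
#' reduction ignores the time-constant ratios, each crossing is also
#' classified with the full Jacobian.
#'
#' @inheritParams input_moments
#' @param focus Index of the focus population.
#' @param grid Imposed focus rates (at least 50 points in \[0, 1\]).
#' @param T_relax Slave relaxation time per grid point.
#' @return An object of class \code{"efr_curve"}: list with \code{grid},
#'   \code{phi_eff}, \code{slaves} (matrix of slave solutions),
#'   \code{valid}, and \code{crossings} (data frame with \code{m_star},
#'   \code{slope}, \code{stable_on_curve}, \code{stable_full},
#'   \code{classification}).
#' @export
effective_response <- function(sys, focus = 1L,
                               grid = seq(0, 1, length.out = 201),
                               T_relax = 30) {
  stopifnot(length(grid) >= 50, all(grid >= 0 & grid <= 1))
  P <- sys$P
  fixed <- rep(FALSE, P); fixed[focus] <- TRUE
  base <- solve_homogeneous(sys)
  slave_state <- base$m

  solve_slaves <- function(mbar, init) {
    m0 <- init; m0[focus] <- mbar
    relax <- integrate_rates(sys, m0, T = T_relax, fixed = fixed,
                             record_every = 0L)
    pol <- mf_newton(sys, relax$final, fixed = fixed)
    if (!pol$converged) return(NULL)
    pol$m
  }
  n <- length(grid)
  phi <- rep(NA_real_, n)
  slaves <- matrix(NA_real_, n, P)
  valid <- rep(FALSE, n)
  for (k in seq_len(n)) {
    m <- solve_slaves(grid[k], slave_state)
    if (is.null(m)) next
    slave_state <- m
    slaves[k, ] <- m
    phi[k] <- mf_gain(sys, m)[focus]
    valid[k] <- TRUE
  }
  if (any(!valid) && any(valid)) # interpolate over isolated failures
    phi[!valid] <- stats::approx(grid[valid], phi[valid], grid[!valid],
                                 rule = 2)$y
  # diagonal crossings: sign changes of phi - m, refined by bisection
  d <- phi - grid
  crossings <- list()
  for (k in seq_len(n - 1)) {
    if (!is.finite(d[k]) || !is.finite(d[k + 1])) next
    if (d[k] == 0 || sign(d[k]) * sign(d[k + 1]) < 0) {
      lo <- grid[k]; hi <- grid[k + 1]
      flo <- d[k]
      init <- slaves[k, ]
      for (b in 1:40) {
        mid <- (lo + hi) / 2
        m <- solve_slaves(mid, init)
        if (is.null(m)) break
        init <- m
        fmid <- mf_gain(sys, m)[focus] - mid
        if (sign(fmid) == sign(flo)) { lo <- mid; flo <- fmid }
        else hi <- mid
        if (hi - lo < 1e-10) break
      }
      m_star <- (lo + hi) / 2
      m_sol <- solve_slaves(m_star, init)
      if (is.null(m_sol)) next
      m_sol[focus] <- m_star
      pol <- mf_newton(sys, m_sol)
      eps <- 1e-4
      up <- solve_slaves(min(m_star + eps, 1), m_sol)
      dn <- solve_slaves(max(m_star - eps, 0), m_sol)
      slope <- if (!is.null(up) && !is.null(dn))
        (mf_gain(sys, up)[focus] - mf_gain(sys, dn)[focus]) /
          (min(m_star + eps, 1) - max(m_star - eps, 0))
      else NA_real_
      full <- if (pol$converged) .make_fixed_point(sys, pol$m) else NULL
      crossings[[length(crossings) + 1]] <- data.frame(
        m_star = m_star,
        slope = slope,
        stable_on_curve = !is.na(slope) && slope < 1,
        stable_full = if (!is.null(full)) full$stable else NA,
        classification = if (!is.null(full)) full$report$classification
                         else NA_character_)
    }
  }
  out <- list(grid = grid, phi_eff = phi, slaves = slaves, valid = valid,
              focus = focus,
              crossings = if (length(crossings)) do.call(rbind, crossings)
                          else data.frame(m_star = numeric(0),
                                          slope = numeric(0),
                                          stable_on_curve = logical(0),
                                          stable_full = logical(0),
                                          classification = character(0)))
  class(out) <- "efr_curve"
  out
}

#' @export
print.efr_curve <- function(x, ...) {
  cat(sprintf("<efr_curve> %d grid points, %d diagonal crossings\n",
              length(x$grid), nrow(x$crossings)))
  invisible(x)
}

# Build the population system for a clustering strength value.
.sys_at <- function(spec, mode, J_Eplus, R_J = spec$R_J) {
  spec$clustering_mode <- mode
  spec$J_Eplus <- J_Eplus
  spec$R_J <- R_J
  reduce_network(spec)
}

# Reduced (active-group, other-group, [partner I, other I] / I) system used
# for the single-focus effective response function.
.efr_reduced <- function(spec, mode, J_Eplus, R_J = spec$R_J) {
  sys <- .sys_at(spec, mode, J_Eplus, R_J)
  .lump_system(sys, .constrained_groups(sys, 1L))$sys
}

#' Critical clustering strength
#'
#' Scans the excitatory clustering strength \eqn{J_{E+}} on a grid and
#' locates either (i) \code{"homogeneous_unstable"}: the smallest value at
#' which the homogeneous fixed point (all clusters at one rate) is linearly
#' unstable in the full clustered system, or (ii) \code{"upstate_emerges"}:
#' the smallest value at which the single-focus effective response function
#' crosses the diagonal more than once (a stable up-state with an
#' intermediate unstable point has appeared). The coarse scan (default
#' step 0.1) is optionally refined by bisection to 0.01.
#'
#' @param spec A \code{\link{network_spec}}.
#' @param mode \code{"E_weights"} or \code{"EI_weights"}.
#' @param R_J Inhibitory clustering ratio (EI mode).
#' @param criterion \code{"homogeneous_unstable"} or
#'   \code{"upstate_emerges"}.
#' @param step Scan step for \eqn{J_{E+}}.
#' @param bounds Scan bounds (defaults to \[1, Q\]).
#' @param refine Bisect between the bracketing grid values down to 0.01.
#' @return List with \code{grid_value} (first grid point meeting the
#'   criterion), \code{refined} (bisection estimate, or the grid value if
#'   \code{refine = FALSE}), and the scan table \code{scan}. Both values
#'   are \code{NA} if the criterion is never met within the bounds.
#' @export
critical_clustering_strength <- function(spec,
                                         mode = c("E_weights", "EI_weights"),
                                         R_J = spec$R_J,
                                         criterion = c("homogeneous_unstable",
                                                       "upstate_emerges"),
                                         step = 0.1,
                                         bounds = c(1, spec$Q),
                                         refine = TRUE) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  test_fun <- if (criterion == "homogeneous_unstable") {
    function(J) {
      sys <- .sys_at(spec, mode, J, R_J)
      hom <- solve_homogeneous(sys)
      classify_fixed_point(sys, hom$m)$max_re > 0
    }
  } else {
    function(J) {
      red <- .efr_reduced(spec, mode, J, R_J)
      nrow(effective_response(red, focus = 1L)$crossings) > 1
    }
  }
  grid <- seq(bounds[1], bounds[2], by = step)
  hit <- rep(NA, length(grid))
  first <- NA_real_
  for (k in seq_along(grid)) {
    hit[k] <- test_fun(grid[k])
    if (hit[k]) { first <- grid[k]; break }
  }
  scan <- data.frame(J_Eplus = grid[seq_len(max(which(!is.na(hit))))],
                     met = hit[seq_len(max(which(!is.na(hit))))])
  if (is.na(first)) {
    warning("criterion '", criterion, "' not met within bounds")
    return(list(grid_value = NA_real_, refined = NA_real_, scan = scan))
  }
  refined <- first
  if (refine && first > bounds[1]) {
    lo <- first - step; hi <- first
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      if (test_fun(mid)) hi <- mid else lo <- mid
    }
    refined <- hi
  }
  list(grid_value = first, refined = refined, scan = scan)
}

#' Attractor landscape sweep over clustering strength
#'
#' For each value of the sweep parameter, collects the stable fixed points
#' found by random-restart sampling together with constrained
#' single-active-cluster (and optionally multi-active) solutions,
#' deduplicated by signature.
#'
#' @param spec A \code{\link{network_spec}}.
#' @param mode Clustering architecture.
#' @param R_J Inhibitory clustering ratio (EI mode).
#' @param grid Values of \eqn{J_{E+}} to sweep.
#' @param n_restarts Restart budget per grid value.
#' @param seed Integer seed.
#' @param n_active_max Also run constrained solves for 1..n_active_max
#'   active clusters.
#' @param include_unstable Keep unstable states in the table (flagged).
#' @return An object of class \code{"attractor_landscape"}: a long-format
#'   data frame (\code{sweep_value}, \code{signature_id}, \code{n_active},
#'   \code{population_label}, \code{rate}, \code{stable},
#'   \code{max_re_lambda}) with the sweep metadata as attributes.
#' @export
landscape_sweep <- function(spec, mode = c("E_weights", "EI_weights"),
                            R_J = spec$R_J,
                            grid = seq(1, spec$Q, by = 0.5),
                            n_restarts = 200L, seed = 1L,
                            n_active_max = 1L, include_unstable = FALSE) {
  mode <- match.arg(mode)
  rows <- list()
  for (v in grid) {
    sys <- .sys_at(spec, mode, v, R_J)
    fps <- tryCatch(
      sample_fixed_points(sys, n_restarts = n_restarts,
                          seed = seed + round(1000 * v)),
      error = function(e) list())
    Q <- spec$Q
    for (na in seq_len(min(n_active_max, Q - 1))) {
      more <- solve_constrained(sys, n_active = na)
      for (fp in more) {
        if (!fp$stable && !include_unstable) next
        fps <- c(fps, list(fp))
      }
    }
    seen <- character(0)
    sid <- 0L
    for (fp in fps) {
      if (fp$signature %in% seen) next
      seen <- c(seen, fp$signature)
      sid <- sid + 1L
      rows[[length(rows) + 1]] <- data.frame(
        sweep_value = v, signature_id = sid, n_active = fp$n_active,
        population_label = sys$labels, rate = fp$m_canonical,
        stable = fp$stable, max_re_lambda = fp$report$max_re)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sweep_parameter") <- "J_Eplus"
  attr(out, "mode") <- mode
  attr(out, "R_J") <- R_J
  attr(out, "n_restarts") <- n_restarts
  attr(out, "seed") <- seed
  class(out) <- c("attractor_landscape", "data.frame")
  out
}

#' Maximum stable up-state rate of a landscape
#'
#' @param landscape An \code{\link{landscape_sweep}} result.
#' @param active_only Restrict to states with at least one active cluster.
#' @return Largest stable excitatory rate in the table.
#' @export
landscape_max_rate <- function(landscape, active_only = TRUE) {
  d <- landscape[landscape$stable &
                   grepl("^E", landscape$population_label), , drop = FALSE]
  if (active_only) d <- d[d$n_active > 0, , drop = FALSE]
  if (nrow(d) == 0) return(NA_real_)
  max(d$rate)
}
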