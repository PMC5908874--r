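#' Across-cluster weight renormalization factor
#'
#' When within-cluster connections are strengthened by \eqn{J_+}, connections
#' between units of different clusters are scaled by
#' \deqn{J_- = \frac{Q - J_+}{Q - 1}}
#' so that the expected row sum of each connectivity quadrant is unchanged
#' ("balance of weights"). \eqn{J_+ = 1} gives homogeneous connectivity
#' (\eqn{J_- = 1}); at \eqn{J_+ = Q} the clusters decouple (\eqn{J_- = 0}).
#'
#' @param Q Number of clusters, at least 2.
#' @param J_plus Within-cluster multiplier; values above \code{Q} yield
#'   negative across-cluster weights and trigger a warning.
#' @return The across-cluster multiplier \eqn{J_-}.
#' @export
#' @examples
#' cluster_scaling(20, 2)   # 18/19
cluster_scaling <- function(Q, J_plus) {
  if (Q < 2) stop("cluster_scaling: Q must be at least 2")
  if (J_plus > Q)
    warning("cluster_scaling: J_plus > Q gives negative across-cluster weights")
  (Q - J_plus) / (Q - 1)
}

#' Cluster parameters for a network spec
#'
#' Collects the cluster multipliers implied by a spec: \eqn{J_{E+}},
#' \eqn{J_{E-}} from \code{\link{cluster_scaling}}, and in EI mode
#' \eqn{J_{I+} = 1 + R_J (J_{E+} - 1)} with its own \eqn{J_{I-}}, plus the
#' unit-to-cluster assignments (contiguous equal-sized blocks).
#'
#' @param spec A \code{\link{network_spec}}.
#' @return List with the multipliers, mode, and \code{assignment_E} /
#'   \code{assignment_I} integer vectors (\code{NA} for unclustered units;
#'   in background mode background units are \code{NA} in
#'   \code{assignment_E}).
#' @export
cluster_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  mode <- spec$clustering_mode
  Q <- spec$Q
  out <- list(Q = Q, mode = mode, J_Eplus = spec$J_Eplus,
              J_Eminus = NA_real_, J_Iplus = NA_real_, J_Iminus = NA_real_,
              R_J = spec$R_J, R_EE = spec$R_EE,
              assignment_E = rep(NA_integer_, spec$N_E),
              assignment_I = rep(NA_integer_, spec$N_I))
  if (mode == "none") return(out)
  if (mode %in% c("E_weights", "EI_weights", "E_probability")) {
    if (spec$N_E %% Q != 0) stop("N_E must be divisible by Q")
    out$assignment_E <- rep(seq_len(Q), each = spec$N_E / Q)
  }
  if (mode %in% c("E_weights", "EI_weights")) {
    out$J_Eminus <- cluster_scaling(Q, spec$J_Eplus)
  }
  if (mode == "EI_weights") {
    if (spec$N_I %% Q != 0) stop("N_I must be divisible by Q in EI mode")
    out$J_Iplus <- 1 + spec$R_J * (spec$J_Eplus - 1)
    out$J_Iminus <- cluster_scaling(Q, out$J_Iplus)
    out$assignment_I <- rep(seq_len(Q), each = spec$N_I / Q)
  }
  if (mode == "E_weights_background") {
    N_bg <- round(spec$background_fraction * spec$N_E)
    N_cl <- spec$N_E - N_bg
    if (N_cl %% Q != 0)
      stop("clustered E units (N_E minus background) must be divisible by Q")
    out$J_Eminus <- cluster_scaling(Q, spec$J_Eplus)
    out$assignment_E <- c(rep(seq_len(Q), each = N_cl / Q),
                          rep(NA_integer_, N_bg))
  }
  out
}

# Draw one presynaptic column of the sparse weight matrix.
# segs: list of (rows = integer range, p, w) for this column.
.draw_column <- function(segs, self = NA_integer_) {
  ii <- integer(0); xx <- numeric(0)
  for (s in segs) {
    nrows <- length(s$rows)
    if (nrows == 0 || s$p <= 0 || s$w == 0) next
    k <- stats::rbinom(1L, nrows, s$p)
    if (k == 0) next
    r <- s$rows[sample.int(nrows, k)]
    ii <- c(ii, r); xx <- c(xx, rep(s$w, k))
  }
  if (!is.na(self)) {
    keep <- ii != self
    ii <- ii[keep]; xx <- xx[keep]
  }
  ord <- sort.int(ii, index.return = TRUE, method = "radix")
  list(i = ord$x, x = xx[ord$ix])
}

#' Build a realized unit-level weight matrix
#'
#' Draws the Bernoulli connectivity \eqn{J^{ij}_{\alpha\beta}} of a network:
#' each ordered pair is connected independently with probability
#' \eqn{p_{\alpha\beta}} and carries weight \eqn{J_{\alpha\beta}} times the
#' cluster multiplier for its (postsynaptic, presynaptic) cluster pair.
#' Rows are postsynaptic, columns presynaptic; units \code{1..N_E} are
#' excitatory. Self-connections are excluded (diagonal forced to zero;
#' negligible at these densities but conventional).
#'
#' Modes: \code{"none"} (uniform), \code{"E_weights"} (EE block gets
#' \eqn{J_{E\pm}}), \code{"EI_weights"} (EE gets \eqn{J_{E\pm}}; EI, IE and
#' II all get \eqn{J_{I\pm}}), \code{"E_weights_background"} (a fraction of
#' E units stays unclustered; renormalization applies among clustered units
#' only), \code{"E_probability"} (within/across connection probabilities
#' \eqn{p_{in} = R_{EE}\, p_{out}} with the mean probability preserved, and
#' a within-cluster weight factor).
#'
#' @param spec A \code{\link{network_spec}} whose \code{clustering_mode}
#'   selects the architecture.
#' @param weights Optional \code{\link{derive_weights}} result.
#' @param seed Integer seed (defaults to \code{spec$seed}).
#' @param prob_weight_factor Within-cluster weight multiplier for
#'   probability-clustering mode.
#' @return An object of class \code{"weight_matrix"}: list with \code{J}
#'   (a \code{dgCMatrix}), \code{N_E}, \code{N_I}, \code{cluster}
#'   (\code{\link{cluster_spec}} result), \code{spec} and \code{seed}.
#' @export
build_matrix <- function(spec, weights = derive_weights(spec),
                         seed = spec$seed, prob_weight_factor = 1.9) {
  stopifnot(inherits(spec, "network_spec"))
  cl <- cluster_spec(spec)
  mode <- spec$clustering_mode
  N_E <- spec$N_E; N_I <- spec$N_I; N <- spec$N
  w <- weights
  set.seed(seed)
  rows_E <- seq_len(N_E)
  rows_I <- N_E + seq_len(N_I)
  aE <- cl$assignment_E
  aI <- cl$assignment_I
  bg_rows <- which(is.na(aE))
  # precomputed within/across row index sets per E cluster
  e_ranges <- i_ranges <- e_out <- i_out <- NULL
  if (mode != "none") {
    e_ranges <- lapply(seq_len(spec$Q), function(q) which(aE == q))
    clustered_E <- which(!is.na(aE))
    e_out <- lapply(seq_len(spec$Q), function(q)
      clustered_E[aE[clustered_E] != q])
  }
  if (mode == "EI_weights") {
    i_ranges <- lapply(seq_len(spec$Q), function(q) N_E + which(aI == q))
    i_out <- lapply(seq_len(spec$Q), function(q) N_E + which(aI != q))
  }

  pp <- if (mode == "E_probability")
    .probability_cluster_probs(spec$p_EE, spec$Q, spec$R_EE) else NULL

  col_parts <- vector("list", N)
  for (j in seq_len(N)) {
    if (j <= N_E) {
      cj <- aE[j]
      segs <- list()
      if (mode == "none" || is.na(cj)) {
        # unclustered presynaptic E unit (or background unit)
        segs <- c(segs, list(list(rows = rows_E, p = spec$p_EE, w = w$J_EE)))
      } else if (mode == "E_probability") {
        segs <- c(segs,
                  list(list(rows = e_ranges[[cj]], p = pp$p_in,
                            w = prob_weight_factor * w$J_EE),
                       list(rows = e_out[[cj]], p = pp$p_out,
                            w = w$J_EE)))
      } else {
        if (mode == "E_weights_background")
          segs <- c(segs, list(list(rows = bg_rows, p = spec$p_EE,
                                    w = w$J_EE)))
        segs <- c(segs,
                  list(list(rows = e_ranges[[cj]], p = spec$p_EE,
                            w = cl$J_Eplus * w$J_EE),
                       list(rows = e_out[[cj]], p = spec$p_EE,
                            w = cl$J_Eminus * w$J_EE)))
      }
      if (mode == "EI_weights") {
        segs <- c(segs,
                  list(list(rows = i_ranges[[cj]], p = spec$p_IE,
                            w = cl$J_Iplus * w$J_IE),
                       list(rows = i_out[[cj]], p = spec$p_IE,
                            w = cl$J_Iminus * w$J_IE)))
      } else {
        segs <- c(segs, list(list(rows = rows_I, p = spec$p_IE, w = w$J_IE)))
      }
      col_parts[[j]] <- .draw_column(segs, self = j)
    } else {
      cj <- aI[j - N_E]
      segs <- list()
      if (mode == "EI_weights" && !is.na(cj)) {
        segs <- list(
          list(rows = e_ranges[[cj]], p = spec$p_EI,
               w = cl$J_Iplus * w$J_EI),
          list(rows = e_out[[cj]], p = spec$p_EI,
               w = cl$J_Iminus * w$J_EI),
          list(rows = i_ranges[[cj]], p = spec$p_II,
               w = cl$J_Iplus * w$J_II),
          list(rows = i_out[[cj]], p = spec$p_II,
               w = cl$J_Iminus * w$J_II))
      } else {
        segs <- list(list(rows = rows_E, p = spec$p_EI, w = w$J_EI),
                     list(rows = rows_I, p = spec$p_II, w = w$J_II))
      }
      col_parts[[j]] <- .draw_column(segs, self = j)
    }
  }
  lens <- vapply(col_parts, function(cp) length(cp$i), integer(1))
  # columns are already row-sorted: assemble the CSC slots directly
  J <- methods::new(methods::getClassDef("dgCMatrix", package = "Matrix"),
                    p = c(0L, cumsum(lens)),
                    i = unlist(lapply(col_parts, `[[`, "i"),
                               use.names = FALSE) - 1L,
                    x = unlist(lapply(col_parts, `[[`, "x"),
                               use.names = FALSE),
                    Dim = c(N, N))
  out <- list(J = J, N_E = N_E, N_I = N_I, cluster = cl, spec = spec,
              seed = seed)
  class(out) <- "weight_matrix"
  out
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d x %d, %d synapses, mode=%s, seed=%d\n",
              nrow(x$J), ncol(x$J), length(x$J@x),
              x$spec$clustering_mode, x$seed))
  invisible(x)
}

# within/across probabilities for probability clustering with the mean
# connection probability preserved: (p_in + (Q-1) p_out)/Q = p_EE,
# p_in = R_EE * p_out.
.probability_cluster_probs <- function(p_EE, Q, R_EE) {
  if (R_EE < 1) stop("R_EE must be >= 1")
  p_out <- p_EE * Q / (R_EE + Q - 1)
  p_in <- R_EE * p_out
  if (p_in > 1)
    stop("probability clustering: p_in = ", signif(p_in, 4), " exceeds 1")
  list(p_in = p_in, p_out = p_out)
}

#' Probability-clustered connectivity
#'
#' Convenience wrapper for \code{\link{build_matrix}} with clustering by an
#' increased within-cluster connection probability
#' (\eqn{R_{EE} = p_{in}/p_{out}}, mean probability preserved) and a
#' within-cluster weight factor.
#'
#' @inheritParams build_matrix
#' @param R_EE Probability ratio, at least 1.
#' @return A \code{weight_matrix}.
#' @export
build_probability_clustered <- function(spec, weights = derive_weights(spec),
                                        R_EE = spec$R_EE, seed = spec$seed,
                                        prob_weight_factor = 1.9) {
  spec$clustering_mode <- "E_probability"
  spec$R_EE <- R_EE
  build_matrix(spec, weights, seed, prob_weight_factor = prob_weight_factor)
}

#' Weight-clustered connectivity with an unstructured background
#'
#' Convenience wrapper for \code{\link{build_matrix}} with a fraction of the
#' E units kept outside all clusters; background units connect everywhere
#' with the unmodified weight, and the across-cluster renormalization is
#' applied among the clustered units only.
#'
#' @inheritParams build_matrix
#' @param background_fraction Fraction of E units in the background; 0
#'   degenerates to plain weight clustering.
#' @return A \code{weight_matrix}.
#' @export
build_background_variant <- function(spec, weights = derive_weights(spec),
                                     background_fraction =
                                       spec$background_fraction,
                                     seed = spec$seed) {
  spec$background_fraction <- background_fraction
  spec$clustering_mode <- if (background_fraction == 0) "E_weights"
                          else "E_weights_background"
  build_matrix(spec, weights, seed)
}

#' Export / import a weight matrix as sparse triplet text
#'
#' Writes a tab-separated file with columns \code{i}, \code{j}, \code{x}
#' (1-based row = postsynaptic, column = presynaptic) preceded by a
#' \code{# nrow ncol} header line, and a two-column TSV of cluster
#' assignments (\code{unit_id}, \code{cluster_id}; 0 means unclustered).
#'
#' @param wm A \code{weight_matrix}.
#' @param file Path for the triplet file.
#' @param assignment_file Optional path for the assignment TSV.
#' @return \code{write_weight_matrix}: invisibly, the file path.
#'   \code{read_weight_matrix}: a \code{dgCMatrix}.
#' @export
write_weight_matrix <- function(wm, file, assignment_file = NULL) {
  stopifnot(inherits(wm, "weight_matrix"))
  trip <- Matrix::summary(wm$J)
  con <- file(file, "w")
  writeLines(sprintf("# %d %d", nrow(wm$J), ncol(wm$J)), con)
  utils::write.table(data.frame(i = trip$i, j = trip$j, x = trip$x),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(assignment_file)) {
    assign_all <- c(wm$cluster$assignment_E,
                    ifelse(is.na(wm$cluster$assignment_I), NA,
                           wm$cluster$assignment_I + wm$spec$Q))
    utils::write.table(
      data.frame(unit_id = seq_len(wm$N_E + wm$N_I),
                 cluster_id = ifelse(is.na(assign_all), 0L, assign_all)),
      assignment_file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(file) {
  hdr <- scan(file, what = character(), nlines = 1, quiet = TRUE)
  dims <- as.integer(hdr[2:3])
  trip <- utils::read.table(file, header = TRUE, skip = 1, sep = "\t")
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = dims)
}
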