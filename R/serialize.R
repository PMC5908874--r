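#' Serialize a population system to JSON
#'
#' Matrices are emitted row-major as nested arrays together with all scalar
#' and vector fields needed to rebuild the system.
#'
#' @param sys A \code{\link{reduce_network}} result.
#' @param file Optional path; when missing the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
sys_to_json <- function(sys, file = NULL) {
  stopifnot(inherits(sys, "population_system"))
  payload <- list(P = sys$P, sizes = sys$sizes,
                  Jbar = apply(sys$Jbar, 1, identity, simplify = FALSE),
                  Jbar2 = apply(sys$Jbar2, 1, identity, simplify = FALSE),
                  theta = sys$theta, Jx = sys$Jx, m_X = sys$m_X,
                  tau = sys$tau, labels = sys$labels,
                  pop_type = sys$pop_type, cluster_id = sys$cluster_id)
  if (is.null(file))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Rate trajectory as a data frame (t, m_1, ..., m_P)
#'
#' @param traj An \code{\link{integrate_rates}} result.
#' @param labels Optional population labels used as column names.
#' @param file Optional CSV path to write.
#' @return The data frame (invisibly when writing).
#' @export
trajectory_df <- function(traj, labels = NULL, file = NULL) {
  m <- traj$m
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  cols <- if (!is.null(labels)) labels else paste0("m_", seq_len(ncol(m)))
  out <- data.frame(t = traj$t, m, check.names = FALSE)
  names(out) <- c("t", cols)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Serialize a stability report to JSON
#'
#' Complex eigenvalues are written as (re, im) pairs.
#'
#' @param report A \code{\link{classify_fixed_point}} result.
#' @param file Optional path.
#' @return JSON string (invisibly, when writing to a file).
#' @export
report_to_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "stability_report"))
  payload <- unclass(report)
  payload$eigenvalues <- lapply(report$eigenvalues, function(z)
    list(re = Re(z), im = Im(z)))
  if (is.null(file))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
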