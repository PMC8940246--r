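#' Solve a bounded linear program
#'
#' Thin contract over the package's built-in bounded-variable two-phase
#' simplex: maximize \code{c'x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}.  All flux-balance computations in the package go
#' through this single entry point, so the backend (and its tolerance) can be
#' swapped or tuned in one place.
#'
#' @param A constraint matrix (dense or \pkg{Matrix} sparse), one row per
#'   balance constraint.
#' @param b right-hand side vector.
#' @param obj objective coefficient vector (maximized).
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param tol optimality/feasibility tolerance (default
#'   \code{getOption("gutbrainflux.lp_tol", 1e-9)}).
#' @return list with \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"iteration_limit"}),
#'   \code{objective} and the primal solution \code{x}.
#' @export
lp_maximize <- function(A, b, obj, lb, ub, tol = lp_tolerance()) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == length(b), ncol(A) == length(obj),
            length(lb) == length(obj), length(ub) == length(obj))
  if (any(lb > ub)) abort("lp_maximize: lb > ub for some variable")
  res <- .simplex_solve(A, as.numeric(b), as.numeric(obj),
                        as.numeric(lb), as.numeric(ub), tol = tol)
  status <- c(`0` = "optimal", `1` = "infeasible", `2` = "unbounded",
              `3` = "iteration_limit")[[as.character(res$status)]]
  list(status = status,
       objective = if (status == "optimal") res$objective else NA_real_,
       x = if (status == "optimal") as.numeric(res$x) else numeric(0))
}
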