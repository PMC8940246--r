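#' Abundance-derived objective weights
#'
#' Reproduces the community weighting scheme: the host biomass keeps a fixed
#' weight (default 1/6); the remainder is split between the beneficial and
#' harmful member classes in the ratio \code{beneficial_percent :
#' (100 - beneficial_percent)} and equally within each class.  The weights
#' sum to 1.
#'
#' @param beneficial_percent percentage abundance of beneficial members
#'   (0-100).
#' @param beneficial_ids,harmful_ids identifiers (tags or biomass reaction
#'   ids) of the members in each class.
#' @param host_weight host share in [0, 1); default \code{1/6}.
#' @param host_id name used for the host entry.
#' @return named numeric vector of weights (beneficials, harmfuls, host).
#' @export
compute_weights <- function(beneficial_percent, beneficial_ids, harmful_ids,
                            host_weight = 1/6, host_id = "host") {
  if (beneficial_percent < 0 || beneficial_percent > 100)
    abort("beneficial_percent must be in [0, 100]")
  if (host_weight < 0 || host_weight >= 1)
    abort("host_weight must be in [0, 1)")
  rest <- 1 - host_weight
  b_share <- rest * beneficial_percent / 100
  h_share <- rest * (100 - beneficial_percent) / 100
  if (b_share > 0 && !length(beneficial_ids))
    abort("beneficial class has nonzero share but no members")
  if (h_share > 0 && !length(harmful_ids))
    abort("harmful class has nonzero share but no members")
  w <- c(setNames(rep(if (length(beneficial_ids)) b_share / length(beneficial_ids) else numeric(0),
                      length(beneficial_ids)), beneficial_ids),
         setNames(rep(if (length(harmful_ids)) h_share / length(harmful_ids) else numeric(0),
                      length(harmful_ids)), harmful_ids))
  w[host_id] <- host_weight
  w
}

#' Define a multi-objective Pareto problem
#'
#' @param model a \code{stoich_model} (community or merged organ model).
#' @param objectives ordered reaction ids of the objectives.
#' @param weights per-objective nonnegative weights; normalized to sum to 1
#'   (default equal).
#' @param max_iterations search iteration cap (default 100).
#' @param tolerance convergence tolerance on the Euclidean norm of the step
#'   between subsequent iterates (default 1e-6).
#' @return a \code{pareto_problem}.
#' @export
pareto_problem <- function(model, objectives, weights = NULL,
                           max_iterations = 100, tolerance = 1e-6) {
  validate_model(model)
  rxn_index(model, objectives)
  n <- length(objectives)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) abort("one weight per objective required")
  if (any(weights < 0)) abort("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) abort("weights must not all be zero")
  weights <- weights / s
  structure(list(model = model, objectives = objectives,
                 weights = setNames(weights, objectives),
                 max_iterations = max_iterations, tolerance = tolerance),
            class = "pareto_problem")
}

# Per-objective minima and maxima under the model's current constraints.
objective_ranges <- function(model, objectives, tol = lp_tolerance()) {
  mins <- maxs <- setNames(numeric(length(objectives)), objectives)
  for (o in objectives) {
    up <- solve_fba(model, setNames(1, o), tol = tol)
    dn <- solve_fba(model, setNames(-1, o), tol = tol)
    if (up$status != "optimal" || dn$status != "optimal")
      abort("no feasible community state")
    maxs[o] <- up$objective_value
    mins[o] <- -dn$objective_value
  }
  list(mins = mins, maxs = maxs)
}

# Feasibility of a candidate objective vector: solve the LP with the
# objective lower bounds raised to the candidate point.
point_solution <- function(model, objectives, point, tol = lp_tolerance()) {
  idx <- rxn_index(model, objectives)
  m2 <- model
  m2$rxns$lb[idx] <- pmax(m2$rxns$lb[idx], point)
  bad <- m2$rxns$lb[idx] > m2$rxns$ub[idx]
  if (any(bad)) return(NULL)
  res <- lp_maximize(m2$S, rep(0, nrow(m2$S)), rep(0, nrow(m2$rxns)),
                     m2$rxns$lb, m2$rxns$ub, tol = tol)
  if (res$status != "optimal") return(NULL)
  setNames(res$x, m2$rxns$id)
}

pareto_solution <- function(point, fluxes, iterations, converged) {
  structure(list(objective_fluxes = point, fluxes = fluxes,
                 iterations = iterations, converged = converged),
            class = "pareto_solution")
}

#' @export
print.pareto_solution <- function(x, ...) {
  cat("<pareto_solution>\n")
  print(round(x$objective_fluxes, 6))
  cat(sprintf("iterations=%d converged=%s\n", x$iterations, x$converged))
  invisible(x)
}

#' Unweighted Pareto optimization by linear search
#'
#' Starting from the per-objective minima, advances all objective lower
#' bounds by equal per-objective increments (each objective's range divided
#' by \code{max_iterations}) while the community LP remains feasible; once a
#' step becomes infeasible the increment is halved, until the step norm
#' falls below the tolerance or the iteration cap is reached.  Returns the
#' last feasible point.
#'
#' @param problem a \code{pareto_problem} with equal weights.
#' @param tol LP tolerance.
#' @return a \code{pareto_solution}.
#' @export
pareto_linear_search <- function(problem, tol = lp_tolerance()) {
  stopifnot(inherits(problem, "pareto_problem"))
  obj <- problem$objectives
  rng <- objective_ranges(problem$model, obj, tol)
  p <- rng$mins
  fx <- point_solution(problem$model, obj, p, tol)
  if (is.null(fx)) abort("no feasible community state")
  delta <- (rng$maxs - rng$mins) / problem$max_iterations
  iter <- 0L
  converged <- FALSE
  while (iter < problem$max_iterations) {
    iter <- iter + 1L
    if (sqrt(sum(delta^2)) < problem$tolerance) { converged <- TRUE; break }
    cand <- pmin(p + delta, rng$maxs)
    sol <- point_solution(problem$model, obj, cand, tol)
    if (is.null(sol)) {
      delta <- delta / 2
    } else {
      p <- cand; fx <- sol
    }
  }
  pareto_solution(p, fx, iter, converged)
}

#' Weighted Pareto optimization by binary search
#'
#' Searches along the ray from the per-objective minima with direction
#' proportional to the weights for the furthest feasible scaling, by
#' bisection; stops when the remaining interval norm falls below the
#' tolerance or at the iteration cap.
#'
#' @param problem a \code{pareto_problem} (weights may be unequal).
#' @param tol LP tolerance.
#' @return a \code{pareto_solution}.
#' @export
pareto_binary_search <- function(problem, tol = lp_tolerance()) {
  stopifnot(inherits(problem, "pareto_problem"))
  obj <- problem$objectives
  d <- problem$weights
  rng <- objective_ranges(problem$model, obj, tol)
  at <- function(t) pmin(rng$mins + t * d, rng$maxs)
  fx0 <- point_solution(problem$model, obj, rng$mins, tol)
  if (is.null(fx0)) abort("no feasible community state")
  pos <- d > 0 & (rng$maxs - rng$mins) > 0
  if (!any(pos))
    return(pareto_solution(rng$mins, fx0, 0L, TRUE))
  t_hi <- max((rng$maxs - rng$mins)[pos] / d[pos])
  sol_hi <- point_solution(problem$model, obj, at(t_hi), tol)
  if (!is.null(sol_hi))
    return(pareto_solution(at(t_hi), sol_hi, 1L, TRUE))
  t_lo <- 0; fx <- fx0
  iter <- 0L
  dn <- sqrt(sum(d^2))
  while (iter < problem$max_iterations &&
         (t_hi - t_lo) * dn >= problem$tolerance) {
    iter <- iter + 1L
    mid <- (t_lo + t_hi) / 2
    sol <- point_solution(problem$model, obj, at(mid), tol)
    if (is.null(sol)) t_hi <- mid else { t_lo <- mid; fx <- sol }
  }
  pareto_solution(at(t_lo), fx, iter,
                  (t_hi - t_lo) * dn < problem$tolerance)
}

#' Pin a model to a Pareto state
#'
#' Fixes each objective reaction's bounds to its Pareto flux
#' (\code{lb = ub = value}), the state under which toxin maximization and
#' FVA are subsequently run.  Errors if the pinned model is infeasible.
#'
#' @param model the \code{stoich_model} the solution was computed on.
#' @param solution a \code{pareto_solution} (or named numeric vector of
#'   reaction fluxes to pin).
#' @param slack half-width of the pinning band (default 0: exact
#'   \code{lb = ub}).  A small positive slack accommodates points located
#'   by an iterative search that stops within its tolerance of the
#'   feasible facet.
#' @param tol LP tolerance.
#' @export
fix_pareto_state <- function(model, solution, slack = 0, tol = lp_tolerance()) {
  vals <- if (inherits(solution, "pareto_solution"))
    solution$objective_fluxes else solution
  if (is.null(names(vals))) abort("pinned values must be named by reaction")
  model <- set_bounds(model, names(vals),
                      lb = as.numeric(vals) - slack,
                      ub = as.numeric(vals) + slack)
  feas <- lp_maximize(model$S, rep(0, nrow(model$S)),
                      rep(0, nrow(model$rxns)),
                      model$rxns$lb, model$rxns$ub, tol = tol)
  if (feas$status != "optimal")
    abort("pinning the pareto state makes the model infeasible")
  model
}

#' @export
tidy.pareto_solution <- function(x, ...) {
  tibble(objective = names(x$objective_fluxes),
         flux = as.numeric(x$objective_fluxes))
}

#' @export
glance.pareto_solution <- function(x, ...) {
  tibble(n_objectives = length(x$objective_fluxes),
         iterations = x$iterations, converged = x$converged)
}
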