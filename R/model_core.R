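#' Create an empty stoichiometric model
#'
#' A \code{stoich_model} holds the data of a constraint-based metabolic
#' model: metabolites, reactions with bounds (mmol/gDW/hr) and subsystem
#' labels, the stoichiometric matrix \code{S}, and the set of reactions
#' eligible as optimization objectives (biomass, ATP maintenance, demand
#' reactions).
#'
#' @param id model identifier.
#' @return an object of class \code{stoich_model}.
#' @export
new_model <- function(id = "model") {
  structure(
    list(id = id,
         mets = tibble(id = character(), name = character(),
                       compartment = character()),
         rxns = tibble(id = character(), name = character(),
                       lb = numeric(), ub = numeric(),
                       subsystem = character()),
         S = Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(0L, 0L)),
         objectives = character()),
    class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %s: %d metabolites, %d reactions, %d objective candidate(s)\n",
              x$id, nrow(x$mets), nrow(x$rxns), length(x$objectives)))
  invisible(x)
}

met_compartment_guess <- function(id) {
  m <- regmatches(id, regexpr("_[a-z]+$", id))
  if (length(m) == 1 && nzchar(m)) sub("^_", "", m) else "c"
}

#' Add metabolites to a model
#'
#' @param model a \code{stoich_model}.
#' @param ids metabolite identifiers; the compartment defaults to the suffix
#'   after the last underscore (e.g. \code{"glc_e"} is placed in \code{"e"}).
#' @param compartment,name optional vectors recycled along \code{ids}.
#' @export
add_metabolites <- function(model, ids, compartment = NULL, name = ids) {
  ids <- setdiff(ids, model$mets$id)
  if (!length(ids)) return(model)
  if (is.null(compartment)) compartment <- vapply(ids, met_compartment_guess, "")
  model$mets <- dplyr::bind_rows(
    model$mets,
    tibble(id = ids, name = rep_len(name, length(ids)),
           compartment = rep_len(compartment, length(ids))))
  model$S <- rbind(model$S,
                   Matrix::sparseMatrix(i = integer(), j = integer(),
                                        x = numeric(),
                                        dims = c(length(ids), ncol(model$S))))
  rownames(model$S) <- model$mets$id
  colnames(model$S) <- model$rxns$id
  model
}

#' Add a reaction to a model
#'
#' @param model a \code{stoich_model}.
#' @param id reaction identifier (must be new).
#' @param stoich named numeric vector, metabolite id -> coefficient
#'   (negative = consumed).  May be empty for pure exchange stubs.
#' @param lb,ub flux bounds in mmol/gDW/hr.
#' @param subsystem subsystem label used by pathway scoring.
#' @param name human-readable name.
#' @param objective if \code{TRUE}, register the reaction as an objective
#'   candidate.
#' @param auto_mets create referenced metabolites that do not exist yet.
#' @export
add_reaction <- function(model, id, stoich, lb = -1000, ub = 1000,
                         subsystem = "unassigned", name = id,
                         objective = FALSE, auto_mets = TRUE) {
  if (id %in% model$rxns$id) abort(sprintf("reaction '%s' already in model", id))
  if (lb > ub) abort(sprintf("reaction '%s': lb > ub", id))
  missing <- setdiff(names(stoich), model$mets$id)
  if (length(missing)) {
    if (!auto_mets)
      abort(sprintf("reaction '%s' references unknown metabolites: %s",
                    id, paste(missing, collapse = ", ")))
    model <- add_metabolites(model, missing)
  }
  model$rxns <- dplyr::bind_rows(
    model$rxns,
    tibble(id = id, name = name, lb = lb, ub = ub, subsystem = subsystem))
  newcol <- Matrix::sparseMatrix(
    i = match(names(stoich), model$mets$id), j = rep(1L, length(stoich)),
    x = as.numeric(stoich), dims = c(nrow(model$mets), 1L))
  model$S <- cbind(model$S, newcol)
  rownames(model$S) <- model$mets$id
  colnames(model$S) <- model$rxns$id
  if (objective) model$objectives <- union(model$objectives, id)
  model
}

rxn_index <- function(model, ids) {
  idx <- match(ids, model$rxns$id)
  if (anyNA(idx))
    abort(sprintf("unknown reaction(s): %s",
                  paste(ids[is.na(idx)], collapse = ", ")))
  idx
}

#' Set flux bounds of one or more reactions
#' @param model a \code{stoich_model}.
#' @param ids reaction ids.
#' @param lb,ub new bounds (recycled); \code{NULL} leaves a bound unchanged.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  idx <- rxn_index(model, ids)
  if (!is.null(lb)) model$rxns$lb[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$rxns$ub[idx] <- rep_len(ub, length(idx))
  bad <- idx[model$rxns$lb[idx] > model$rxns$ub[idx]]
  if (length(bad))
    abort(sprintf("set_bounds leaves lb > ub for: %s",
                  paste(model$rxns$id[bad], collapse = ", ")))
  model
}

#' Validate the structural invariants of a model
#'
#' Checks that bounds are ordered, that the stoichiometric matrix is
#' consistent with the metabolite and reaction tables, and that exchange
#' reactions touch exactly one metabolite.
#' @param model a \code{stoich_model}.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  if (nrow(model$S) != nrow(model$mets) || ncol(model$S) != nrow(model$rxns))
    abort("S dimensions disagree with metabolite/reaction tables")
  if (any(model$rxns$lb > model$rxns$ub))
    abort("some reaction has lb > ub")
  if (anyDuplicated(model$rxns$id)) abort("duplicate reaction ids")
  if (anyDuplicated(model$mets$id)) abort("duplicate metabolite ids")
  unknown <- setdiff(model$objectives, model$rxns$id)
  if (length(unknown))
    abort(sprintf("objective candidates not in model: %s",
                  paste(unknown, collapse = ", ")))
  invisible(model)
}

#' Identify exchange reactions
#'
#' An exchange reaction has exactly one metabolite with nonzero
#' stoichiometric coefficient (a system boundary).
#' @param model a \code{stoich_model}.
#' @return logical vector along the reaction table.
#' @export
is_exchange <- function(model) {
  Matrix::colSums(model$S != 0) == 1
}

#' Metabolite carried by each exchange reaction (NA for non-exchanges)
#' @param model a \code{stoich_model}.
#' @export
exchanged_metabolite <- function(model) {
  n <- Matrix::colSums(model$S != 0)
  out <- rep(NA_character_, ncol(model$S))
  ex <- which(n == 1)
  for (j in ex) out[j] <- model$mets$id[which(model$S[, j] != 0)]
  setNames(out, model$rxns$id)
}

objective_vector <- function(model, objective) {
  w <- rep(0, nrow(model$rxns))
  if (is.character(objective)) {
    w[rxn_index(model, objective)] <- 1
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    if (!length(objective)) abort("objective must map at least one reaction")
    if (any(!is.finite(objective))) abort("objective weights must be finite")
    w[rxn_index(model, names(objective))] <- as.numeric(objective)
  } else abort("objective must be reaction ids or a named numeric vector")
  w
}

#' Flux balance analysis
#'
#' Maximizes a weighted combination of reaction fluxes over the steady-state
#' polytope \eqn{S v = 0,\ lb \le v \le ub}.
#'
#' @param model a \code{stoich_model}.
#' @param objective reaction id(s) (weight 1 each) or a named numeric vector
#'   of weights.
#' @param tol LP tolerance.
#' @return a \code{flux_solution}: list with \code{status}
#'   (\code{"optimal"}, \code{"infeasible"} or \code{"unbounded"}),
#'   \code{objective_value} and named \code{fluxes}.
#' @export
solve_fba <- function(model, objective = model$objectives, tol = lp_tolerance()) {
  validate_model(model)
  w <- objective_vector(model, objective)
  res <- lp_maximize(model$S, rep(0, nrow(model$S)), w,
                     model$rxns$lb, model$rxns$ub, tol = tol)
  structure(
    list(status = res$status,
         objective_value = res$objective,
         fluxes = if (res$status == "optimal")
           setNames(res$x, model$rxns$id) else NULL,
         model_id = model$id),
    class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s objective=%s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux under the
#' model's current (already fixed) constraints; run after pinning e.g. the
#' Pareto-optimal biomass state.
#'
#' @param model a \code{stoich_model} with any fixed-state constraints
#'   already applied to its bounds.
#' @param reactions reaction ids (default: all).
#' @param tol LP tolerance.
#' @return an \code{fva_result}: tibble with \code{reaction},
#'   \code{fva_min}, \code{fva_max}, \code{subsystem}.
#' @export
run_fva <- function(model, reactions = model$rxns$id, tol = lp_tolerance()) {
  validate_model(model)
  idx <- rxn_index(model, reactions)
  # fail fast on an infeasible fixed state, before any per-reaction solve
  feas <- lp_maximize(model$S, rep(0, nrow(model$S)),
                      rep(0, nrow(model$rxns)),
                      model$rxns$lb, model$rxns$ub, tol = tol)
  if (feas$status != "optimal")
    abort(sprintf("FVA fixed state is %s", feas$status))
  A <- as.matrix(model$S)
  b <- rep(0, nrow(A))
  lo <- model$rxns$lb; hi <- model$rxns$ub
  fmin <- fmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    w <- rep(0, length(lo)); w[idx[k]] <- 1
    up <- .simplex_solve(A, b, w, lo, hi, tol = tol)
    dn <- .simplex_solve(A, b, -w, lo, hi, tol = tol)
    if (up$status != 0 || dn$status != 0)
      abort(sprintf("FVA subproblem for '%s' did not solve",
                    model$rxns$id[idx[k]]))
    fmax[k] <- up$objective
    fmin[k] <- -dn$objective
  }
  out <- tibble(reaction = model$rxns$id[idx],
                fva_min = pmin(fmin, fmax), fva_max = pmax(fmin, fmax),
                subsystem = model$rxns$subsystem[idx])
  class(out) <- c("fva_result", class(out))
  attr(out, "model_id") <- model$id
  out
}

#' Write an FVA result as TSV (reaction_id, min, max, subsystem)
#' @param fva an \code{fva_result}.
#' @param path output file.
#' @export
write_fva_tsv <- function(fva, path) {
  utils::write.table(
    data.frame(reaction_id = fva$reaction, min = fva$fva_min,
               max = fva$fva_max, subsystem = fva$subsystem),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.flux_solution <- function(x, ...) {
  if (is.null(x$fluxes))
    return(tibble(reaction = character(), flux = numeric()))
  tibble(reaction = names(x$fluxes), flux = as.numeric(x$fluxes))
}

#' @export
glance.flux_solution <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value,
         n_reactions = length(x$fluxes))
}
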