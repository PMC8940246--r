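#' FVA interval comparison metrics
#'
#' For each reaction present in both FVA results, the mean shift
#' \eqn{|\,(max_1+min_1)/2 - (max_2+min_2)/2\,|} (absolute displacement of
#' the interval midpoint) and the signed range change
#' \eqn{(max_1-min_1) - (max_2-min_2)}.
#'
#' @param fva1,fva2 \code{fva_result}s for the two model states.
#' @param reactions reactions to compare (default: all in \code{fva1});
#'   a reaction missing from either result is an error.
#' @return a \code{comparison_metrics} tibble: \code{reaction},
#'   \code{mean_shift}, \code{range_change}, \code{subsystem}.
#' @export
compare_fva <- function(fva1, fva2, reactions = fva1$reaction) {
  miss <- c(setdiff(reactions, fva1$reaction), setdiff(reactions, fva2$reaction))
  if (length(miss))
    abort(sprintf("reaction(s) missing from an FVA result: %s",
                  paste(unique(miss), collapse = ", ")))
  a <- fva1[match(reactions, fva1$reaction), ]
  b <- fva2[match(reactions, fva2$reaction), ]
  out <- tibble(
    reaction = reactions,
    mean_shift = abs((a$fva_max + a$fva_min) / 2 - (b$fva_max + b$fva_min) / 2),
    range_change = (a$fva_max - a$fva_min) - (b$fva_max - b$fva_min),
    subsystem = a$subsystem)
  class(out) <- c("comparison_metrics", class(out))
  out
}

#' @rdname compare_fva
#' @param reaction a single reaction id.
#' @export
mean_shift <- function(fva1, fva2, reaction) {
  compare_fva(fva1, fva2, reaction)$mean_shift
}

#' @rdname compare_fva
#' @export
range_change <- function(fva1, fva2, reaction) {
  compare_fva(fva1, fva2, reaction)$range_change
}

#' Rank reactions by response to a condition change
#'
#' Decreasing mean shift; ties broken by decreasing range change; residual
#' ties by reaction id.
#'
#' @param metrics a \code{comparison_metrics} tibble.
#' @return character vector of reaction ids (a permutation of the input).
#' @export
rank_reactions <- function(metrics) {
  ord <- order(-metrics$mean_shift, -metrics$range_change, metrics$reaction)
  metrics$reaction[ord]
}

#' Subsystem pathway scores
#'
#' Fraction of each subsystem's reactions whose FVA interval midpoint
#' shifted by more than \code{shift_threshold}.
#'
#' @param metrics a \code{comparison_metrics} tibble.
#' @param shift_threshold mean-shift threshold defining a "shifted"
#'   reaction (default 1e-6, the numerical noise floor).
#' @return tibble: \code{subsystem}, \code{shifted}, \code{total},
#'   \code{score} in [0, 1].
#' @export
pathway_score <- function(metrics, shift_threshold = 1e-6) {
  out <- dplyr::summarise(
    dplyr::group_by(metrics, .data$subsystem),
    shifted = sum(.data$mean_shift > shift_threshold),
    total = dplyr::n(), .groups = "drop")
  dplyr::arrange(dplyr::mutate(out, score = .data$shifted / .data$total),
                 dplyr::desc(.data$score), .data$subsystem)
}

#' Rank community secretion products
#'
#' Runs FVA over the fecal exchange reactions of a (pinned) community and
#' ranks the metabolites with nonzero maximal secretion by their FVA
#' maxima, attributing each to members via the luminal transport fluxes of
#' the flux distribution that attains the maximum (a representative optimum;
#' alternate optima may distribute contributions differently).
#'
#' @param community a \code{community_model}, typically already pinned to a
#'   Pareto growth state via \code{\link{fix_pareto_state}}.
#' @param solution optional \code{pareto_solution} to pin before the scan.
#' @param tol fluxes below this are treated as zero.
#' @return tibble: \code{exchange}, \code{metabolite}, \code{fva_min},
#'   \code{fva_max}, and a nested \code{contributions} tibble
#'   (\code{member}, \code{flux}) per row.
#' @export
secretion_products <- function(community, solution = NULL, tol = 1e-9) {
  stopifnot(inherits(community, "community_model"))
  if (!is.null(solution)) community <- fix_pareto_state(community, solution)
  fecal <- intersect(community$fecal_rxns, community$rxns$id)
  fva <- run_fva(community, fecal)
  keep <- fva[fva$fva_max > tol, ]
  if (!nrow(keep))
    return(tibble(exchange = character(), metabolite = character(),
                  fva_min = numeric(), fva_max = numeric(),
                  contributions = list()))
  tags <- c(community$member_tags, community$host_tag)
  contribs <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    ex <- keep$reaction[i]
    met <- sub("^EX_(.*)_lu_fecal$", "\\1", ex)
    sol <- solve_fba(community, setNames(1, ex))
    tr <- paste0("T_", met, "_", tags, "_lu")
    have <- tr %in% names(sol$fluxes)
    fl <- sol$fluxes[tr[have]]
    pos <- fl > tol  # positive = secretion into the lumen
    contribs[[i]] <- tibble(member = tags[have][pos],
                            flux = as.numeric(fl[pos]))
  }
  out <- tibble(exchange = keep$reaction,
                metabolite = sub("^EX_(.*)_lu_fecal$", "\\1", keep$reaction),
                fva_min = keep$fva_min, fva_max = keep$fva_max,
                contributions = contribs)
  dplyr::arrange(out, dplyr::desc(.data$fva_max), .data$exchange)
}

#' Compare toxic and non-toxic model states
#'
#' Builds a "toxic" variant of the model by raising the lower bounds of the
#' named toxin input/output exchanges to their steady-state flux values
#' (from the hybrid integration), and a "non-toxic" variant with those
#' bounds scaled by \code{low_exchange_fraction}; runs FVA on both and
#' returns the comparison metrics, ranking and pathway scores.
#'
#' @param model the organ \code{stoich_model} (toxin exchanges already
#'   split into input/output pairs).
#' @param steady_state_toxin_fluxes named numeric: reaction id ->
#'   steady-state flux (>= 0).
#' @param low_exchange_fraction scale of the non-toxic bounds (default 0).
#' @param reactions reactions to compare (default: all shared).
#' @param shift_threshold see \code{\link{pathway_score}}.
#' @return list of class \code{toxic_comparison} with \code{metrics},
#'   \code{ranking}, \code{pathway_scores}, \code{fva_toxic},
#'   \code{fva_nontoxic}.
#' @export
compare_toxic_nontoxic <- function(model, steady_state_toxin_fluxes,
                                   low_exchange_fraction = 0,
                                   reactions = NULL,
                                   shift_threshold = 1e-6) {
  vals <- steady_state_toxin_fluxes
  if (is.null(names(vals)) || any(vals < 0))
    abort("steady_state_toxin_fluxes must be named and nonnegative")
  mk <- function(scale) {
    m <- set_bounds(model, names(vals), lb = as.numeric(vals) * scale,
                    ub = pmax(model$rxns$ub[rxn_index(model, names(vals))],
                              as.numeric(vals) * scale))
    m
  }
  toxic <- mk(1); nontoxic <- mk(low_exchange_fraction)
  if (is.null(reactions)) reactions <- model$rxns$id
  fva1 <- tryCatch(run_fva(toxic, reactions),
                   error = function(e) abort(sprintf(
                     "toxic bounds infeasible: %s", conditionMessage(e))))
  fva2 <- run_fva(nontoxic, reactions)
  metrics <- compare_fva(fva1, fva2)
  structure(list(metrics = metrics,
                 ranking = rank_reactions(metrics),
                 pathway_scores = pathway_score(metrics, shift_threshold),
                 fva_toxic = fva1, fva_nontoxic = fva2),
            class = "toxic_comparison")
}

#' @export
print.toxic_comparison <- function(x, ...) {
  cat("<toxic_comparison> top shifted reactions:\n")
  print(utils::head(x$metrics[match(x$ranking, x$metrics$reaction), ], 5))
  invisible(x)
}

#' @export
tidy.toxic_comparison <- function(x, ...) x$metrics

#' @export
glance.toxic_comparison <- function(x, ...) {
  tibble(n_reactions = nrow(x$metrics),
         n_shifted = sum(x$metrics$mean_shift > 1e-6),
         top_reaction = x$ranking[1],
         top_subsystem = x$pathway_scores$subsystem[1])
}

#' Write comparison metrics as TSV
#' @param comparison a \code{toxic_comparison}.
#' @param metrics_path,scores_path output files (NULL to skip one).
#' @export
write_comparison_tsv <- function(comparison, metrics_path = NULL,
                                 scores_path = NULL) {
  if (!is.null(metrics_path))
    utils::write.table(as.data.frame(comparison$metrics), metrics_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scores_path))
    utils::write.table(as.data.frame(comparison$pathway_scores), scores_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(invisible(NULL))
}
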