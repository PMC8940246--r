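#' Build a gut community model with a shared lumen compartment
#'
#' Merges N bacterial member models and (optionally) a host model into one
#' community.  Every member/host id is suffixed with its tag; each
#' extracellular metabolite of a member is connected to a shared lumen
#' compartment (\code{"lu"}) by a reversible luminal transport reaction
#' (positive flux = secretion into the lumen); each lumen metabolite gets a
#' diet exchange (uptake side, negative flux) and a fecal exchange
#' (secretion side, positive flux).  The host is linked to the lumen exactly
#' like a member.
#'
#' @param member_models named list of \code{stoich_model}s; names are the
#'   member tags.
#' @param host_model optional \code{stoich_model} for the host epithelium.
#' @param host_tag tag for the host (default \code{"host"}).
#' @param ext_comp compartment id regarded as extracellular (default
#'   \code{"e"}).
#' @return a \code{community_model} (also a valid \code{stoich_model}) with
#'   extra fields: \code{member_tags}, \code{host_tag},
#'   \code{biomass_reactions} (tag -> reaction id), \code{lumen_mets},
#'   \code{transport_rxns}, \code{diet_rxns}, \code{fecal_rxns},
#'   \code{n_transport_added}.
#' @export
build_community <- function(member_models, host_model = NULL,
                            host_tag = "host", ext_comp = "e") {
  tags <- names(member_models)
  if (length(member_models) && (is.null(tags) || any(!nzchar(tags))))
    abort("member_models must be a named list (names are member tags)")
  tags <- as.character(tags)
  if (anyDuplicated(tags)) abort("duplicate member tags")
  if (!is.null(host_model) && host_tag %in% tags)
    abort(sprintf("host tag '%s' collides with a member tag", host_tag))

  all_models <- member_models
  if (!is.null(host_model)) all_models[[host_tag]] <- host_model

  comm <- new_model("community")
  biomass <- character()
  transports <- character()
  lumen <- character()

  for (tag in names(all_models)) {
    m <- validate_model(all_models[[tag]])
    ext_mets <- m$mets$id[m$mets$compartment == ext_comp]
    if (!length(ext_mets))
      warn(sprintf("member '%s' has no extracellular metabolites", tag))
    if (!length(m$objectives))
      abort(sprintf("member '%s' has no objective candidate (biomass) registered", tag))

    ex <- is_exchange(m)
    ex_met <- exchanged_metabolite(m)
    drop_rxn <- ex & ex_met %in% ext_mets  # member boundary exchanges -> lumen

    tagged <- function(x) paste0(x, "_", tag)
    keep <- which(!drop_rxn)
    for (j in keep) {
      coefs <- m$S[, j]
      nz <- which(coefs != 0)
      sto <- setNames(as.numeric(coefs[nz]), tagged(m$mets$id[nz]))
      comm <- add_reaction(comm, tagged(m$rxns$id[j]), sto,
                           lb = m$rxns$lb[j], ub = m$rxns$ub[j],
                           subsystem = m$rxns$subsystem[j],
                           name = m$rxns$name[j])
    }
    # carry over compartments for the tagged metabolites
    idx <- match(tagged(m$mets$id), comm$mets$id)
    ok <- !is.na(idx)
    comm$mets$compartment[idx[ok]] <- m$mets$compartment[ok]

    for (met in ext_mets) {
      base <- sub(paste0("_", ext_comp, "$"), "", met)
      lu <- paste0(base, "_lu")
      tid <- paste0("T_", base, "_", tag, "_lu")
      sto <- setNames(c(-1, 1), c(tagged(met), lu))
      comm <- add_reaction(comm, tid, sto, lb = -1000, ub = 1000,
                           subsystem = "Luminal transport")
      comm$mets$compartment[match(lu, comm$mets$id)] <- "lu"
      transports <- c(transports, tid)
      lumen <- union(lumen, lu)
    }
    biomass[tag] <- tagged(m$objectives[1])
  }

  diet_rxns <- fecal_rxns <- character()
  for (lu in lumen) {
    base <- sub("_lu$", "", lu)
    did <- paste0("EX_", base, "_lu_diet")
    fid <- paste0("EX_", base, "_lu_fecal")
    comm <- add_reaction(comm, did, setNames(-1, lu), lb = -1000, ub = 0,
                         subsystem = "Exchange")
    comm <- add_reaction(comm, fid, setNames(-1, lu), lb = 0, ub = 1000,
                         subsystem = "Exchange")
    diet_rxns <- c(diet_rxns, did); fecal_rxns <- c(fecal_rxns, fid)
  }

  comm$objectives <- unname(biomass)
  comm$member_tags <- tags
  comm$host_tag <- if (is.null(host_model)) NULL else host_tag
  comm$biomass_reactions <- biomass
  comm$lumen_mets <- lumen
  comm$transport_rxns <- transports
  comm$diet_rxns <- diet_rxns
  comm$fecal_rxns <- fecal_rxns
  comm$n_transport_added <- length(transports)
  class(comm) <- c("community_model", class(comm))
  validate_model(comm)
  comm
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d member(s)%s | %d lumen metabolites | %d luminal transport reactions\n",
              length(x$member_tags),
              if (is.null(x$host_tag)) "" else sprintf(" + host '%s'", x$host_tag),
              length(x$lumen_mets), x$n_transport_added))
  NextMethod()
}

#' Define a diet
#'
#' @param name diet name.
#' @param entries named numeric vector: lumen metabolite base name (without
#'   the \code{"_lu"} suffix) -> maximum uptake flux (mmol/hr, nonnegative).
#' @return a \code{diet_spec}.
#' @export
diet_spec <- function(name, entries) {
  if (any(entries < 0)) abort("diet uptake magnitudes must be >= 0")
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    abort("diet entries must be named by metabolite")
  structure(list(name = name,
                 entries = tibble(metabolite = names(entries),
                                  max_uptake = as.numeric(entries))),
            class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("<diet_spec> %s: %d metabolite(s)\n", x$name, nrow(x$entries)))
  invisible(x)
}

#' Constrain a community with a diet
#'
#' Sets the lower bound of each listed metabolite's diet exchange to minus
#' its maximum uptake; every other diet exchange is closed for uptake
#' (lb = 0).  Fecal (secretion) bounds are untouched.  Unknown metabolites
#' produce a warning and are skipped.
#'
#' @param community a \code{community_model}.
#' @param diet a \code{diet_spec} or named numeric vector.
#' @export
apply_diet <- function(community, diet) {
  stopifnot(inherits(community, "community_model"))
  if (!inherits(diet, "diet_spec"))
    diet <- diet_spec("diet", diet)
  ids <- paste0("EX_", diet$entries$metabolite, "_lu_diet", recycle0 = TRUE)
  known <- ids %in% community$rxns$id
  if (any(!known))
    warn(sprintf("diet metabolites not in lumen, skipped: %s",
                 paste(diet$entries$metabolite[!known], collapse = ", ")))
  community <- set_bounds(community, community$diet_rxns, lb = 0)
  if (any(known))
    community <- set_bounds(community, ids[known],
                            lb = -diet$entries$max_uptake[known])
  community$diet_name <- diet$name
  community
}

#' Set the luminal oxygen uptake condition for every member
#'
#' Sets the lower bound of each member's (and host's) oxygen luminal
#' transport reaction, capping uptake from the lumen; the default
#' \code{lb = -1} mmol/gDW/hr is the aerobic small-intestine condition.
#'
#' @param community a \code{community_model}.
#' @param lb_value new lower bound (default \code{-1}).
#' @param o2_id oxygen metabolite base name (default \code{"o2"}).
#' @export
set_oxygen_condition <- function(community, lb_value = -1, o2_id = "o2") {
  stopifnot(inherits(community, "community_model"))
  tags <- c(community$member_tags, community$host_tag)
  ids <- paste0("T_", o2_id, "_", tags, "_lu")
  known <- ids %in% community$rxns$id
  if (!any(known)) {
    warn(sprintf("no oxygen ('%s') transport reactions found", o2_id))
    return(community)
  }
  set_bounds(community, ids[known], lb = lb_value)
}

#' Split a reversible exchange reaction into an input/output pair
#'
#' Replaces an exchange reaction by two irreversible reactions: an input
#' reaction carrying the metabolite into the system (nonnegative flux, upper
#' bound = the uptake capacity of the original) and an output reaction
#' carrying it out (nonnegative flux, upper bound = the secretion capacity).
#' The net flux space is unchanged; the input bound can then be driven by
#' the transport model at each coupling step.
#'
#' @param model a \code{stoich_model}.
#' @param reaction_id id of an exchange reaction.
#' @return the model with \code{<id>_in} and \code{<id>_out} replacing
#'   \code{reaction_id}.
#' @export
split_reversible_exchange <- function(model, reaction_id) {
  j <- rxn_index(model, reaction_id)
  if (!is_exchange(model)[j])
    abort(sprintf("'%s' is not an exchange reaction", reaction_id))
  coef <- model$S[, j]
  i <- which(coef != 0)
  met <- model$mets$id[i]
  cf <- coef[i]
  lb <- model$rxns$lb[j]; ub <- model$rxns$ub[j]
  # uptake capacity: flux direction that brings the metabolite in
  in_cap <- if (cf < 0) max(0, -lb) else max(0, ub)
  out_cap <- if (cf < 0) max(0, ub) else max(0, -lb)
  sub <- model$rxns$subsystem[j]
  model <- drop_reactions(model, reaction_id)
  model <- add_reaction(model, paste0(reaction_id, "_in"),
                        setNames(abs(cf), met), lb = 0, ub = in_cap,
                        subsystem = sub)
  model <- add_reaction(model, paste0(reaction_id, "_out"),
                        setNames(-abs(cf), met), lb = 0, ub = out_cap,
                        subsystem = sub)
  model
}

#' Remove reactions from a model
#' @param model a \code{stoich_model}.
#' @param ids reaction ids to drop.
#' @export
drop_reactions <- function(model, ids) {
  idx <- rxn_index(model, ids)
  model$rxns <- model$rxns[-idx, ]
  model$S <- model$S[, -idx, drop = FALSE]
  model$objectives <- setdiff(model$objectives, ids)
  model
}

#' Community build report
#'
#' Counts of the boundary structures added during community assembly,
#' suitable for JSON serialization.
#' @param community a \code{community_model}.
#' @export
build_report <- function(community) {
  stopifnot(inherits(community, "community_model"))
  list(members = length(community$member_tags),
       host = !is.null(community$host_tag),
       luminal_transport_reactions = community$n_transport_added,
       lumen_metabolites = length(community$lumen_mets),
       diet_exchanges = length(community$diet_rxns),
       fecal_exchanges = length(community$fecal_rxns),
       reactions = nrow(community$rxns),
       metabolites = nrow(community$mets))
}
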