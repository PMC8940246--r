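#' SBML import and export
#'
#' Reads and writes SBML Level 3 documents with the FBC (flux bounds,
#' objectives) and Groups (subsystems) packages — the subset needed to
#' round-trip the models this package constructs and to ingest externally
#' supplied constraint-based models that follow the same conventions.
#'
#' @name sbml_io
NULL

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"

sid_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)

#' Write a model to SBML
#'
#' @param model a \code{stoich_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @rdname sbml_io
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  bad <- c(model$mets$id[!sid_ok(model$mets$id)],
           model$rxns$id[!sid_ok(model$rxns$id)])
  if (length(bad))
    abort(sprintf("ids not valid SBML SIds: %s", paste(bad, collapse = ", ")))

  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, level = "3", version = "1",
    "xmlns:fbc" = SBML_FBC_NS, "fbc:required" = "false",
    "xmlns:groups" = SBML_GROUPS_NS, "groups:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "false")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$mets$compartment))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")

  # one shared parameter per distinct bound value
  vals <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  fmt <- function(v) sprintf("%.17g", v)
  pid <- setNames(sprintf("bnd_%d", seq_along(vals)), vapply(vals, fmt, ""))
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(vals))
    xml2::xml_add_child(pars, "parameter", id = pid[[i]], value = fmt(vals[i]),
                        constant = "true")

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$mets)))
    xml2::xml_add_child(sps, "species", id = paste0("M_", model$mets$id[i]),
                        name = model$mets$name[i],
                        compartment = model$mets$compartment[i],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$rxns))) {
    r <- model$rxns[j, ]
    rn <- xml2::xml_add_child(
      rxs, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = pid[[fmt(r$lb)]],
      "fbc:upperFluxBound" = pid[[fmt(r$ub)]])
    coefs <- model$S[, j]
    nz <- which(coefs != 0)
    reac <- nz[coefs[nz] < 0]; prod <- nz[coefs[nz] > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", model$mets$id[i]),
                            stoichiometry = format(-coefs[i], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", model$mets$id[i]),
                            stoichiometry = format(coefs[i], digits = 17),
                            constant = "true")
    }
  }

  if (length(model$objectives)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj_1")
    for (k in seq_along(model$objectives)) {
      ob <- xml2::xml_add_child(lo, "fbc:objective",
                                "fbc:id" = sprintf("obj_%d", k),
                                "fbc:type" = "maximize")
      lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
      xml2::xml_add_child(lf, "fbc:fluxObjective",
                          "fbc:reaction" = paste0("R_", model$objectives[k]),
                          "fbc:coefficient" = "1")
    }
  }

  subs <- split(model$rxns$id, model$rxns$subsystem)
  subs <- subs[setdiff(names(subs), "unassigned")]
  if (length(subs)) {
    lg <- xml2::xml_add_child(mdl, "groups:listOfGroups")
    for (k in seq_along(subs)) {
      g <- xml2::xml_add_child(lg, "groups:group",
                               "groups:id" = sprintf("g_%d", k),
                               "groups:name" = names(subs)[k],
                               "groups:kind" = "partonomy")
      lm <- xml2::xml_add_child(g, "groups:listOfMembers")
      for (rid in subs[[k]])
        xml2::xml_add_child(lm, "groups:member",
                            "groups:idRef" = paste0("R_", rid))
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

#' Read a model from SBML
#'
#' Reactions lacking FBC flux bounds default to \code{(-1000, 1000)} with a
#' warning.  Subsystems come from SBML groups when present, otherwise
#' \code{"unassigned"}.  Objective candidates are collected from all FBC
#' objectives.
#'
#' @param path path to an SBML file.
#' @return a \code{stoich_model}.
#' @rdname sbml_io
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(sprintf(
                    "cannot parse SBML file '%s': %s", path, conditionMessage(e))))
  ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS, g = SBML_GROUPS_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(mdl)) abort(sprintf("SBML parse error in '%s': no <model> element", path))
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) abort(sprintf("SBML parse error in '%s': empty <listOfSpecies>", path))
  met_ids <- strip_prefix(xml2::xml_attr(sp, "id"), "M_")
  met_names <- xml2::xml_attr(sp, "name")
  met_names[is.na(met_names)] <- met_ids[is.na(met_names)]
  model <- new_model(model_id)
  model <- add_metabolites(model, met_ids,
                           compartment = xml2::xml_attr(sp, "compartment"),
                           name = met_names)

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  missing_bounds <- character()
  for (node in rx) {
    rid_raw <- xml2::xml_attr(node, "id")
    if (is.na(rid_raw))
      abort(sprintf("SBML parse error in '%s': <reaction> without id", path))
    rid <- strip_prefix(rid_raw, "R_")
    rname <- xml2::xml_attr(node, "name")
    if (is.na(rname)) rname <- rid
    lbp <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    ubp <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    if (is.na(lbp) || is.na(ubp) ||
        !(lbp %in% names(parval)) || !(ubp %in% names(parval))) {
      missing_bounds <- c(missing_bounds, rid)
      lb <- -1000; ub <- 1000
    } else {
      lb <- parval[[lbp]]; ub <- parval[[ubp]]
    }
    sto <- numeric(0)
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      mid <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      if (!mid %in% model$mets$id)
        abort(sprintf("SBML parse error in '%s': reaction '%s' references unknown species '%s'",
                      path, rid, mid))
      sto[mid] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      mid <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      if (!mid %in% model$mets$id)
        abort(sprintf("SBML parse error in '%s': reaction '%s' references unknown species '%s'",
                      path, rid, mid))
      sto[mid] <- as.numeric(xml2::xml_attr(sr, "stoichiometry")) +
        if (mid %in% names(sto)) sto[[mid]] else 0
    }
    model <- add_reaction(model, rid, sto, lb = lb, ub = ub,
                          name = rname, auto_mets = FALSE)
  }
  if (length(missing_bounds))
    warn(sprintf("%d reaction(s) lacked FBC bounds; defaulted to (-1000, 1000): %s",
                 length(missing_bounds),
                 paste(utils::head(missing_bounds, 5), collapse = ", ")))

  fo <- xml2::xml_find_all(mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (length(fo)) {
    objs <- unique(strip_prefix(xml2::xml_attr(fo, "fbc:reaction", ns), "R_"))
    model$objectives <- intersect(objs, model$rxns$id)
  }

  for (grp in xml2::xml_find_all(mdl, ".//g:listOfGroups/g:group", ns)) {
    gname <- xml2::xml_attr(grp, "g:name", ns)
    if (is.na(gname)) gname <- xml2::xml_attr(grp, "g:id", ns)
    members <- strip_prefix(
      xml2::xml_attr(xml2::xml_find_all(grp, ".//g:member", ns), "g:idRef", ns), "R_")
    idx <- match(intersect(members, model$rxns$id), model$rxns$id)
    model$rxns$subsystem[idx] <- gname
  }

  validate_model(model)
}
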