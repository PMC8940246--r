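#' Fixture specification for the toy gut-brain system
#'
#' The toy fixtures are hand-designed minimal networks with analytically
#' known optima: fermenting gut bacteria that grow on two dietary carbon
#' sources (a fiber-like and a Western starch-like carbohydrate), a host
#' epithelial cell that feeds on the fermentation product acetate and
#' detoxifies reactive oxygen species (superoxide dismutase, catalase), and
#' a brain network whose neurotransmitter output competes with toxin
#' detoxification for reducing power.
#'
#' @param n_beneficial,n_harmful member counts (defaults 2 and 3, the
#'   five-member layout; use 5 and 5 for the ten-member layout).
#' @param toxin_yield_harmful named vector: stoichiometric toxin yield
#'   (both H2O2 and superoxide) per unit of starch and fiber catabolized by
#'   a harmful member.
#' @param include_sod add the dismutation reaction
#'   \code{2 h + 2 o2s -> o2 + h2o2} to the host.
#' @param sod_capacity,catalase_capacity host detoxification flux caps
#'   (mmol/gDW/hr).
#' @param seed,jitter optional reproducible jitter (relative, applied to
#'   member carbon transporter capacities); \code{jitter = 0} disables it.
#' @export
fixture_spec <- function(n_beneficial = 2, n_harmful = 3,
                         toxin_yield_harmful = c(starch = 1, fiber = 0.2),
                         include_sod = TRUE,
                         sod_capacity = 50, catalase_capacity = 10,
                         seed = 0, jitter = 0) {
  structure(list(n_beneficial = n_beneficial, n_harmful = n_harmful,
                 toxin_yield_harmful = toxin_yield_harmful,
                 include_sod = include_sod, sod_capacity = sod_capacity,
                 catalase_capacity = catalase_capacity,
                 seed = seed, jitter = jitter),
            class = "fixture_spec")
}

jittered <- function(base, spec, key) {
  if (spec$jitter <= 0) return(base)
  set.seed(spec$seed + sum(utf8ToInt(key)))
  base * (1 + stats::runif(1, -spec$jitter, spec$jitter))
}

#' Toy gut bacterium
#'
#' A ~10-reaction fermenter: carbon uptake, catabolism to ATP and acetate,
#' and a biomass drain.  Harmful members additionally secrete H2O2 and
#' superoxide stoichiometrically with catabolism (more per unit of starch
#' than of fiber); beneficial members ferment cleanly and extract more ATP
#' from fiber than from starch.
#'
#' @param class \code{"beneficial"} or \code{"harmful"}.
#' @param spec a \code{fixture_spec}.
#' @param id model id.
#' @return a \code{stoich_model}.
#' @export
make_toy_member <- function(class = c("beneficial", "harmful"),
                            spec = fixture_spec(), id = class) {
  class <- match.arg(class)
  m <- new_model(id)
  tcap <- jittered(1000, spec, paste0(id, class))
  m <- add_reaction(m, "T_starch", c(starch_e = -1, starch_c = 1),
                    lb = 0, ub = tcap, subsystem = "Transport")
  m <- add_reaction(m, "T_fiber", c(fiber_e = -1, fiber_c = 1),
                    lb = 0, ub = tcap, subsystem = "Transport")
  m <- add_reaction(m, "T_o2", c(o2_e = -1, o2_c = 1),
                    lb = -1000, ub = 1000, subsystem = "Transport")
  if (class == "harmful") {
    y <- spec$toxin_yield_harmful
    m <- add_reaction(m, "CAT_starch",
                      c(starch_c = -1, atp_c = 2, ac_e = 1,
                        h2o2_e = y[["starch"]], o2s_e = y[["starch"]]),
                      lb = 0, ub = 1000, subsystem = "Central carbon")
    m <- add_reaction(m, "CAT_fiber",
                      c(fiber_c = -1, atp_c = 1, ac_e = 1,
                        h2o2_e = y[["fiber"]], o2s_e = y[["fiber"]]),
                      lb = 0, ub = 1000, subsystem = "Central carbon")
  } else {
    m <- add_reaction(m, "CAT_fiber",
                      c(fiber_c = -1, atp_c = 2, ac_e = 1),
                      lb = 0, ub = 1000, subsystem = "Central carbon")
    m <- add_reaction(m, "CAT_starch",
                      c(starch_c = -1, atp_c = 1, ac_e = 1),
                      lb = 0, ub = 1000, subsystem = "Central carbon")
  }
  m <- add_reaction(m, "BIOMASS", c(atp_c = -2), lb = 0, ub = 1000,
                    subsystem = "Biomass", objective = TRUE)
  # standalone boundary; replaced by luminal transports inside a community
  m <- add_reaction(m, "EX_starch_e", c(starch_e = -1), lb = -10, ub = 1000,
                    subsystem = "Exchange")
  m <- add_reaction(m, "EX_fiber_e", c(fiber_e = -1), lb = -10, ub = 1000,
                    subsystem = "Exchange")
  m <- add_reaction(m, "EX_ac_e", c(ac_e = -1), lb = 0, ub = 1000,
                    subsystem = "Exchange")
  m <- add_reaction(m, "EX_o2_e", c(o2_e = -1), lb = -10, ub = 1000,
                    subsystem = "Exchange")
  if (class == "harmful") {
    m <- add_reaction(m, "EX_h2o2_e", c(h2o2_e = -1), lb = 0, ub = 1000,
                      subsystem = "Exchange")
    m <- add_reaction(m, "EX_o2s_e", c(o2s_e = -1), lb = 0, ub = 1000,
                      subsystem = "Exchange")
  }
  validate_model(m)
}

#' Toy host enterocyte
#'
#' Grows on luminal acetate and carries the reactive-oxygen handling
#' machinery: toxin uptake, a capacity-limited catalase
#' (\code{2 h2o2 -> o2}) and, when \code{include_sod}, superoxide dismutase
#' (\code{2 h + 2 o2s -> o2 + h2o2}).
#'
#' @param include_sod include the dismutation reaction.
#' @param spec a \code{fixture_spec}.
#' @return a \code{stoich_model}.
#' @export
make_toy_host <- function(include_sod = TRUE, spec = fixture_spec()) {
  m <- new_model("host")
  m <- add_reaction(m, "T_ac", c(ac_e = -1, ac_c = 1), lb = 0, ub = 1000,
                    subsystem = "Transport")
  m <- add_reaction(m, "CAT_ac", c(ac_c = -1, atp_c = 0.5), lb = 0, ub = 1000,
                    subsystem = "Central carbon")
  m <- add_reaction(m, "BIOMASS_host", c(atp_c = -1), lb = 0, ub = 1000,
                    subsystem = "Biomass", objective = TRUE)
  m <- add_reaction(m, "T_h2o2", c(h2o2_e = -1, h2o2_c = 1),
                    lb = -1000, ub = 1000, subsystem = "Transport")
  m <- add_reaction(m, "T_o2s", c(o2s_e = -1, o2s_c = 1),
                    lb = -1000, ub = 1000, subsystem = "Transport")
  m <- add_reaction(m, "T_o2", c(o2_e = -1, o2_c = 1),
                    lb = -1000, ub = 1000, subsystem = "Transport")
  m <- add_reaction(m, "T_h", c(h_e = -1, h_c = 1), lb = 0, ub = 1000,
                    subsystem = "Transport")
  m <- add_reaction(m, "CATALASE", c(h2o2_c = -2, o2_c = 1),
                    lb = 0, ub = spec$catalase_capacity,
                    subsystem = "ROS detoxification")
  if (include_sod)
    m <- add_reaction(m, "SOD", c(h_c = -2, o2s_c = -2, o2_c = 1, h2o2_c = 1),
                      lb = 0, ub = spec$sod_capacity,
                      subsystem = "ROS detoxification")
  for (met in c("ac", "h2o2", "o2s", "o2", "h")) {
    rev_lb <- if (met %in% c("ac", "h")) -10 else -1000
    m <- add_reaction(m, paste0("EX_", met, "_e"),
                      setNames(-1, paste0(met, "_e")),
                      lb = rev_lb, ub = 1000, subsystem = "Exchange")
  }
  validate_model(m)
}

#' Toy brain network
#'
#' Glucose fuels glycolysis, which yields ATP (drained by the maintenance
#' objective), reducing power (NADPH) and a carbon skeleton; glutamate and
#' GABA demands compete with H2O2/superoxide detoxification for NADPH, so
#' forced toxin influx lowers the attainable neurotransmitter demand flux.
#'
#' @return a \code{stoich_model} with objective candidates
#'   \code{ATPM} (ATP maintenance), \code{DM_glu}, \code{DM_gaba}.
#' @export
make_toy_brain <- function() {
  m <- new_model("brain")
  m <- add_reaction(m, "T_glc", c(glc_e = -1, glc_c = 1), lb = 0, ub = 1000,
                    subsystem = "Transport")
  m <- add_reaction(m, "GLYC", c(glc_c = -1, atp_c = 2, nadph_c = 1),
                    lb = 0, ub = 1000, subsystem = "Central carbon")
  m <- add_reaction(m, "AKGSYN", c(glc_c = -1, akg_c = 1),
                    lb = 0, ub = 1000, subsystem = "Central carbon")
  m <- add_reaction(m, "ATPM", c(atp_c = -1), lb = 0, ub = 1000,
                    subsystem = "Energy maintenance", objective = TRUE)
  m <- add_reaction(m, "GLUSYN", c(akg_c = -1, nadph_c = -1, glu_c = 1),
                    lb = 0, ub = 1000, subsystem = "Neurotransmitter synthesis")
  m <- add_reaction(m, "GAD", c(glu_c = -1, gaba_c = 1), lb = 0, ub = 1000,
                    subsystem = "Neurotransmitter synthesis")
  m <- add_reaction(m, "DM_glu", c(glu_c = -1), lb = 0, ub = 1000,
                    subsystem = "Neurotransmitter demand", objective = TRUE)
  m <- add_reaction(m, "DM_gaba", c(gaba_c = -1), lb = 0, ub = 1000,
                    subsystem = "Neurotransmitter demand", objective = TRUE)
  m <- add_reaction(m, "T_h2o2", c(h2o2_e = -1, h2o2_c = 1), lb = 0, ub = 1000,
                    subsystem = "Transport")
  m <- add_reaction(m, "GPX", c(h2o2_c = -1, nadph_c = -1), lb = 0, ub = 1000,
                    subsystem = "ROS detoxification")
  m <- add_reaction(m, "T_o2s", c(o2s_e = -1, o2s_c = 1), lb = 0, ub = 1000,
                    subsystem = "Transport")
  m <- add_reaction(m, "SOR", c(o2s_c = -1, nadph_c = -1), lb = 0, ub = 1000,
                    subsystem = "ROS detoxification")
  m <- add_reaction(m, "EX_glc_e", c(glc_e = -1), lb = -5, ub = 1000,
                    subsystem = "Exchange")
  m <- add_reaction(m, "EX_h2o2_e", c(h2o2_e = -1), lb = -1000, ub = 1000,
                    subsystem = "Exchange")
  m <- add_reaction(m, "EX_o2s_e", c(o2s_e = -1), lb = -1000, ub = 1000,
                    subsystem = "Exchange")
  validate_model(m)
}

#' Toy high-fiber and Western diets
#'
#' Two diets over the fixture lumen metabolites: the high-fiber diet is rich
#' in the fiber-like carbohydrate (which beneficial members ferment
#' efficiently and cleanly), the Western diet in the starch-like one (which
#' harmful members ferment efficiently, secreting more toxins per unit).
#'
#' @return named list with \code{high_fiber} and \code{western}
#'   \code{diet_spec}s.
#' @export
make_toy_diets <- function() {
  list(high_fiber = diet_spec("high_fiber",
                              c(fiber = 500, starch = 100, ac = 5,
                                o2 = 10, h = 1000)),
       western = diet_spec("western",
                           c(starch = 500, fiber = 100, ac = 5,
                             o2 = 10, h = 1000)))
}

#' Toy six-tissue transport parameter set
#'
#' Rat-scale organ volumes (litres) and blood flows (L/hr) for brain,
#' heart, adipose, liver, gut and kidney, with the rat organ gram weights
#' used by the flux-concentration conversion (small intestine 7.26 g,
#' brain 2 g), unit partition coefficients, and a small renal clearance.
#'
#' @param CL_renal renal clearance (L/hr); default 0.02.
#' @return a \code{pbpk_parameters}.
#' @export
make_toy_pbpk_params <- function(CL_renal = 0.02) {
  tis <- tibble(
    tissue = c("brain", "heart", "adipose", "liver", "gut", "kidney"),
    Q = c(0.06, 0.04, 0.02, 0.10, 0.08, 0.06),
    V = c(0.002, 0.001, 0.010, 0.010, 0.007, 0.002),
    V_ev = c(0.0012, 0.0006, 0.0060, 0.0060, 0.0042, 0.0012),
    P = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    S_area = 1,
    K = 1,
    gram_weight = c(2, 1, 10, 10, 7.26, 2))
  pbpk_parameters(tis, V_blood = 0.015, CL_renal = CL_renal)
}

member_tag_pool <- list(
  beneficial = c("LA", "BL", "PR", "AM", "BA"),
  harmful = c("BV", "DD", "CP", "CD", "RT"))

#' Assemble the toy gut community
#'
#' Builds the members and host from a \code{fixture_spec}, merges them
#' through the lumen, applies the aerobic oxygen condition
#' (\code{lb = -1}) and, optionally, a diet.
#'
#' @param spec a \code{fixture_spec}.
#' @param diet optional \code{diet_spec} applied after assembly.
#' @param include_beneficial,include_harmful select member classes (e.g.
#'   \code{include_beneficial = FALSE} gives the harmful-only, "purely
#'   autistic" community).
#' @return a \code{community_model} with \code{beneficial_tags} and
#'   \code{harmful_tags} fields.
#' @export
make_toy_community <- function(spec = fixture_spec(), diet = NULL,
                               include_beneficial = TRUE,
                               include_harmful = TRUE) {
  btags <- if (include_beneficial)
    member_tag_pool$beneficial[seq_len(spec$n_beneficial)] else character()
  htags <- if (include_harmful)
    member_tag_pool$harmful[seq_len(spec$n_harmful)] else character()
  members <- c(
    setNames(lapply(btags, function(t)
      make_toy_member("beneficial", spec, id = t)), btags),
    setNames(lapply(htags, function(t)
      make_toy_member("harmful", spec, id = t)), htags))
  comm <- build_community(members, make_toy_host(spec$include_sod, spec))
  comm <- set_oxygen_condition(comm, -1)
  if (!is.null(diet)) comm <- apply_diet(comm, diet)
  comm$beneficial_tags <- btags
  comm$harmful_tags <- htags
  comm
}

#' Write the full fixture set to a directory
#'
#' Emits member/host/brain SBML files, the two diets as JSON, and the
#' transport parameters as YAML.
#'
#' @param dir output directory (created if needed).
#' @param spec a \code{fixture_spec}.
#' @return the directory path, invisibly.
#' @export
write_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  btags <- member_tag_pool$beneficial[seq_len(spec$n_beneficial)]
  htags <- member_tag_pool$harmful[seq_len(spec$n_harmful)]
  for (t in btags)
    write_sbml(make_toy_member("beneficial", spec, id = t),
               file.path(dir, sprintf("member_%s.xml", t)))
  for (t in htags)
    write_sbml(make_toy_member("harmful", spec, id = t),
               file.path(dir, sprintf("member_%s.xml", t)))
  write_sbml(make_toy_host(spec$include_sod, spec), file.path(dir, "host.xml"))
  write_sbml(make_toy_brain(), file.path(dir, "brain.xml"))
  diets <- make_toy_diets()
  for (d in diets)
    jsonlite::write_json(
      setNames(as.list(d$entries$max_uptake), d$entries$metabolite),
      file.path(dir, sprintf("diet_%s.json", d$name)), auto_unbox = TRUE)
  p <- make_toy_pbpk_params()
  yaml::write_yaml(list(tissues = as.data.frame(p$tissues[setdiff(names(p$tissues), "f")]),
                        V_blood = p$V_blood, CL_renal = p$CL_renal,
                        clearance_site = p$clearance_site),
                   file.path(dir, "pbpk_params.yaml"))
  invisible(dir)
}

#' Read a diet from JSON/TSV
#' @param path a JSON object (metabolite -> max uptake) or a TSV with
#'   columns \code{metabolite}, \code{max_uptake}.
#' @param name diet name (default: file stem).
#' @export
read_diet <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    diet_spec(name, unlist(x))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    diet_spec(name, setNames(df$max_uptake, df$metabolite))
  }
}

#' Read transport parameters from YAML/JSON
#' @param path file with fields \code{tissues} (records), \code{V_blood},
#'   \code{CL_renal}, optional \code{clearance_site}.
#' @export
read_pbpk_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  pbpk_parameters(as_tibble(x$tissues), V_blood = x$V_blood,
                  CL_renal = x$CL_renal,
                  clearance_site = x$clearance_site %||% "arterial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
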