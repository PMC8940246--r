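#' Coupling configuration
#'
#' Settings of the discretized exchange between the constraint-based organ
#' models and the whole-body transport model: a 15-minute step over a
#' 6-hour horizon, both toxin pools initialized at 1e-4 M, and the explicit
#' unit conversion (M to nmol, per-step time base) used to turn organ
#' extravascular concentrations into flux bounds and realized fluxes into
#' generation/consumption terms.
#'
#' @param dt_hours coupling step (hr, default 0.25 = 15 min); must divide
#'   the horizon evenly.
#' @param horizon_hours total simulated time (hr, default 6).
#' @param initial_concentration initial toxin concentration in every
#'   compartment (M, default 1e-4).
#' @param toxins named character vector: species name -> metabolite base id
#'   (default \code{c(h2o2 = "h2o2", o2s = "o2s")}).
#' @param organ_map named character vector: organ model name -> tissue
#'   (default gut -> gut, brain -> brain).
#' @param conversion_scale M -> nmol factor (1e9).
#' @param pareto_max_iterations,pareto_tolerance search settings used for
#'   every within-step multi-objective optimization.
#' @param steady_state_tol relative change between steps below which the
#'   trajectory is flagged as steady.
#' @export
coupling_config <- function(dt_hours = 0.25, horizon_hours = 6,
                            initial_concentration = 1e-4,
                            toxins = c(h2o2 = "h2o2", o2s = "o2s"),
                            organ_map = c(gut = "gut", brain = "brain"),
                            conversion_scale = 1e9,
                            pareto_max_iterations = 100,
                            pareto_tolerance = 1e-6,
                            steady_state_tol = 1e-6) {
  if (dt_hours <= 0 || horizon_hours <= 0)
    abort("dt_hours and horizon_hours must be positive")
  n <- horizon_hours / dt_hours
  if (abs(n - round(n)) > 1e-9)
    abort("dt_hours must divide horizon_hours evenly")
  structure(list(dt_hours = dt_hours, horizon_hours = horizon_hours,
                 n_steps = as.integer(round(n)),
                 initial_concentration = initial_concentration,
                 toxins = toxins, organ_map = organ_map,
                 conversion_scale = conversion_scale,
                 pareto_max_iterations = pareto_max_iterations,
                 pareto_tolerance = pareto_tolerance,
                 steady_state_tol = steady_state_tol),
            class = "coupling_config")
}

#' Convert an extravascular concentration to a per-step flux bound
#'
#' The static assumption of the discretized coupling: within one step a
#' model may consume at most the whole extravascular pool, so the bound is
#' \code{C (M) * V_EV (L) * scale / gram_weight (g) / dt (hr)} in
#' nmol/gDW/hr (with the organ model's gDW equated to the organ gram
#' weight).
#'
#' @param C concentration (M, >= 0).
#' @param V_EV_organ extravascular volume (L).
#' @param gram_weight organ weight (g, > 0).
#' @param dt_hours step size (hr, > 0).
#' @param scale M -> nmol factor (default 1e9).
#' @export
concentration_to_flux_bound <- function(C, V_EV_organ, gram_weight, dt_hours,
                                        scale = 1e9) {
  if (any(c(C, V_EV_organ) < 0)) abort("concentration and volume must be >= 0")
  if (gram_weight <= 0 || dt_hours <= 0)
    abort("gram_weight and dt_hours must be positive")
  C * V_EV_organ * scale / gram_weight / dt_hours
}

#' Convert a realized exchange flux to a transport-model source term
#'
#' Inverse direction of the unit conversion: a nonnegative organ-model flux
#' (nmol/gDW/hr) becomes a generation or consumption term in mol/hr for the
#' organ's extravascular compartment.  Direction (generation vs
#' consumption) is carried separately.
#'
#' @param flux realized flux magnitude (nmol/gDW/hr, >= 0).
#' @param V_EV_organ extravascular volume (L); part of the conversion
#'   contract with \code{\link{concentration_to_flux_bound}}.
#' @param gram_weight organ weight (g).
#' @param scale M -> nmol factor (default 1e9).
#' @return term in mol/hr.
#' @export
flux_to_concentration_rate <- function(flux, V_EV_organ, gram_weight,
                                       scale = 1e9) {
  if (any(flux < 0)) abort("flux magnitudes must be >= 0 (direction is separate)")
  flux * gram_weight / scale
}

#' Prepare an organ model for coupling
#'
#' Identifies (and where necessary creates, by splitting reversible
#' exchanges) the irreversible toxin input/output exchange pairs, and
#' records the growth objective specification for the per-step
#' optimization.
#'
#' @param model a \code{stoich_model} or \code{community_model}.
#' @param tissue tissue this organ maps to.
#' @param gram_weight organ gram weight (g).
#' @param objectives named growth objectives (reaction ids); for a
#'   community the registered biomass reactions are used by default.
#' @param weights pareto weights over \code{objectives} (default equal).
#' @param extra_objectives reaction ids optimized under the pinned state
#'   (e.g. neurotransmitter demands), or NULL.
#' @param toxins named character vector: species -> metabolite base id.
#' @return an \code{organ_spec}.
#' @export
organ_spec <- function(model, tissue, gram_weight, objectives = NULL,
                       weights = NULL, extra_objectives = NULL,
                       toxins = c(h2o2 = "h2o2", o2s = "o2s")) {
  validate_model(model)
  tox_in <- tox_out <- character(0)
  if (inherits(model, "community_model")) {
    if (is.null(objectives)) objectives <- model$biomass_reactions
    for (sp in names(toxins)) {
      did <- paste0("EX_", toxins[[sp]], "_lu_diet")
      fid <- paste0("EX_", toxins[[sp]], "_lu_fecal")
      if (!did %in% model$rxns$id)
        abort(sprintf("community lacks a lumen exchange for toxin '%s'", sp))
      model <- split_reversible_exchange(model, did)
      tox_in[sp] <- paste0(did, "_in")
      tox_out[sp] <- fid
      # route all toxin outflow through the fecal exchange
      model <- set_bounds(model, paste0(did, "_out"), lb = 0, ub = 0)
    }
  } else {
    if (is.null(objectives)) objectives <- model$objectives[1]
    for (sp in names(toxins)) {
      eid <- paste0("EX_", toxins[[sp]], "_e")
      if (!eid %in% model$rxns$id)
        abort(sprintf("model lacks an exchange for toxin '%s'", sp))
      model <- split_reversible_exchange(model, eid)
      tox_in[sp] <- paste0(eid, "_in")
      tox_out[sp] <- paste0(eid, "_out")
    }
  }
  if (is.null(weights)) weights <- rep(1 / length(objectives), length(objectives))
  structure(list(model = model, tissue = tissue, gram_weight = gram_weight,
                 objectives = objectives, weights = weights,
                 extra_objectives = extra_objectives,
                 toxin_in = tox_in, toxin_out = tox_out),
            class = "organ_spec")
}

# equal-weight pareto maximization of a reaction set under current bounds,
# by binary search (consistent with linear search within tolerance)
pareto_max <- function(model, rxns, config, weights = NULL) {
  if (length(rxns) == 1) {
    s <- solve_fba(model, setNames(1, rxns))
    if (s$status != "optimal") abort("optimization infeasible")
    return(setNames(s$objective_value, rxns))
  }
  pr <- pareto_problem(model, rxns, weights = weights,
                       max_iterations = config$pareto_max_iterations,
                       tolerance = config$pareto_tolerance)
  pareto_binary_search(pr)$objective_fluxes
}

#' One constraint-based step of an organ model
#'
#' Implements the within-step protocol: (1) compute the Pareto-optimal
#' growth state under the applied toxin input bounds and pin it; (2)
#' maximize the toxin output exchanges (generation) and pin them; (3)
#' maximize the toxin input exchanges (consumption); (4) optimize any extra
#' demand objectives (e.g. GABA/glutamate) under the pinned state.
#'
#' @param spec an \code{organ_spec}.
#' @param toxin_bounds named per-species input flux bounds (nmol/gDW/hr).
#' @param config a \code{coupling_config}.
#' @return list with \code{generation}, \code{consumption} (named
#'   per-species realized fluxes), \code{net} (generation - consumption),
#'   \code{objective_fluxes}, \code{extra_fluxes}.
#' @export
step_cobra_organ <- function(spec, toxin_bounds, config = coupling_config()) {
  stopifnot(inherits(spec, "organ_spec"))
  m <- spec$model
  stage <- "applying toxin input bounds"
  res <- tryCatch({
    m <- set_bounds(m, spec$toxin_in[names(toxin_bounds)], lb = 0,
                    ub = as.numeric(toxin_bounds))
    stage <- "pareto growth optimization"
    slack <- max(10 * config$pareto_tolerance, 1e-8)
    growth <- pareto_max(m, spec$objectives, config, spec$weights)
    m <- fix_pareto_state(m, growth, slack = slack)
    stage <- "toxin output (generation) maximization"
    gen <- pareto_max(m, unname(spec$toxin_out), config)
    m <- fix_pareto_state(m, gen, slack = slack)
    stage <- "toxin input (consumption) maximization"
    cons <- pareto_max(m, unname(spec$toxin_in), config)
    extra <- NULL
    if (!is.null(spec$extra_objectives)) {
      stage <- "demand objective optimization"
      m2 <- fix_pareto_state(m, cons, slack = slack)
      extra <- pareto_max(m2, spec$extra_objectives, config)
    }
    list(generation = setNames(unname(gen), names(spec$toxin_out)),
         consumption = setNames(unname(cons), names(spec$toxin_in)),
         objective_fluxes = growth, extra_fluxes = extra)
  }, error = function(e) {
    abort(sprintf("organ '%s' failed during %s: %s",
                  spec$tissue, stage, conditionMessage(e)))
  })
  res$net <- res$generation - res$consumption
  res
}

#' Run the discretized hybrid integration
#'
#' The coupling loop: at each step, the toxin input bound of every organ
#' model is derived from its current extravascular concentration; the organ
#' models are optimized (growth, then toxin generation and consumption);
#' the realized net exchange fluxes are converted to generation/consumption
#' terms; and the transport model is advanced one step.  Organ models see
#' start-of-step concentrations (explicit splitting).
#'
#' Simultaneous uptake and re-secretion through a split exchange pair is
#' feasible in the LP; the transport terms therefore use the net flux per
#' species (gross realized fluxes are kept in the records).
#'
#' @param gut a \code{community_model} (diet applied).
#' @param brain a \code{stoich_model} from \code{\link{make_toy_brain}} or
#'   compatible (ATP-maintenance objective first among its candidates).
#' @param pbpk_params a \code{pbpk_parameters}.
#' @param config a \code{coupling_config}.
#' @param gut_weights pareto weights for the gut biomass objectives
#'   (default equal).
#' @param organ_specs advanced: a named list of \code{organ_spec}s to use
#'   instead of building them from \code{gut}/\code{brain}.
#' @return a \code{coupling_trajectory}.
#' @export
run_integration <- function(gut, brain, pbpk_params,
                            config = coupling_config(), gut_weights = NULL,
                            organ_specs = NULL) {
  stopifnot(inherits(pbpk_params, "pbpk_parameters"))
  tis <- pbpk_params$tissues
  if (is.null(organ_specs)) {
    specs <- list()
    if (!is.null(gut)) {
      gw <- tis$gram_weight[tis$tissue == config$organ_map[["gut"]]]
      specs$gut <- organ_spec(gut, config$organ_map[["gut"]], gw,
                              weights = gut_weights, toxins = config$toxins)
    }
    if (!is.null(brain)) {
      gw <- tis$gram_weight[tis$tissue == config$organ_map[["brain"]]]
      atp <- grep("^ATPM", brain$objectives, value = TRUE)
      if (!length(atp)) atp <- brain$objectives[1]
      dem <- grep("^DM_", brain$rxns$id, value = TRUE)
      specs$brain <- organ_spec(brain, config$organ_map[["brain"]], gw,
                                objectives = atp[1],
                                extra_objectives = if (length(dem)) dem,
                                toxins = config$toxins)
    }
  } else specs <- organ_specs
  if (!length(specs)) abort("no organ models supplied")
  for (s in specs)
    if (!s$tissue %in% tis$tissue)
      abort(sprintf("organ tissue '%s' not in the transport model", s$tissue))

  species <- names(config$toxins)
  state <- setNames(lapply(species, function(sp)
    state_vector(pbpk_params, config$initial_concentration,
                 config$initial_concentration,
                 config$initial_concentration)), species)

  ev_of <- function(st, tissue) st[[paste0("CEV_", tissue)]]
  exch <- list(); objs <- list(); states <- list()
  record_state <- function(step, time) {
    states[[length(states) + 1]] <<- dplyr::bind_rows(lapply(species, function(sp) {
      nm <- names(state[[sp]]); vals <- as.numeric(state[[sp]])
      tibble(step = step, time = time, species = sp,
             state = nm, concentration = vals)
    }))
  }
  record_state(0L, 0)
  steady_state_step <- NA_integer_

  for (k in seq_len(config$n_steps)) {
    gen_terms <- cons_terms <- setNames(
      rep(list(setNames(numeric(0), character(0))), length(species)), species)
    for (org in names(specs)) {
      sp_org <- specs[[org]]
      V_ev <- tis$V_ev[tis$tissue == sp_org$tissue]
      bounds <- vapply(species, function(sp)
        concentration_to_flux_bound(ev_of(state[[sp]], sp_org$tissue), V_ev,
                                    sp_org$gram_weight, config$dt_hours,
                                    config$conversion_scale), 0)
      res <- tryCatch(step_cobra_organ(sp_org, bounds, config),
                      error = function(e)
                        abort(sprintf("integration aborted at step %d: %s",
                                      k, conditionMessage(e))))
      for (sp in species) {
        net <- res$net[[sp]]
        if (net >= 0) {
          gen_terms[[sp]][sp_org$tissue] <-
            flux_to_concentration_rate(net, V_ev, sp_org$gram_weight,
                                       config$conversion_scale)
        } else {
          cons_terms[[sp]][sp_org$tissue] <-
            flux_to_concentration_rate(-net, V_ev, sp_org$gram_weight,
                                       config$conversion_scale)
        }
        exch[[length(exch) + 1]] <- tibble(
          step = k, time = k * config$dt_hours, organ = org,
          tissue = sp_org$tissue, species = sp,
          input_bound = bounds[[sp]],
          generation_flux = res$generation[[sp]],
          consumption_flux = res$consumption[[sp]],
          net_flux = net)
      }
      objs[[length(objs) + 1]] <- tibble(
        step = k, organ = org,
        objective = c(names(res$objective_fluxes),
                      names(res$extra_fluxes)),
        flux = c(as.numeric(res$objective_fluxes),
                 as.numeric(res$extra_fluxes)))
    }
    prev <- state
    for (sp in species) {
      deriv <- function(t, y, parms)
        list(tissue_derivatives(y, pbpk_params,
                                generation = gen_terms[[sp]],
                                consumption = cons_terms[[sp]]))
      sol <- deSolve::lsoda(state[[sp]], c(0, config$dt_hours), deriv, NULL,
                            rtol = 1e-8, atol = 1e-12)
      y <- sol[nrow(sol), -1]
      y[y < 0] <- 0
      state[[sp]] <- setNames(as.numeric(y), names(state[[sp]]))
    }
    record_state(k, k * config$dt_hours)
    relchg <- max(vapply(species, function(sp)
      max(abs(state[[sp]] - prev[[sp]]) /
            pmax(abs(prev[[sp]]), 1e-30)), 0))
    if (is.na(steady_state_step) && relchg < config$steady_state_tol)
      steady_state_step <- k
  }

  st <- dplyr::bind_rows(states)
  st <- dplyr::mutate(
    st,
    compartment = dplyr::case_when(
      .data$state == "C_ART" ~ "blood",
      startsWith(.data$state, "CEV_") ~ sub("^CEV_", "", .data$state),
      TRUE ~ sub("^C_", "", .data$state)),
    pool = dplyr::case_when(
      .data$state == "C_ART" ~ "blood",
      startsWith(.data$state, "CEV_") ~ "extravascular",
      TRUE ~ "vascular"))
  structure(list(states = dplyr::select(st, -"state"),
                 exchanges = dplyr::bind_rows(exch),
                 objectives = dplyr::bind_rows(objs),
                 config = config, params = pbpk_params,
                 steady_state_step = steady_state_step),
            class = "coupling_trajectory")
}

#' @export
print.coupling_trajectory <- function(x, ...) {
  cat(sprintf("<coupling_trajectory> %d steps of %g hr%s\n",
              x$config$n_steps, x$config$dt_hours,
              if (is.na(x$steady_state_step)) ""
              else sprintf(" | steady state at step %d", x$steady_state_step)))
  invisible(x)
}

#' @export
tidy.coupling_trajectory <- function(x, ...) x$states

#' @export
glance.coupling_trajectory <- function(x, ...) {
  finals <- dplyr::filter(x$states, .data$time == max(.data$time))
  tibble(n_steps = x$config$n_steps,
         horizon_hours = x$config$horizon_hours,
         steady_state_step = x$steady_state_step,
         max_final_concentration = max(finals$concentration))
}

#' @export
autoplot.coupling_trajectory <- function(object, pool = "extravascular", ...) {
  d <- dplyr::filter(object$states, .data$pool == !!pool)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$concentration,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (hr)", y = "concentration (M)",
                  title = sprintf("%s concentrations", pool))
}

#' Write a coupling trajectory as TSV
#' @param trajectory a \code{coupling_trajectory}.
#' @param path output file.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory$states), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Steady-state toxin exchange fluxes from a trajectory
#'
#' Last-step realized input/output exchange fluxes per organ and species,
#' used to constrain the toxic-model comparison.
#' @param trajectory a \code{coupling_trajectory}.
#' @param organ organ name (default \code{"gut"}).
#' @export
steady_state_fluxes <- function(trajectory, organ = "gut") {
  last <- dplyr::filter(trajectory$exchanges,
                        .data$organ == !!organ,
                        .data$step == max(.data$step))
  setNames(lapply(seq_len(nrow(last)), function(i)
    c(input = last$consumption_flux[i], output = last$generation_flux[i])),
    last$species)
}
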