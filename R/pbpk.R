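#' Physiological parameters for the whole-body transport model
#'
#' Defines the six-tissue, permeability-limited, two-subcompartment
#' whole-body model.  Each tissue is a well-stirred tank split into a
#' vascular and an extravascular compartment exchanging through the
#' permeability-surface product \code{P*S} with partition coefficient
#' \code{K}; tissues communicate through a common blood pool; renal
#' clearance removes substance from the arterial blood (switchable to the
#' kidney vascular compartment).
#'
#' @param tissues tibble/data frame with columns \code{tissue}, \code{Q}
#'   (blood flow, L/hr), \code{V} (total tissue volume, L), \code{V_ev}
#'   (extravascular volume, L, < V), \code{P} (permeability, L/hr per unit
#'   area), \code{S_area} (surface area), \code{K} (partition coefficient),
#'   \code{gram_weight} (organ weight, g, used by the flux-concentration
#'   conversion).
#' @param V_blood blood pool volume (L).
#' @param CL_renal renal clearance (L/hr).
#' @param clearance_site \code{"arterial"} (default) or \code{"kidney"}.
#' @return a \code{pbpk_parameters} object; the volume ratio
#'   \code{f = V / V_ev} is computed and stored.
#' @export
pbpk_parameters <- function(tissues, V_blood, CL_renal,
                            clearance_site = c("arterial", "kidney")) {
  clearance_site <- match.arg(clearance_site)
  tissues <- as_tibble(tissues)
  need <- c("tissue", "Q", "V", "V_ev", "P", "S_area", "K", "gram_weight")
  missing <- setdiff(need, names(tissues))
  if (length(missing))
    abort(sprintf("tissues table lacks columns: %s", paste(missing, collapse = ", ")))
  num <- tissues[setdiff(need, "tissue")]
  if (any(as.matrix(num) <= 0))
    abort("all tissue parameters must be strictly positive")
  if (any(tissues$V_ev >= tissues$V))
    abort("extravascular volume must be smaller than total tissue volume")
  if (V_blood <= 0) abort("V_blood must be positive")
  if (CL_renal < 0) abort("CL_renal must be nonnegative")
  if (clearance_site == "kidney" && !"kidney" %in% tissues$tissue)
    abort("clearance_site 'kidney' requires a 'kidney' tissue")
  tissues$f <- compute_f(tissues$V, tissues$V_ev)
  structure(list(tissues = tissues, V_blood = V_blood,
                 CL_renal = CL_renal, clearance_site = clearance_site),
            class = "pbpk_parameters")
}

#' @export
print.pbpk_parameters <- function(x, ...) {
  cat(sprintf("<pbpk_parameters> %d tissues | V_blood=%g L | CL_renal=%g L/hr (%s)\n",
              nrow(x$tissues), x$V_blood, x$CL_renal, x$clearance_site))
  print(x$tissues)
  invisible(x)
}

#' Vascular-to-extravascular volume ratio
#'
#' \code{f = V_T / V_EV,T}, the tissue volume over its extravascular
#' volume.
#' @param V_T total tissue volume (> 0).
#' @param V_EV_T extravascular volume (> 0).
#' @export
compute_f <- function(V_T, V_EV_T) {
  if (any(V_T <= 0) || any(V_EV_T <= 0))
    abort("volumes must be strictly positive")
  V_T / V_EV_T
}

# State layout for one species: c(C_ART, C_T (per tissue), C_EV (per tissue))
state_vector <- function(params, C_art, C_t, C_ev) {
  tis <- params$tissues$tissue
  c(C_ART = unname(C_art),
    setNames(rep_len(C_t, length(tis)), paste0("C_", tis)),
    setNames(rep_len(C_ev, length(tis)), paste0("CEV_", tis)))
}

#' Time derivatives of the tissue mass balances
#'
#' Implements the permeability-limited two-compartment balances (with the
#' printed left-hand-side volume factors \code{f V/(1+f)} vascular and
#' \code{V/(1+f)} extravascular) plus a well-mixed blood pool with
#' flow-weighted return and renal clearance:
#' \deqn{\frac{f V_T}{1+f}\dot C_T = Q_T (C_{ART} - C_T) + P_T S_T (C_{EV,T}/K_T - C_T)}
#' \deqn{\frac{V_T}{1+f}\dot C_{EV,T} = P_T S_T (C_T - C_{EV,T}/K_T) + gen_T - cons_T}
#' \deqn{V_B \dot C_{ART} = \sum_T Q_T C_T - (\sum_T Q_T)\, C_{ART} - CL_R\, C_{ART}}
#'
#' @param state numeric vector \code{c(C_ART, C_<tissue>..., CEV_<tissue>...)}
#'   in M, as built by \code{simulate_pbpk}'s initial state.
#' @param params a \code{pbpk_parameters}.
#' @param generation,consumption named vectors (tissue -> mol/hr) applied to
#'   the extravascular compartments; default zero.
#' @return derivative vector (M/hr) in the same layout.
#' @export
tissue_derivatives <- function(state, params,
                               generation = NULL, consumption = NULL) {
  tis <- params$tissues
  n <- nrow(tis)
  if (length(state) != 2 * n + 1)
    abort("state length does not match the tissue table")
  C_art <- state[1]
  C_t <- state[1 + seq_len(n)]
  C_ev <- state[1 + n + seq_len(n)]
  gen <- cons <- rep(0, n)
  if (!is.null(generation)) {
    i <- match(names(generation), tis$tissue)
    if (anyNA(i)) abort("generation names must be tissues")
    gen[i] <- generation
  }
  if (!is.null(consumption)) {
    i <- match(names(consumption), tis$tissue)
    if (anyNA(i)) abort("consumption names must be tissues")
    cons[i] <- consumption
  }
  PS <- tis$P * tis$S_area
  V_vasc <- tis$f * tis$V / (1 + tis$f)
  V_ev_eff <- tis$V / (1 + tis$f)
  dC_t <- (tis$Q * (C_art - C_t) + PS * (C_ev / tis$K - C_t)) / V_vasc
  dC_ev <- (PS * (C_t - C_ev / tis$K) + gen - cons) / V_ev_eff
  if (params$clearance_site == "kidney") {
    k <- which(tis$tissue == "kidney")
    dC_t[k] <- dC_t[k] - params$CL_renal * C_t[k] / V_vasc[k]
    dC_art <- (sum(tis$Q * C_t) - sum(tis$Q) * C_art) / params$V_blood
  } else {
    dC_art <- (sum(tis$Q * C_t) - sum(tis$Q) * C_art -
                 params$CL_renal * C_art) / params$V_blood
  }
  out <- c(dC_art, dC_t, dC_ev)
  names(out) <- names(state)
  out
}

#' Total amount of substance in the system (mol)
#'
#' Uses the effective compartment volumes implied by the printed balance
#' equations (\code{f V/(1+f)} vascular, \code{V/(1+f)} extravascular) plus
#' the blood pool; conserved when clearance and source terms vanish.
#' @param state state vector (one species).
#' @param params a \code{pbpk_parameters}.
#' @export
total_amount <- function(state, params) {
  tis <- params$tissues
  n <- nrow(tis)
  V_vasc <- tis$f * tis$V / (1 + tis$f)
  V_ev_eff <- tis$V / (1 + tis$f)
  params$V_blood * state[[1]] +
    sum(V_vasc * state[1 + seq_len(n)]) +
    sum(V_ev_eff * state[1 + n + seq_len(n)])
}

#' Simulate the whole-body transport model
#'
#' Integrates the tissue mass balances for one or more toxin species with a
#' stiff-capable adaptive integrator (\code{deSolve::lsoda}), sampling on a
#' fixed output grid.
#'
#' @param params a \code{pbpk_parameters}.
#' @param initial named list (species -> state vector) or a single number
#'   used for every compartment of every species.
#' @param duration total time (hr).
#' @param step output step (hr, default 0.25).
#' @param species character vector of species names when \code{initial} is
#'   scalar (default \code{c("h2o2", "o2s")}).
#' @param generation,consumption per-species named lists of tissue ->
#'   mol/hr terms (constant over the simulation).
#' @param rtol,atol integrator tolerances.
#' @return a \code{pbpk_trajectory} tibble: \code{time}, \code{species},
#'   \code{compartment} (\code{"blood"} or tissue), \code{pool}
#'   (\code{"blood"}, \code{"vascular"}, \code{"extravascular"}),
#'   \code{concentration} (M).
#' @export
simulate_pbpk <- function(params, initial, duration, step = 0.25,
                          species = c("h2o2", "o2s"),
                          generation = NULL, consumption = NULL,
                          rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "pbpk_parameters"))
  if (duration <= 0) abort("duration must be positive")
  if (is.numeric(initial) && length(initial) == 1)
    initial <- setNames(
      lapply(species, function(s) state_vector(params, initial, initial, initial)),
      species)
  times <- seq(0, duration, by = step)
  rows <- list()
  for (sp in names(initial)) {
    y0 <- initial[[sp]]
    gen <- if (!is.null(generation)) generation[[sp]] else NULL
    cons <- if (!is.null(consumption)) consumption[[sp]] else NULL
    deriv <- function(t, y, parms) list(tissue_derivatives(y, params, gen, cons))
    sol <- deSolve::lsoda(y0, times, deriv, NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      abort(sprintf("integrator failure for species '%s' at t=%g",
                    sp, max(sol[, "time"], na.rm = TRUE)))
    m <- as.matrix(sol)
    undershoot <- m[, -1, drop = FALSE] < -10 * atol
    if (any(undershoot))
      warn(sprintf("negative concentrations clipped to 0 for species '%s'", sp))
    m[, -1][m[, -1] < 0] <- 0
    tis <- params$tissues$tissue
    long <- tibble(
      time = rep(m[, "time"], times = ncol(m) - 1),
      species = sp,
      state = rep(colnames(m)[-1], each = nrow(m)),
      concentration = as.numeric(m[, -1]))
    rows[[sp]] <- long
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(
    out,
    compartment = dplyr::case_when(
      .data$state == "C_ART" ~ "blood",
      startsWith(.data$state, "CEV_") ~ sub("^CEV_", "", .data$state),
      TRUE ~ sub("^C_", "", .data$state)),
    pool = dplyr::case_when(
      .data$state == "C_ART" ~ "blood",
      startsWith(.data$state, "CEV_") ~ "extravascular",
      TRUE ~ "vascular"))
  out <- dplyr::select(out, "time", "species", "compartment", "pool",
                       "concentration")
  class(out) <- c("pbpk_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' @export
autoplot.pbpk_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$concentration,
                               colour = .data$compartment,
                               linetype = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (hr)", y = "concentration (M)")
}
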