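test_that("the concentration/flux unit conversion is a consistent inverse pair", {
  expect_equal(concentration_to_flux_bound(0, 0.004, 7.26, 0.25), 0)
  # equal pools: the bound scales inversely with organ gram weight
  b_gut <- concentration_to_flux_bound(1e-4, 0.002, 7.26, 0.25)
  b_brain <- concentration_to_flux_bound(1e-4, 0.002, 2, 0.25)
  expect_equal(b_gut, (2 / 7.26) * b_brain)

  # hand case: flux chosen to give exactly 1 nmol/hr
  expect_equal(flux_to_concentration_rate(0.5, 0.001, 2), 1e-9)  # 1 nmol/hr
  expect_equal(flux_to_concentration_rate(1, 0.001, 2),
               2 * flux_to_concentration_rate(0.5, 0.001, 2))  # linear

  # round trip: consuming the whole pool in one step recovers C
  set.seed(21)
  for (i in 1:5) {
    C <- runif(1, 1e-6, 1e-3); V <- runif(1, 1e-4, 1e-2)
    gw <- runif(1, 1, 10); dt <- 0.25
    bound <- concentration_to_flux_bound(C, V, gw, dt)
    removed <- flux_to_concentration_rate(bound, V, gw) * dt  # mol
    expect_equal(removed / V, C, tolerance = 1e-12)
  }

  expect_error(concentration_to_flux_bound(1e-4, 0.01, 0, 0.25), "positive")
  expect_error(concentration_to_flux_bound(-1, 0.01, 1, 0.25), ">= 0")
  expect_error(flux_to_concentration_rate(-1, 0.01, 1), ">= 0")
})

test_that("a producer gut generates toxins; a closed system exchanges nothing", {
  diets <- make_toy_diets()
  comm <- make_toy_community(diet = diets$western, include_beneficial = FALSE)
  sp <- organ_spec(comm, "gut", 7.26)
  res <- step_cobra_organ(sp, c(h2o2 = 0, o2s = 0))
  expect_true(all(res$generation > 0))
  expect_equal(unname(res$consumption), c(0, 0))
  expect_true(all(res$net > 0))
  # realized consumption never exceeds the applied bound
  res2 <- step_cobra_organ(sp, c(h2o2 = 5, o2s = 5))
  expect_true(all(res2$consumption <= c(5, 5) + 1e-6))

  # no diet carbon, no toxin bound: nothing moves
  closed <- apply_diet(comm, setNames(numeric(0), character(0)))
  spc <- organ_spec(closed, "gut", 7.26)
  r0 <- step_cobra_organ(spc, c(h2o2 = 0, o2s = 0))
  expect_equal(unname(r0$generation), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(r0$consumption), c(0, 0), tolerance = 1e-8)
})

test_that("host dismutation inside the community halves superoxide into peroxide", {
  # community of host only: superoxide inflow must leave as half as much peroxide
  comm <- build_community(list(), host_model = make_toy_host(TRUE))
  comm <- apply_diet(comm, c(h = 1000))
  sp <- organ_spec(comm, "gut", 7.26)
  res <- step_cobra_organ(sp, c(h2o2 = 0, o2s = 4))
  # peroxide appears at half the molar rate of net superoxide disappearance
  expect_lt(res$net[["o2s"]], 0)
  expect_gt(res$net[["h2o2"]], 0)
  expect_equal(res$net[["h2o2"]], -res$net[["o2s"]] / 2, tolerance = 1e-4)
})

test_that("the default integration runs 24 steps with per-step bookkeeping", {
  traj <- default_integration()
  expect_equal(traj$config$n_steps, 24)
  expect_equal(max(traj$states$time), 6)
  expect_equal(dplyr::n_distinct(traj$states$step), 25)  # initial + 24
  # the realized input flux respects the applied bound at every step
  expect_true(all(traj$exchanges$consumption_flux <=
                    traj$exchanges$input_bound + 1e-6))
  # trajectory is deterministic
  diets <- make_toy_diets()
  comm <- make_toy_community(diet = diets$western)
  again <- run_integration(comm, make_toy_brain(), make_toy_pbpk_params(),
                           coupling_config(),
                           gut_weights = toy_weights_vector(comm, 40))
  expect_equal(again$states$concentration, traj$states$concentration,
               tolerance = 1e-12)
})

test_that("per-step toxin bookkeeping closes without renal clearance", {
  diets <- make_toy_diets()
  comm <- make_toy_community(diet = diets$western)
  cfg <- coupling_config(horizon_hours = 1)
  p0 <- make_toy_pbpk_params(CL_renal = 0)
  traj <- run_integration(comm, make_toy_brain(), p0, cfg,
                          gut_weights = toy_weights_vector(comm, 40))
  for (sp in c("h2o2", "o2s")) {
    states <- dplyr::filter(traj$states, .data$species == sp)
    amount <- vapply(split(states, states$step), function(d) {
      vasc <- d[d$pool == "vascular", ]; ev <- d[d$pool == "extravascular", ]
      tis <- p0$tissues$tissue
      total_amount(c(d$concentration[d$pool == "blood"],
                     vasc$concentration[match(tis, vasc$compartment)],
                     ev$concentration[match(tis, ev$compartment)]), p0)
    }, 0)
    amount <- amount[order(as.integer(names(amount)))]
    ex <- dplyr::filter(traj$exchanges, .data$species == sp)
    net_mol <- vapply(split(ex, ex$step), function(d)
      sum(flux_to_concentration_rate(abs(d$net_flux), 1,
                                     ifelse(d$organ == "gut", 7.26, 2)) *
            sign(d$net_flux)) * cfg$dt_hours, 0)
    expect_equal(unname(diff(amount)), unname(net_mol), tolerance = 1e-10)
  }
})

test_that("zero-production organs with clearance give monotone decay", {
  # beneficial-only community produces no toxins; renal clearance drains
  diets <- make_toy_diets()
  comm <- make_toy_community(diet = diets$high_fiber, include_harmful = FALSE)
  cfg <- coupling_config(horizon_hours = 2)
  traj <- run_integration(comm, make_toy_brain(), make_toy_pbpk_params(), cfg,
                          gut_weights = toy_weights_vector(comm, 100))
  blood <- dplyr::filter(traj$states, .data$pool == "blood",
                         .data$species == "h2o2")
  blood <- dplyr::arrange(blood, .data$time)
  expect_true(all(diff(blood$concentration) < 0))
})

test_that("identical organ models with symmetric parameters give identical trajectories", {
  tis <- tibble::tibble(
    tissue = c("gut", "brain"),
    Q = 0.05, V = 0.004, V_ev = 0.002, P = 0.05, S_area = 1, K = 1,
    gram_weight = 2)
  p <- pbpk_parameters(tis, V_blood = 0.01, CL_renal = 0.01)
  mk_spec <- function(tissue)
    organ_spec(make_toy_brain(), tissue, 2, objectives = "ATPM")
  cfg <- coupling_config(horizon_hours = 1)
  traj <- run_integration(NULL, NULL, p, cfg,
                          organ_specs = list(gut = mk_spec("gut"),
                                             brain = mk_spec("brain")))
  for (sp in c("h2o2", "o2s")) {
    d <- dplyr::filter(traj$states, .data$species == sp,
                       .data$pool == "extravascular")
    g <- dplyr::arrange(dplyr::filter(d, .data$compartment == "gut"), .data$time)
    b <- dplyr::arrange(dplyr::filter(d, .data$compartment == "brain"), .data$time)
    expect_equal(g$concentration, b$concentration, tolerance = 1e-10)
  }
})

test_that("config validation and stage-error reporting work", {
  expect_error(coupling_config(dt_hours = 0.7), "divide")
  expect_error(coupling_config(dt_hours = -1), "positive")
  # an infeasible organ aborts with step and stage context
  m <- toy_two_objective(10)
  m <- add_reaction(m, "EX_h2o2_e", c(h2o2_e = -1), lb = 0, ub = 0)
  m <- add_reaction(m, "EX_o2s_e", c(o2s_e = -1), lb = 0, ub = 0)
  m <- set_bounds(m, "v1", lb = 20, ub = 30)  # infeasible objective
  sp <- organ_spec(m, "gut", 7.26, objectives = c("v1", "v2"))
  expect_error(step_cobra_organ(sp, c(h2o2 = 0, o2s = 0)),
               "pareto growth")
})
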