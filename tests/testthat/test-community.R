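# two-bacteria + host counting fixture: member A has 4 extracellular
# metabolites, member B 3 (one shared with A), host 2 (both already seen),
# so set arithmetic gives 6 lumen metabolites and 4+3+2 = 9 transports.
tiny_member <- function(id, ext) {
  m <- new_model(id)
  for (met in ext)
    m <- add_reaction(m, paste0("EX_", met, "_e"),
                      setNames(-1, paste0(met, "_e")), lb = -10, ub = 10)
  m <- add_reaction(m, "USE", setNames(c(-1, 1), paste0(c(ext[1], "x"), c("_e", "_c"))),
                    lb = 0, ub = 100)
  add_reaction(m, "BIO", c(x_c = -1), lb = 0, ub = 100, objective = TRUE)
}

test_that("community assembly counts transports and lumen metabolites by set arithmetic", {
  A <- tiny_member("A", c("m1", "m2", "m3", "m4"))
  B <- tiny_member("B", c("m4", "m5", "m6"))
  H <- tiny_member("H", c("m1", "m5"))
  comm <- build_community(list(a = A, b = B), host_model = H)
  expect_equal(comm$n_transport_added, 9)
  expect_equal(length(comm$lumen_mets), 6)
  expect_setequal(comm$lumen_mets, paste0("m", 1:6, "_lu"))
  # one diet + one fecal exchange per lumen metabolite
  expect_equal(length(comm$diet_rxns), 6)
  expect_equal(length(comm$fecal_rxns), 6)
  # one biomass objective per member and host
  expect_equal(sort(names(comm$biomass_reactions)), c("a", "b", "host"))
  # no id collisions
  expect_false(anyDuplicated(comm$rxns$id) > 0)

  # determinism: rebuilding yields the identical reaction id set
  comm2 <- build_community(list(a = A, b = B), host_model = H)
  expect_identical(comm$rxns$id, comm2$rxns$id)

  expect_error(build_community(list(a = A, a = B)), "duplicate")
})

test_that("members without extracellular metabolites warn but are included", {
  closed <- new_model("closed")
  closed <- add_reaction(closed, "SRC", c(x_c = 1), lb = 0, ub = 5)
  closed <- add_reaction(closed, "BIO", c(x_c = -1), lb = 0, ub = 100,
                         objective = TRUE)
  A <- tiny_member("A", "m1")
  expect_warning(comm <- build_community(list(a = A, z = closed)),
                 "no extracellular")
  expect_equal(comm$n_transport_added, 1)
  expect_true("BIO_z" %in% comm$rxns$id)
})

test_that("the merged matrix is block-diagonal apart from luminal transport", {
  A <- tiny_member("A", c("m1", "m2"))
  B <- tiny_member("B", c("m2", "m3"))
  comm <- build_community(list(a = A, b = B))
  S <- as.matrix(comm$S)
  boundary <- c(comm$transport_rxns, comm$diet_rxns, comm$fecal_rxns)
  inner <- setdiff(comm$rxns$id, boundary)
  for (rid in inner) {
    touched <- rownames(S)[S[, rid] != 0]
    tags <- unique(sub(".*_", "", touched))
    expect_length(tags, 1)  # one member block per internal reaction
  }
})

test_that("apply_diet opens exactly the listed uptakes", {
  A <- tiny_member("A", c("m1", "m2", "m3"))
  comm <- build_community(list(a = A))
  comm <- apply_diet(comm, c(m1 = 10))
  idx <- match(c("EX_m1_lu_diet", "EX_m2_lu_diet", "EX_m3_lu_diet"),
               comm$rxns$id)
  expect_equal(comm$rxns$lb[idx], c(-10, 0, 0))
  # fecal side untouched
  fid <- match("EX_m1_lu_fecal", comm$rxns$id)
  expect_equal(c(comm$rxns$lb[fid], comm$rxns$ub[fid]), c(0, 1000))
  expect_warning(apply_diet(comm, c(nope = 1)), "skipped")

  # empty diet starves the community
  starved <- apply_diet(comm, setNames(numeric(0), character(0)))
  expect_equal(solve_fba(starved, "BIO_a")$objective_value, 0)
})

test_that("pareto growth is monotone in diet availability", {
  spec <- fixture_spec()
  diets <- make_toy_diets()
  comm <- make_toy_community(spec)
  grow <- function(diet) {
    c2 <- apply_diet(comm, diet)
    pr <- pareto_problem(c2, unname(c2$biomass_reactions))
    sum(pareto_binary_search(pr)$objective_fluxes)
  }
  small <- diet_spec("small", c(starch = 50, fiber = 50, ac = 5, o2 = 10, h = 1000))
  big <- diet_spec("big", c(starch = 100, fiber = 100, ac = 5, o2 = 10, h = 1000))
  expect_gt(grow(big), grow(small))
  # superset diet never decreases growth
  super <- diet_spec("super", c(starch = 50, fiber = 50, ac = 50, o2 = 10, h = 1000))
  expect_gte(grow(super), grow(small) - 1e-6)
})

test_that("oxygen condition is applied per member, idempotently", {
  comm <- make_toy_community()
  o2 <- paste0("T_o2_", c(comm$member_tags, comm$host_tag), "_lu")
  idx <- match(o2, comm$rxns$id)
  expect_true(all(comm$rxns$lb[idx] == -1))  # applied by the builder
  again <- set_oxygen_condition(comm, -1)
  expect_identical(again$rxns, comm$rxns)
  anaerobic <- set_oxygen_condition(comm, 0)
  expect_equal(anaerobic$rxns$lb[match(o2, anaerobic$rxns$id)], rep(0, 6))

  nomatch <- make_toy_community()
  expect_warning(set_oxygen_condition(nomatch, -1, o2_id = "xyz"),
                 "no oxygen")
})

test_that("anaerobic condition kills an obligate aerobe community", {
  ae <- toy_aerobe()
  # give it extracellular mets so it can join a community
  comm <- build_community(list(ob = ae))
  comm <- apply_diet(comm, c(glc = 10, o2 = 10))
  expect_gt(solve_fba(comm, "BIOMASS_ob")$objective_value, 0)
  comm0 <- set_oxygen_condition(comm, 0)
  expect_equal(solve_fba(comm0, "BIOMASS_ob")$objective_value, 0)
})

test_that("split exchange pairs preserve the flux space", {
  m <- new_model("split")
  m <- add_reaction(m, "EX_a", c(a_e = -1), lb = -5, ub = 8)
  m <- add_reaction(m, "USE", c(a_e = -1, b_c = 1), lb = 0, ub = 100)
  m <- add_reaction(m, "BIO", c(b_c = -1), lb = 0, ub = 100, objective = TRUE)
  s <- split_reversible_exchange(m, "EX_a")
  idx <- match(c("EX_a_in", "EX_a_out"), s$rxns$id)
  expect_equal(s$rxns$lb[idx], c(0, 0))
  expect_equal(s$rxns$ub[idx], c(5, 8))
  expect_false("EX_a" %in% s$rxns$id)

  # already-irreversible exchange: input capacity zero
  m2 <- set_bounds(m, "EX_a", lb = 0, ub = 8)
  s2 <- split_reversible_exchange(m2, "EX_a")
  idx2 <- match(c("EX_a_in", "EX_a_out"), s2$rxns$id)
  expect_equal(s2$rxns$ub[idx2], c(0, 8))

  expect_error(split_reversible_exchange(m, "USE"), "not an exchange")
})

test_that("splitting every exchange preserves FBA optima", {
  for (model in list(make_toy_member("harmful"), make_toy_brain())) {
    base <- solve_fba(model, model$objectives[1])$objective_value
    s <- model
    boundary <- grep("^EX_", model$rxns$id[is_exchange(model)], value = TRUE)
    for (rid in boundary)
      s <- split_reversible_exchange(s, rid)
    expect_equal(solve_fba(s, model$objectives[1])$objective_value, base,
                 tolerance = 1e-9)
  }
})
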