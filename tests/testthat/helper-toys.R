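# Hand-built toy networks with analytically known optima, plus small
# oracles (vertex enumeration, grid non-domination) used across the suite.

# linear chain: R_up (0,5) -> A -> R_ab -> B -> R_bc -> C -> R_out
toy_chain <- function(cap = 5) {
  m <- new_model("chain")
  m <- add_reaction(m, "R_up", c(A = 1), lb = 0, ub = cap)
  m <- add_reaction(m, "R_ab", c(A = -1, B = 1), lb = 0, ub = 1000)
  m <- add_reaction(m, "R_bc", c(B = -1, C = 1), lb = 0, ub = 1000)
  m <- add_reaction(m, "R_out", c(C = -1), lb = 0, ub = 1000)
  m
}

# uptake bottleneck: EX (0,10) -> M -> biomass
toy_bottleneck <- function() {
  m <- new_model("bottleneck")
  m <- add_reaction(m, "R_up", c(M = 1), lb = 0, ub = 10)
  m <- add_reaction(m, "R_bio", c(M = -1), lb = 0, ub = 1000,
                    objective = TRUE)
  m
}

# two parallel routes A -> B sharing uptake capacity 10
toy_parallel <- function() {
  m <- new_model("parallel")
  m <- add_reaction(m, "R_up", c(A = 1), lb = 0, ub = 10)
  m <- add_reaction(m, "R_p1", c(A = -1, B = 1), lb = 0, ub = 1000)
  m <- add_reaction(m, "R_p2", c(A = -1, B = 1), lb = 0, ub = 1000)
  m <- add_reaction(m, "R_out", c(B = -1), lb = 0, ub = 1000)
  m
}

# shared capacity: v1 + v2 <= cap via a common precursor
toy_two_objective <- function(cap = 10) {
  m <- new_model("two_obj")
  m <- add_reaction(m, "R_src", c(P = 1), lb = 0, ub = cap)
  m <- add_reaction(m, "v1", c(P = -1), lb = 0, ub = 1000, objective = TRUE)
  m <- add_reaction(m, "v2", c(P = -1), lb = 0, ub = 1000, objective = TRUE)
  m
}

toy_three_objective <- function(cap = 9) {
  m <- new_model("three_obj")
  m <- add_reaction(m, "R_src", c(P = 1), lb = 0, ub = cap)
  for (v in c("v1", "v2", "v3"))
    m <- add_reaction(m, v, c(P = -1), lb = 0, ub = 1000, objective = TRUE)
  m
}

# obligate aerobe: growth strictly requires oxygen
toy_aerobe <- function() {
  m <- new_model("aerobe")
  m <- add_reaction(m, "EX_glc_e", c(glc_e = -1), lb = -10, ub = 0)
  m <- add_reaction(m, "EX_o2_e", c(o2_e = -1), lb = -10, ub = 0)
  m <- add_reaction(m, "RESP", c(glc_e = -1, o2_e = -1, atp_c = 2),
                    lb = 0, ub = 1000)
  m <- add_reaction(m, "BIOMASS", c(atp_c = -1), lb = 0, ub = 1000,
                    objective = TRUE)
  m
}

# enumerate the vertices of {S v = 0, lb <= v <= ub} by fixing n - rank(S)
# variables at a bound and solving for the rest; brute-force oracle for FVA
enumerate_vertices <- function(model, tol = 1e-9) {
  S <- as.matrix(model$S)
  lb <- model$rxns$lb; ub <- model$rxns$ub
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  verts <- list()
  for (fix_idx in utils::combn(n, k, simplify = FALSE)) {
    free_idx <- setdiff(seq_len(n), fix_idx)
    Sf <- S[, free_idx, drop = FALSE]
    if (qr(Sf)$rank < r) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fix_idx] <- ifelse(unlist(grid[g, ]), ub[fix_idx], lb[fix_idx])
      rhs <- -S[, fix_idx, drop = FALSE] %*% v[fix_idx]
      sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v[free_idx] <- sol
      if (max(abs(S %*% v)) > 1e-7) next
      if (all(v >= lb - tol) && all(v <= ub + tol))
        verts[[length(verts) + 1]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  out <- unique(do.call(rbind, lapply(verts, round, digits = 9)))
  colnames(out) <- model$rxns$id
  out
}

# grid oracle: is 'point' dominated by any feasible objective vector on a
# grid (componentwise >= with at least one strictly greater)?
grid_dominates <- function(model, objectives, point, n_grid = 50,
                           eps = 1e-6) {
  rng <- lapply(objectives, function(o) {
    mx <- solve_fba(model, setNames(1, o))$objective_value
    seq(0, mx, length.out = n_grid)
  })
  grid <- as.matrix(expand.grid(rng))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (all(g >= point - eps) && any(g > point + eps)) {
      m2 <- set_bounds(model, objectives, lb = as.numeric(g))
      ok <- lp_maximize(m2$S, rep(0, nrow(m2$S)), rep(0, nrow(m2$rxns)),
                        m2$rxns$lb, m2$rxns$ub)
      if (ok$status == "optimal") return(TRUE)
    }
  }
  FALSE
}

# permute the reaction order of a model (invariance checks)
permute_reactions <- function(model, perm) {
  model$rxns <- model$rxns[perm, ]
  model$S <- model$S[, perm, drop = FALSE]
  model
}

# shared expensive fixtures, computed once per test run
.toy_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .toy_cache)) assign(key, force(expr), .toy_cache)
  get(key, .toy_cache)
}

toy_weights_vector <- function(comm, beneficial_percent) {
  w <- compute_weights(beneficial_percent,
                       comm$beneficial_tags, comm$harmful_tags,
                       host_id = comm$host_tag)
  unname(w[c(comm$beneficial_tags, comm$harmful_tags, comm$host_tag)])
}

default_integration <- function() {
  cached("default_integration", {
    diets <- make_toy_diets()
    comm <- make_toy_community(diet = diets$western)
    run_integration(comm, make_toy_brain(), make_toy_pbpk_params(),
                    coupling_config(),
                    gut_weights = toy_weights_vector(comm, 40))
  })
}

harmful_only_integration <- function() {
  cached("harmful_only_integration", {
    diets <- make_toy_diets()
    comm <- make_toy_community(diet = diets$western,
                               include_beneficial = FALSE)
    run_integration(comm, make_toy_brain(), make_toy_pbpk_params(),
                    coupling_config(),
                    gut_weights = toy_weights_vector(comm, 0))
  })
}

gut_ev_series <- function(traj, sp = "h2o2") {
  d <- dplyr::filter(traj$states, .data$compartment == "gut",
                     .data$pool == "extravascular", .data$species == sp)
  d <- dplyr::arrange(d, .data$time)
  setNames(d$concentration, d$time)
}
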