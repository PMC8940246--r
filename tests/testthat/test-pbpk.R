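test_that("the volume ratio follows its defining identity", {
  expect_equal(compute_f(1.0, 0.8), 1.25)
  expect_equal(compute_f(2, 2), 1)
  set.seed(5)
  v <- runif(20, 0.1, 10); ev <- v * runif(20, 0.05, 0.99)
  expect_equal(compute_f(v, ev), v / ev)
  expect_error(compute_f(-1, 1), "positive")
  expect_error(compute_f(1, 0), "positive")
})

test_that("parameter validation enforces positivity and volume ordering", {
  p <- make_toy_pbpk_params()
  expect_s3_class(p, "pbpk_parameters")
  expect_true(all(p$tissues$f > 1))
  expect_equal(p$tissues$gram_weight[p$tissues$tissue == "gut"], 7.26)
  expect_equal(p$tissues$gram_weight[p$tissues$tissue == "brain"], 2)
  bad <- p$tissues; bad$V_ev[1] <- bad$V[1]
  expect_error(pbpk_parameters(bad, 1, 0), "smaller")
  bad2 <- p$tissues; bad2$Q[2] <- 0
  expect_error(pbpk_parameters(bad2, 1, 0), "positive")
})

test_that("the equilibrium point of the mass balances is stationary", {
  p <- make_toy_pbpk_params(CL_renal = 0)
  n <- nrow(p$tissues)
  # C_T = C_ART, C_EV = K_T * C_T
  st <- c(C_ART = 2e-4,
          setNames(rep(2e-4, n), paste0("C_", p$tissues$tissue)),
          setNames(2e-4 * p$tissues$K, paste0("CEV_", p$tissues$tissue)))
  d <- tissue_derivatives(st, p)
  expect_equal(max(abs(d)), 0)
})

test_that("the permeability-free limit decouples the extravascular balance", {
  p <- make_toy_pbpk_params()
  p$tissues$P[] <- 1e-300  # validation requires > 0; numerically zero
  n <- nrow(p$tissues)
  st <- c(C_ART = 1e-4,
          setNames(runif(n, 0, 1e-4), paste0("C_", p$tissues$tissue)),
          setNames(runif(n, 0, 1e-4), paste0("CEV_", p$tissues$tissue)))
  gen <- c(gut = 3e-6)
  d <- tissue_derivatives(st, p, generation = gen)
  V_ev_eff <- p$tissues$V / (1 + p$tissues$f)
  expected <- ifelse(p$tissues$tissue == "gut", 3e-6, 0) / V_ev_eff
  expect_equal(unname(d[1 + n + seq_len(n)]), expected, tolerance = 1e-12)
})

test_that("a single tissue reproduces hand-substituted derivatives", {
  tis <- tibble::tibble(tissue = "gut", Q = 2, V = 1, V_ev = 0.8,
                        P = 3, S_area = 1.5, K = 2, gram_weight = 7.26)
  p <- pbpk_parameters(tis, V_blood = 0.5, CL_renal = 0.7)
  st <- c(C_ART = 4, C_gut = 1, CEV_gut = 3)
  d <- tissue_derivatives(st, p, generation = c(gut = 0.25),
                          consumption = c(gut = 0.05))
  f <- 1 / 0.8
  PS <- 3 * 1.5
  expect_equal(d[["C_gut"]], (2 * (4 - 1) + PS * (3 / 2 - 1)) / (f * 1 / (1 + f)))
  expect_equal(d[["CEV_gut"]], (PS * (1 - 3 / 2) + 0.25 - 0.05) / (1 / (1 + f)))
  expect_equal(d[["C_ART"]], (2 * 1 - 2 * 4 - 0.7 * 4) / 0.5)
  expect_error(tissue_derivatives(st[1:2], p), "state length")
})

test_that("mass is conserved and the mixed state is attracting without clearance", {
  p <- make_toy_pbpk_params(CL_renal = 0)
  n <- nrow(p$tissues)
  st0 <- c(C_ART = 3e-4,
           setNames(seq(1e-4, 2e-4, length.out = n), paste0("C_", p$tissues$tissue)),
           setNames(rep(0.5e-4, n), paste0("CEV_", p$tissues$tissue)))
  traj <- simulate_pbpk(p, list(h2o2 = st0), duration = 6, step = 0.25)
  expect_equal(nrow(dplyr::distinct(traj, time)), 25)  # 24 intervals

  amount_at <- function(tt) {
    d <- dplyr::filter(traj, .data$time == tt)
    art <- d$concentration[d$pool == "blood"]
    vasc <- d[d$pool == "vascular", ]
    ev <- d[d$pool == "extravascular", ]
    cv <- vasc$concentration[match(p$tissues$tissue, vasc$compartment)]
    ce <- ev$concentration[match(p$tissues$tissue, ev$compartment)]
    total_amount(c(art, cv, ce), p)
  }
  a0 <- amount_at(0); a6 <- amount_at(6)
  expect_equal(a6, a0, tolerance = 1e-8)

  # with K = 1 all compartments approach the common mixed concentration
  final <- dplyr::filter(traj, .data$time == 6)
  mixed <- a0 / (p$V_blood + sum(p$tissues$V))
  expect_equal(max(abs(final$concentration - mixed)) / mixed, 0,
               tolerance = 1e-3)
})

test_that("concentrations stay nonnegative and the grid has the right shape", {
  p <- make_toy_pbpk_params()
  # a constant drain large enough to undershoot: values are clipped at 0,
  # with a warning
  w <- testthat::capture_warnings(
    traj <- simulate_pbpk(p, 1e-4, duration = 6, step = 0.25,
                          consumption = list(h2o2 = c(gut = 1e-5),
                                             o2s = c(gut = 1e-5))))
  expect_true(length(w) > 0 && all(grepl("clipped", w)))
  expect_true(all(traj$concentration >= 0))
  expect_equal(nrow(dplyr::distinct(traj, .data$time)), 25)
  expect_setequal(unique(traj$species), c("h2o2", "o2s"))
})

test_that("generation with clearance rises to a plateau; halving the step converges", {
  p <- make_toy_pbpk_params(CL_renal = 0.02)
  gen <- list(h2o2 = c(gut = 3e-6))
  tr <- simulate_pbpk(p, 1e-4, duration = 6, step = 0.25, species = "h2o2",
                      generation = gen)
  gut <- dplyr::filter(tr, .data$compartment == "gut",
                       .data$pool == "extravascular")
  inc <- diff(gut$concentration)
  expect_true(all(inc > 0))
  expect_lt(inc[length(inc)], inc[1])  # saturating rise

  # output-grid refinement leaves the adaptive-integrator endpoint unchanged
  tr2 <- simulate_pbpk(p, 1e-4, duration = 6, step = 0.125, species = "h2o2",
                       generation = gen)
  end1 <- dplyr::filter(tr, .data$time == 6)
  end2 <- dplyr::filter(tr2, .data$time == 6)
  expect_equal(end1$concentration, end2$concentration, tolerance = 1e-6)

  # renal clearance on the kidney vascular side is the switchable variant
  pk <- pbpk_parameters(p$tissues, p$V_blood, 0.02, clearance_site = "kidney")
  trk <- simulate_pbpk(pk, 1e-4, duration = 1, step = 0.25, species = "h2o2")
  expect_lt(dplyr::filter(trk, .data$time == 1, .data$pool == "blood")$concentration,
            1e-4)
})
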