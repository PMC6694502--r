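test_that("FBA finds the bottleneck optimum and handles degenerate bounds", {
  f <- fba(chain_model(caps = c(10, 4, 10)))
  expect_equal(f$objective_value, 4, tolerance = 1e-9)
  expect_equal(unname(f$fluxes), rep(4, 3), tolerance = 1e-9)

  m0 <- chain_model(caps = c(0, 0, 0))
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-12)

  # branched toy against an independently formulated LP
  m <- branched_model()
  expect_equal(fba(m)$objective_value, oracle_fba_split(m), tolerance = 1e-9)
  expect_equal(fba(m)$objective_value, 7, tolerance = 1e-9)  # min(10, 6+3, 7)
})

test_that("pFBA zeroes futile cycles and picks the shortest route", {
  p <- pfba(futile_cycle_model())
  expect_equal(p$objective_value, 10, tolerance = 1e-9)
  expect_equal(p$fluxes[["cyc1"]], 0, tolerance = 1e-9)
  expect_equal(p$fluxes[["cyc2"]], 0, tolerance = 1e-9)

  # one-step route vs two-step route with equal capacity: all flux direct
  m <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 5),
    list(id = "direct", mets = c(A = -1, B = 1), lb = 0, ub = 5),
    list(id = "via1", mets = c(A = -1, Cc = 1), lb = 0, ub = 5),
    list(id = "via2", mets = c(Cc = -1, B = 1), lb = 0, ub = 5),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 5)), objective = "out")
  p2 <- pfba(m)
  expect_equal(p2$fluxes[["direct"]], 5, tolerance = 1e-9)
  expect_equal(p2$fluxes[["via1"]], 0, tolerance = 1e-9)

  # unique optimum: pFBA equals FBA
  mc <- chain_model(caps = c(10, 4, 10))
  expect_equal(pfba(mc)$fluxes, fba(mc)$fluxes, tolerance = 1e-9)

  # total absolute flux never exceeds the plain FBA solution's
  expect_lte(pfba(m)$total_flux, sum(abs(fba(m)$fluxes)) + 1e-9)
})

test_that("GIMME reproduces the hand-solved chain and its degenerate cases", {
  m <- chain_model(caps = c(10, 10, 10), gpr_mid = "gm")
  cfg <- integration_config(gimme_threshold_mode = "absolute", gimme_threshold_value = 5)
  sc <- reaction_scores(m, expression_profile(c(gm = 2)), cfg)
  g <- gimme(m, sc, cfg)
  # flux 9 through the chain, penalty (5 - 2) * 9 = 27
  expect_equal(g$inconsistency, 27, tolerance = 1e-6)
  expect_equal(g$fluxes[["r_mid"]], 9, tolerance = 1e-6)
  expect_true(all(g$activity))

  # every score at or above threshold: no penalty, a valid FBA-optimal flux
  sc_hi <- reaction_scores(m, expression_profile(c(gm = 7)), cfg)
  g2 <- gimme(m, sc_hi, cfg)
  expect_equal(g2$inconsistency, 0, tolerance = 1e-12)
  expect_gte(g2$fluxes[[m$objective]], 0.9 * 10 - 1e-6)

  # mean + SD of constant scores {2,2,2} is 2: nothing falls below
  m3 <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "s1", mets = c(A = -1, B = 1), lb = 0, ub = 10, gpr = "x1"),
    list(id = "s2", mets = c(B = -1, Cc = 1), lb = 0, ub = 10, gpr = "x2"),
    list(id = "s3", mets = c(Cc = -1, D = 1), lb = 0, ub = 10, gpr = "x3"),
    list(id = "out", mets = c(D = -1), lb = 0, ub = 10)), objective = "out")
  cfg_sd <- integration_config()   # mean_plus_sd default
  sc3 <- reaction_scores(m3, expression_profile(c(x1 = 2, x2 = 2, x3 = 2)), cfg_sd)
  g3 <- gimme(m3, sc3, cfg_sd)
  expect_equal(g3$threshold, 2)
  expect_equal(g3$inconsistency, 0, tolerance = 1e-9)

  # a zero-capacity network has a zero optimum, hence a trivially met RMF
  m4 <- set_bounds(m, "r_up", upper = 0)
  g4 <- gimme(m4, sc, cfg)
  expect_equal(g4$inconsistency, 0, tolerance = 1e-12)
  expect_true(all(abs(g4$fluxes) < 1e-9))
})

test_that("iMAT activates the high route and silences the low isozyme", {
  # two isozyme routes A -> B; high one must carry flux, low one none
  m <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "hi", mets = c(A = -1, B = 1), lb = 0, ub = 10, gpr = "gh"),
    list(id = "lo", mets = c(A = -1, B = 1), lb = 0, ub = 10, gpr = "gl"),
    list(id = "mid", mets = c(A = -1, Cc = 1), lb = 0, ub = 10, gpr = "gm"),
    list(id = "exC", mets = c(Cc = -1), lb = 0, ub = 10),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 10)), objective = "out")
  cfg <- integration_config()
  sc <- reaction_scores(m, expression_profile(c(gh = 10, gl = 1, gm = 5)), cfg)
  res <- imat(m, sc, cfg)
  expect_identical(unname(res$status[c("hi", "lo", "mid")]),
                   c("high", "low", "moderate"))
  expect_equal(res$objective, 2)
  expect_true(res$activity[["hi"]])
  expect_false(res$activity[["lo"]])
  expect_gte(abs(res$fluxes[["hi"]]), cfg$flux_epsilon - 1e-9)

  # all moderate: zero reward, any feasible flux (witness is all-zero here)
  sc_flat <- reaction_scores(m, expression_profile(c(gh = 5, gl = 5, gm = 5)), cfg)
  res2 <- imat(m, sc_flat, cfg)
  expect_equal(res2$objective, 0)

  # MILP optimum equals exhaustive enumeration on small seeded toys
  for (seed in c(11, 12, 13)) {
    spec <- fixture_spec(seed = seed, n_chains = 2L, chain_length = 2L, n_branches = 0L)
    tm <- generate_toy_model(spec)
    planted <- c("EX_A_in", grep("^R_c1_", tm$reactions$id, value = TRUE), "EX_c1_out")
    pe <- generate_expression(tm, planted, spec)
    sct <- reaction_scores(tm, pe$control, cfg)
    rt <- imat(tm, sct, cfg)
    expect_equal(rt$objective,
                 oracle_imat_enum(tm, rt$status, cfg$flux_epsilon))
  }
})

test_that("bound rescaling follows the control flux and the expression ratio", {
  m <- metabolic_model(list(
    list(id = "r1", mets = c(A = 1), lb = 0, ub = 8),
    list(id = "r2", mets = c(A = -1, B = 1), lb = 0, ub = 10, gpr = "g"),
    list(id = "r3", mets = c(B = -1), lb = 0, ub = 10)), objective = "r3")
  cfg <- integration_config()

  # ratios of 1 collapse the interval onto the control flux
  sc1 <- reaction_scores(m, expression_profile(c(g = 1)), cfg)
  gv1 <- goncalves(m, sc1, cfg)
  expect_equal(gv1$treated_fluxes, gv1$control_fluxes, tolerance = 1e-9)

  # halving expression on the bottleneck halves the treated flux
  sc05 <- reaction_scores(m, expression_profile(c(g = 0.5)), cfg)
  gv05 <- goncalves(m, sc05, cfg)
  expect_equal(gv05$control_fluxes[["r2"]], 8, tolerance = 1e-9)
  expect_equal(gv05$treated_fluxes[["r2"]], 4, tolerance = 1e-9)

  # doubling expression on a reaction already at capacity changes nothing
  m_cap <- metabolic_model(list(
    list(id = "r1", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "r2", mets = c(A = -1, B = 1), lb = 0, ub = 8, gpr = "g"),
    list(id = "r3", mets = c(B = -1), lb = 0, ub = 10)), objective = "r3")
  sc2 <- reaction_scores(m_cap, expression_profile(c(g = 2)), cfg)
  gv2 <- goncalves(m_cap, sc2, cfg)
  expect_equal(gv2$treated_fluxes[["r2"]], 8, tolerance = 1e-9)
})

test_that("MADE realizes achievable transitions and reports their weight", {
  cfg <- integration_config()
  # an optional gated reaction with one significantly up gene
  m <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "robj", mets = c(A = -1, B = 1), lb = 0, ub = 10),
    list(id = "rg", mets = c(A = -1, Cc = 1), lb = 0, ub = 10, gpr = "gg"),
    list(id = "exC", mets = c(Cc = -1), lb = 0, ub = 10),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 10)), objective = "out")
  profs <- list(
    control = expression_profile(c(gg = 2), condition = "control"),
    treated = expression_profile(c(gg = 8), p_value = c(gg = 0.01),
                                 log_fc = c(gg = 2), condition = "treated"))
  res <- made(m, profs, cfg)
  expect_equal(res$objective, 0.99, tolerance = 1e-9)
  expect_false(res$control_activity[["rg"]])
  expect_true(res$treated_activity[["rg"]])

  # identical profiles: identical states under the deterministic tie-break
  profs_same <- list(
    control = profs$control,
    treated = expression_profile(c(gg = 2), p_value = c(gg = 1),
                                 log_fc = c(gg = 0), condition = "treated"))
  res2 <- made(m, profs_same, cfg)
  expect_true(all(res2$control_activity == res2$treated_activity))

  # a desired shutdown of an RMF-essential reaction stays unmatched
  m3 <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "robj", mets = c(A = -1, B = 1), lb = 0, ub = 10, gpr = "gg"),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 10)), objective = "out")
  profs_down <- list(
    control = expression_profile(c(gg = 8), condition = "control"),
    treated = expression_profile(c(gg = 2), p_value = c(gg = 0.01),
                                 log_fc = c(gg = -2), condition = "treated"))
  res3 <- made(m3, profs_down, cfg)
  expect_equal(res3$objective, 0, tolerance = 1e-9)
  expect_true(res3$control_activity[["robj"]])
  expect_true(res3$treated_activity[["robj"]])
})

test_that("activity classification uses flux magnitude in either direction", {
  cfg <- integration_config()
  v <- c(r1 = 0, r2 = -2, r3 = 1e-9, r4 = 2)
  st <- classify_activity(v, cfg)
  expect_identical(unname(state_vec(st)), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("methods are deterministic and mode-degenerate at unit copies", {
  spec <- fixture_spec(seed = 21, n_chains = 2L, chain_length = 2L,
                       n_branches = 1L, n_complexes = 0L)
  tm <- generate_toy_model(spec)
  planted <- c("EX_A_in", grep("^R_c1_", tm$reactions$id, value = TRUE), "EX_c1_out")
  pe <- generate_expression(tm, planted, spec)
  for (mode in c("GPR", "SGPR")) assign(paste0("cfg_", mode), {
    cfg <- integration_config(); cfg$gpr_mode <- mode; cfg
  })
  sg <- reaction_scores(tm, pe$control, cfg_GPR)
  ss <- reaction_scores(tm, pe$control, cfg_SGPR)
  expect_equal(sg$score, ss$score)   # all copy numbers are 1

  r1 <- imat(tm, sg, cfg_GPR); r2 <- imat(tm, ss, cfg_SGPR)
  expect_identical(state_vec(r1$activity), state_vec(r2$activity))
  g1 <- gimme(tm, sg, cfg_GPR); g2 <- gimme(tm, ss, cfg_SGPR)
  expect_equal(g1$inconsistency, g2$inconsistency)

  # bit-identical reruns
  r1b <- imat(tm, sg, cfg_GPR)
  expect_identical(r1$fluxes, r1b$fluxes)
  g1b <- gimme(tm, sg, cfg_GPR)
  expect_identical(g1$fluxes, g1b$fluxes)
})
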