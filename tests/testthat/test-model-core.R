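test_that("model construction validates ids, bounds and stoichiometry", {
  expect_error(metabolic_model(list(
    list(id = "r", mets = c(A = 1)), list(id = "r", mets = c(A = -1))),
    objective = "r"), "duplicate")
  expect_error(metabolic_model(list(list(id = "r", mets = c(A = 1))),
                               objective = "nope"), "objective")
  expect_error(metabolic_model(list(list(id = "r", mets = c(A = 1), lb = 5, ub = 1)),
                               objective = "r"), "bound")
  m <- chain_model()
  expect_s3_class(validate_model(m), "metabolic_model")
  expect_true(m$reactions$is_exchange[m$reactions$id == "r_up"])
  expect_false(m$reactions$is_exchange[m$reactions$id == "r_mid"])
})

test_that("exchange augmentation adds only the missing directions", {
  m <- chain_model()
  # B has no secretion exchange of its own beyond r_out... r_out is one; A has r_up only
  res <- add_exchange_reactions(m, "A")
  expect_equal(res$n_added, 1L)    # uptake exists, only secretion added
  expect_true("EX_A_out" %in% res$model$reactions$id)

  # a metabolite with no exchange at all gains both directions
  m2 <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "ab", mets = c(A = -1, B = 1), lb = 0, ub = 10),
    list(id = "bc", mets = c(B = -1, Cc = 1), lb = 0, ub = 10),
    list(id = "out", mets = c(Cc = -1), lb = 0, ub = 10)), objective = "out")
  res2 <- add_exchange_reactions(m2, "B")
  expect_equal(res2$n_added, 2L)

  # an existing reversible exchange covers both directions
  m3 <- metabolic_model(list(
    list(id = "exY", mets = c(Y = 1), lb = -10, ub = 10),
    list(id = "yz", mets = c(Y = -1, Z = 1), lb = 0, ub = 10),
    list(id = "exZ", mets = c(Z = -1), lb = 0, ub = 10)), objective = "exZ")
  expect_equal(add_exchange_reactions(m3, "Y")$n_added, 0L)

  expect_equal(add_exchange_reactions(m, character())$n_added, 0L)
  expect_error(add_exchange_reactions(m, "nope"), "unknown metabolite")
})

test_that("exchange augmentation leaves untouched exchanges' FVA ranges alone", {
  # r_up is A's uptake; augmenting B's exchanges must not move its range
  m <- chain_model(caps = c(8, 10, 10))
  before <- flux_variability(m, reactions = "r_up")
  res <- add_exchange_reactions(m, "B")
  after <- flux_variability(res$model, reactions = "r_up")
  expect_equal(before$max, after$max, tolerance = 1e-8)
  expect_equal(before$min, after$min, tolerance = 1e-8)
})

test_that("FVA ranges match hand-solved chains and detect dead ends", {
  m <- chain_model(caps = c(10, 10, 10))
  rng <- flux_variability(m)
  expect_equal(rng$min, rep(0, 3), tolerance = 1e-9)
  expect_equal(rng$max, rep(10, 3), tolerance = 1e-9)

  # a reaction producing something nothing consumes is pinned at zero
  m2 <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "ab", mets = c(A = -1, B = 1), lb = 0, ub = 10),
    list(id = "ad", mets = c(A = -1, D = 1), lb = 0, ub = 10),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 10)), objective = "out")
  rng2 <- flux_variability(m2, reactions = "ad")
  expect_equal(c(rng2$min, rng2$max), c(0, 0), tolerance = 1e-9)

  # forced flux beyond what the network can produce is infeasible
  m3 <- set_bounds(m2, "ad", lower = 5, upper = 5)
  m3 <- set_bounds(m3, "up", upper = 0)
  expect_error(flux_variability(m3), "infeasible")
})

test_that("pruning removes blocked reactions, tightens reversibles, drops dead ends", {
  m <- metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "ab", mets = c(A = -1, B = 1), lb = -10, ub = 10),
    list(id = "ad", mets = c(A = -1, D = 1), lb = 0, ub = 10),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 10)), objective = "out")
  pr <- prune_model(m)
  expect_identical(pr$report$removed_reactions, "ad")
  expect_identical(pr$report$removed_metabolites, "D")
  expect_identical(pr$report$tightened_reactions, "ab")
  i <- match("ab", pr$model$reactions$id)
  expect_equal(pr$model$reactions$lower_bound[i], 0)

  # fully coupled chain: nothing to do
  pr2 <- prune_model(chain_model())
  expect_length(pr2$report$removed_reactions, 0)
  expect_length(pr2$report$tightened_reactions, 0)

  # a blocked objective is an error
  m4 <- set_bounds(m, "up", upper = 0)
  expect_error(prune_model(m4), "objective")
})

test_that("pruning preserves retained FVA ranges and is idempotent", {
  for (seed in 1:4) {
    m <- toy_with_prunable_parts(seed)
    before <- flux_variability(m)
    pr <- prune_model(m)
    expect_gt(length(pr$report$removed_reactions) +
              length(pr$report$tightened_reactions), 0)
    after <- flux_variability(pr$model)
    keep <- match(after$id, before$id)
    expect_equal(after$min, before$min[keep], tolerance = 1e-6)
    expect_equal(after$max, before$max[keep], tolerance = 1e-6)
    pr2 <- prune_model(pr$model)
    expect_length(pr2$report$removed_reactions, 0)
    expect_length(pr2$report$tightened_reactions, 0)
    expect_length(pr2$report$removed_metabolites, 0)
  }
})

test_that("the JSON dialect round-trips losslessly", {
  m <- generate_discriminating_case()$model
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$reactions, m$reactions)
  expect_identical(m2$metabolites, m$metabolites)
  expect_identical(m2$objective, m$objective)
  expect_equal(as.matrix(m2$stoich), as.matrix(m$stoich))
  expect_error(read_model(file.path(tempdir(), "does_not_exist.json")), "no such file")
})

test_that("the SBML subset round-trips bounds, rules and pathways", {
  m <- generate_discriminating_case()$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path, format = "sbml")
  m2 <- read_model(path)
  expect_identical(m2$reactions$gpr, m$reactions$gpr)
  expect_identical(m2$reactions$pathway, m$reactions$pathway)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_identical(m2$objective, m$objective)
})

test_that("SBML without the sgpr annotation falls back to the fbc association", {
  m <- generate_discriminating_case()$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path, format = "sbml")
  doc <- xml2::read_xml(path)
  ann <- xml2::xml_find_all(doc, "//*[local-name() = 'sgpr']")
  xml2::xml_remove(ann)
  xml2::write_xml(doc, path)
  m2 <- read_model(path)
  gated <- m2$reactions$gpr[m2$reactions$id == "R_gated"]
  expect_identical(gated, "g1 and g2")   # coefficients are lost without the annotation
})
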