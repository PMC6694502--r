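test_that("Mann-Whitney calls are exact at desk scale", {
  # identical samples: no evidence of change
  expect_equal(mann_whitney_p(c(5, 5, 5), c(5, 5, 5)), 1)
  # fully separated 3 vs 3: exact two-sided p is 2/20
  expect_equal(mann_whitney_p(c(1, 2, 3), c(10, 11, 12)), 0.1, tolerance = 1e-12)

  # implementation equals full permutation enumeration, with and without ties
  set.seed(31)
  for (i in 1:12) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- round(stats::runif(n, 0, 10), 1)
    y <- round(stats::runif(m, 0, 10), 1)
    expect_equal(mann_whitney_p(x, y), oracle_mw_p(x, y), tolerance = 1e-12)
    x2 <- sample(1:3, n, replace = TRUE)   # heavy ties
    y2 <- sample(2:4, m, replace = TRUE)
    expect_equal(mann_whitney_p(x2, y2), oracle_mw_p(x2, y2), tolerance = 1e-12)
  }
})

test_that("exchange calls follow significance and median direction", {
  meas <- rbind(
    data.frame(metabolite_id = "down", timepoint = rep(c("t0", "t5"), each = 4),
               area = c(10, 11, 12, 13, 1, 2, 3, 4)),
    data.frame(metabolite_id = "up", timepoint = rep(c("t0", "t5"), each = 4),
               area = c(1, 2, 3, 4, 10, 11, 12, 13)),
    data.frame(metabolite_id = "flat", timepoint = rep(c("t0", "t5"), each = 3),
               area = c(5, 6, 7, 6, 5, 7)),
    data.frame(metabolite_id = "thin", timepoint = c("t0", "t5", "t5"),
               area = c(5, 6, 7)))
  calls <- call_exchanges(meas, alpha = 0.05)
  get <- function(m, f) calls[[f]][calls$metabolite_id == m]
  expect_identical(get("down", "call"), "consumed")
  expect_identical(get("up", "call"), "produced")
  expect_identical(get("flat", "call"), "unchanged")
  expect_identical(get("thin", "call"), "untestable")
  # 3 vs 3 separated data cannot reach 0.05: stays unchanged
  meas33 <- data.frame(metabolite_id = "m", timepoint = rep(c("t0", "t5"), each = 3),
                       area = c(1, 2, 3, 10, 11, 12))
  expect_identical(call_exchanges(meas33)$call, "unchanged")
})

test_that("Fisher p and right proportion match closed forms", {
  # the [[3,1],[1,3]] table: two-sided p = 34/70
  expect_equal(oracle_fisher_p(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(stats::fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value,
               34 / 70, tolerance = 1e-12)

  # comparison built from synthetic calls reproducing that table
  mk_inputs <- function(a, b, c_, d) {
    n <- a + b + c_ + d
    mets <- paste0("m", seq_len(n))
    pred <- c(rep(TRUE, a + b), rep(FALSE, c_ + d))
    measured <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c_), rep(FALSE, d))
    calls <- data.frame(metabolite_id = mets,
                        p_value = ifelse(measured, 0.01, 0.5),
                        call = ifelse(measured, "consumed", "unchanged"),
                        stringsAsFactors = FALSE)
    act <- classify_activity(stats::setNames(as.numeric(pred), paste0("EX_", mets)), 1e-6)
    map <- data.frame(metabolite_id = mets, reaction_id = paste0("EX_", mets))
    list(act = act, calls = calls, map = map)
  }
  inp <- mk_inputs(3, 1, 1, 3)
  cmp <- compare_predictions(inp$act, inp$calls, inp$map)
  expect_equal(unname(as.vector(t(cmp$table))), c(3, 1, 1, 3))
  expect_equal(cmp$fisher_p, 34 / 70, tolerance = 1e-12)
  expect_equal(cmp$right_proportion, 6 / 8)

  # perfect agreement and degenerate margins
  perf <- mk_inputs(4, 0, 0, 4)
  expect_equal(compare_predictions(perf$act, perf$calls, perf$map)$right_proportion, 1)
  dg <- mk_inputs(0, 0, 0, 4)
  cmp_dg <- compare_predictions(dg$act, dg$calls, dg$map)
  expect_equal(cmp_dg$right_proportion, 1)
  expect_equal(cmp_dg$fisher_p, 1)

  # invariance to metabolite ordering
  sh <- mk_inputs(3, 1, 1, 3)
  ord <- sample(nrow(sh$calls))
  cmp_sh <- compare_predictions(sh$act, sh$calls[ord, ], sh$map)
  expect_equal(cmp_sh$right_proportion, cmp$right_proportion)
  expect_equal(cmp_sh$fisher_p, cmp$fisher_p)

  expect_error(compare_predictions(inp$act, inp$calls[0, ], inp$map), "no evaluable")
})

test_that("improvement is the percentage-point gain in right predictions", {
  inp <- local({
    mk <- function(right) {
      n <- 29
      structure(list(right_proportion = right / n,
                     detail = data.frame(metabolite_id = paste0("m", 1:n))),
                class = "comparison_result")
    }
    list(g = mk(23), s = mk(25))
  })
  expect_equal(as.numeric(improvement(inp$g, inp$s)), 100 * 2 / 29, tolerance = 1e-9)
  expect_equal(as.numeric(improvement(inp$g, inp$g)), 0)
  # a worse S-GPR run keeps its negative sign
  mk20 <- function(right) structure(list(right_proportion = right / 20,
    detail = data.frame(metabolite_id = paste0("m", 1:20))), class = "comparison_result")
  expect_equal(as.numeric(improvement(mk20(15), mk20(14))), -5)
  bad <- structure(list(right_proportion = 1,
    detail = data.frame(metabolite_id = "other")), class = "comparison_result")
  expect_error(improvement(inp$g, bad), "different metabolite sets")
})

test_that("activity differences are reported as percent of reactions", {
  a <- classify_activity(stats::setNames(rep(1, 100), paste0("r", 1:100)), 1e-6)
  b <- a; b[1:2] <- FALSE
  expect_equal(activity_difference(a, a), 0)
  expect_equal(activity_difference(a, b), 2)
  flip <- classify_activity(stats::setNames(rep(0, 100), paste0("r", 1:100)), 1e-6)
  expect_equal(activity_difference(a, flip), 100)
  expect_error(activity_difference(a, flip[1:50]), "different reaction sets")
})

test_that("pathway report counts, weights, exclusivity and significance", {
  rxns <- paste0("r", 1:24)
  pw <- stats::setNames(rep(c("P1", "P2", "P3"), each = 8), rxns)
  ctrl <- classify_activity(stats::setNames(
    c(rep(1, 4), rep(0, 4),   # P1: 4 active
      rep(1, 4), rep(0, 4),   # P2: 4 active
      rep(0, 8)),             # P3: none
    rxns), 1e-6)
  trt <- classify_activity(stats::setNames(
    c(rep(1, 6), rep(0, 2),   # P1: 6 active
      rep(1, 4), rep(0, 4),   # P2: equal
      rep(1, 3), rep(0, 5)),  # P3: exclusive
    rxns), 1e-6)
  rep_ <- pathway_overactivation(list(control = ctrl, treated = trt), pw)
  p1 <- rep_[rep_$pathway == "P1", ]
  expect_equal(p1$relative_weight, 1.5)
  expect_false(p1$exclusive)
  expect_equal(rep_[rep_$pathway == "P2", ]$relative_weight, 1)
  p3 <- rep_[rep_$pathway == "P3", ]
  expect_true(p3$exclusive)
  expect_true(is.na(p3$relative_weight))
  expect_true(all(rep_$p_value >= 0 | is.na(rep_$p_value)))
})
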