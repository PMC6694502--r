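# Shared in-code fixtures: tiny hand-built networks and random rule trees.

chain_model <- function(caps = c(10, 10, 10), gpr_mid = NULL) {
  metabolic_model(list(
    list(id = "r_up", mets = c(A = 1), lb = 0, ub = caps[1]),
    list(id = "r_mid", mets = c(A = -1, B = 1), lb = 0, ub = caps[2], gpr = gpr_mid),
    list(id = "r_out", mets = c(B = -1), lb = 0, ub = caps[3])),
    objective = "r_out")
}

branched_model <- function() {
  # A feeds two routes to B (caps 6 and 3), B leaves through a cap-7 outlet
  metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "route1", mets = c(A = -1, B = 1), lb = 0, ub = 6),
    list(id = "route2", mets = c(A = -1, B = 1), lb = 0, ub = 3),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 7)),
    objective = "out")
}

futile_cycle_model <- function() {
  metabolic_model(list(
    list(id = "up", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "ab", mets = c(A = -1, B = 1), lb = 0, ub = 10),
    list(id = "cyc1", mets = c(B = -1, Cc = 1), lb = -10, ub = 10),
    list(id = "cyc2", mets = c(Cc = -1, B = 1), lb = -10, ub = 10),
    list(id = "out", mets = c(B = -1), lb = 0, ub = 10)),
    objective = "out")
}

# random rule tree over a gene pool; all-copies-one when unit_copies is TRUE
random_tree <- function(genes, depth = 3L, unit_copies = FALSE) {
  if (depth == 0L || stats::runif(1) < 0.4) {
    cp <- if (unit_copies) 1L else sample(1:3, 1L)
    return(gpr_gene(sample(genes, 1L), cp))
  }
  k <- sample(2:3, 1L)
  kids <- lapply(seq_len(k), function(i) random_tree(genes, depth - 1L, unit_copies))
  if (stats::runif(1) < 0.5) do.call(gpr_and, kids) else do.call(gpr_or, kids)
}

random_profile <- function(genes, missing_frac = 0) {
  keep <- genes[stats::runif(length(genes)) >= missing_frac]
  stats::setNames(stats::runif(length(keep), 0, 20), keep)
}

# a generated toy plus a deliberately prunable appendage (dead-end branch
# and a reversible reaction whose backward direction is blocked)
toy_with_prunable_parts <- function(seed) {
  m <- generate_toy_model(fixture_spec(seed = seed, n_chains = 2L, chain_length = 2L,
                                       n_branches = 1L))
  m <- append_to_model(m, list(id = "R_deadend", mets = c(A = -1, DEAD = 1), lb = 0, ub = 10))
  # NEW is only made by R_rev and only drained by its secretion, so the
  # backward direction of R_rev can never carry flux at steady state
  m <- append_to_model(m, list(id = "R_rev", mets = c(C1M1 = -1, NEW = 1),
                               lb = -10, ub = 10))
  m <- append_to_model(m, list(id = "EX_NEW_out", mets = c(NEW = -1), lb = 0, ub = 10))
  m
}

append_to_model <- function(model, r) sgpr:::append_reaction(model, r)

# activity state as a bare named logical (drops class and label attributes)
state_vec <- function(s) stats::setNames(as.logical(s), names(s))
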