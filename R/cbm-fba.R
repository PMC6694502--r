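#' Settings for transcriptomic integration methods
#'
#' Extends [gpr_config()] with the thresholds and tolerances of the four
#' integration algorithms. `activity_epsilon` is the minimal flux magnitude
#' counted as active when classifying; `flux_epsilon` is the larger
#' flux-forcing epsilon used inside the iMAT and MADE MILPs (original iMAT
#' convention, default 1.0). GIMME's expression threshold defaults to the
#' mean plus one standard deviation of the defined reaction scores; iMAT's
#' low/high cutoffs default to the 40th and 60th percentiles. `rmf_fraction`
#' is the fraction of the flux-balance optimum the required metabolic
#' functionality (objective flux) must retain in GIMME and MADE.
#'
#' @inheritParams gpr_config
#' @param activity_epsilon flux magnitude below which a reaction is inactive
#' @param flux_epsilon flux magnitude the MILPs force through an "on" reaction
#' @param gimme_threshold_mode `"mean_plus_sd"`, `"percentile"` or `"absolute"`
#' @param gimme_threshold_value percentile (in \[0,1\]) or absolute threshold,
#'   per mode
#' @param rmf_fraction required fraction of the objective optimum, in (0, 1\]
#' @param imat_quantiles length-2 vector, lower and upper score quantiles
#' @param made_alpha significance level for desired activity transitions
#' @return object of class `c("integration_config", "gpr_config")`
#' @export
integration_config <- function(or_mode = c("mean", "max"),
                               gpr_mode = c("GPR", "SGPR"),
                               missing_gene_policy = c("skip", "constant"),
                               missing_value = 0,
                               activity_epsilon = 1e-6,
                               flux_epsilon = 1.0,
                               gimme_threshold_mode = c("mean_plus_sd", "percentile", "absolute"),
                               gimme_threshold_value = NULL,
                               rmf_fraction = 0.9,
                               imat_quantiles = c(0.40, 0.60),
                               made_alpha = 0.05) {
  cfg <- gpr_config(or_mode, gpr_mode, missing_gene_policy, missing_value)
  stopifnot(length(imat_quantiles) == 2L, imat_quantiles[1] < imat_quantiles[2],
            all(imat_quantiles >= 0 & imat_quantiles <= 1),
            rmf_fraction > 0, rmf_fraction <= 1,
            activity_epsilon > 0, flux_epsilon > 0)
  cfg$activity_epsilon <- activity_epsilon
  cfg$flux_epsilon <- flux_epsilon
  cfg$gimme_threshold_mode <- match.arg(gimme_threshold_mode)
  cfg$gimme_threshold_value <- gimme_threshold_value
  cfg$rmf_fraction <- rmf_fraction
  cfg$imat_quantiles <- imat_quantiles
  cfg$made_alpha <- made_alpha
  class(cfg) <- c("integration_config", "gpr_config")
  cfg
}

#' Reaction scores from an expression profile
#'
#' Evaluates every reaction's rule tree against the profile, in GPR or S-GPR
#' mode per the configuration. Only reactions carrying a rule receive a
#' score; a score is `NA` when all the rule's genes are missing under the
#' skip policy.
#'
#' @param model a [metabolic_model]
#' @param profile an [expression_profile]
#' @param config a [gpr_config] or [integration_config]
#' @return data.frame with columns `reaction_id`, `score`; attributes
#'   `provenance` (`"GPR"`/`"SGPR"`) and `condition`
#' @export
reaction_scores <- function(model, profile, config = integration_config()) {
  trees <- model_gpr_trees(model)
  has <- !vapply(trees, is.null, logical(1L))
  score <- vapply(trees[has], evaluate_gpr, numeric(1L),
                  profile = profile, config = config)
  out <- data.frame(reaction_id = names(trees)[has], score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- config$gpr_mode
  attr(out, "condition") <- if (inherits(profile, "expression_profile"))
    profile$condition else NA_character_
  out
}

score_vector <- function(model, scores) {
  s <- rep(NA_real_, nrow(model$reactions))
  names(s) <- model$reactions$id
  i <- match(scores$reaction_id, names(s))
  if (anyNA(i)) stop("scores refer to unknown reactions: ",
                     paste(scores$reaction_id[is.na(i)], collapse = ", "))
  s[i] <- scores$score
  s
}

## ---- flux balance analysis -------------------------------------------------

#' Flux balance analysis
#'
#' Maximizes flux through the objective reaction subject to steady state
#' (`S v = 0`) and the flux bounds.
#'
#' @param model a [metabolic_model]
#' @param objective objective reaction id (default: the model's)
#' @return list with `objective_value` and `fluxes` (named vector)
#' @export
fba <- function(model, objective = model$objective) {
  i <- reaction_index(model, objective)
  n <- nrow(model$reactions)
  obj <- numeric(n); obj[i] <- 1
  res <- solve_lp(obj, as.matrix(model$stoich),
                  rep("=", nrow(model$stoich)), numeric(nrow(model$stoich)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  maximize = TRUE)
  if (res$status != "optimal") stop("FBA failed: model ", res$status)
  list(objective_value = res$objval,
       fluxes = stats::setNames(res$solution, model$reactions$id))
}

# Split-variable (p, q >= 0, v = p - q) steady-state problem skeleton.
# Returns the base constraint blocks over x = [p; q] plus bounds.
pq_base <- function(model) {
  n <- nrow(model$reactions)
  S <- as.matrix(model$stoich)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  mat <- cbind(S, -S)
  dir <- rep("=", nrow(S)); rhs <- numeric(nrow(S))
  # bounds not representable as boxes on p/q: forced-positive or forced-negative flux
  forced <- which(lb > 0 | ub < 0)
  for (i in forced) {
    row <- numeric(2 * n); row[i] <- 1; row[n + i] <- -1
    if (lb[i] > 0) { mat <- rbind(mat, row); dir <- c(dir, ">="); rhs <- c(rhs, lb[i]) }
    if (ub[i] < 0) { mat <- rbind(mat, row); dir <- c(dir, "<="); rhs <- c(rhs, ub[i]) }
  }
  list(n = n, mat = mat, dir = dir, rhs = rhs,
       lower = rep(0, 2 * n),
       upper = c(pmax(ub, 0), pmax(-lb, 0)))
}

pq_row <- function(n, v_coef) c(v_coef, -v_coef)

#' Parsimonious flux balance analysis
#'
#' Two-step FBA: the objective flux is fixed at its optimum, then the total
#' absolute flux is minimized, which removes futile cycles and picks the
#' shortest of otherwise equivalent routes.
#'
#' @inheritParams fba
#' @return list with `objective_value` (the FBA optimum), `total_flux` (the
#'   minimized L1 norm) and `fluxes`
#' @export
pfba <- function(model, objective = model$objective) {
  opt <- fba(model, objective)$objective_value
  base <- pq_base(model)
  n <- base$n
  oi <- reaction_index(model, objective)
  orow <- numeric(n); orow[oi] <- 1
  mat <- rbind(base$mat, pq_row(n, orow))
  dir <- c(base$dir, ">="); rhs <- c(base$rhs, opt - 1e-9)
  res <- solve_lp(rep(1, 2 * n), mat, dir, rhs, base$lower, base$upper)
  if (res$status != "optimal") stop("pFBA minimization failed: ", res$status)
  v <- res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
  list(objective_value = opt, total_flux = res$objval,
       fluxes = stats::setNames(v, model$reactions$id))
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux over the steady-state polytope,
#' optionally with the objective constrained to a fraction of its optimum.
#'
#' @param model a [metabolic_model]
#' @param fraction_of_optimum number in \[0, 1\], or `NULL` for the
#'   unconstrained polytope
#' @param reactions reaction ids to analyze (default all)
#' @return data.frame with columns `id`, `min`, `max`
#' @export
flux_variability <- function(model, fraction_of_optimum = NULL, reactions = NULL) {
  n <- nrow(model$reactions)
  S <- as.matrix(model$stoich)
  mat <- S; dir <- rep("=", nrow(S)); rhs <- numeric(nrow(S))
  if (!is.null(fraction_of_optimum)) {
    stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
    opt <- fba(model)$objective_value
    row <- numeric(n); row[reaction_index(model, model$objective)] <- 1
    mat <- rbind(mat, row); dir <- c(dir, ">=")
    rhs <- c(rhs, fraction_of_optimum * opt - 1e-9)
  }
  ids <- if (is.null(reactions)) model$reactions$id else reactions
  idx <- reaction_index(model, ids)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  mm <- t(vapply(idx, function(j) {
    obj <- numeric(n); obj[j] <- 1
    lo <- solve_lp(obj, mat, dir, rhs, lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, mat, dir, rhs, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA infeasible at reaction ", model$reactions$id[j])
    c(lo$objval, hi$objval)
  }, numeric(2L)))
  data.frame(id = ids, min = mm[, 1L], max = mm[, 2L], stringsAsFactors = FALSE)
}

## ---- activity states -------------------------------------------------------

#' Binary reaction activity from a flux distribution
#'
#' A reaction is active when it carries non-zero flux in either the forward
#' or the backward direction, i.e. `|v| >= activity_epsilon`.
#'
#' @param fluxes named flux vector
#' @param config an [integration_config], or a bare numeric epsilon
#' @param labels optional per-reaction input labels to attach (e.g. iMAT's
#'   high/moderate/low)
#' @param condition optional condition label
#' @return named logical vector of class `activity_state` (TRUE = active)
#' @export
classify_activity <- function(fluxes, config = integration_config(),
                              labels = NULL, condition = NA_character_) {
  eps <- if (is.numeric(config)) config else config$activity_epsilon
  st <- abs(fluxes) >= eps
  structure(st, class = "activity_state", labels = labels, condition = condition)
}

#' @export
print.activity_state <- function(x, ...) {
  cat(sprintf("<activity_state> %d reactions: %d active, %d inactive%s\n",
              length(x), sum(x), sum(!x),
              if (!is.na(attr(x, "condition")))
                paste0(" (", attr(x, "condition"), ")") else ""))
  invisible(x)
}

#' Fraction of reactions whose activity label differs between two states
#'
#' @param state_a,state_b [classify_activity()] results over the same
#'   reaction set
#' @return percentage in \[0, 100\]
#' @export
activity_difference <- function(state_a, state_b) {
  if (!setequal(names(state_a), names(state_b)))
    stop("activity states cover different reaction sets")
  b <- state_b[names(state_a)]
  100 * mean(unclass(state_a) != unclass(b))
}
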