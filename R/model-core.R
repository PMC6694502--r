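#' Constraint-based metabolic model
#'
#' A `metabolic_model` bundles metabolites, reactions with flux bounds and
#' optional pathway / EC / S-GPR annotations, the stoichiometric matrix, and
#' an objective reaction. Flux bounds are finite; infinite bounds are capped
#' at `bound_cap` (±1000 by convention). Exchange reactions are boundary
#' reactions with a single metabolite; by sign convention uptake is written
#' `∅ -> M` (positive flux imports) and secretion `M -> ∅`.
#'
#' @param reactions a list; each element is a list with fields `id`,
#'   `mets` (named numeric stoichiometry, negative = substrate), and
#'   optionally `name`, `lb`, `ub` (defaults 0 and `bound_cap`), `pathway`,
#'   `ec` (character vector of EC codes), `gpr` (S-GPR rule string or
#'   [gpr_tree])
#' @param objective id of the objective reaction
#' @param metabolite_info optional data.frame with columns `id`,
#'   `compartment` (default compartment `"c"`) and optionally `name`
#' @param compartments named character vector of compartment names
#' @param id model identifier
#' @param bound_cap cap applied to non-finite bounds
#' @return an object of class `metabolic_model`
#' @examples
#' m <- metabolic_model(list(
#'   list(id = "EX_A_in", mets = c(A = 1), ub = 10),
#'   list(id = "R1", mets = c(A = -1, B = 1), gpr = "g1 and 2*g2"),
#'   list(id = "EX_B_out", mets = c(B = -1))
#' ), objective = "EX_B_out")
#' @export
metabolic_model <- function(reactions, objective,
                            metabolite_info = NULL,
                            compartments = c(c = "cytosol"),
                            id = "model", bound_cap = 1000) {
  stopifnot(is.list(reactions), length(reactions) > 0L)
  rids <- vapply(reactions, function(r) r$id, character(1L))
  if (anyDuplicated(rids)) stop("duplicate reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))
  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$mets))))
  if (is.null(met_ids) || any(!nzchar(met_ids))) stop("reactions must name their metabolites")

  mets <- data.frame(id = met_ids,
                     name = met_ids,
                     compartment = rep(names(compartments)[1L], length(met_ids)),
                     stringsAsFactors = FALSE)
  if (!is.null(metabolite_info)) {
    stopifnot(all(c("id", "compartment") %in% names(metabolite_info)))
    idx <- match(mets$id, metabolite_info$id)
    ok <- !is.na(idx)
    mets$compartment[ok] <- metabolite_info$compartment[idx[ok]]
    if ("name" %in% names(metabolite_info)) mets$name[ok] <- metabolite_info$name[idx[ok]]
  }
  unknown_comp <- setdiff(unique(mets$compartment), names(compartments))
  if (length(unknown_comp))
    compartments <- c(compartments, stats::setNames(unknown_comp, unknown_comp))

  getf <- function(r, f, default) if (!is.null(r[[f]])) r[[f]] else default
  lb <- vapply(reactions, getf, numeric(1L), f = "lb", default = 0)
  ub <- vapply(reactions, getf, numeric(1L), f = "ub", default = bound_cap)
  lb <- pmax(lb, -bound_cap); ub <- pmin(ub, bound_cap)
  if (any(lb > ub)) stop("lower bound exceeds upper bound for: ",
                         paste(rids[lb > ub], collapse = ", "))
  gpr <- vapply(reactions, function(r) {
    g <- r$gpr
    if (is.null(g)) return(NA_character_)
    if (inherits(g, "gpr_tree")) serialize_gpr(g, "SGPR") else as.character(g)
  }, character(1L))
  ec <- vapply(reactions, function(r) {
    e <- r$ec
    if (is.null(e) || !length(e)) NA_character_ else paste(e, collapse = ";")
  }, character(1L))
  rxns <- data.frame(
    id = rids,
    name = vapply(reactions, getf, character(1L), f = "name", default = NA_character_),
    lower_bound = lb, upper_bound = ub,
    pathway = vapply(reactions, getf, character(1L), f = "pathway", default = NA_character_),
    ec = ec, gpr = gpr,
    is_exchange = vapply(reactions, function(r) length(r$mets) == 1L, logical(1L)),
    stringsAsFactors = FALSE)

  S <- Matrix::sparseMatrix(
    i = unlist(lapply(reactions, function(r) match(names(r$mets), met_ids))),
    j = rep(seq_along(reactions), vapply(reactions, function(r) length(r$mets), integer(1L))),
    x = unlist(lapply(reactions, function(r) unname(r$mets))),
    dims = c(length(met_ids), length(reactions)),
    dimnames = list(met_ids, rids))

  model <- structure(list(id = id, compartments = compartments,
                          metabolites = mets, reactions = rxns,
                          stoich = S, objective = objective,
                          bound_cap = bound_cap),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions (%d exchange), objective %s\n",
              x$id, nrow(x$metabolites), nrow(x$reactions),
              sum(x$reactions$is_exchange), x$objective))
  invisible(x)
}

#' Validate internal consistency of a model
#' @param model a [metabolic_model]
#' @return the model, invisibly; errors name the offending elements
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  r <- model$reactions
  if (!(model$objective %in% r$id))
    stop("objective reaction not in the model: ", model$objective)
  if (anyDuplicated(model$metabolites$id))
    stop("duplicate metabolite ids")
  if (!identical(rownames(model$stoich), model$metabolites$id) ||
      !identical(colnames(model$stoich), r$id))
    stop("stoichiometric matrix dimnames out of step with tables")
  nz <- Matrix::colSums(model$stoich != 0)
  empty <- r$id[nz == 0L]
  if (length(empty)) stop("reactions with empty stoichiometry: ",
                          paste(empty, collapse = ", "))
  multi <- r$id[nz > 1L & r$is_exchange]
  if (length(multi)) stop("exchange reactions with more than one metabolite: ",
                          paste(multi, collapse = ", "))
  bad <- r$id[!is.finite(r$lower_bound) | !is.finite(r$upper_bound) |
                r$lower_bound > r$upper_bound]
  if (length(bad)) stop("invalid bounds for: ", paste(bad, collapse = ", "))
  for (i in which(!is.na(r$gpr))) parse_gpr(r$gpr[i])
  invisible(model)
}

#' Genes referenced by a model's rules
#' @param model a [metabolic_model]
#' @export
model_genes <- function(model) {
  g <- unlist(lapply(stats::na.omit(model$reactions$gpr),
                     function(s) gpr_genes(parse_gpr(s))))
  sort(unique(g))
}

#' Parsed rule trees per reaction
#' @param model a [metabolic_model]
#' @return named list of [gpr_tree] (NULL where a reaction carries no rule)
#' @export
model_gpr_trees <- function(model) {
  out <- vector("list", nrow(model$reactions))
  names(out) <- model$reactions$id
  for (i in which(!is.na(model$reactions$gpr)))
    out[[i]] <- parse_gpr(model$reactions$gpr[i])
  out
}

reaction_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Replace flux bounds of selected reactions
#' @param model a [metabolic_model]
#' @param ids reaction ids
#' @param lower,upper replacement bounds (recycled)
#' @export
set_bounds <- function(model, ids, lower = NULL, upper = NULL) {
  i <- reaction_index(model, ids)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- rep_len(lower, length(i))
  if (!is.null(upper)) model$reactions$upper_bound[i] <- rep_len(upper, length(i))
  validate_model(model)
}

subset_reactions <- function(model, keep) {
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoich <- model$stoich[, keep, drop = FALSE]
  model
}

#' Which exchange reactions move a given metabolite
#'
#' @param model a [metabolic_model]
#' @return data.frame with columns `metabolite_id`, `reaction_id`,
#'   `direction` (`"uptake"`, `"secretion"` or `"reversible"`)
#' @export
exchange_map <- function(model) {
  ex <- which(model$reactions$is_exchange)
  if (!length(ex))
    return(data.frame(metabolite_id = character(), reaction_id = character(),
                      direction = character(), stringsAsFactors = FALSE))
  met <- vapply(ex, function(j) {
    rownames(model$stoich)[which(model$stoich[, j] != 0)]
  }, character(1L))
  coef <- vapply(seq_along(ex), function(k) model$stoich[met[k], ex[k]], numeric(1L))
  lb <- model$reactions$lower_bound[ex]; ub <- model$reactions$upper_bound[ex]
  dir <- ifelse(lb < 0 & ub > 0, "reversible",
                ifelse(coef > 0, ifelse(ub > 0, "uptake", "secretion"),
                       ifelse(ub > 0, "secretion", "uptake")))
  data.frame(metabolite_id = met, reaction_id = model$reactions$id[ex],
             direction = dir, stringsAsFactors = FALSE)
}

#' Add uptake and secretion exchange reactions for metabolites
#'
#' For each listed metabolite lacking an exchange, two irreversible boundary
#' reactions are added: an uptake `∅ -> M` and a secretion `M -> ∅`, both
#' with bounds `[0, bound_cap]`. No reaction is added where the exchange
#' already exists; an existing reversible exchange covers both directions.
#'
#' @param model a [metabolic_model]
#' @param metabolite_ids metabolites to expose
#' @return list with the augmented `model` and the count `n_added`
#' @export
add_exchange_reactions <- function(model, metabolite_ids) {
  unknown <- setdiff(metabolite_ids, model$metabolites$id)
  if (length(unknown)) stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "))
  emap <- exchange_map(model)
  n_added <- 0L
  for (m in metabolite_ids) {
    have <- emap[emap$metabolite_id == m, , drop = FALSE]
    covered_up <- any(have$direction %in% c("uptake", "reversible"))
    covered_out <- any(have$direction %in% c("secretion", "reversible"))
    add <- list()
    if (!covered_up)
      add <- c(add, list(list(id = paste0("EX_", m, "_in"),
                              mets = stats::setNames(1, m), lb = 0, ub = model$bound_cap)))
    if (!covered_out)
      add <- c(add, list(list(id = paste0("EX_", m, "_out"),
                              mets = stats::setNames(-1, m), lb = 0, ub = model$bound_cap)))
    for (r in add) model <- append_reaction(model, r)
    n_added <- n_added + length(add)
  }
  list(model = model, n_added = n_added)
}

append_reaction <- function(model, r) {
  if (r$id %in% model$reactions$id) stop("reaction id already present: ", r$id)
  new_mets <- setdiff(names(r$mets), model$metabolites$id)
  if (length(new_mets)) {
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = new_mets, name = new_mets,
                 compartment = names(model$compartments)[1L], stringsAsFactors = FALSE))
    model$stoich <- rbind(model$stoich,
      Matrix::Matrix(0, length(new_mets), ncol(model$stoich), sparse = TRUE,
                     dimnames = list(new_mets, colnames(model$stoich))))
  }
  col <- Matrix::sparseMatrix(i = match(names(r$mets), rownames(model$stoich)),
                              j = rep(1L, length(r$mets)), x = unname(r$mets),
                              dims = c(nrow(model$stoich), 1L),
                              dimnames = list(rownames(model$stoich), r$id))
  model$stoich <- cbind(model$stoich, col)
  model$reactions <- rbind(model$reactions, data.frame(
    id = r$id, name = if (is.null(r$name)) NA_character_ else r$name,
    lower_bound = if (is.null(r$lb)) 0 else r$lb,
    upper_bound = if (is.null(r$ub)) model$bound_cap else r$ub,
    pathway = if (is.null(r$pathway)) NA_character_ else r$pathway,
    ec = if (is.null(r$ec)) NA_character_ else paste(r$ec, collapse = ";"),
    gpr = if (is.null(r$gpr)) NA_character_ else
      if (inherits(r$gpr, "gpr_tree")) serialize_gpr(r$gpr, "SGPR") else r$gpr,
    is_exchange = length(r$mets) == 1L, stringsAsFactors = FALSE))
  validate_model(model)
}

#' Prune blocked reactions, tighten reversibility, drop dead-end metabolites
#'
#' Flux variability analysis over the unconstrained steady-state polytope
#' identifies reactions that cannot carry non-zero flux in any condition
#' (blocked, range `[0, 0]`): these are removed. A reversible reaction with
#' exactly one feasible direction is turned irreversible by tightening the
#' infeasible bound to zero. Metabolites left participating in no reaction
#' (dead ends) are removed. The procedure iterates to a fixed point.
#'
#' @param model a [metabolic_model]
#' @param tol numeric zero for blockedness (default 1e-9)
#' @return list with the reduced `model` and a `report` (lists of removed
#'   reaction ids, tightened reaction ids, removed metabolite ids)
#' @export
prune_model <- function(model, tol = 1e-9) {
  removed_rxns <- character(); tightened <- character(); removed_mets <- character()
  repeat {
    rng <- flux_variability(model, fraction_of_optimum = NULL)
    blocked <- abs(rng$min) < tol & abs(rng$max) < tol
    if (blocked[match(model$objective, rng$id)])
      stop("objective reaction is blocked: ", model$objective)
    rev_ <- model$reactions$lower_bound < 0 & model$reactions$upper_bound > 0
    tighten_fwd <- rev_ & !blocked & rng$min > -tol   # backward direction infeasible
    tighten_bwd <- rev_ & !blocked & rng$max < tol    # forward direction infeasible
    if (!any(blocked) && !any(tighten_fwd) && !any(tighten_bwd)) break
    model$reactions$lower_bound[tighten_fwd] <- 0
    model$reactions$upper_bound[tighten_bwd] <- 0
    tightened <- union(tightened, model$reactions$id[tighten_fwd | tighten_bwd])
    removed_rxns <- c(removed_rxns, model$reactions$id[blocked])
    model <- subset_reactions(model, !blocked)
  }
  orphan <- Matrix::rowSums(model$stoich != 0) == 0L
  if (any(orphan)) {
    removed_mets <- model$metabolites$id[orphan]
    model$metabolites <- model$metabolites[!orphan, , drop = FALSE]
    rownames(model$metabolites) <- NULL
    model$stoich <- model$stoich[!orphan, , drop = FALSE]
  }
  validate_model(model)
  list(model = model,
       report = list(removed_reactions = removed_rxns,
                     tightened_reactions = tightened,
                     removed_metabolites = removed_mets))
}
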