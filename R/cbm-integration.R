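# The four transcriptomic integration algorithms. Each consumes reaction
# scores produced by evaluate_gpr() through either GPR or S-GPR rules, so the
# stoichiometric variant plugs into all of them unchanged.

resolve_gimme_threshold <- function(scores, config) {
  s <- scores[!is.na(scores)]
  if (!length(s)) stop("no defined reaction scores to derive a threshold from")
  switch(config$gimme_threshold_mode,
    mean_plus_sd = mean(s) + (if (length(s) > 1L) stats::sd(s) else 0),
    percentile = {
      q <- config$gimme_threshold_value
      if (is.null(q) || q < 0 || q > 1) stop("percentile mode needs gimme_threshold_value in [0, 1]")
      unname(stats::quantile(s, q, type = 7))
    },
    absolute = {
      if (is.null(config$gimme_threshold_value)) stop("absolute mode needs gimme_threshold_value")
      config$gimme_threshold_value
    })
}

#' GIMME: penalize flux through lowly-expressed reactions
#'
#' Reactions whose score falls below the expression threshold are penalized
#' in proportion to the shortfall: the LP minimizes
#' `sum_i max(0, t - score_i) * |v_i|` subject to steady state, the flux
#' bounds, and the required metabolic functionality (objective flux at least
#' `rmf_fraction` of the FBA optimum). The optimal penalty sum is the
#' inconsistency score: zero means the network can meet the RMF using only
#' reactions expressed at or above the threshold. A second stage fixes the
#' penalty sum and minimizes total absolute flux so the reported activity
#' state is reproducible across solver degeneracies.
#'
#' @param model a [metabolic_model]
#' @param scores a [reaction_scores()] data.frame
#' @param config an [integration_config]
#' @return list with `fluxes`, `inconsistency`, `activity`, `threshold`,
#'   `penalties`, `rmf`
#' @export
gimme <- function(model, scores, config = integration_config()) {
  s <- score_vector(model, scores)
  t_ <- resolve_gimme_threshold(s, config)
  w <- ifelse(is.na(s), 0, pmax(0, t_ - s))

  opt <- fba(model)$objective_value
  rmf <- config$rmf_fraction * opt
  base <- pq_base(model)
  n <- base$n
  orow <- numeric(n); orow[reaction_index(model, model$objective)] <- 1
  mat <- rbind(base$mat, pq_row(n, orow))
  dir <- c(base$dir, ">="); rhs <- c(base$rhs, rmf - 1e-9)

  st1 <- solve_lp(c(w, w), mat, dir, rhs, base$lower, base$upper)
  if (st1$status != "optimal")
    stop("GIMME infeasible: the required metabolic functionality cannot be met")
  inconsistency <- st1$objval

  mat2 <- rbind(mat, c(w, w)); dir2 <- c(dir, "<="); rhs2 <- c(rhs, inconsistency + 1e-7)
  st2 <- solve_lp(rep(1, 2 * n), mat2, dir2, rhs2, base$lower, base$upper)
  if (st2$status != "optimal") stop("GIMME tie-break stage failed: ", st2$status)
  v <- stats::setNames(st2$solution[seq_len(n)] - st2$solution[n + seq_len(n)],
                       model$reactions$id)
  list(fluxes = v,
       inconsistency = inconsistency,
       activity = classify_activity(v, config),
       threshold = t_,
       penalties = stats::setNames(w, model$reactions$id),
       rmf = rmf)
}

imat_partition <- function(s, config) {
  def <- s[!is.na(s)]
  if (!length(def)) stop("no defined reaction scores")
  qs <- stats::quantile(def, config$imat_quantiles, type = 7, names = FALSE)
  status <- rep("none", length(s)); names(status) <- names(s)
  # >= at the upper cutoff so a tied top group still counts as high; a flat
  # distribution (both cutoffs equal to every score) stays all-moderate
  status[!is.na(s) & s >= qs[2] & s > qs[1]] <- "high"
  status[!is.na(s) & s < qs[1] & status != "high"] <- "low"
  status[!is.na(s) & status == "none"] <- "moderate"
  list(status = status, cutoffs = qs)
}

#' iMAT: match reaction activity to expression tertiles
#'
#' Scored reactions are split into high (score above the upper quantile of
#' the defined-score distribution), low (below the lower quantile) and
#' moderate. A MILP maximizes the number of high reactions carrying at least
#' `flux_epsilon` in either direction plus the number of low reactions
#' carrying no flux. The reported activity comes from a witness flux vector,
#' tie-broken by minimizing total absolute flux at the optimal assignment.
#'
#' @inheritParams gimme
#' @return list with `activity`, `fluxes`, `objective` (the achieved
#'   reward), `status` (per-reaction high/moderate/low/none input labels)
#'   and `cutoffs`
#' @export
imat <- function(model, scores, config = integration_config()) {
  s <- score_vector(model, scores)
  part <- imat_partition(s, config)
  status <- part$status
  high <- which(status == "high"); low <- which(status == "low")
  eps <- config$flux_epsilon
  base <- pq_base(model)
  n <- base$n
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound

  nb <- 0L; ycols <- list()   # (kind, rxn) per binary
  add_y <- function(kind, i) {
    nb <<- nb + 1L
    ycols[[nb]] <<- list(kind = kind, rxn = i)
    nb
  }
  rows <- list()
  add_row <- function(vrow, ycoef, d, r) {
    rows[[length(rows) + 1L]] <<- list(v = vrow, y = ycoef, dir = d, rhs = r)
  }
  for (i in high) {
    yf <- add_y("fwd", i)
    vrow <- numeric(n); vrow[i] <- 1
    # y = 1 forces v_i >= eps (valid for y = 0 since v_i >= lb_i)
    add_row(vrow, stats::setNames(-(eps - lb[i]), yf), ">=", lb[i])
    if (lb[i] < 0) {
      yb <- add_y("bwd", i)
      add_row(vrow, stats::setNames(ub[i] + eps, yb), "<=", ub[i])
      add_row(numeric(n), stats::setNames(c(1, 1), c(yf, yb)), "<=", 1)
    }
  }
  for (i in low) {
    yo <- add_y("off", i)
    vrow <- numeric(n); vrow[i] <- 1
    add_row(vrow, stats::setNames(ub[i], yo), "<=", ub[i])   # y = 1 -> v <= 0
    add_row(vrow, stats::setNames(lb[i], yo), ">=", lb[i])   # y = 1 -> v >= 0
  }

  nvar <- 2L * n + nb
  build <- function(rl) {
    m <- matrix(0, length(rl), nvar)
    for (k in seq_along(rl)) {
      m[k, seq_len(2 * n)] <- pq_row(n, rl[[k]]$v)
      if (length(rl[[k]]$y)) m[k, 2L * n + as.integer(names(rl[[k]]$y))] <- rl[[k]]$y
    }
    m
  }
  mat <- rbind(cbind(base$mat, matrix(0, nrow(base$mat), nb)), build(rows))
  dir <- c(base$dir, vapply(rows, `[[`, character(1L), "dir"))
  rhs <- c(base$rhs, vapply(rows, `[[`, numeric(1L), "rhs"))
  lower <- c(base$lower, rep(0, nb))
  upper <- c(base$upper, rep(1, nb))

  if (nb == 0L) {
    res <- solve_lp(rep(1, nvar), mat, dir, rhs, lower, upper)
    if (res$status != "optimal") stop("iMAT infeasible")
    v <- res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
    v <- stats::setNames(v, model$reactions$id)
    return(list(activity = classify_activity(v, config, labels = status),
                fluxes = v, objective = 0,
                status = status, cutoffs = part$cutoffs))
  }

  obj <- c(rep(0, 2 * n), rep(1, nb))
  mi <- solve_milp(obj, mat, dir, rhs, lower, upper,
                   binary_idx = 2L * n + seq_len(nb), maximize = TRUE)
  if (mi$status != "optimal") stop("iMAT MILP infeasible")
  yfix <- round(mi$solution[2L * n + seq_len(nb)])
  lower[2L * n + seq_len(nb)] <- yfix
  upper[2L * n + seq_len(nb)] <- yfix
  tb <- solve_lp(c(rep(1, 2 * n), rep(0, nb)), mat, dir, rhs, lower, upper)
  if (tb$status != "optimal") stop("iMAT tie-break stage failed")
  v <- stats::setNames(tb$solution[seq_len(n)] - tb$solution[n + seq_len(n)],
                       model$reactions$id)
  list(activity = classify_activity(v, config, labels = status),
       fluxes = v, objective = round(mi$objval),
       status = status, cutoffs = part$cutoffs)
}

#' Relative-expression bound rescaling (Gonçalves et al.-style)
#'
#' Integrates treated/control expression ratios as continuous flux bounds.
#' Step 1: parsimonious FBA on the unmodified model gives the control flux
#' `v_c`. Step 2: each reaction with a defined ratio `r` has its treated
#' flux magnitude bounded by the product `r * |v_c|` (clipped to the
#' original bounds), with the control direction preserved: down-regulation
#' (`r < 1`) tightens the cap below the control flux, up-regulation
#' (`r > 1`) relaxes it above, and a control flux of zero pins the reaction
#' at zero. Lower bounds are never raised, so the rescaled model always
#' admits the all-zero flux and joint infeasibility cannot arise from the
#' rescaling itself. Step 3: parsimonious FBA under the new bounds gives
#' the treated flux.
#'
#' @param model a [metabolic_model]
#' @param relative_scores [reaction_scores()] computed from a profile of
#'   treated/control expression ratios
#' @param config an [integration_config]
#' @return list with `control_fluxes`, `treated_fluxes`, `control_activity`,
#'   `treated_activity` and the rescaled `bounds` table
#' @export
goncalves <- function(model, relative_scores, config = integration_config()) {
  ctrl <- pfba(model)
  vc <- ctrl$fluxes
  r_ <- score_vector(model, relative_scores)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  lb2 <- lb; ub2 <- ub
  scored <- which(!is.na(r_))
  for (i in scored) {
    s <- vc[i]; r <- r_[i]
    if (abs(s) < 1e-9) { lb2[i] <- max(lb[i], 0); ub2[i] <- min(ub[i], 0); next }
    if (s > 0) { lb2[i] <- max(lb[i], 0); ub2[i] <- min(r * s, ub[i]) }
    else       { ub2[i] <- min(ub[i], 0); lb2[i] <- max(r * s, lb[i]) }
  }
  bad <- which(lb2 > ub2 + 1e-12)
  if (length(bad))
    stop("contradictory rescaled bounds for: ",
         paste(model$reactions$id[bad], collapse = ", "))
  treated_model <- model
  treated_model$reactions$lower_bound <- lb2
  treated_model$reactions$upper_bound <- ub2
  trt <- pfba(treated_model)
  list(control_fluxes = vc,
       treated_fluxes = trt$fluxes,
       control_activity = classify_activity(vc, config, condition = "control"),
       treated_activity = classify_activity(trt$fluxes, config, condition = "treated"),
       bounds = data.frame(id = model$reactions$id, ratio = unname(r_),
                           lower = lb2, upper = ub2, stringsAsFactors = FALSE))
}

# Propagate per-gene (log fold change, p-value) pairs to a reaction through
# its rule tree: AND keeps the child with the smallest log fold change (the
# limiting subunit), OR averages (mean mode) or keeps the largest (max mode).
# In S-GPR mode the leaf log fold change is divided by the copy number, like
# any other leaf value; the sign is unaffected.
propagate_lfc <- function(tree, log_fc, p_value, config) {
  prop <- function(node) {
    if (node$kind == "gene") {
      g <- node$gene
      if (!(g %in% names(log_fc)) || !(g %in% names(p_value))) return(NULL)
      lfc <- unname(log_fc[[g]])
      if (config$gpr_mode == "SGPR") lfc <- lfc / node$copies
      return(c(lfc = lfc, p = unname(p_value[[g]])))
    }
    kids <- Filter(Negate(is.null), lapply(node$children, prop))
    if (!length(kids)) return(NULL)
    lfcs <- vapply(kids, `[[`, numeric(1L), "lfc")
    if (node$kind == "and") return(kids[[which.min(lfcs)]])
    if (config$or_mode == "max") return(kids[[which.max(lfcs)]])
    c(lfc = mean(lfcs), p = mean(vapply(kids, `[[`, numeric(1L), "p")))
  }
  prop(tree)
}

made_desired <- function(model, treated_profile, config) {
  lfc <- treated_profile$log_fc; pv <- treated_profile$p_value
  if (is.null(lfc) || is.null(pv))
    stop("MADE needs per-gene log_fc and p_value on the treated profile")
  pv <- ifelse(is.na(pv), 1, pv)
  trees <- model_gpr_trees(model)
  out <- list()
  for (id in names(trees)) {
    if (is.null(trees[[id]])) next
    pr <- propagate_lfc(trees[[id]], lfc, pv, config)
    if (is.null(pr)) next
    desired <- if (pr[["p"]] < config$made_alpha && pr[["lfc"]] > 0) "up"
      else if (pr[["p"]] < config$made_alpha && pr[["lfc"]] < 0) "down"
      else "same"
    out[[id]] <- data.frame(reaction_id = id, log_fc = pr[["lfc"]],
                            p_value = pr[["p"]], desired = desired,
                            weight = 1 - pr[["p"]], stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' MADE: match activity transitions to differential expression
#'
#' Per-reaction desired transitions (up / down / same between control and
#' treated) are derived from gene-level log fold changes and p-values
#' propagated through the rules and thresholded at `made_alpha`. A MILP over
#' two binary activity vectors — one per condition, each constrained to a
#' steady-state flux pattern meeting the required metabolic functionality —
#' maximizes the weighted number of realized transitions that match the
#' desired ones, with weight `1 - p`. Reactions with weight zero impose no
#' constraint. Activity is classified from the tie-broken witness fluxes
#' (binaries fixed at the optimum, total absolute flux minimized).
#'
#' @param model a [metabolic_model] (both conditions share the network)
#' @param profiles list with elements `control` and `treated`
#'   ([expression_profile]s; `treated` must carry `log_fc` and `p_value`)
#' @param config an [integration_config]
#' @return list with `control_activity`, `treated_activity`,
#'   `control_fluxes`, `treated_fluxes`, `objective` (achieved matched
#'   weight) and the `desired` transition table
#' @export
made <- function(model, profiles, config = integration_config()) {
  stopifnot(all(c("control", "treated") %in% names(profiles)))
  des <- made_desired(model, profiles$treated, config)
  if (!is.null(des)) des <- des[des$weight > 0, , drop = FALSE]
  n <- nrow(model$reactions)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  eps <- config$flux_epsilon
  opt <- fba(model)$objective_value
  rmf <- config$rmf_fraction * opt
  base <- pq_base(model)
  orow <- numeric(n); orow[reaction_index(model, model$objective)] <- 1

  # variable layout: [p_c q_c | p_t q_t | binaries dp/dq per condition | m]
  nflux <- 4L * n
  rows <- list(); nb <- 0L; ylab <- character()
  des_ids <- if (is.null(des)) character() else des$reaction_id
  # binary bookkeeping: for each desired reaction x condition, dp (and dq if
  # the reaction can run backward)
  ymap <- list()
  for (id in des_ids) {
    i <- reaction_index(model, id)
    for (cond in c("c", "t")) {
      dp <- nb + 1L; nb <- nb + 1L; ylab[dp] <- paste0(id, ".", cond, ".dp")
      dq <- if (lb[i] < 0) { nb <- nb + 1L; ylab[nb] <- paste0(id, ".", cond, ".dq"); nb } else NA_integer_
      ymap[[paste0(id, ".", cond)]] <- list(rxn = i, dp = dp, dq = dq)
    }
  }
  nmvar <- length(des_ids)
  nvar <- nflux + nb + nmvar
  pcol <- function(cond, i) if (cond == "c") i else 2L * n + i
  qcol <- function(cond, i) if (cond == "c") n + i else 3L * n + i
  ycol <- function(k) nflux + k
  mcol <- function(j) nflux + nb + j

  mk <- function() numeric(nvar)
  add <- function(row, d, r) rows[[length(rows) + 1L]] <<- list(row = row, dir = d, rhs = r)

  # per-condition steady state, forced bounds, RMF
  for (cond in c("c", "t")) {
    off <- if (cond == "c") 0L else 2L * n
    bm <- rbind(base$mat, pq_row(n, orow))
    bd <- c(base$dir, ">="); br <- c(base$rhs, rmf - 1e-9)
    for (k in seq_len(nrow(bm))) {
      row <- mk(); row[off + seq_len(2 * n)] <- bm[k, ]
      add(row, bd[k], br[k])
    }
  }
  pumax <- pmax(ub, 0); qumax <- pmax(-lb, 0)
  for (id in des_ids) {
    for (cond in c("c", "t")) {
      y <- ymap[[paste0(id, ".", cond)]]
      i <- y$rxn
      row <- mk(); row[pcol(cond, i)] <- 1; row[ycol(y$dp)] <- -pumax[i]
      add(row, "<=", 0)                                   # p <= Pmax * dp
      row <- mk(); row[pcol(cond, i)] <- 1; row[ycol(y$dp)] <- -eps
      add(row, ">=", 0)                                   # p >= eps * dp
      if (!is.na(y$dq)) {
        row <- mk(); row[qcol(cond, i)] <- 1; row[ycol(y$dq)] <- -qumax[i]
        add(row, "<=", 0)
        row <- mk(); row[qcol(cond, i)] <- 1; row[ycol(y$dq)] <- -eps
        add(row, ">=", 0)
        row <- mk(); row[ycol(y$dp)] <- 1; row[ycol(y$dq)] <- 1
        add(row, "<=", 1)
      } else {
        row <- mk(); row[qcol(cond, i)] <- 1
        add(row, "<=", 0)                                 # no backward direction
      }
    }
  }
  a_coef <- function(row, cond, id, coef) {
    y <- ymap[[paste0(id, ".", cond)]]
    row[ycol(y$dp)] <- row[ycol(y$dp)] + coef
    if (!is.na(y$dq)) row[ycol(y$dq)] <- row[ycol(y$dq)] + coef
    row
  }
  if (nmvar) for (j in seq_len(nmvar)) {
    id <- des_ids[j]; want <- des$desired[j]
    if (want == "up") {            # match: a_c = 0 and a_t = 1
      row <- mk(); row[mcol(j)] <- 1; row <- a_coef(row, "c", id, 1); add(row, "<=", 1)
      row <- mk(); row[mcol(j)] <- 1; row <- a_coef(row, "t", id, -1); add(row, "<=", 0)
    } else if (want == "down") {   # match: a_c = 1 and a_t = 0
      row <- mk(); row[mcol(j)] <- 1; row <- a_coef(row, "c", id, -1); add(row, "<=", 0)
      row <- mk(); row[mcol(j)] <- 1; row <- a_coef(row, "t", id, 1); add(row, "<=", 1)
    } else {                       # match: a_c = a_t
      row <- mk(); row[mcol(j)] <- 1
      row <- a_coef(row, "c", id, 1); row <- a_coef(row, "t", id, -1); add(row, "<=", 1)
      row <- mk(); row[mcol(j)] <- 1
      row <- a_coef(row, "c", id, -1); row <- a_coef(row, "t", id, 1); add(row, "<=", 1)
    }
  }

  mat <- do.call(rbind, lapply(rows, `[[`, "row"))
  dir <- vapply(rows, `[[`, character(1L), "dir")
  rhs <- vapply(rows, `[[`, numeric(1L), "rhs")
  lower <- rep(0, nvar)
  upper <- c(pumax, qumax, pumax, qumax, rep(1, nb), rep(1, nmvar))

  obj <- mk()
  if (nmvar) obj[vapply(seq_len(nmvar), mcol, integer(1L))] <- des$weight

  if (nb == 0L) {
    res <- solve_lp(c(rep(1, nflux), numeric(nb + nmvar)), mat, dir, rhs, lower, upper)
    if (res$status != "optimal") stop("MADE infeasible")
    sol <- res$solution; objval <- 0
  } else {
    mi <- solve_milp(obj, mat, dir, rhs, lower, upper,
                     binary_idx = nflux + seq_len(nb), maximize = TRUE)
    if (mi$status != "optimal") stop("MADE MILP infeasible")
    yfix <- round(mi$solution[nflux + seq_len(nb)])
    lower[nflux + seq_len(nb)] <- yfix
    upper[nflux + seq_len(nb)] <- yfix
    tb <- solve_lp(c(rep(1, nflux), numeric(nb + nmvar)), mat, dir, rhs, lower, upper)
    if (tb$status != "optimal") stop("MADE tie-break stage failed")
    sol <- tb$solution; objval <- sum(obj * mi$solution)
  }
  vc <- stats::setNames(sol[seq_len(n)] - sol[n + seq_len(n)], model$reactions$id)
  vt <- stats::setNames(sol[2L * n + seq_len(n)] - sol[3L * n + seq_len(n)],
                        model$reactions$id)
  list(control_activity = classify_activity(vc, config, condition = "control"),
       treated_activity = classify_activity(vt, config, condition = "treated"),
       control_fluxes = vc, treated_fluxes = vt,
       objective = objval, desired = des)
}
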