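# Qualitative evaluation of predicted exchange activity against measured
# metabolite consumption/production, and pathway over-activation scoring.

# Exact two-sided Mann-Whitney p-value by enumeration of all C(n+m, n) group
# assignments of the pooled sample; handles ties, used at desk scale.
mw_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled); nx <- length(x)
  u_stat <- function(xi) {
    r <- rank(pooled)
    sum(r[xi]) - nx * (nx + 1) / 2
  }
  idx <- utils::combn(N, nx)
  r <- rank(pooled)
  us <- apply(idx, 2L, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  lo <- mean(us <= u_obs + 1e-12)
  hi <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

#' Two-sided Mann-Whitney test of a metabolite's two time points
#'
#' Exact for small samples (full enumeration when ties are present,
#' `stats::wilcox.test(exact = TRUE)` otherwise); the normal approximation
#' is used only above 25 observations per group.
#'
#' @param x,y numeric replicate peak areas at the two time points
#' @return two-sided p-value
#' @export
mann_whitney_p <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(x) > 25L || length(y) > 25L)
    return(suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value))
  if (!ties)
    return(stats::wilcox.test(x, y, exact = TRUE)$p.value)
  mw_exact_enum(x, y)
}

#' Call metabolite consumption / production from peak areas
#'
#' For each metabolite, replicate peak areas at the start (`t0`) and after
#' incubation (`t5`) are compared by a two-sided exact Mann-Whitney test.
#' When the difference is significant at `alpha`, the direction follows the
#' median change (increase: produced; decrease: consumed); otherwise the
#' metabolite is called unchanged. Metabolites with fewer than two
#' replicates in either group are flagged untestable.
#'
#' @param measurements data.frame with columns `metabolite_id`, `timepoint`
#'   (`"t0"` or `"t5"`), `area` (positive peak areas)
#' @param alpha significance level (default 0.05)
#' @return data.frame of class `exchange_calls` with columns
#'   `metabolite_id`, `p_value`, `call` in
#'   `consumed`/`produced`/`unchanged`/`untestable`
#' @export
call_exchanges <- function(measurements, alpha = 0.05) {
  stopifnot(all(c("metabolite_id", "timepoint", "area") %in% names(measurements)),
            all(measurements$timepoint %in% c("t0", "t5")))
  mets <- unique(measurements$metabolite_id)
  out <- lapply(mets, function(m) {
    x0 <- measurements$area[measurements$metabolite_id == m & measurements$timepoint == "t0"]
    x5 <- measurements$area[measurements$metabolite_id == m & measurements$timepoint == "t5"]
    if (length(x0) < 2L || length(x5) < 2L)
      return(data.frame(metabolite_id = m, p_value = NA_real_, call = "untestable",
                        stringsAsFactors = FALSE))
    p <- mann_whitney_p(x0, x5)
    call <- if (p < alpha) {
      if (stats::median(x5) > stats::median(x0)) "produced" else "consumed"
    } else "unchanged"
    data.frame(metabolite_id = m, p_value = p, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("exchange_calls", "data.frame")
  out
}

#' Compare predicted exchange activity with measured exchange calls
#'
#' A metabolite is predicted-active when any of its exchange reactions
#' (either direction) is active in the supplied state; it is
#' measured-exchanging when its call is `consumed` or `produced`. The 2x2
#' agreement table (rows: predicted active/inactive; columns: measured
#' exchange/no-exchange) yields the proportion of right predictions
#' `(a + d) / n` and a two-sided Fisher exact p-value. Untestable
#' metabolites are excluded.
#'
#' @param activity an `activity_state` covering the exchange reactions
#' @param calls an `exchange_calls` data.frame from [call_exchanges()]
#' @param met_map data.frame mapping `metabolite_id` to `reaction_id`
#'   (one row per exchange reaction; see [exchange_map()])
#' @param alpha unused for the table itself; kept for interface symmetry
#' @return list of class `comparison_result` with `table` (2x2 counts),
#'   `right_proportion`, `fisher_p`, `n`, and a per-metabolite `detail`
#' @export
compare_predictions <- function(activity, calls, met_map, alpha = 0.05) {
  stopifnot(all(c("metabolite_id", "reaction_id") %in% names(met_map)))
  usable <- calls[calls$call != "untestable", , drop = FALSE]
  usable <- usable[usable$metabolite_id %in% met_map$metabolite_id, , drop = FALSE]
  if (!nrow(usable)) stop("no evaluable metabolites (all untestable or unmapped)")
  pred <- vapply(usable$metabolite_id, function(m) {
    rxns <- met_map$reaction_id[met_map$metabolite_id == m]
    rxns <- intersect(rxns, names(activity))
    if (!length(rxns)) return(NA)
    any(unclass(activity)[rxns])
  }, logical(1L))
  keep <- !is.na(pred)
  usable <- usable[keep, , drop = FALSE]; pred <- pred[keep]
  if (!nrow(usable)) stop("no evaluable metabolites (no mapped exchange reactions)")
  meas <- usable$call %in% c("consumed", "produced")
  a <- sum(pred & meas); b <- sum(pred & !meas)
  c_ <- sum(!pred & meas); d <- sum(!pred & !meas)
  tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE,
                dimnames = list(predicted = c("active", "inactive"),
                                measured = c("exchange", "no_exchange")))
  fisher_p <- stats::fisher.test(tab)$p.value
  structure(list(table = tab,
                 right_proportion = (a + d) / sum(tab),
                 fisher_p = fisher_p,
                 n = sum(tab),
                 detail = data.frame(metabolite_id = usable$metabolite_id,
                                     predicted_active = pred,
                                     measured_call = usable$call,
                                     right = (pred & meas) | (!pred & !meas),
                                     stringsAsFactors = FALSE)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d metabolites, right proportion %.3f, Fisher p = %.4g\n",
              x$n, x$right_proportion, x$fisher_p))
  print(x$table)
  invisible(x)
}

#' Improvement of S-GPR over GPR predictions
#'
#' Percentage-point difference of the right-prediction proportions over the
#' same metabolite set (primary metric); the relative change in percent is
#' attached as attribute `"relative_percent"`.
#'
#' @param gpr_result,sgpr_result [compare_predictions()] results over the
#'   same metabolites
#' @return numeric percentage points (positive: S-GPR better)
#' @export
improvement <- function(gpr_result, sgpr_result) {
  if (!setequal(gpr_result$detail$metabolite_id, sgpr_result$detail$metabolite_id))
    stop("results cover different metabolite sets")
  pts <- 100 * (sgpr_result$right_proportion - gpr_result$right_proportion)
  rel <- if (gpr_result$right_proportion > 0)
    100 * (sgpr_result$right_proportion / gpr_result$right_proportion - 1) else NA_real_
  structure(pts, relative_percent = rel)
}

#' Pathway over-activation between two conditions
#'
#' Per pathway, counts active reactions in each condition and reports the
#' relative weight (active in the second condition / active in the first).
#' A pathway active only in the second condition is flagged exclusive. The
#' p-value is a two-sample t-test on the per-reaction 0/1 activity
#' indicators between conditions (NA when degenerate).
#'
#' @param states_by_condition named list of two `activity_state`s; the
#'   first is the reference (control), the second the treated condition
#' @param pathway_map named character vector reaction id -> pathway label
#'   (reactions with `NA` pathway are ignored), or a [metabolic_model]
#' @return data.frame with columns `pathway`, `n_reactions`,
#'   `active_control`, `active_treated`, `relative_weight`, `exclusive`,
#'   `p_value`
#' @export
pathway_overactivation <- function(states_by_condition, pathway_map) {
  stopifnot(length(states_by_condition) == 2L)
  if (inherits(pathway_map, "metabolic_model"))
    pathway_map <- stats::setNames(pathway_map$reactions$pathway, pathway_map$reactions$id)
  ctrl <- states_by_condition[[1L]]; trt <- states_by_condition[[2L]]
  pathway_map <- pathway_map[!is.na(pathway_map)]
  pathway_map <- pathway_map[names(pathway_map) %in% names(ctrl)]
  pws <- sort(unique(pathway_map))
  out <- lapply(pws, function(pw) {
    rxns <- names(pathway_map)[pathway_map == pw]
    if (!length(rxns)) {
      message("pathway with zero reactions skipped: ", pw)
      return(NULL)
    }
    ac <- as.numeric(unclass(ctrl)[rxns]); at <- as.numeric(unclass(trt)[rxns])
    n_ac <- sum(ac); n_at <- sum(at)
    rw <- if (n_ac > 0) n_at / n_ac else NA_real_
    excl <- n_ac == 0 && n_at > 0
    pv <- tryCatch(stats::t.test(at, ac)$p.value, error = function(e) NA_real_)
    data.frame(pathway = pw, n_reactions = length(rxns),
               active_control = n_ac, active_treated = n_at,
               relative_weight = rw, exclusive = excl, p_value = pv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(Filter(Negate(is.null), out), list(make.row.names = FALSE)))
}
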