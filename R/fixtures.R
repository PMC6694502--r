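# Seeded generators for toy metabolic networks, two-condition expression
# profiles and metabolite peak-area tables. These define the study
# conditions the test-suite runs under; the discriminating fixture realizes
# the scenario in which a multi-copy subunit makes S-GPR and GPR
# evaluations, and hence downstream predictions, diverge.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for the toy-fixture generators
#'
#' The defaults describe the emulated study conditions: a small connected
#' network with isoenzyme (`or`) and multi-copy complex (`and` with copies
#' above 1) motifs, two highly similar conditions differing at a small
#' fraction of genes, log-normal expression with a four-fold separation
#' between genes of planted-active and other reactions, and five replicate
#' peak areas per time point.
#'
#' @param seed integer seed; the same seed yields a bit-identical fixture
#' @param n_chains number of linear pathway chains off the hub metabolite
#' @param chain_length reactions per chain
#' @param n_branches extra parallel (duplicate-route) reactions
#' @param n_isozyme_pairs reactions carrying an `or` of two genes
#' @param n_complexes reactions carrying an `and` with a copy number >= 2
#' @param complex_max_copies largest copy number drawn for complex subunits
#' @param noise_sd replicate noise, standard deviation on the log2 scale
#' @param n_replicates replicates per condition and per time point
#' @param effect_size fold separation between high and low expression
#' @param fraction_different fraction of genes whose level flips between
#'   control and treated
#' @export
fixture_spec <- function(seed = 1L, n_chains = 2L, chain_length = 3L,
                         n_branches = 1L, n_isozyme_pairs = 1L,
                         n_complexes = 1L, complex_max_copies = 2L,
                         noise_sd = 0.1, n_replicates = 5L,
                         effect_size = 4, fraction_different = 0.1) {
  spec <- list(seed = as.integer(seed), n_chains = as.integer(n_chains),
               chain_length = as.integer(chain_length),
               n_branches = as.integer(n_branches),
               n_isozyme_pairs = as.integer(n_isozyme_pairs),
               n_complexes = as.integer(n_complexes),
               complex_max_copies = as.integer(complex_max_copies),
               noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
               effect_size = effect_size, fraction_different = fraction_different)
  stopifnot(spec$n_chains >= 0, spec$chain_length >= 1, spec$n_branches >= 0,
            spec$n_isozyme_pairs >= 0, spec$n_complexes >= 0,
            spec$complex_max_copies >= 2, spec$noise_sd >= 0,
            spec$n_replicates >= 1, spec$effect_size > 0,
            spec$fraction_different >= 0, spec$fraction_different <= 1)
  structure(spec, class = "fixture_spec")
}

#' Generate a seeded toy metabolic model
#'
#' Builds a connected network: an uptake exchange feeds a hub metabolite
#' `A`; each chain converts it over `chain_length` catalyzed steps to a
#' terminal metabolite with a secretion exchange. Extra branches duplicate
#' random chain steps (parallel routes), isoenzyme pairs receive `or` rules
#' and complexes `and` rules with a copy number of at least 2. Pathway
#' labels partition the internal reactions by chain; the objective is the
#' secretion exchange of the first chain. All reactions are irreversible
#' with capacity 10, so every generated model is feasible and prunes to
#' itself.
#'
#' @param spec a [fixture_spec]
#' @return a [metabolic_model]
#' @export
generate_toy_model <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    gene_counter <- 0L
    next_gene <- function() {
      gene_counter <<- gene_counter + 1L
      paste0("g", gene_counter)
    }
    rx <- list(list(id = "EX_A_in", mets = c(A = 1), lb = 0, ub = 10))
    internal <- character()
    if (spec$n_chains == 0L) {
      rx <- c(rx, list(list(id = "EX_A_out", mets = c(A = -1), lb = 0, ub = 10)))
      objective <- "EX_A_out"
    } else {
      for (k in seq_len(spec$n_chains)) {
        prev <- "A"
        for (j in seq_len(spec$chain_length)) {
          met <- paste0("C", k, "M", j)
          id <- paste0("R_c", k, "_", j)
          rx <- c(rx, list(list(id = id,
                                mets = stats::setNames(c(-1, 1), c(prev, met)),
                                lb = 0, ub = 10,
                                pathway = paste0("pathway_", k),
                                gpr = next_gene())))
          internal <- c(internal, id)
          prev <- met
        }
        rx <- c(rx, list(list(id = paste0("EX_c", k, "_out"),
                              mets = stats::setNames(-1, prev), lb = 0, ub = 10)))
      }
      objective <- "EX_c1_out"
      # parallel branches: duplicate routes for random chain steps
      if (spec$n_branches > 0L) {
        dup <- sample(internal, min(spec$n_branches, length(internal)))
        for (d in dup) {
          src <- rx[[which(vapply(rx, `[[`, character(1L), "id") == d)]]
          rx <- c(rx, list(list(id = paste0(d, "_alt"), mets = src$mets,
                                lb = 0, ub = 10, pathway = src$pathway,
                                gpr = next_gene())))
        }
      }
    }
    all_ids <- vapply(rx, `[[`, character(1L), "id")
    catalyzed <- which(vapply(rx, function(r) !is.null(r$gpr), logical(1L)))
    # isoenzyme pairs: or-rules
    if (spec$n_isozyme_pairs > 0L && length(catalyzed)) {
      pick <- sample(catalyzed, min(spec$n_isozyme_pairs, length(catalyzed)))
      for (i in pick)
        rx[[i]]$gpr <- paste(rx[[i]]$gpr, "or", next_gene())
    }
    # complexes with copy number >= 2
    remaining <- setdiff(catalyzed, if (exists("pick")) pick else integer())
    if (spec$n_complexes > 0L && length(remaining)) {
      pick2 <- sample(remaining, min(spec$n_complexes, length(remaining)))
      for (i in pick2) {
        copies <- sample(2:spec$complex_max_copies, 1L)
        rx[[i]]$gpr <- paste0(rx[[i]]$gpr, " and ", copies, "*", next_gene())
      }
    }
    metabolic_model(rx, objective = objective,
                    id = paste0("toy_seed", spec$seed))
  })
}

#' Generate two-condition expression profiles around a planted activity
#' pattern
#'
#' Genes of planted-active reactions draw log-normal replicates around a
#' high mean, all other rule genes around a low mean `effect_size`-fold
#' below, with log2-scale replicate noise `noise_sd`. The treated condition
#' flips the level of a `fraction_different` subset of genes; per-gene
#' p-values (Welch t-test on log2 replicates) and log2 fold changes come
#' from the replicate draws. Errors if the planted set admits no
#' steady-state witness flux.
#'
#' @param model a [metabolic_model]
#' @param planted_active reaction ids meant to carry flux
#' @param spec a [fixture_spec]
#' @return list with [expression_profile]s `control` and `treated`, and the
#'   `flipped` gene ids
#' @export
generate_expression <- function(model, planted_active, spec = fixture_spec()) {
  idx <- reaction_index(model, planted_active)
  # witness: planted reactions must be able to carry flux simultaneously
  n <- nrow(model$reactions)
  lo <- model$reactions$lower_bound; up <- model$reactions$upper_bound
  lo[idx] <- pmax(lo[idx], 1e-3)
  wit <- solve_lp(numeric(n), as.matrix(model$stoich),
                  rep("=", nrow(model$stoich)), numeric(nrow(model$stoich)),
                  lo, up)
  if (wit$status != "optimal")
    stop("planted active set is infeasible as a flux pattern")

  trees <- model_gpr_trees(model)
  planted_genes <- unique(unlist(lapply(trees[planted_active], function(t_)
    if (is.null(t_)) NULL else gpr_genes(t_))))
  genes <- model_genes(model)
  base_log2 <- 3
  mu <- ifelse(genes %in% planted_genes, base_log2 + log2(spec$effect_size), base_log2)
  names(mu) <- genes

  with_seed(spec$seed + 1L, {
    n_flip <- round(spec$fraction_different * length(genes))
    flipped <- if (n_flip > 0) sample(genes, n_flip) else character()
    mu_t <- mu
    hi <- base_log2 + log2(spec$effect_size)
    mu_t[flipped] <- ifelse(mu[flipped] > base_log2, base_log2, hi)
    draw <- function(mus) {
      reps <- vapply(seq_len(spec$n_replicates), function(r)
        stats::rnorm(length(mus), mus, spec$noise_sd), numeric(length(mus)))
      matrix(reps, nrow = length(mus), dimnames = list(names(mus), NULL))
    }
    rc <- draw(mu); rt <- draw(mu_t)
    pv <- vapply(genes, function(g) {
      if (spec$noise_sd == 0 || spec$n_replicates < 2L)
        return(if (isTRUE(all.equal(mu[[g]], mu_t[[g]]))) 1 else 0)
      tryCatch(stats::t.test(rt[g, ], rc[g, ])$p.value, error = function(e) 1)
    }, numeric(1L))
    lfc <- rowMeans(rt) - rowMeans(rc)
    list(control = expression_profile(rowMeans(2^rc), condition = "control"),
         treated = expression_profile(rowMeans(2^rt),
                                      p_value = pv, log_fc = lfc,
                                      condition = "treated"),
         flipped = flipped)
  })
}

#' Generate replicate peak areas consistent with given exchange calls
#'
#' Peak areas with multiplicative (log-normal) noise: consumed metabolites
#' drop to 40% of their baseline by the second time point, produced ones
#' rise 2.5-fold, unchanged ones stay at baseline.
#'
#' @param truth named character vector metabolite ->
#'   `consumed`/`produced`/`unchanged`
#' @param spec a [fixture_spec]
#' @param baseline mean peak area at the first time point
#' @param meas_noise_sd log-scale noise of replicate areas
#' @return long data.frame (`metabolite_id`, `timepoint`, `area`)
#' @export
generate_measurements <- function(truth, spec = fixture_spec(),
                                  baseline = 100, meas_noise_sd = 0.05) {
  stopifnot(all(truth %in% c("consumed", "produced", "unchanged")))
  with_seed(spec$seed + 2L, {
    out <- lapply(names(truth), function(m) {
      fold <- switch(truth[[m]], consumed = 0.4, produced = 2.5, unchanged = 1)
      t0 <- baseline * exp(stats::rnorm(spec$n_replicates, 0, meas_noise_sd))
      t5 <- baseline * fold * exp(stats::rnorm(spec$n_replicates, 0, meas_noise_sd))
      data.frame(metabolite_id = m,
                 timepoint = rep(c("t0", "t5"), each = spec$n_replicates),
                 area = c(t0, t5), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' The discriminating fixture: where stoichiometry changes the prediction
#'
#' A reaction gated by the rule `"2*g1 and g2"` with expression
#' `g1 = 3, g2 = 2` scores `min(3, 2) = 2` under GPR but
#' `min(3/2, 2) = 1.5` under S-GPR. The fixture places the integration
#' thresholds between 1.5 and 2 (GIMME absolute threshold 1.75; iMAT 40th /
#' 60th percentiles over filler scores 1.6–1.9), so the gated reaction — and
#' the secretion exchange of its byproduct X — is predicted active under GPR
#' and inactive under S-GPR. The bundled measurements show no significant
#' exchange for X, so only the S-GPR call is right. GIMME is additionally
#' steered by an alternative route to the objective whose penalty lies
#' between the gated reaction's GPR penalty (0) and its S-GPR penalty.
#'
#' @return list with `model`, `profiles` (control = treated), `scores`
#'   (the fixed gene expression), `measurements`, `met_map`
#'   (metabolite -> exchange reactions), and `config` (the fixture's
#'   [integration_config] with the placed thresholds; set `gpr_mode` per
#'   run)
#' @export
generate_discriminating_case <- function() {
  rx <- list(
    list(id = "EX_A_in", mets = c(A = 1), lb = 0, ub = 10),
    list(id = "R_gated", mets = c(A = -1, M = 1, X = 1), lb = 0, ub = 10,
         gpr = "2*g1 and g2", pathway = "gated_route"),
    list(id = "R_alt", mets = c(A = -1, M = 1), lb = 0, ub = 10,
         gpr = "g_alt", pathway = "alt_route"),
    list(id = "EX_M_out", mets = c(M = -1), lb = 0, ub = 10),
    list(id = "EX_X_out", mets = c(X = -1), lb = 0, ub = 10),
    list(id = "R_f1", mets = c(A = -1, F1 = 1), lb = 0, ub = 10, gpr = "gf1",
         pathway = "filler"),
    list(id = "EX_F1_out", mets = c(F1 = -1), lb = 0, ub = 10),
    list(id = "R_f2", mets = c(A = -1, F2 = 1), lb = 0, ub = 10, gpr = "gf2",
         pathway = "filler"),
    list(id = "EX_F2_out", mets = c(F2 = -1), lb = 0, ub = 10),
    list(id = "R_f3", mets = c(A = -1, F3 = 1), lb = 0, ub = 10, gpr = "gf3",
         pathway = "filler"),
    list(id = "EX_F3_out", mets = c(F3 = -1), lb = 0, ub = 10),
    list(id = "R_y", mets = c(A = -1, Y = 1), lb = 0, ub = 10, gpr = "g_y",
         pathway = "dead_route"),
    list(id = "EX_Y_out", mets = c(Y = -1), lb = 0, ub = 10))
  model <- metabolic_model(rx, objective = "EX_M_out", id = "discriminating")

  expr <- c(g1 = 3, g2 = 2, g_alt = 1.6, gf1 = 1.7, gf2 = 1.8, gf3 = 1.9, g_y = 0.5)
  profile <- expression_profile(expr, condition = "fixture")

  # fixed replicate areas: A clearly consumed, X and Y unchanged
  meas <- rbind(
    data.frame(metabolite_id = "A", timepoint = rep(c("t0", "t5"), each = 5L),
               area = c(100, 102, 98, 101, 99, 40, 41, 39, 42, 38)),
    data.frame(metabolite_id = "X", timepoint = rep(c("t0", "t5"), each = 5L),
               area = c(100, 101, 99, 102, 98, 99, 102, 100, 98, 101)),
    data.frame(metabolite_id = "Y", timepoint = rep(c("t0", "t5"), each = 5L),
               area = c(95, 97, 96, 98, 94, 96, 95, 98, 97, 94)))

  met_map <- data.frame(metabolite_id = c("A", "X", "Y"),
                        reaction_id = c("EX_A_in", "EX_X_out", "EX_Y_out"),
                        stringsAsFactors = FALSE)

  config <- integration_config(gimme_threshold_mode = "absolute",
                               gimme_threshold_value = 1.75,
                               imat_quantiles = c(0.40, 0.60))
  list(model = model,
       profiles = list(control = profile, treated = profile),
       scores = expr,
       measurements = meas,
       met_map = met_map,
       config = config)
}

#' Write a full fixture set to a directory
#'
#' Serializes a generated model, its two expression profiles and a
#' measurement table to plain-text files (`model.json`, `expr_control.tsv`,
#' `expr_treated.tsv`, `measurements.tsv`).
#'
#' @param dir output directory (created if needed)
#' @param spec a [fixture_spec]
#' @param planted_active reaction ids planted as active (default: first
#'   chain plus its exchanges)
#' @return the directory, invisibly
#' @export
write_fixture_set <- function(dir, spec = fixture_spec(), planted_active = NULL) {
  model <- generate_toy_model(spec)
  if (is.null(planted_active)) {
    ids <- model$reactions$id
    planted_active <- c("EX_A_in", grep("^R_c1_", ids, value = TRUE),
                        intersect("EX_c1_out", ids))
  }
  prof <- generate_expression(model, planted_active, spec)
  emap <- exchange_map(model)
  truth <- stats::setNames(rep("unchanged", nrow(emap)), emap$metabolite_id)
  meas <- generate_measurements(truth, spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(model, file.path(dir, "model.json"), format = "json")
  write_expression(prof$control, file.path(dir, "expr_control.tsv"))
  write_expression(prof$treated, file.path(dir, "expr_treated.tsv"))
  write_measurements(meas, file.path(dir, "measurements.tsv"))
  invisible(dir)
}
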