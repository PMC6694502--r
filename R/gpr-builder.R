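#' Build GPR / S-GPR rules from an enzyme-composition table
#'
#' The composition table is the offline stand-in for live database
#' retrieval: one row per (EC code, compartment, catalytic unit, gene) with
#' the transcript copy number. A catalytic unit groups the subunits of one
#' isoenzyme or complex; units of the same EC code are isoenzymes.
#'
#' @section Table format:
#' Tab-separated with header `ec_code`, `compartment`, `unit_id`,
#' `gene_id`, `copies`. `(ec_code, compartment, unit_id, gene_id)` must be
#' unique and `copies >= 1`.
#'
#' @param path TSV file path
#' @return validated data.frame of composition rows
#' @export
read_composition_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_composition_table(tab)
}

#' @rdname read_composition_table
#' @param table a data.frame of composition rows
#' @export
validate_composition_table <- function(table) {
  need <- c("ec_code", "compartment", "unit_id", "gene_id", "copies")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("composition table lacks columns: ", paste(miss, collapse = ", "))
  table$copies <- as.integer(table$copies)
  if (anyNA(table$copies) || any(table$copies < 1L))
    stop("copies must be integers >= 1")
  key <- do.call(paste, c(table[c("ec_code", "compartment", "unit_id", "gene_id")], sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate (ec_code, compartment, unit_id, gene_id) rows")
  table
}

#' Infer a reaction's sub-cellular compartment from its metabolites
#'
#' Returns the single compartment all participating metabolites share, or —
#' for transport reactions spanning two or more compartments — the sorted
#' set of compartments involved.
#'
#' @param model a [metabolic_model]
#' @param reaction_id reaction id
#' @return character vector of compartment ids (length 1 unless transport)
#' @export
infer_reaction_compartment <- function(model, reaction_id) {
  j <- reaction_index(model, reaction_id)
  mets <- rownames(model$stoich)[which(model$stoich[, j] != 0)]
  if (!length(mets)) stop("reaction has no metabolites: ", reaction_id)
  comps <- model$metabolites$compartment[match(mets, model$metabolites$id)]
  sort(unique(comps))
}

#' Build the rule tree for one reaction from composition rows
#'
#' Rows are filtered to the reaction's EC codes and compartments (a
#' transport reaction matches a row whose compartment lies anywhere in its
#' compartment set). Within an EC code, each catalytic unit becomes an `and`
#' of its gene leaves with their copy numbers (a single-gene unit is a bare
#' leaf); units join by `or` (isoenzymes); multiple EC codes join by `and`
#' (sequential activities all required). Units and genes are sorted
#' lexicographically so building is deterministic.
#'
#' @param ec_codes character vector of EC codes for the reaction
#' @param compartments the reaction's compartment set
#' @param table composition rows (see [read_composition_table()])
#' @return a [gpr_tree], or `NULL` when no row survives the filters
#' @export
build_gpr_for_reaction <- function(ec_codes, compartments, table) {
  table <- validate_composition_table(table)
  rows <- table[table$ec_code %in% ec_codes & table$compartment %in% compartments, ,
                drop = FALSE]
  if (!nrow(rows)) return(NULL)
  ec_trees <- lapply(sort(unique(rows$ec_code)), function(ec) {
    sub <- rows[rows$ec_code == ec, , drop = FALSE]
    unit_trees <- lapply(sort(unique(sub$unit_id)), function(u) {
      us <- sub[sub$unit_id == u, , drop = FALSE]
      us <- us[order(us$gene_id), , drop = FALSE]
      leaves <- Map(gpr_gene, us$gene_id, us$copies)
      gpr_nary("and", leaves)
    })
    gpr_nary("or", unit_trees)
  })
  gpr_nary("and", ec_trees)
}

#' Annotate every EC-tagged reaction of a model with built rules
#'
#' Batch driver over [build_gpr_for_reaction()]: each reaction carrying EC
#' codes gains an S-GPR string built from the table (the classical GPR is
#' recovered by stripping coefficients). Reactions whose EC codes find no
#' matching composition rows are logged and left without a rule.
#'
#' @param model a [metabolic_model] whose reactions carry `ec` annotations
#' @param table composition rows
#' @return list with the annotated `model`, `n_annotated`, and `skipped`
#'   reaction ids
#' @export
annotate_model <- function(model, table) {
  table <- validate_composition_table(table)
  annotated <- character(); skipped <- character()
  for (i in seq_len(nrow(model$reactions))) {
    ec <- model$reactions$ec[i]
    if (is.na(ec)) next
    ecs <- strsplit(ec, ";", fixed = TRUE)[[1L]]
    comps <- infer_reaction_compartment(model, model$reactions$id[i])
    tree <- build_gpr_for_reaction(ecs, comps, table)
    if (is.null(tree)) {
      skipped <- c(skipped, model$reactions$id[i])
      next
    }
    model$reactions$gpr[i] <- serialize_gpr(tree, "SGPR")
    annotated <- c(annotated, model$reactions$id[i])
  }
  message(sprintf("annotated %d reaction(s); skipped %d without matching composition rows",
                  length(annotated), length(skipped)))
  list(model = model, n_annotated = length(annotated), skipped = skipped)
}
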