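# Model and table I/O. The native JSON dialect is lossless and carries both
# rule strings (gpr without coefficients, sgpr with) plus pathway labels; the
# SBML writer emits an L3v1 + fbc v2 subset in which the classical GPR goes
# to the standard gene-product association and the S-GPR string to a reaction
# annotation (fbc has no slot for stoichiometric coefficients on genes).

SGPR_XMLNS <- "https://sgpr.r-lib.org/ns"

#' Read / write a metabolic model
#'
#' Formats: `"json"` (native dialect, lossless round-trip) or `"sbml"`
#' (Level 3 + fbc v2 subset; the S-GPR string travels in a reaction
#' annotation under the `sgpr` key and the pathway label alongside it).
#' The format is guessed from the file extension when not given.
#'
#' @param path file path
#' @param format `"json"` or `"sbml"`
#' @return a [metabolic_model]
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' @rdname read_model
#' @param model a [metabolic_model]
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  r <- model$reactions
  rx <- lapply(seq_len(nrow(r)), function(i) {
    mets <- model$stoich[, i]
    mets <- mets[mets != 0]
    sg <- r$gpr[i]
    list(id = r$id[i], name = r$name[i],
         metabolites = as.list(mets),
         lower_bound = r$lower_bound[i], upper_bound = r$upper_bound[i],
         pathway = r$pathway[i], ec = r$ec[i],
         gpr = if (is.na(sg)) NA else serialize_gpr(parse_gpr(sg), "GPR"),
         sgpr = sg,
         is_exchange = r$is_exchange[i])
  })
  obj <- list(id = model$id,
              bound_cap = model$bound_cap,
              compartments = as.list(model$compartments),
              metabolites = model$metabolites,
              reactions = rx,
              objective = model$objective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("id", "metabolites", "reactions", "objective"))
    if (is.null(obj[[f]])) stop("model JSON lacks field: ", f)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment, stringsAsFactors = FALSE)))
  rx <- lapply(obj$reactions, function(r) {
    st <- unlist(r$metabolites)
    gpr <- if (!is.null(r$sgpr)) r$sgpr else r$gpr
    list(id = r$id, name = if (is.null(r$name)) NA_character_ else r$name,
         mets = st,
         lb = r$lower_bound, ub = r$upper_bound,
         pathway = if (is.null(r$pathway)) NA_character_ else r$pathway,
         ec = if (is.null(r$ec)) NULL else strsplit(r$ec, ";", fixed = TRUE)[[1L]],
         gpr = gpr)
  })
  comp <- unlist(obj$compartments)
  metabolic_model(rx, objective = obj$objective, metabolite_info = mets,
                  compartments = if (is.null(comp)) c(c = "cytosol") else comp,
                  id = obj$id,
                  bound_cap = if (is.null(obj$bound_cap)) 1000 else obj$bound_cap)
}

## ---- SBML L3 + fbc v2 subset ----------------------------------------------

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$id), "fbc:strict" = "false")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_along(model$compartments))
    xml2::xml_add_child(lc, "compartment", id = names(model$compartments)[i],
                        name = model$compartments[[i]], constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(ls, "species", id = paste0("M_", sbml_id(m$id)), name = m$name,
                        compartment = m$compartment, hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  genes <- model_genes(model)
  lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in genes)
    xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = paste0("G_", sbml_id(g)),
                        "fbc:label" = g)

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    plb <- paste0("lb_", sbml_id(r$id)); pub <- paste0("ub_", sbml_id(r$id))
    xml2::xml_add_child(lp, "parameter", id = plb, value = format(r$lower_bound, digits = 17),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = pub, value = format(r$upper_bound, digits = 17),
                        constant = "true")
    rn <- xml2::xml_add_child(lr, "reaction", id = paste0("R_", sbml_id(r$id)),
                              reversible = tolower(r$lower_bound < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = plb, "fbc:upperFluxBound" = pub)
    if (!is.na(r$name)) xml2::xml_set_attr(rn, "name", r$name)
    ann <- xml2::xml_add_child(rn, "annotation")
    meta <- xml2::xml_add_child(ann, "sgprAnnotation", xmlns = SGPR_XMLNS)
    if (!is.na(r$gpr)) xml2::xml_add_child(meta, "sgpr", r$gpr)
    if (!is.na(r$pathway)) xml2::xml_add_child(meta, "pathway", r$pathway)
    if (!is.na(r$ec)) xml2::xml_add_child(meta, "ec", r$ec)
    st <- model$stoich[, i]; st <- st[st != 0]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lrt <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(subs))
        xml2::xml_add_child(lrt, "speciesReference",
                            species = paste0("M_", sbml_id(names(subs)[k])),
                            stoichiometry = format(-subs[[k]], digits = 17),
                            constant = "true")
    }
    if (length(prods)) {
      lpt <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(prods))
        xml2::xml_add_child(lpt, "speciesReference",
                            species = paste0("M_", sbml_id(names(prods)[k])),
                            stoichiometry = format(prods[[k]], digits = 17),
                            constant = "true")
    }
    if (!is.na(r$gpr)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      write_gpa <- function(parent, node) {
        if (node$kind == "gene") {
          xml2::xml_add_child(parent, "fbc:geneProductRef",
                              "fbc:geneProduct" = paste0("G_", sbml_id(node$gene)))
        } else {
          el <- xml2::xml_add_child(parent, paste0("fbc:", node$kind))
          for (ch in node$children) write_gpa(el, ch)
        }
      }
      write_gpa(gpa, gpr_strip(parse_gpr(r$gpr)))
    }
  }
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", sbml_id(model$objective)),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          sg = SGPR_XMLNS)
  strip_pref <- function(x, pref) sub(paste0("^", pref), "", x)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("not an SBML L3 document: ", path)

  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  comps <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"), xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))
  if (!length(comps)) comps <- c(c = "cytosol")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(id = strip_pref(xml2::xml_attr(sp, "id"), "M_"),
                     name = xml2::xml_attr(sp, "name"),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  glabel <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gmap <- stats::setNames(xml2::xml_attr(glabel, "label"), xml2::xml_attr(glabel, "id"))

  read_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lbl <- if (ref %in% names(gmap) && !is.na(gmap[[ref]])) gmap[[ref]] else strip_pref(ref, "G_")
      return(gpr_gene(lbl))
    }
    kids <- lapply(xml2::xml_children(node), read_gpa)
    gpr_nary(nm, kids)
  }

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rx <- lapply(rnodes, function(rn) {
    rid <- strip_pref(xml2::xml_attr(rn, "id"), "R_")
    get_side <- function(which, sign) {
      refs <- xml2::xml_find_all(rn, paste0("./s:", which, "/s:speciesReference"), ns)
      if (!length(refs)) return(numeric())
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      strip_pref(xml2::xml_attr(refs, "species"), "M_"))
    }
    st0 <- get_side("listOfReactants", -1); st1 <- get_side("listOfProducts", 1)
    st <- c(st0, st1)
    if (!length(st)) stop("SBML reaction without species references: ", rid)
    lbid <- xml2::xml_attr(rn, "lowerFluxBound"); ubid <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]] else -1000
    ub <- if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]] else 1000
    sgpr <- xml2::xml_text(xml2::xml_find_first(rn, ".//sg:sgpr", ns))
    pathway <- xml2::xml_text(xml2::xml_find_first(rn, ".//sg:pathway", ns))
    ec <- xml2::xml_text(xml2::xml_find_first(rn, ".//sg:ec", ns))
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (!is.na(sgpr)) sgpr
      else if (!inherits(gpa, "xml_missing"))
        serialize_gpr(read_gpa(xml2::xml_child(gpa)), "SGPR")
      else NULL
    list(id = rid, mets = st, lb = lb, ub = ub,
         pathway = if (is.na(pathway)) NA_character_ else pathway,
         ec = if (is.na(ec)) NULL else strsplit(ec, ";", fixed = TRUE)[[1L]],
         gpr = gpr)
  })

  objref <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  if (inherits(objref, "xml_missing")) stop("SBML model lacks an fbc objective")
  objective <- strip_pref(xml2::xml_attr(objref, "reaction"), "R_")
  metabolic_model(rx, objective = objective, metabolite_info = mets,
                  compartments = comps,
                  id = if (is.na(xml2::xml_attr(mdl, "id"))) "model" else xml2::xml_attr(mdl, "id"))
}

## ---- expression and measurement tables -------------------------------------

#' Read a per-gene expression table
#'
#' TSV with header `gene_id`, `value`, and optionally `p_value` and
#' `log_fc`. Duplicate gene rows (multiple probes) are collapsed by their
#' maximum value before profile construction; p-values/log-FC then keep the
#' row of the maximal probe.
#'
#' @param path TSV file path
#' @param condition optional condition label
#' @return an [expression_profile]
#' @export
read_expression <- function(path, condition = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "value") %in% names(tab)))
    stop("expression table needs columns gene_id, value")
  ord <- order(tab$gene_id, -tab$value)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  expression_profile(
    stats::setNames(tab$value, tab$gene_id),
    p_value = if ("p_value" %in% names(tab)) stats::setNames(tab$p_value, tab$gene_id),
    log_fc = if ("log_fc" %in% names(tab)) stats::setNames(tab$log_fc, tab$gene_id),
    condition = condition)
}

#' @rdname read_expression
#' @param profile an [expression_profile]
#' @export
write_expression <- function(profile, path) {
  tab <- data.frame(gene_id = names(profile$values), value = unname(profile$values),
                    stringsAsFactors = FALSE)
  if (!is.null(profile$p_value)) tab$p_value <- unname(profile$p_value[tab$gene_id])
  if (!is.null(profile$log_fc)) tab$log_fc <- unname(profile$log_fc[tab$gene_id])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a metabolite measurement table
#'
#' Long TSV with header `metabolite_id`, `timepoint` (`t0`/`t5`), `area`.
#' @param path TSV file path
#' @export
read_measurements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "timepoint", "area")
  if (!all(need %in% names(tab)))
    stop("measurement table needs columns ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_measurements
#' @param measurements measurement data.frame
#' @export
write_measurements <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
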