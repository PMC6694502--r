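#' Gene-protein-reaction rules with subunit stoichiometry
#'
#' A GPR rule is a boolean expression over genes in which `and` joins the
#' subunits of an enzyme complex and `or` joins isoenzymes. A stoichiometric
#' GPR (S-GPR) additionally records, on each gene leaf, the number of
#' transcript copies needed to assemble one functional catalytic unit: a
#' complex with three subunits, one encoded by gene `a` and two by gene `b`,
#' has GPR `"a and b"` and S-GPR `"a and 2*b"`. During evaluation the
#' expression of each gene is divided by its copy number (S-GPR mode only)
#' before the boolean operators are replaced by arithmetic ones: `and` by
#' `min`, `or` by `mean` or `max`.
#'
#' Trees are plain recursive lists of class `gpr_tree`: a gene node has
#' `kind = "gene"`, `gene` and `copies`; `and`/`or` nodes have `kind` and a
#' list `children` (length >= 2, flattened so an `and` never directly nests
#' an `and`).
#'
#' @param gene gene identifier (non-empty string)
#' @param copies positive integer transcript copy number
#' @name gpr_tree
NULL

new_gpr_node <- function(x) structure(x, class = "gpr_tree")

#' @rdname gpr_tree
#' @export
gpr_gene <- function(gene, copies = 1L) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  copies <- as.integer(copies)
  if (is.na(copies) || copies < 1L) stop("copies must be a positive integer")
  new_gpr_node(list(kind = "gene", gene = gene, copies = copies))
}

gpr_nary <- function(kind, children) {
  children <- lapply(children, function(ch) {
    if (!inherits(ch, "gpr_tree")) stop("children must be gpr_tree nodes")
    ch
  })
  # flatten same-operator nests so the tree is canonical
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  new_gpr_node(list(kind = kind, children = flat))
}

#' @rdname gpr_tree
#' @param ... child `gpr_tree` nodes
#' @export
gpr_and <- function(...) gpr_nary("and", list(...))

#' @rdname gpr_tree
#' @export
gpr_or <- function(...) gpr_nary("or", list(...))

#' @export
print.gpr_tree <- function(x, ...) {
  cat("<gpr_tree> ", serialize_gpr(x, mode = "SGPR"), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a rule tree
#' @param tree a `gpr_tree`
#' @return character vector of unique gene identifiers
#' @export
gpr_genes <- function(tree) {
  if (tree$kind == "gene") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Drop stoichiometric coefficients from a rule tree
#'
#' Returns the classical GPR corresponding to an S-GPR: the same tree with
#' every copy number set to 1.
#' @param tree a `gpr_tree`
#' @export
gpr_strip <- function(tree) {
  if (tree$kind == "gene") return(gpr_gene(tree$gene, 1L))
  gpr_nary(tree$kind, lapply(tree$children, gpr_strip))
}

## ---- parsing ---------------------------------------------------------------

gpr_tokenize <- function(text) {
  pats <- c(
    ws = "\\s+",
    lparen = "\\(",
    rparen = "\\)",
    coef = "[0-9]+\\s*\\*",
    id = "[A-Za-z_][A-Za-z0-9_.:-]*"
  )
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(paste0("^", pats[[ty]]), substr(text, pos, n))
      if (m == 1L) {
        len <- attr(m, "match.length")
        val <- substr(text, pos, pos + len - 1L)
        if (ty != "ws") {
          if (ty == "id" && tolower(val) %in% c("and", "or")) ty <- tolower(val)
          tokens[[length(tokens) + 1L]] <- list(type = ty, value = val, pos = pos)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop(sprintf("malformed token at position %d: \"%s\"", pos,
                   substr(text, pos, min(n, pos + 10L))))
  }
  tokens
}

#' Parse a GPR / S-GPR rule string
#'
#' The grammar: gene identifiers, case-insensitive `and` / `or`, parentheses,
#' and an optional integer coefficient prefix `n*` attached to a gene leaf
#' (`"a and 2*b"`). `and` binds tighter than `or`; a coefficient on a
#' parenthesized group is rejected.
#'
#' @param text rule string
#' @return a [gpr_tree]
#' @examples
#' parse_gpr("a and 2*b")
#' parse_gpr("a or b and c")   # or(a, and(b, c))
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty rule string")
  toks <- gpr_tokenize(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect_more <- function(what) {
    if (is.null(peek()))
      stop(sprintf("unexpected end of rule, expected %s in \"%s\"", what, text))
  }

  parse_factor <- function() {
    expect_more("a gene or \"(\"")
    t <- advance()
    if (t$type == "coef") {
      cf <- as.integer(sub("\\s*\\*$", "", t$value))
      if (is.na(cf) || cf < 1L)
        stop(sprintf("zero or negative coefficient \"%s\" at position %d", t$value, t$pos))
      expect_more("a gene after the coefficient")
      g <- advance()
      if (g$type == "lparen")
        stop(sprintf("coefficient applied to a parenthesized group at position %d", t$pos))
      if (g$type != "id")
        stop(sprintf("expected a gene after coefficient at position %d, got \"%s\"", g$pos, g$value))
      return(gpr_gene(g$value, cf))
    }
    if (t$type == "lparen") {
      e <- parse_expr()
      expect_more("\")\"")
      cl <- advance()
      if (cl$type != "rparen")
        stop(sprintf("unbalanced parentheses near position %d", cl$pos))
      return(e)
    }
    if (t$type == "id") return(gpr_gene(t$value, 1L))
    stop(sprintf("unexpected \"%s\" at position %d", t$value, t$pos))
  }
  parse_term <- function() {
    kids <- list(parse_factor())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      kids <- c(kids, list(parse_factor()))
    }
    gpr_nary("and", kids)
  }
  parse_expr <- function() {
    kids <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      kids <- c(kids, list(parse_term()))
    }
    gpr_nary("or", kids)
  }

  out <- parse_expr()
  if (!is.null(peek())) {
    t <- peek()
    stop(sprintf("unexpected \"%s\" at position %d (unbalanced parentheses?)", t$value, t$pos))
  }
  out
}

## ---- serialization ---------------------------------------------------------

#' Serialize a rule tree to a GPR or S-GPR string
#'
#' `mode = "SGPR"` writes `n*gene` for copy numbers above 1; `mode = "GPR"`
#' omits all coefficients (the classical rule is the S-GPR with the
#' stoichiometric information removed). Output re-parses to an equivalent
#' tree.
#'
#' @param tree a [gpr_tree]
#' @param mode `"SGPR"` or `"GPR"`
#' @export
serialize_gpr <- function(tree, mode = c("SGPR", "GPR")) {
  mode <- match.arg(mode)
  ser <- function(node, parent) {
    if (node$kind == "gene") {
      if (mode == "SGPR" && node$copies > 1L)
        return(paste0(node$copies, "*", node$gene))
      return(node$gene)
    }
    parts <- vapply(node$children, ser, character(1L), parent = node$kind)
    s <- paste(parts, collapse = paste0(" ", node$kind, " "))
    # 'and' binds tighter than 'or': an or-node under an and-node needs parens
    if (node$kind == "or" && identical(parent, "and")) s <- paste0("(", s, ")")
    s
  }
  ser(tree, parent = NA_character_)
}

## ---- expression profiles ---------------------------------------------------

#' Per-gene expression profile
#'
#' Houses normalized per-gene expression values (absolute intensities, or
#' treated/control ratios for relative methods), with optional per-gene
#' p-values and log fold changes from a two-condition comparison. Multiple
#' probes per gene must be collapsed to one value beforehand (see
#' [collapse_probes()]).
#'
#' @param values named non-negative numeric vector, names are gene ids
#' @param p_value optional named numeric in \[0, 1\]
#' @param log_fc optional named numeric
#' @param condition optional condition label
#' @export
expression_profile <- function(values, p_value = NULL, log_fc = NULL,
                               condition = NA_character_) {
  stopifnot(is.numeric(values), !is.null(names(values)), all(nzchar(names(values))))
  if (anyNA(values) || any(values < 0)) stop("expression values must be non-negative")
  if (!is.null(p_value)) {
    stopifnot(is.numeric(p_value), !is.null(names(p_value)))
    if (any(p_value < 0 | p_value > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  }
  structure(list(values = values, p_value = p_value, log_fc = log_fc,
                 condition = condition),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d genes%s%s\n", length(x$values),
              if (!is.na(x$condition)) paste0(", condition ", x$condition) else "",
              if (!is.null(x$p_value)) ", with p-values/log-FC" else ""))
  invisible(x)
}

#' Collapse multiple probes per gene to a single value
#'
#' Probe-level intensities mapping to the same gene are collapsed by their
#' maximum, a conservative choice toward detecting activity.
#'
#' @param gene character vector of gene ids (one per probe)
#' @param value numeric probe intensities
#' @return named numeric vector, one value per gene
#' @export
collapse_probes <- function(gene, value) {
  stopifnot(length(gene) == length(value))
  ug <- unique(gene)
  stats::setNames(vapply(ug, function(g) max(value[gene == g]), numeric(1L)), ug)
}

#' Evaluation settings for GPR / S-GPR rules
#'
#' `or_mode` selects the operator replacing `or` (`"mean"` or `"max"`); `and`
#' is always replaced by `min`. `gpr_mode = "SGPR"` divides each gene's
#' expression by its leaf copy number before aggregation; `"GPR"` ignores the
#' coefficients. Genes absent from the profile are either skipped (operators
#' aggregate the defined children only; a rule with no defined leaf evaluates
#' to `NA`) or replaced by a constant.
#'
#' @param or_mode `"mean"` or `"max"`
#' @param gpr_mode `"GPR"` or `"SGPR"`
#' @param missing_gene_policy `"skip"` or `"constant"`
#' @param missing_value constant used when `missing_gene_policy = "constant"`
#' @export
gpr_config <- function(or_mode = c("mean", "max"),
                       gpr_mode = c("GPR", "SGPR"),
                       missing_gene_policy = c("skip", "constant"),
                       missing_value = 0) {
  structure(list(or_mode = match.arg(or_mode),
                 and_mode = "min",
                 gpr_mode = match.arg(gpr_mode),
                 missing_gene_policy = match.arg(missing_gene_policy),
                 missing_value = missing_value),
            class = "gpr_config")
}

#' Evaluate a rule tree against an expression profile
#'
#' Leaf value: the gene's expression (GPR mode) or expression divided by the
#' leaf copy number (S-GPR mode). `and` nodes take the minimum of their
#' defined children, `or` nodes the mean or maximum per `config`. Returns
#' `NA` when every leaf is undefined under the skip policy.
#'
#' @param tree a [gpr_tree]
#' @param profile an [expression_profile] (or named numeric vector)
#' @param config a [gpr_config]
#' @return numeric reaction score, or `NA_real_`
#' @examples
#' cfg <- gpr_config(gpr_mode = "SGPR")
#' evaluate_gpr(parse_gpr("a and 2*b"), c(a = 4, b = 10), cfg)  # min(4, 5) = 4
#' @export
evaluate_gpr <- function(tree, profile, config = gpr_config()) {
  vals <- if (inherits(profile, "expression_profile")) profile$values else profile
  stopifnot(is.numeric(vals), !is.null(names(vals)))
  ev <- function(node) {
    if (node$kind == "gene") {
      v <- if (node$gene %in% names(vals)) unname(vals[[node$gene]]) else {
        if (config$missing_gene_policy == "constant") config$missing_value else NA_real_
      }
      if (is.na(v)) return(NA_real_)
      if (config$gpr_mode == "SGPR") v <- v / node$copies
      return(v)
    }
    xs <- vapply(node$children, ev, numeric(1L))
    xs <- xs[!is.na(xs)]
    if (length(xs) == 0L) return(NA_real_)
    if (node$kind == "and") return(min(xs))
    if (config$or_mode == "max") max(xs) else mean(xs)
  }
  ev(tree)
}
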