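# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar (AND binds tighter than OR, parentheses respected):
#   expr   := term ("or" term)*
#   term   := factor ("and" factor)*
#   factor := gene-id | "(" expr ")"
# Operators are case-insensitive. A gene id is any run of characters in
# [A-Za-z0-9_.:-] that is not "and"/"or".

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR string into an expression tree. `and` binds
#' tighter than `or`; parentheses override precedence. The empty string
#' parses to `NULL` (no gene association).
#'
#' @param rule A GPR string, e.g. `"(g1 or g2) and g3"`.
#' @return An object of class `gpr`: a nested list with fields `op`
#'   (`"and"`, `"or"` or `"gene"`), and either `children` (a list of
#'   subtrees) or `gene` (a gene id). `NULL` for an empty rule.
#' @examples
#' parse_gpr("hk1 or hk2")
#' parse_gpr("pdha1 and dlat and dld")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_expr(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error: unexpected token '", st$toks[st$pos],
         "' in rule: ", rule, call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  if (!length(toks)) stop("GPR parse error: empty rule", call. = FALSE)
  bad <- grepl("[^A-Za-z0-9_.:()-]", toks)
  if (any(bad)) {
    stop("GPR parse error: invalid token '", toks[bad][1], "'", call. = FALSE)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_expr <- function(st) {
  kids <- list(gpr_parse_term(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_term(st)))
  }
  if (length(kids) == 1L) kids[[1]] else gpr_node("or", kids)
}

gpr_parse_term <- function(st) {
  kids <- list(gpr_parse_factor(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_factor(st)))
  }
  if (length(kids) == 1L) kids[[1]] else gpr_node("and", kids)
}

gpr_parse_factor <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: missing operand", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_expr(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("GPR parse error: unbalanced parentheses", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")") stop("GPR parse error: unbalanced parentheses", call. = FALSE)
  if (tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: empty operand before '", tk, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  gpr_node("gene", gene = tk)
}

gpr_node <- function(op, children = NULL, gene = NULL) {
  structure(list(op = op, children = children, gene = gene), class = "gpr")
}

#' List the genes referenced by a GPR tree
#' @param tree A `gpr` tree from [parse_gpr()], or `NULL`.
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Deparse a GPR tree back to a rule string
#' @param tree A `gpr` tree or `NULL`.
#' @return A GPR string (empty string for `NULL`). Parentheses are emitted
#'   around `or` groups nested in `and` so the string re-parses to the
#'   same tree.
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$op == "gene") return(tree$gene)
  parts <- vapply(tree$children, function(k) {
    s <- gpr_to_string(k)
    if (tree$op == "and" && !is.null(k$op) && k$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR tree as a boolean
#'
#' @param tree A `gpr` tree or `NULL`.
#' @param present Named logical vector; genes missing from it are taken
#'   as absent (`FALSE`).
#' @return Logical. `NULL` trees (no association) evaluate `TRUE`: a
#'   reaction without a gene rule cannot be disabled by gene deletion.
#' @export
eval_gpr <- function(tree, present) {
  if (is.null(tree)) return(TRUE)
  switch(tree$op,
    gene = isTRUE(unname(present[tree$gene])),
    and = all(vapply(tree$children, eval_gpr, logical(1), present = present)),
    or = any(vapply(tree$children, eval_gpr, logical(1), present = present))
  )
}

#' Score a GPR tree from gene intensities
#'
#' Maps gene expression onto a reaction: `and` takes the minimum of its
#' children (complex subunits limit each other) and `or` the maximum
#' (isozymes substitute). Genes without a measurement are dropped from
#' `or` nodes; an `and` node is unknown only when all children are
#' unknown.
#'
#' @param tree A `gpr` tree or `NULL`.
#' @param values Named numeric vector of gene intensities.
#' @return A single numeric score, or `NA` when the rule cannot be
#'   scored (unknown).
#' @export
score_gpr <- function(tree, values) {
  if (is.null(tree)) return(NA_real_)
  switch(tree$op,
    gene = {
      v <- unname(values[tree$gene])
      if (length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
    },
    and = {
      vs <- vapply(tree$children, score_gpr, numeric(1), values = values)
      if (all(is.na(vs))) NA_real_ else min(vs, na.rm = TRUE)
    },
    or = {
      vs <- vapply(tree$children, score_gpr, numeric(1), values = values)
      if (all(is.na(vs))) NA_real_ else max(vs, na.rm = TRUE)
    }
  )
}
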