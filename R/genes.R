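# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar: identifiers, `and`, `or` (case-insensitive; `&&`/`&` and
# `||`/`|` accepted as synonyms), parentheses.  The tree is monotone
# (no negation), so deleting more genes can only disable more reactions.

#' Parse a gene-protein-reaction boolean rule
#'
#' @param text Rule string, e.g. `"(g1 and g2) or g3"`.
#' @return An object of class `gem_genes`: a tree of `and`/`or` nodes over
#'   gene identifiers.
#' @export
parse_gene_rule <- function(text) {
  if (!is_string(text)) gem_stop("gene rule must be a single string")
  toks <- regmatches(text, gregexpr("\\(|\\)|&&|\\|\\||&|\\||[^()&|[:space:]]+",
                                    text))[[1]]
  pos <- 1L
  peek <- function() if (pos > length(toks)) "" else toks[pos]
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  is_kw <- function(t, kw) tolower(t) %in% kw
  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), c("or", "|", "||"))) {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_kw(peek(), c("and", "&", "&&"))) {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (t == "(") {
      e <- parse_or()
      if (take() != ")")
        gem_stop("missing ')' in gene rule '", text, "'",
                 class = "gem_parse_error")
      return(e)
    }
    if (t == "" || t == ")" || is_kw(t, c("and", "or", "&", "|", "&&", "||")))
      gem_stop("unexpected token '", t, "' at position ", pos - 1L,
               " in gene rule '", text, "'", class = "gem_parse_error")
    list(op = "id", id = t)
  }
  tree <- parse_or()
  if (peek() != "")
    gem_stop("trailing token '", peek(), "' in gene rule '", text, "'",
             class = "gem_parse_error")
  structure(tree, class = "gem_genes")
}

#' Evaluate a gene rule under a set of gene deletions
#'
#' Deleted genes evaluate to `FALSE`, all other genes to `TRUE`.
#'
#' @param expr A `gem_genes` tree from [parse_gene_rule()] (a string is
#'   parsed on the fly).
#' @param deleted Character vector of deleted gene identifiers.
#' @return Logical scalar: whether the reaction remains active.
#' @export
evaluate_genes <- function(expr, deleted = character()) {
  if (is.character(expr)) expr <- parse_gene_rule(expr)
  ev <- function(node) {
    switch(node$op,
           id = !(node$id %in% deleted),
           and = all(vapply(node$args, ev, logical(1))),
           or = any(vapply(node$args, ev, logical(1))))
  }
  ev(unclass(expr))
}

#' Render a gene rule as text
#'
#' Parsing the rendered text reproduces the same tree (idempotent).
#'
#' @param expr A `gem_genes` tree.
#' @return A single string.
#' @export
render_gene_rule <- function(expr) {
  rend <- function(node, parent_op = "") {
    if (node$op == "id") return(node$id)
    sep <- if (node$op == "and") " and " else " or "
    txt <- paste(vapply(node$args, rend, character(1), parent_op = node$op),
                 collapse = sep)
    # parenthesize an "or" nested under an "and" (and any nested group
    # whose operator differs from its parent's)
    if (nzchar(parent_op) && parent_op != node$op) paste0("(", txt, ")")
    else txt
  }
  rend(unclass(expr))
}

#' List the gene identifiers appearing in a rule
#'
#' @param expr A `gem_genes` tree or rule string.
#' @return Character vector of unique gene ids, in order of appearance.
#' @export
genes_in_rule <- function(expr) {
  if (is.character(expr)) expr <- parse_gene_rule(expr)
  acc <- character(0)
  walk <- function(node) {
    if (node$op == "id") acc <<- c(acc, node$id)
    else for (a in node$args) walk(a)
  }
  walk(unclass(expr))
  unique(acc)
}

#' @export
print.gem_genes <- function(x, ...) {
  cat(render_gene_rule(x), "\n")
  invisible(x)
}
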