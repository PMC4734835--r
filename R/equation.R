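# Reaction equation objects and their text grammar.
#
# An equation is a signed stoichiometry over compartmentalized compounds
# plus a direction.  The text grammar accepted by parse_equation():
#
#   [c]: A + (2) B <==> C        global compartment prefix
#   A[e] => B[c]                 per-compound compartment suffix
#   A[e] =>                      exchange-style, one side empty
#
# Arrows: -->, =>  (forward);  <--, <=  (reverse);  <==>, <=>  (both).
# Coefficients are "(k)" or a bare numeric token; default 1.  Compound
# names may contain spaces and "+" (terms are split on " + " only).

ARROWS <- c("<==>" = "both", "<=>" = "both",
            "-->" = "forward", "=>" = "forward",
            "<--" = "reverse", "<=" = "reverse")

#' Construct a reaction equation
#'
#' @param left,right Data frames with columns `compound` (character),
#'   `compartment` (character, may be `""`) and `coef` (positive numeric),
#'   or `NULL` for an empty side.
#' @param direction One of `"forward"`, `"reverse"`, `"both"`.
#' @return An object of class `gem_equation`.
#' @seealso [parse_equation()], [render_equation()]
#' @export
equation <- function(left = NULL, right = NULL,
                     direction = c("both", "forward", "reverse")) {
  direction <- match.arg(direction)
  fix_side <- function(x) {
    if (is.null(x) || nrow(x) == 0)
      return(data.frame(compound = character(0), compartment = character(0),
                        coef = numeric(0), stringsAsFactors = FALSE))
    stopifnot(all(c("compound", "compartment", "coef") %in% names(x)))
    if (any(x$coef <= 0)) gem_stop("stoichiometric coefficients must be positive")
    if (any(!nzchar(x$compound))) gem_stop("compound ids must be non-empty")
    data.frame(compound = as.character(x$compound),
               compartment = as.character(x$compartment),
               coef = as.numeric(x$coef),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(left = fix_side(left), right = fix_side(right),
                 direction = direction),
            class = "gem_equation")
}

eq_side <- function(compound, compartment = "", coef = 1) {
  data.frame(compound = compound,
             compartment = rep_len(compartment, length(compound)),
             coef = rep_len(coef, length(compound)),
             stringsAsFactors = FALSE)
}

parse_term <- function(term, global_cmpt, text) {
  orig <- term
  coef <- 1
  m <- regmatches(term, regexec("^\\(([0-9]+(\\.[0-9]+)?)\\)\\s+(.*)$", term))[[1]]
  if (length(m)) {
    coef <- as.numeric(m[2])
    term <- m[4]
  } else {
    # bare numeric coefficient must be a standalone token ("2 A" but not
    # "2-Oxoglutarate")
    m <- regmatches(term, regexec("^([0-9]+(\\.[0-9]+)?)\\s+(.*)$", term))[[1]]
    if (length(m)) {
      coef <- as.numeric(m[2])
      term <- m[4]
    }
  }
  cmpt <- global_cmpt
  m <- regmatches(term, regexec("^(.*)\\[([A-Za-z0-9_]+)\\]$", term))[[1]]
  if (length(m)) {
    term <- m[2]
    cmpt <- m[3]
  }
  term <- trimws(term)
  if (!nzchar(term))
    gem_stop("empty compound name in term '", orig, "' of equation '", text,
             "'", class = "gem_parse_error")
  # a lone "+" or one set off by whitespace is a dangling separator, not a
  # compound name ("H+" and "NAD+" remain legal)
  if (term == "+" || grepl("\\s\\+$|^\\+\\s", term))
    gem_stop("dangling '+' in term '", orig, "' of equation '", text, "'",
             class = "gem_parse_error")
  if (coef <= 0)
    gem_stop("non-positive coefficient in term '", orig, "'",
             class = "gem_parse_error")
  eq_side(term, cmpt, coef)
}

parse_side <- function(side, global_cmpt, text) {
  side <- trimws(side)
  if (!nzchar(side)) return(NULL)
  terms <- strsplit(side, "\\s\\+\\s")[[1]]
  do.call(rbind, lapply(terms, parse_term, global_cmpt = global_cmpt,
                        text = text))
}

#' Parse a reaction equation from text
#'
#' @param text Equation string, e.g. `"[c]: A + (2) B <==> C"`.
#' @return A [equation()] object.  A global compartment prefix `"[x]:"` is
#'   applied to every compound lacking its own suffix; coefficients default
#'   to 1; one side may be empty (exchange form).
#' @export
parse_equation <- function(text) {
  if (!is_string(text)) gem_stop("equation must be a single string")
  s <- trimws(text)
  global_cmpt <- ""
  m <- regmatches(s, regexec("^\\[([A-Za-z0-9_]+)\\]\\s*:\\s*(.*)$", s))[[1]]
  if (length(m)) {
    global_cmpt <- m[2]
    s <- m[3]
  }
  # locate the arrow: must be a whitespace-delimited token (or at an end)
  arrow_re <- "(^|\\s)(<==>|<=>|-->|<--|=>|<=)(\\s|$)"
  am <- regexpr(arrow_re, s)
  if (am == -1)
    gem_stop("no reaction arrow found in equation '", text, "'",
             class = "gem_parse_error")
  tok <- regmatches(s, am)
  arrow <- trimws(tok)
  lhs <- substr(s, 1, am - 1)
  rhs <- substr(s, am + attr(am, "match.length"), nchar(s))
  if (grepl(arrow_re, rhs))
    gem_stop("multiple arrows in equation '", text, "'",
             class = "gem_parse_error")
  left <- parse_side(lhs, global_cmpt, text)
  right <- parse_side(rhs, global_cmpt, text)
  if (is.null(left) && is.null(right))
    gem_stop("both sides empty in equation '", text, "'",
             class = "gem_parse_error")
  equation(left, right, direction = ARROWS[[arrow]])
}

#' Render a reaction equation as text
#'
#' Produces the canonical textual form that [parse_equation()] reads back
#' to an identical equation.  When every compound shares one non-empty
#' compartment and the equation has at least two terms, the compact global
#' form `"[c]: ..."` is used; otherwise each compound carries its own
#' `"[x]"` suffix.
#'
#' @param eq A [equation()] object.
#' @return A single string.
#' @export
render_equation <- function(eq) {
  stopifnot(inherits(eq, "gem_equation"))
  all_terms <- rbind(eq$left, eq$right)
  cmpts <- unique(all_terms$compartment)
  global <- length(cmpts) == 1 && nzchar(cmpts) && nrow(all_terms) >= 2
  term_txt <- function(side) {
    if (nrow(side) == 0) return("")
    paste(vapply(seq_len(nrow(side)), function(i) {
      nm <- side$compound[i]
      if (!global && nzchar(side$compartment[i]))
        nm <- paste0(nm, "[", side$compartment[i], "]")
      if (side$coef[i] != 1) paste0("(", num_fmt(side$coef[i]), ") ", nm)
      else nm
    }, character(1)), collapse = " + ")
  }
  arrow <- switch(eq$direction, both = "<==>", forward = "-->",
                  reverse = "<--")
  lhs <- term_txt(eq$left)
  rhs <- term_txt(eq$right)
  body <- trimws(paste(lhs, arrow, rhs))
  if (global) paste0("[", cmpts, "]: ", body) else body
}

#' @export
print.gem_equation <- function(x, ...) {
  cat(render_equation(x), "\n")
  invisible(x)
}

#' @export
format.gem_equation <- function(x, ...) render_equation(x)

# key used for matrix rows: "base" or "base[cmpt]"
compound_key <- function(compound, compartment = "") {
  ifelse(nzchar(compartment), paste0(compound, "[", compartment, "]"),
         compound)
}

# net stoichiometry of an equation: named numeric over compound keys,
# negative for consumed (left), positive for produced (right)
equation_stoichiometry <- function(eq) {
  keys <- c(compound_key(eq$left$compound, eq$left$compartment),
            compound_key(eq$right$compound, eq$right$compartment))
  vals <- c(-eq$left$coef, eq$right$coef)
  out <- tapply(vals, factor(keys, levels = unique(keys)), sum)
  out <- stats::setNames(as.numeric(out), names(out))
  out[out != 0]
}

# compounds appearing on both sides of the equation (validation flag)
equation_duplicates <- function(eq) {
  intersect(compound_key(eq$left$compound, eq$left$compartment),
            compound_key(eq$right$compound, eq$right$compartment))
}

equations_equal <- function(a, b) {
  isTRUE(all.equal(a$left, b$left, check.attributes = FALSE)) &&
    isTRUE(all.equal(a$right, b$right, check.attributes = FALSE)) &&
    a$direction == b$direction
}

# rewrite an equation so that its operative direction is "forward"
# ("reverse" equations have their sides swapped); "both" is unchanged
normalize_equation <- function(eq) {
  if (eq$direction != "reverse") return(eq)
  equation(eq$right, eq$left, direction = "forward")
}

# chemically reversed copy: products become reactants (direction kept
# "forward"); used for gap-filling reversal candidates
reverse_equation <- function(eq) {
  eq <- normalize_equation(eq)
  equation(eq$right, eq$left, direction = "forward")
}
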