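#' Parse a chemical formula into an element composition
#'
#' Parses a Hill-style formula such as `"C6H12O6"` into a named numeric
#' vector of element counts.  Parenthesized groups with an integer
#' multiplier (e.g. `"C2H3(CH2)2COOH"`) are expanded.
#'
#' @param text Formula string.
#' @return Named numeric vector mapping element symbols to counts; elements
#'   with zero count are absent.  An empty formula gives a zero-length
#'   vector.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C2H3(CH2)2COOH")
#' @export
parse_formula <- function(text) {
  if (!is_string(text)) gem_stop("formula must be a single string")
  s <- gsub("\\s", "", text)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos > n) "" else substr(s, pos, pos)
  read_count <- function() {
    start <- pos
    while (grepl("[0-9]", peek())) pos <<- pos + 1L
    if (pos == start) return(1)
    as.numeric(substr(s, start, pos - 1L))
  }
  parse_group <- function() {
    comp <- numeric(0)
    repeat {
      ch <- peek()
      if (ch == "") break
      if (ch == ")") break
      if (ch == "(") {
        open_at <- pos
        pos <<- pos + 1L
        inner <- parse_group()
        if (peek() != ")")
          gem_stop("unbalanced parenthesis in formula '", text,
                   "' opened at position ", open_at, class = "gem_parse_error")
        pos <<- pos + 1L
        k <- read_count()
        comp <- composition_add(comp, composition_scale(inner, k))
      } else if (grepl("[A-Z]", ch)) {
        sym <- ch
        pos <<- pos + 1L
        while (grepl("[a-z]", peek())) {
          sym <- paste0(sym, peek())
          pos <<- pos + 1L
        }
        k <- read_count()
        add <- k
        names(add) <- sym
        comp <- composition_add(comp, add)
      } else {
        gem_stop("unexpected token '", ch, "' at position ", pos,
                 " in formula '", text, "'", class = "gem_parse_error")
      }
    }
    comp
  }
  out <- parse_group()
  if (peek() == ")")
    gem_stop("dangling ')' at position ", pos, " in formula '", text, "'",
             class = "gem_parse_error")
  out
}

#' Elementwise arithmetic on element compositions
#'
#' Compositions are named numeric vectors as returned by [parse_formula()].
#' `composition_add` sums two compositions, `composition_scale` multiplies
#' all counts, and `composition_diff` returns `a - b`.  Zero entries are
#' dropped so equal compositions compare equal with `identical` on sorted
#' names.
#'
#' @param a,b Compositions (named numeric vectors).
#' @param k Scalar multiplier.
#' @return A composition.
#' @export
composition_add <- function(a, b) {
  all_el <- union(names(a), names(b))
  out <- vapply(all_el, function(e) {
    va <- if (e %in% names(a)) a[[e]] else 0
    vb <- if (e %in% names(b)) b[[e]] else 0
    va + vb
  }, numeric(1))
  composition_clean(out)
}

#' @rdname composition_add
#' @export
composition_scale <- function(a, k) composition_clean(a * k)

#' @rdname composition_add
#' @export
composition_diff <- function(a, b) composition_add(a, composition_scale(b, -1))

composition_clean <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  x[order(names(x))]
}

composition_equal <- function(a, b) {
  length(composition_diff(a, b)) == 0
}

render_formula <- function(comp) {
  if (length(comp) == 0) return("")
  comp <- composition_clean(comp)
  # Hill order: C, H, then alphabetic
  el <- names(comp)
  ord <- order(match(el, c("C", "H"), nomatch = 3L), el)
  paste0(vapply(el[ord], function(e) {
    k <- comp[[e]]
    if (k == 1) e else paste0(e, num_fmt(k))
  }, character(1)), collapse = "")
}
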