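# Delimited-table import/export and small model-interfacing helpers.

#' Import a model from delimited text tables
#'
#' The reaction table must have a header; columns are assigned to model
#' fields via `mapping` (defaults to matching header names).  Any row
#' whose cell count differs from the header is reported with its row
#' number -- the "column shift" failure mode of hand-edited tables.
#' Unmapped columns are preserved in each reaction's `extra` data.
#'
#' @param reaction_file Path to the reaction table.
#' @param compound_file Optional path to a compound table (columns `id`,
#'   `name`, `formula`, `charge` as available).
#' @param mapping Named character vector mapping model fields (`id`,
#'   `equation`, `genes`, `subsystem`, `ec`, `name`) to column names.
#'   Defaults to identically named columns.
#' @param sep Field separator (default tab).
#' @param synonyms Optional named character vector mapping misspelled
#'   compound identifiers (as they appear in equations) to corrected
#'   ones; applied after parsing.
#' @param name Model name.
#' @return A [gem_model()].
#' @export
import_table <- function(reaction_file, compound_file = NULL,
                         mapping = NULL, sep = "\t", synonyms = NULL,
                         name = "imported") {
  read_strict <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    cells <- strsplit(lines, sep, fixed = TRUE)
    # strsplit drops trailing empty fields; restore them from the
    # separator count so genuinely empty cells are not miscounted
    nsep <- lengths(regmatches(lines, gregexpr(sep, lines, fixed = TRUE)))
    cells <- Map(function(cc, k) c(cc, rep("", k + 1L - length(cc))),
                 cells, nsep)
    header <- cells[[1]]
    n <- length(header)
    for (i in seq_along(cells)[-1]) {
      if (length(cells[[i]]) != n)
        gem_stop("row ", i, " of '", path, "' has ", length(cells[[i]]),
                 " columns, expected ", n,
                 " (possible column shift)")
    }
    body <- cells[-1]
    df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
    names(df) <- header
    df
  }
  tab <- read_strict(reaction_file)
  field_col <- function(field) {
    col <- if (!is.null(mapping) && field %in% names(mapping))
      mapping[[field]] else field
    if (col %in% names(tab)) col else NULL
  }
  id_col <- field_col("id")
  eq_col <- field_col("equation")
  if (is.null(id_col) || is.null(eq_col))
    gem_stop("reaction table needs 'id' and 'equation' columns ",
             "(directly or via mapping)")
  mapped <- vapply(c("id", "equation", "genes", "subsystem", "ec", "name"),
                   function(f) field_col(f) %||% NA_character_,
                   character(1))
  reactions <- lapply(seq_len(nrow(tab)), function(i) {
    eq <- parse_equation(tab[[eq_col]][i])
    if (!is.null(synonyms)) {
      ren <- function(side) {
        hit <- side$compound %in% names(synonyms)
        side$compound[hit] <- unname(synonyms[side$compound[hit]])
        side
      }
      eq <- equation(ren(eq$left), ren(eq$right), eq$direction)
    }
    getf <- function(f) {
      col <- mapped[[f]]
      if (is.na(col)) return(NULL)
      v <- tab[[col]][i]
      if (!nzchar(v)) NULL else v
    }
    extra_cols <- setdiff(names(tab), stats::na.omit(mapped))
    extra <- as.list(tab[i, extra_cols, drop = FALSE])
    reaction_entry(tab[[id_col]][i], eq, genes = getf("genes"),
                   name = getf("name"), subsystem = getf("subsystem"),
                   ec = getf("ec"), extra = extra)
  })
  compounds <- list()
  if (!is.null(compound_file)) {
    ctab <- read_strict(compound_file)
    if (!"id" %in% names(ctab))
      gem_stop("compound table needs an 'id' column")
    compounds <- lapply(seq_len(nrow(ctab)), function(i) {
      gv <- function(col) {
        if (!col %in% names(ctab)) return(NULL)
        v <- ctab[[col]][i]
        if (!nzchar(v)) NULL else v
      }
      compound_entry(ctab$id[i], name = gv("name"), formula = gv("formula"),
                     charge = if (!is.null(gv("charge")))
                       as.integer(gv("charge")))
    })
  }
  suppressWarnings(gem_model(name = name, reactions = reactions,
                             compounds = compounds))
}

#' Export the model's reactions as a delimited table
#'
#' @param model A [gem_model()].
#' @param file Output path or `""` for standard output.
#' @param sep Field separator.
#' @return The file path, invisibly.
#' @export
export_table <- function(model, file = "", sep = "\t") {
  header <- c("id", "equation", "genes", "subsystem", "ec")
  rows <- vapply(model$reactions, function(r) {
    paste(c(r$id, render_equation(r$equation),
            if (is.null(r$genes)) "" else render_gene_rule(r$genes),
            r$subsystem %||% "", r$ec %||% ""), collapse = sep)
  }, character(1))
  con <- if (identical(file, "")) stdout() else file
  writeLines(c(paste(header, collapse = sep), rows), con = con)
  invisible(file)
}

#' Detect the biomass reaction
#'
#' First priority: the unique reaction with a non-zero objective
#' coefficient (as read from COBRA-dialect SBML).  Fallback: reaction
#' ids containing the string "biomass" (case-insensitive).  Ties are
#' resolved to the first reaction in model order, with a warning.
#'
#' @param model A [gem_model()].
#' @param objectives Named numeric vector of objective coefficients by
#'   reaction id (may be empty).
#' @return A reaction id, or `NULL` when nothing matches.
#' @export
detect_biomass <- function(model, objectives = numeric(0)) {
  nz <- names(objectives)[objectives != 0]
  nz <- intersect(names(model$reactions), nz)
  if (length(nz) >= 1) {
    if (length(nz) > 1)
      gem_warn("multiple reactions carry objective coefficients (",
               paste(nz, collapse = ", "), "); using '", nz[1], "'")
    return(nz[1])
  }
  hits <- names(model$reactions)[grepl("biomass", names(model$reactions),
                                       ignore.case = TRUE)]
  if (length(hits) >= 1) {
    if (length(hits) > 1)
      gem_warn("multiple reaction ids match 'biomass' (",
               paste(hits, collapse = ", "), "); using '", hits[1], "'")
    return(hits[1])
  }
  NULL
}

#' Search compounds or reactions
#'
#' Case-insensitive substring match on ids and names.
#'
#' @param model A [gem_model()].
#' @param query Substring to look for.
#' @param domain `"compound"` or `"reaction"`.
#' @return A list of matching entries (possibly empty).
#' @export
search_model <- function(model, query, domain = c("compound", "reaction")) {
  domain <- match.arg(domain)
  q <- tolower(query)
  hit <- function(entry) {
    grepl(q, tolower(entry$id), fixed = TRUE) ||
      (!is.null(entry$name) && grepl(q, tolower(entry$name), fixed = TRUE))
  }
  pool <- if (domain == "compound") model$compounds else model$reactions
  Filter(hit, pool)
}
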