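# Native YAML model format.
#
# A model is a directory with a central model.yaml:
#
#   name: my model
#   biomass: BIO
#   default_flux_limit: 1000
#   compounds:
#     - include: compounds.yaml
#   reactions:
#     - include: reactions.yaml
#     - include: tca-cycle.tsv          # tab-delimited tables work too
#   media:
#     - compound: A
#       compartment: e
#       lower: -10
#   limits:
#     - reaction: r1
#       lower: 0
#       upper: 5
#   model:
#     - include: model_rxn.tsv          # optional model subset
#
# Sections may be inlined or split across included files (transparent
# either way); includes resolve relative to the including file and may
# nest, but not cycle.  Reading uses the yaml package; writing uses a
# purpose-built line-oriented emitter so that a one-field edit changes
# exactly one line (friendly to line-based version control).

RESERVED_REACTION_KEYS <- c("id", "name", "equation", "genes", "subsystem",
                            "ec")
RESERVED_COMPOUND_KEYS <- c("id", "name", "formula", "charge", "boundary")

# resolve a section into a flat list of records, expanding includes
resolve_section <- function(entries, base_dir, visited) {
  out <- list()
  for (e in entries) {
    if (is.list(e) && !is.null(e$include)) {
      path <- file.path(base_dir, e$include)
      npath <- normalizePath(path, mustWork = FALSE)
      if (npath %in% visited)
        gem_stop("cyclic include: '", e$include, "'")
      if (!file.exists(path))
        gem_stop("included file not found: '", path, "'")
      if (grepl("\\.(tsv|csv|tab)$", path, ignore.case = TRUE)) {
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
        tab <- utils::read.table(path, sep = sep, header = TRUE,
                                 stringsAsFactors = FALSE, quote = "",
                                 comment.char = "", check.names = FALSE)
        recs <- lapply(seq_len(nrow(tab)), function(i) {
          rec <- as.list(tab[i, , drop = FALSE])
          names(rec) <- names(tab)
          rec
        })
        out <- c(out, recs)
      } else {
        sub <- yaml::read_yaml(path)
        out <- c(out, resolve_section(sub, dirname(path),
                                      c(visited, npath)))
      }
    } else {
      out <- c(out, list(e))
    }
  }
  out
}

record_to_reaction <- function(rec) {
  extra <- rec[setdiff(names(rec), RESERVED_REACTION_KEYS)]
  reaction_entry(as.character(rec$id), rec$equation,
                 genes = if (!is.null(rec$genes)) as.character(rec$genes),
                 name = rec$name, subsystem = rec$subsystem, ec = rec$ec,
                 extra = extra)
}

record_to_compound <- function(rec) {
  extra <- rec[setdiff(names(rec), RESERVED_COMPOUND_KEYS)]
  compound_entry(as.character(rec$id), name = rec$name,
                 formula = rec$formula,
                 charge = if (!is.null(rec$charge)) as.integer(rec$charge),
                 boundary = isTRUE(rec$boundary), extra = extra)
}

#' Read a model from the native YAML format
#'
#' @param path Path to the central `model.yaml` file, or to a directory
#'   containing one.
#' @return A [gem_model()].
#' @export
read_gem_yaml <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "model.yaml")
  if (!file.exists(path)) gem_stop("model file not found: '", path, "'")
  base_dir <- dirname(path)
  root <- yaml::read_yaml(path)
  visited <- normalizePath(path)
  rxn_recs <- resolve_section(root$reactions %||% list(), base_dir, visited)
  cpd_recs <- resolve_section(root$compounds %||% list(), base_dir, visited)
  reactions <- lapply(rxn_recs, record_to_reaction)
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    gem_stop("duplicate reaction id '", ids[duplicated(ids)][1],
             "' in model files")
  compounds <- lapply(cpd_recs, record_to_compound)
  media <- list()
  for (me in root$media %||% list()) {
    if (!is.null(me$compounds)) {
      # grouped form: a list of per-compound settings
      media <- c(media, lapply(me$compounds, as.list))
    } else media <- c(media, list(as.list(me)))
  }
  limits <- lapply(root$limits %||% list(), as.list)
  subset_recs <- resolve_section(root$model %||% list(), base_dir, visited)
  model_subset <- if (length(subset_recs)) {
    vapply(subset_recs, function(x) {
      if (is.list(x)) as.character(x$id %||% x[[1]]) else as.character(x)
    }, character(1))
  } else NULL
  gem_model(name = root$name %||% "model",
            reactions = reactions, compounds = compounds,
            biomass = root$biomass,
            media = media, limits = limits, model_subset = model_subset,
            default_flux_limit = root$default_flux_limit %||% 1000)
}

# --- deterministic writer -------------------------------------------------

yaml_scalar <- function(x) {
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(num_fmt(x))
  s <- as.character(x)
  if (grepl("^[A-Za-z0-9_][A-Za-z0-9_ .,+()/-]*$", s) &&
      !grepl("^(true|false|yes|no|null)$", s, ignore.case = TRUE) &&
      !grepl("^[0-9.+-]", s) && !grepl("[ ]$", s))
    return(s)
  paste0("'", gsub("'", "''", s), "'")
}

emit_record <- function(rec, keys) {
  # first line "- key: value", following "  key: value"
  lines <- character(0)
  first <- TRUE
  for (k in keys) {
    v <- rec[[k]]
    if (is.null(v)) next
    prefix <- if (first) "- " else "  "
    lines <- c(lines, paste0(prefix, k, ": ", yaml_scalar(v)))
    first <- FALSE
  }
  lines
}

reaction_record <- function(r) {
  rec <- list(id = r$id, name = r$name,
              equation = render_equation(r$equation),
              genes = if (!is.null(r$genes)) render_gene_rule(r$genes),
              subsystem = r$subsystem, ec = r$ec)
  c(rec, r$extra)
}

compound_record <- function(cp) {
  rec <- list(id = cp$id, name = cp$name, formula = cp$formula,
              charge = cp$charge,
              boundary = if (isTRUE(cp$boundary)) TRUE)
  c(rec, cp$extra)
}

#' Write a model in the native YAML format
#'
#' Produces `model.yaml`, `compounds.yaml` and `reactions.yaml` in the
#' given directory.  Serialization is deterministic and line-oriented
#' (one scalar field per line, fixed key order, records in model order),
#' so edits produce minimal diffs and
#' `read_gem_yaml(write_gem_yaml(m))` reproduces `m`.
#'
#' @param model A [gem_model()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_gem_yaml <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpd_lines <- unlist(lapply(model$compounds, function(cp) {
    rec <- compound_record(cp)
    emit_record(rec, names(rec))
  })) %||% character(0)
  writeLines(cpd_lines, file.path(dir, "compounds.yaml"))
  # media-created exchanges regenerate on read; do not serialize them
  auto <- vapply(model$reactions,
                 function(r) isTRUE(r$extra$auto_exchange), logical(1))
  rxn_lines <- unlist(lapply(model$reactions[!auto], function(r) {
    rec <- reaction_record(r)
    rec$extra <- NULL
    emit_record(rec, names(rec))
  })) %||% character(0)
  writeLines(rxn_lines, file.path(dir, "reactions.yaml"))
  lines <- c(paste0("name: ", yaml_scalar(model$name)),
             if (!is.null(model$biomass))
               paste0("biomass: ", yaml_scalar(model$biomass)),
             paste0("default_flux_limit: ",
                    num_fmt(model$default_flux_limit)),
             "compounds:",
             "  - include: compounds.yaml",
             "reactions:",
             "  - include: reactions.yaml")
  if (length(model$media)) {
    lines <- c(lines, "media:")
    for (me in model$media) {
      # references to auto-created exchanges regenerate on read
      if (!is.null(me$reaction) &&
          isTRUE(model$reactions[[me$reaction]]$extra$auto_exchange))
        me$reaction <- NULL
      keys <- intersect(c("compound", "compartment", "reaction",
                          "lower", "upper"), names(me))
      lines <- c(lines, paste0("  ",
                               emit_record(me[keys], keys)))
    }
  }
  if (length(model$limits)) {
    lines <- c(lines, "limits:")
    for (le in model$limits) {
      keys <- intersect(c("reaction", "lower", "upper"), names(le))
      lines <- c(lines, paste0("  ", emit_record(le[keys], keys)))
    }
  }
  if (!is.null(model$model_subset)) {
    auto_ids <- names(model$reactions)[auto]
    lines <- c(lines, "model:")
    for (rid in setdiff(model$model_subset, auto_ids))
      lines <- c(lines, paste0("  - id: ", yaml_scalar(rid)))
  }
  writeLines(lines, file.path(dir, "model.yaml"))
  invisible(dir)
}
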