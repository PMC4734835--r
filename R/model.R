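# The metabolic model container: reactions, compounds, biomass designation,
# media (exchange) definitions, explicit flux limits and the default flux
# bound, plus the sparse stoichiometric matrix view consumed by every
# analysis.

#' Create a reaction entry
#'
#' @param id Reaction identifier, unique within a model.
#' @param equation A [equation()] object or equation string.
#' @param genes Optional gene-protein-reaction rule (string or
#'   [parse_gene_rule()] tree).
#' @param name,subsystem,ec Optional annotation fields.
#' @param extra Named list of arbitrary additional annotation, preserved
#'   verbatim through read/write round trips.
#' @return An object of class `gem_reaction`.
#' @export
reaction_entry <- function(id, equation, genes = NULL, name = NULL,
                           subsystem = NULL, ec = NULL, extra = list()) {
  if (!is_string(id) || !nzchar(id)) gem_stop("reaction id must be non-empty")
  if (is.character(equation)) equation <- parse_equation(equation)
  stopifnot(inherits(equation, "gem_equation"))
  if (is.character(genes)) genes <- parse_gene_rule(genes)
  structure(list(id = id, equation = equation, genes = genes, name = name,
                 subsystem = subsystem, ec = ec, extra = extra),
            class = "gem_reaction")
}

#' Create a compound entry
#'
#' @param id Compound base identifier (without compartment).
#' @param name Optional human-readable name.
#' @param formula Optional chemical formula string (see [parse_formula()]).
#' @param charge Optional integer charge.
#' @param boundary Whether the compound is a boundary species (external to
#'   the mass balance; excluded from the stoichiometric matrix).
#' @param extra Named list of arbitrary additional annotation.
#' @return An object of class `gem_compound`.
#' @export
compound_entry <- function(id, name = NULL, formula = NULL, charge = NULL,
                           boundary = FALSE, extra = list()) {
  if (!is_string(id) || !nzchar(id)) gem_stop("compound id must be non-empty")
  structure(list(id = id, name = name, formula = formula, charge = charge,
                 boundary = boundary, extra = extra),
            class = "gem_compound")
}

#' Assemble a metabolic model
#'
#' Validates cross-references and auto-registers compounds that appear in
#' equations but have no entry (with a warning).  Media entries that do not
#' name an existing exchange reaction get one auto-created
#' (`EX_<compound>_<compartment>`).
#'
#' @param name Model name.
#' @param reactions List of [reaction_entry()] objects.
#' @param compounds List of [compound_entry()] objects.
#' @param biomass Optional id of the biomass (objective) reaction.
#' @param media Optional list of media entries, each a list with fields
#'   `compound`, `compartment` (optional), `reaction` (optional), `lower`,
#'   `upper` (all bounds optional).
#' @param limits Optional list of limit entries `list(reaction, lower,
#'   upper)` overriding default bounds per side.
#' @param model_subset Optional character vector of reaction ids that make
#'   up the model proper; remaining reactions form the broader database
#'   (used by gap filling).
#' @param default_flux_limit Positive number `x`; reversible reactions
#'   default to bounds `[-x, x]`, irreversible to `[0, x]`.
#' @return An object of class `gem_model`.  Validation warnings are
#'   attached as the `"validation"` attribute.
#' @export
gem_model <- function(name = "model", reactions = list(),
                      compounds = list(), biomass = NULL, media = list(),
                      limits = list(), model_subset = NULL,
                      default_flux_limit = 1000) {
  if (!is.numeric(default_flux_limit) || default_flux_limit <= 0)
    gem_stop("default_flux_limit must be positive")
  notes <- character(0)
  rxn <- list()
  for (r in reactions) {
    stopifnot(inherits(r, "gem_reaction"))
    if (r$id %in% names(rxn)) gem_stop("duplicate reaction id '", r$id, "'")
    rxn[[r$id]] <- r
  }
  cpd <- list()
  for (cp in compounds) {
    stopifnot(inherits(cp, "gem_compound"))
    if (cp$id %in% names(cpd)) gem_stop("duplicate compound id '", cp$id, "'")
    cpd[[cp$id]] <- cp
  }
  # auto-register compounds referenced only in equations
  for (r in rxn) {
    for (side in list(r$equation$left, r$equation$right)) {
      for (cname in setdiff(unique(side$compound), names(cpd))) {
        cpd[[cname]] <- compound_entry(cname)
        notes <- c(notes, paste0("compound '", cname,
                                 "' auto-registered from equation of '",
                                 r$id, "'"))
      }
    }
    dup <- equation_duplicates(r$equation)
    if (length(dup))
      notes <- c(notes, paste0("reaction '", r$id,
                               "' has compound(s) on both sides: ",
                               paste(dup, collapse = ", ")))
  }
  if (!is.null(biomass) && !biomass %in% names(rxn))
    gem_stop("biomass reaction '", biomass, "' not in model")
  if (!is.null(model_subset)) {
    bad <- setdiff(model_subset, names(rxn))
    if (length(bad))
      gem_stop("model subset names unknown reaction(s): ",
               paste(bad, collapse = ", "))
  }
  # media entries: resolve or create the exchange reaction they configure
  media_out <- list()
  for (mentry in media) {
    me <- as.list(mentry)
    if (is.null(me$reaction)) {
      if (is.null(me$compound))
        gem_stop("media entry needs a 'compound' or 'reaction' field")
      cmpt <- me$compartment %||% ""
      key <- compound_key(me$compound, cmpt)
      ex_id <- NULL
      for (r in rxn) {
        if (!is_exchange_equation(r$equation)) next
        st <- equation_stoichiometry(r$equation)
        if (length(st) == 1 && names(st) == key) { ex_id <- r$id; break }
      }
      if (is.null(ex_id)) {
        ex_id <- paste0("EX_", me$compound, if (nzchar(cmpt)) paste0("_", cmpt))
        if (ex_id %in% names(rxn))
          gem_stop("cannot auto-create exchange '", ex_id, "': id taken")
        rxn[[ex_id]] <- reaction_entry(
          ex_id, equation(eq_side(me$compound, cmpt), NULL, "both"),
          extra = list(auto_exchange = TRUE))
        notes <- c(notes, paste0("exchange reaction '", ex_id,
                                 "' auto-created for media compound '",
                                 key, "'"))
        if (!is.null(model_subset)) model_subset <- c(model_subset, ex_id)
      }
      me$reaction <- ex_id
    } else if (!me$reaction %in% names(rxn)) {
      gem_stop("media entry names unknown reaction '", me$reaction, "'")
    }
    media_out[[length(media_out) + 1L]] <- me
  }
  lim_out <- list()
  for (lentry in limits) {
    le <- as.list(lentry)
    if (is.null(le$reaction))
      gem_stop("limit entry needs a 'reaction' field")
    if (!le$reaction %in% names(rxn))
      gem_stop("limits name unknown reaction '", le$reaction, "'")
    lim_out[[le$reaction]] <- le
  }
  model <- structure(list(name = name, reactions = rxn, compounds = cpd,
                          biomass = biomass, media = media_out,
                          limits = lim_out, model_subset = model_subset,
                          default_flux_limit = default_flux_limit),
                     class = "gem_model")
  # reversibility vs explicit-bound conflicts are recorded, not fatal
  for (rid in names(lim_out)) {
    bb <- resolve_bounds(rxn[[rid]], lim_out[[rid]], default_flux_limit,
                         warn = FALSE)
    if (attr(bb, "conflict"))
      notes <- c(notes, paste0("limits for '", rid,
                               "' conflict with equation reversibility"))
  }
  attr(model, "validation") <- notes
  model
}

is_exchange_equation <- function(eq) {
  nrow(eq$left) == 0 || nrow(eq$right) == 0
}

#' Reaction ids of exchange reactions
#'
#' Exchange (boundary) reactions are those with an empty equation side.
#'
#' @param model A [gem_model()].
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  ids <- names(model$reactions)
  ids[vapply(model$reactions,
             function(r) is_exchange_equation(r$equation), logical(1))]
}

#' Reaction ids included in the model proper
#'
#' Either `model_subset` (in its stated order) or all reactions.
#'
#' @param model A [gem_model()].
#' @return Character vector of reaction ids.
#' @export
model_reactions <- function(model) {
  model$model_subset %||% names(model$reactions)
}

#' Resolve the flux bounds of one reaction
#'
#' Defaults follow the equation direction: `both` gives `(-x, x)`,
#' `forward` gives `(0, x)`, `reverse` gives `(-x, 0)` where `x` is the
#' default flux limit.  An explicit limit overrides per side; a media
#' bound applies where no explicit limit does.
#'
#' @param reaction A [reaction_entry()].
#' @param limit Optional `list(lower=, upper=)` explicit override.
#' @param default_limit Positive default flux limit.
#' @param warn Emit a warning when the explicit bounds conflict with the
#'   equation's stated reversibility.
#' @return Numeric `c(lower, upper)`.
#' @export
resolve_bounds <- function(reaction, limit = NULL, default_limit = 1000,
                           warn = TRUE) {
  x <- default_limit
  base <- switch(reaction$equation$direction,
                 both = c(-x, x), forward = c(0, x), reverse = c(-x, 0))
  lo <- base[1]; hi <- base[2]
  conflict <- FALSE
  if (!is.null(limit)) {
    if (!is.null(limit$lower)) lo <- limit$lower
    if (!is.null(limit$upper)) hi <- limit$upper
    dir <- reaction$equation$direction
    if ((dir == "forward" && lo < 0) || (dir == "reverse" && hi > 0)) {
      conflict <- TRUE
      if (warn)
        gem_warn("bounds (", lo, ", ", hi, ") for '", reaction$id,
                 "' conflict with its ", dir, " direction")
    }
  }
  if (lo > hi)
    gem_stop("lower bound ", lo, " exceeds upper bound ", hi,
             " for reaction '", reaction$id, "'")
  structure(c(lo, hi), conflict = conflict)
}

# effective bounds for one reaction id, applying limits > media > defaults
model_bounds <- function(model, rid) {
  lim <- model$limits[[rid]]
  if (is.null(lim)) {
    for (me in model$media) {
      if (identical(me$reaction, rid)) {
        x <- model$default_flux_limit
        lo <- me$lower %||% -x
        hi <- me$upper %||% x
        return(c(lo, hi))
      }
    }
  }
  as.numeric(resolve_bounds(model$reactions[[rid]], lim,
                            model$default_flux_limit, warn = FALSE))
}

#' Build the sparse stoichiometric matrix view of a model
#'
#' Rows are compartmentalized compounds (keys like `"glc[c]"`), columns
#' are the reactions of the model subset.  Entries are negative for
#' consumed (left-side) compounds and positive for produced ones.
#' Boundary compounds are excluded from the rows, which makes them
#' unconstrained external pools.
#'
#' @param model A [gem_model()].
#' @param unrestricted_exchanges Widen all exchange-reaction bounds to
#'   `[-x, x]` (used by flux-consistency checking to neutralize medium
#'   settings).
#' @return A list of class `gem_matrix` with elements `S` (a
#'   `Matrix::dgCMatrix`), `bounds` (two-column matrix, rows named by
#'   reaction), `reactions` and `compounds` (the dimension names).
#' @export
matrix_view <- function(model, unrestricted_exchanges = FALSE) {
  rids <- model_reactions(model)
  boundary_ids <- names(model$compounds)[vapply(model$compounds,
                                                function(cp) isTRUE(cp$boundary),
                                                logical(1))]
  triplets <- list()
  keys <- character(0)
  for (j in seq_along(rids)) {
    st <- equation_stoichiometry(model$reactions[[rids[j]]]$equation)
    if (length(boundary_ids)) {
      base <- sub("\\[[^]]*\\]$", "", names(st))
      st <- st[!(base %in% boundary_ids)]
    }
    if (!length(st)) next
    triplets[[length(triplets) + 1L]] <-
      data.frame(key = names(st), j = j, v = as.numeric(st),
                 stringsAsFactors = FALSE)
  }
  tri <- if (length(triplets)) do.call(rbind, triplets)
         else data.frame(key = character(0), j = integer(0), v = numeric(0))
  keys <- unique(tri$key)
  S <- Matrix::sparseMatrix(i = match(tri$key, keys), j = tri$j, x = tri$v,
                            dims = c(length(keys), length(rids)),
                            dimnames = list(keys, rids))
  bounds <- t(vapply(rids, function(rid) model_bounds(model, rid),
                     numeric(2)))
  colnames(bounds) <- c("lower", "upper")
  if (unrestricted_exchanges) {
    x <- model$default_flux_limit
    ex <- intersect(exchange_reactions(model), rids)
    bounds[ex, "lower"] <- -x
    bounds[ex, "upper"] <- x
  }
  structure(list(S = S, bounds = bounds, reactions = rids,
                 compounds = keys),
            class = "gem_matrix")
}

#' @export
print.gem_model <- function(x, ...) {
  cat("Metabolic model '", x$name, "'\n", sep = "")
  cat("  reactions: ", length(x$reactions),
      if (!is.null(x$model_subset))
        paste0(" (model subset: ", length(x$model_subset), ")"), "\n",
      sep = "")
  cat("  compounds: ", length(x$compounds), "\n", sep = "")
  cat("  biomass:   ", x$biomass %||% "<none>", "\n", sep = "")
  cat("  exchanges: ", length(exchange_reactions(x)), "\n", sep = "")
  notes <- attr(x, "validation")
  if (length(notes))
    cat("  validation notes: ", length(notes), "\n", sep = "")
  invisible(x)
}

#' @export
print.gem_reaction <- function(x, ...) {
  cat(x$id, "\t", render_equation(x$equation), "\n", sep = "")
  invisible(x)
}
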