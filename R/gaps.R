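# Gap analysis: locate compounds that cannot be produced (GapFind) and
# propose a minimum-penalty set of additions that restores production
# (GapFill).  Both are MILPs over a relaxed mass balance S v >= 0 --
# accumulation is allowed, so "producible" means net production can be
# driven to at least epsilon.

gap_epsilon <- function(model) 1e-3 * model$default_flux_limit

# production-indicator pairs: (compound row, reaction col) that can push
# the compound's net production up: forward use of a product, or reverse
# use of a reactant
producing_pairs <- function(mv) {
  out <- list()
  for (j in seq_along(mv$reactions)) {
    col <- mv$S[, j]
    nz <- which(col != 0)
    for (i in nz) {
      if ((col[i] > 0 && mv$bounds[j, 2] > 0) ||
          (col[i] < 0 && mv$bounds[j, 1] < 0))
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

#' Find unproducible (blocked) compounds
#'
#' MILP with a binary production indicator per compound: a compound
#' counts as produced when some reaction pushes at least `epsilon` of it
#' into its pool, under the relaxed balance `S v >= 0` and the flux
#' bounds.  The number of produced compounds is maximized; the rest are
#' the blocked compounds.  `root_gaps` are the topological subset with no
#' producing reaction at all.
#'
#' @param model A [gem_model()].
#' @param epsilon Production threshold; defaults to `1e-3` of the default
#'   flux limit.
#' @param solver Solver backend name (must support MILP).
#' @return An object of class `gem_gap_report`: `blocked_compounds`,
#'   `root_gaps`, `produced`.
#' @export
gapfind <- function(model, epsilon = gap_epsilon(model),
                    solver = default_solver()) {
  mv <- matrix_view(model)
  bigM <- model$default_flux_limit *
    max(1, max(abs(mv$S))) + epsilon
  p <- lp_problem()
  for (j in seq_along(mv$reactions))
    lp_add_variable(p, mv$reactions[j], mv$bounds[j, 1], mv$bounds[j, 2])
  for (i in seq_along(mv$compounds)) {
    row <- mv$S[i, ]
    nz <- which(row != 0)
    lp_add_constraint(p, stats::setNames(as.numeric(row[nz]),
                                         mv$reactions[nz]), ">=", 0)
  }
  pairs <- producing_pairs(mv)
  has_producer <- logical(length(mv$compounds))
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    has_producer[i] <- TRUE
    xn <- paste0("x:", mv$compounds[i], ":", mv$reactions[j])
    lp_add_variable(p, xn, 0, 1, type = "binary")
    # x = 1  ->  S[i,j] * v[j] >= epsilon
    lp_add_constraint(p, stats::setNames(c(mv$S[i, j], -bigM),
                                         c(mv$reactions[j], xn)),
                      ">=", epsilon - bigM)
  }
  for (i in seq_along(mv$compounds)) {
    wn <- paste0("w:", mv$compounds[i])
    lp_add_variable(p, wn, 0, 1, type = "binary")
    pj <- Filter(function(pr) pr[1] == i, pairs)
    if (length(pj) == 0) {
      lp_add_constraint(p, stats::setNames(1, wn), "<=", 0)
    } else {
      coefs <- stats::setNames(
        c(1, rep(-1, length(pj))),
        c(wn, vapply(pj, function(pr)
          paste0("x:", mv$compounds[pr[1]], ":", mv$reactions[pr[2]]),
          character(1))))
      lp_add_constraint(p, coefs, "<=", 0)
    }
  }
  lp_set_objective(p, stats::setNames(rep(1, length(mv$compounds)),
                                      paste0("w:", mv$compounds)), "max")
  sol <- lp_solve(p, solver)
  if (sol$status != "optimal")
    gem_stop("GapFind MILP reported status '", sol$status, "'",
             class = "gem_solver_error")
  w <- sol$assignment[paste0("w:", mv$compounds)]
  produced <- mv$compounds[w > 0.5]
  blocked <- setdiff(mv$compounds, produced)
  structure(list(blocked_compounds = blocked,
                 root_gaps = mv$compounds[!has_producer],
                 produced = produced, epsilon = epsilon),
            class = "gem_gap_report")
}

#' Propose reactions that close production gaps
#'
#' Chooses a minimum-penalty subset of candidate additions -- database
#' reactions outside the model subset, artificial uptake exchanges for
#' the target compounds, and (optionally) reversals of irreversible model
#' reactions -- such that one flux distribution under `S v >= 0` produces
#' at least `epsilon` of every target compound.
#'
#' @param model A [gem_model()] whose `model_subset` (or full reaction
#'   set) defines the reactions already present.
#' @param database Optional [gem_model()] that is a superset of the model
#'   and supplies candidate reactions.  When `model` itself has a
#'   `model_subset`, its out-of-subset reactions are candidates too.
#' @param targets Compound keys to make producible; defaults to
#'   [gapfind()]'s blocked set.
#' @param penalties Named list with per-origin penalties: `database`,
#'   `reversal`, `exchange`.
#' @param allow_reversals Offer reversed copies of irreversible model
#'   reactions as candidates.
#' @param epsilon Production threshold (see [gapfind()]).
#' @param solver Solver backend name (must support MILP).
#' @return An object of class `gem_gap_proposal`: `added` (data frame
#'   with `id`, `origin`, `penalty`), `targets`, `unfixable`,
#'   `objective`.  When no candidate set suffices, `added` is `NULL` and
#'   `unfixable` lists the targets that cannot be fixed.
#' @export
gapfill <- function(model, database = NULL, targets = NULL,
                    penalties = list(database = 1, reversal = 5,
                                     exchange = 10),
                    allow_reversals = TRUE,
                    epsilon = gap_epsilon(model),
                    solver = default_solver()) {
  if (is.null(targets)) targets <- gapfind(model, epsilon, solver)$blocked_compounds
  if (length(targets) == 0)
    return(structure(list(added = data.frame(id = character(0),
                                             origin = character(0),
                                             penalty = numeric(0),
                                             stringsAsFactors = FALSE),
                          targets = character(0), unfixable = character(0),
                          objective = 0),
                     class = "gem_gap_proposal"))
  model_ids <- model_reactions(model)
  # candidate reactions, each with an origin and penalty
  cand <- list()
  add_cand <- function(id, entry, origin, penalty) {
    cand[[id]] <<- list(entry = entry, origin = origin, penalty = penalty)
  }
  for (rid in setdiff(names(model$reactions), model_ids))
    add_cand(rid, model$reactions[[rid]], "database", penalties$database)
  if (!is.null(database)) {
    for (rid in setdiff(names(database$reactions),
                        c(model_ids, names(cand))))
      add_cand(rid, database$reactions[[rid]], "database",
               penalties$database)
  }
  if (allow_reversals) {
    for (rid in model_ids) {
      r <- model$reactions[[rid]]
      if (r$equation$direction != "both") {
        rev_id <- paste0(rid, "_rev")
        if (!rev_id %in% c(model_ids, names(cand)))
          add_cand(rev_id,
                   reaction_entry(rev_id, reverse_equation(r$equation)),
                   "reversal", penalties$reversal)
      }
    }
  }
  # artificial uptake exchanges only for targets the network knows about:
  # a compound in no reaction at all cannot meaningfully be "produced"
  known_keys <- unique(unlist(c(
    lapply(model$reactions, function(r)
      names(equation_stoichiometry(r$equation))),
    lapply(cand, function(cc)
      names(equation_stoichiometry(cc$entry$equation))))))
  missing_targets <- setdiff(targets, known_keys)
  if (length(missing_targets))
    gem_stop("target compound(s) not in model or database: ",
             paste(missing_targets, collapse = ", "))
  for (ck in targets) {
    ex_id <- paste0("GFEX_", gsub("[^A-Za-z0-9_]", "_", ck))
    base <- sub("\\[[^]]*\\]$", "", ck)
    cmpt <- if (grepl("\\[", ck)) sub("^.*\\[([^]]*)\\]$", "\\1", ck) else ""
    add_cand(ex_id,
             reaction_entry(ex_id, equation(NULL, eq_side(base, cmpt),
                                            "forward")),
             "exchange", penalties$exchange)
  }

  x <- model$default_flux_limit
  p <- lp_problem()
  all_keys <- character(0)
  stoich <- list()   # reaction id -> named stoichiometry
  bounds <- list()
  for (rid in model_ids) {
    stoich[[rid]] <- equation_stoichiometry(model$reactions[[rid]]$equation)
    bounds[[rid]] <- model_bounds(model, rid)
  }
  for (cid in names(cand)) {
    eq <- cand[[cid]]$entry$equation
    stoich[[cid]] <- equation_stoichiometry(eq)
    bounds[[cid]] <- as.numeric(resolve_bounds(cand[[cid]]$entry, NULL, x,
                                               warn = FALSE))
  }
  for (rid in names(stoich)) all_keys <- union(all_keys, names(stoich[[rid]]))
  for (rid in model_ids)
    lp_add_variable(p, rid, bounds[[rid]][1], bounds[[rid]][2])
  for (cid in names(cand)) {
    lp_add_variable(p, cid, min(bounds[[cid]][1], 0),
                    max(bounds[[cid]][2], 0))
    yn <- paste0("y:", cid)
    lp_add_variable(p, yn, 0, 1, type = "binary")
    # y gates the candidate's flux: y = 0 -> v = 0
    lp_add_constraint(p, stats::setNames(c(1, -max(bounds[[cid]][2], 0)),
                                         c(cid, yn)), "<=", 0)
    lp_add_constraint(p, stats::setNames(c(1, -min(bounds[[cid]][1], 0)),
                                         c(cid, yn)), ">=", 0)
  }
  for (ck in all_keys) {
    coefs <- numeric(0)
    for (rid in names(stoich)) {
      v <- stoich[[rid]][ck]
      if (!is.na(v)) coefs[rid] <- v
    }
    lp_add_constraint(p, coefs, ">=", if (ck %in% targets) epsilon else 0)
  }
  lp_set_objective(p, stats::setNames(
    vapply(names(cand), function(cid) cand[[cid]]$penalty, numeric(1)),
    paste0("y:", names(cand))), "min")
  sol <- lp_solve(p, solver)
  if (sol$status != "optimal") {
    if (length(targets) == 1)
      return(structure(list(added = NULL, targets = targets,
                            unfixable = targets, objective = NA_real_),
                       class = "gem_gap_proposal"))
    # identify which targets cannot be fixed even singly
    unfix <- character(0)
    for (ck in targets) {
      single <- tryCatch(
        gapfill(model, database, targets = ck, penalties = penalties,
                allow_reversals = allow_reversals, epsilon = epsilon,
                solver = solver),
        error = function(e) NULL)
      if (is.null(single) || is.null(single$added) ||
          !is.null(single$unfixable) && length(single$unfixable))
        unfix <- c(unfix, ck)
    }
    return(structure(list(added = NULL, targets = targets,
                          unfixable = if (length(unfix)) unfix else targets,
                          objective = NA_real_),
                     class = "gem_gap_proposal"))
  }
  y <- sol$assignment[paste0("y:", names(cand))]
  chosen <- names(cand)[y > 0.5]
  added <- data.frame(
    id = chosen,
    origin = vapply(chosen, function(cid) cand[[cid]]$origin, character(1)),
    penalty = vapply(chosen, function(cid) cand[[cid]]$penalty, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(added = added, targets = targets, unfixable = character(0),
                 objective = sol$objective,
                 proposed_entries = lapply(chosen,
                                           function(cid) cand[[cid]]$entry)),
            class = "gem_gap_proposal")
}

#' Apply a gap proposal to a model
#'
#' Adds the proposed reactions (database reactions, reversals, artificial
#' exchanges) to the model, extending `model_subset` when present, so the
#' closure property can be re-checked with [gapfind()].
#'
#' @param model A [gem_model()].
#' @param proposal A `gem_gap_proposal` from [gapfill()].
#' @return The extended [gem_model()].
#' @export
apply_gap_proposal <- function(model, proposal) {
  if (is.null(proposal$added) || nrow(proposal$added) == 0) return(model)
  rxns <- unname(model$reactions)
  have <- names(model$reactions)
  subset <- model$model_subset
  for (entry in proposal$proposed_entries) {
    if (!entry$id %in% have) rxns <- c(rxns, list(entry))
    if (!is.null(subset)) subset <- union(subset, entry$id)
  }
  suppressWarnings(
    gem_model(name = model$name, reactions = rxns,
              compounds = unname(model$compounds), biomass = model$biomass,
              media = model$media, limits = unname(model$limits),
              model_subset = subset,
              default_flux_limit = model$default_flux_limit))
}

#' @export
print.gem_gap_report <- function(x, ...) {
  cat("Gap report\n")
  cat("  blocked compounds: ", length(x$blocked_compounds), "\n", sep = "")
  if (length(x$blocked_compounds))
    cat("    ", paste(x$blocked_compounds, collapse = ", "), "\n", sep = "")
  cat("  root gaps: ", length(x$root_gaps), "\n", sep = "")
  invisible(x)
}

#' @export
print.gem_gap_proposal <- function(x, ...) {
  cat("Gap-filling proposal\n")
  if (is.null(x$added)) {
    cat("  infeasible; unfixable targets: ",
        paste(x$unfixable, collapse = ", "), "\n", sep = "")
  } else if (nrow(x$added) == 0) {
    cat("  no additions needed\n")
  } else {
    for (i in seq_len(nrow(x$added)))
      cat("  + ", x$added$id[i], " (", x$added$origin[i], ", penalty ",
          num_fmt(x$added$penalty[i]), ")\n", sep = "")
  }
  invisible(x)
}
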