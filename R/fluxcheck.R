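# Flux-consistency (blocked reaction) detection.  A reaction is flux
# inconsistent (blocked) when no steady-state flux distribution
# (S v = 0 within bounds) gives it a non-zero flux.  Two routes: an FVA
# sweep that maximizes (and, for reversibles, minimizes) each reaction on
# one reused LP, and the FASTCC block-elimination scheme that certifies
# many reactions per LP.

# one steady-state LP over the matrix view; the problem is built once and
# only the objective (or bounds) mutated afterwards
steady_state_problem <- function(mv) {
  p <- lp_problem()
  for (j in seq_along(mv$reactions))
    lp_add_variable(p, mv$reactions[j], mv$bounds[j, 1], mv$bounds[j, 2])
  for (i in seq_along(mv$compounds)) {
    row <- mv$S[i, ]
    nz <- which(row != 0)
    if (!length(nz)) next
    lp_add_constraint(p, stats::setNames(as.numeric(row[nz]),
                                         mv$reactions[nz]), "=", 0)
  }
  p
}

#' Flux consistency check by FVA sweep
#'
#' Builds the steady-state LP once and, reusing it with only the
#' objective changing, maximizes each reaction's flux (and minimizes it
#' for reactions that can run in reverse).  A reaction is consistent iff
#' some direction attains a flux beyond `tol`.
#'
#' @param model A [gem_model()].
#' @param unrestricted_exchanges Widen exchange bounds to the default
#'   flux limit in both directions before the sweep, removing the
#'   influence of the medium.
#' @param tol Flux classification tolerance.
#' @param solver Solver backend name.
#' @return An object of class `gem_fluxcheck`: list with `consistent` and
#'   `blocked` (character vectors partitioning the checked reactions) and
#'   `method`.
#' @export
fluxcheck_fva <- function(model, unrestricted_exchanges = FALSE,
                          tol = 1e-6, solver = default_solver()) {
  mv <- matrix_view(model, unrestricted_exchanges = unrestricted_exchanges)
  p <- steady_state_problem(mv)
  consistent <- character(0)
  for (j in seq_along(mv$reactions)) {
    rid <- mv$reactions[j]
    lp_set_objective(p, stats::setNames(1, rid), "max")
    smax <- lp_solve(p, solver)
    ok <- smax$status == "optimal" && smax$objective > tol
    if (!ok && mv$bounds[j, 1] < -tol) {
      lp_set_objective(p, stats::setNames(1, rid), "min")
      smin <- lp_solve(p, solver)
      ok <- smin$status == "optimal" && smin$objective < -tol
    }
    if (ok) consistent <- c(consistent, rid)
  }
  structure(list(consistent = consistent,
                 blocked = setdiff(mv$reactions, consistent),
                 method = "fva"),
            class = "gem_fluxcheck")
}

#' Flux consistency check by the FASTCC scheme
#'
#' Computes the same consistent/blocked partition as [fluxcheck_fva()]
#' with fewer LP solves: one block LP first pushes all irreversible
#' reactions jointly above `epsilon`, certifying every reaction in the
#' support of the solution at once; remaining candidates are then rescued
#' one at a time, with a direction flip for reversibles.
#'
#' @inheritParams fluxcheck_fva
#' @param epsilon Flux threshold a consistent reaction must attain.
#' @return An object of class `gem_fluxcheck` with `method = "fastcc"`.
#' @export
fluxcheck_fastcc <- function(model, epsilon = 1e-4,
                             unrestricted_exchanges = FALSE,
                             solver = default_solver()) {
  stopifnot(epsilon > 0)
  mv <- matrix_view(model, unrestricted_exchanges = unrestricted_exchanges)
  rids <- mv$reactions
  n <- length(rids)
  p <- steady_state_problem(mv)
  # auxiliary z+_j <= v_j and z-_j <= -v_j, each capped at eps: maximizing
  # a subset of the z pushes those reactions jointly toward at least eps
  # flux in the chosen direction (the LP7 block problem).  The lower bound
  # sits below any feasible flux so untargeted z never constrain v.
  zlb <- -10 * model$default_flux_limit - 1
  for (rid in rids) {
    lp_add_variable(p, paste0("z+", rid), zlb, epsilon)
    lp_add_constraint(p, stats::setNames(c(1, -1), c(paste0("z+", rid), rid)),
                      "<=", 0)
    lp_add_variable(p, paste0("z-", rid), zlb, epsilon)
    lp_add_constraint(p, stats::setNames(c(1, 1), c(paste0("z-", rid), rid)),
                      "<=", 0)
  }
  lp7 <- function(targets, dirs) {
    # dirs: +1 push forward, -1 push backward, per target
    obj <- stats::setNames(rep(1, length(targets)),
                           paste0(ifelse(dirs > 0, "z+", "z-"), targets))
    lp_set_objective(p, obj, "max")
    sol <- lp_solve(p, solver)
    if (sol$status != "optimal")
      gem_stop("FASTCC steady-state LP not optimal: ", sol$status,
               class = "gem_solver_error")
    sol$assignment[rids]
  }
  supp <- function(v) rids[abs(v) >= epsilon * 0.999]
  irrev <- rids[mv$bounds[, 1] >= 0]
  consistent <- character(0)
  if (length(irrev)) {
    v <- lp7(irrev, rep(1, length(irrev)))
    consistent <- union(consistent, supp(v))
  }
  remaining <- setdiff(rids, consistent)
  for (rid in remaining) {
    if (rid %in% consistent) next
    j <- match(rid, rids)
    v <- lp7(rid, 1)
    if (v[rid] >= epsilon * 0.999) {
      consistent <- union(consistent, supp(v))
      next
    }
    if (mv$bounds[j, 1] < 0) {
      v <- lp7(rid, -1)
      if (v[rid] <= -epsilon * 0.999) {
        consistent <- union(consistent, supp(v))
        next
      }
    }
  }
  structure(list(consistent = intersect(rids, consistent),
                 blocked = setdiff(rids, consistent),
                 method = "fastcc"),
            class = "gem_fluxcheck")
}

#' Fraction of blocked reactions per metabolic pathway
#'
#' Aggregates a flux-consistency result over the subsystem annotations of
#' the internal (non-exchange) reactions.  Subsystems absent from
#' `pathway_map` are grouped under `"other"`.
#'
#' @param model A [gem_model()].
#' @param pathway_map Named character vector or list mapping subsystem
#'   names to pathway names; empty means everything lands in `"other"`.
#' @param result A `gem_fluxcheck` result; computed with
#'   [fluxcheck_fva()] defaults when omitted.
#' @param ... Passed to [fluxcheck_fva()] when `result` is missing.
#' @return A data frame with columns `pathway`, `n_reactions`,
#'   `n_blocked`, `fraction`.
#' @export
blocked_fraction_by_subsystem <- function(model, pathway_map = list(),
                                          result = NULL, ...) {
  if (is.null(result)) result <- fluxcheck_fva(model, ...)
  internal <- setdiff(model_reactions(model), exchange_reactions(model))
  sub <- vapply(internal, function(rid)
    model$reactions[[rid]]$subsystem %||% "", character(1))
  pw <- vapply(sub, function(s) {
    if (nzchar(s) && s %in% names(pathway_map)) as.character(pathway_map[[s]])
    else "other"
  }, character(1))
  pws <- unique(pw)
  out <- do.call(rbind, lapply(pws, function(pl) {
    rxns <- internal[pw == pl]
    nb <- sum(rxns %in% result$blocked)
    data.frame(pathway = pl, n_reactions = length(rxns), n_blocked = nb,
               fraction = nb / length(rxns), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.gem_fluxcheck <- function(x, ...) {
  cat("Flux consistency check (", x$method, ")\n", sep = "")
  cat("  consistent: ", length(x$consistent), "\n", sep = "")
  cat("  blocked:    ", length(x$blocked), "\n", sep = "")
  if (length(x$blocked))
    cat("    ", paste(x$blocked, collapse = ", "), "\n", sep = "")
  invisible(x)
}
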