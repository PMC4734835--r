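# Constraint-based simulation: FBA (optionally with thermodynamic loop
# removal), FVA, robustness curves, and random minimal networks.
#
# Loop removal follows the standard indicator formulation: every internal
# (non-exchange) reaction gets a binary direction indicator y and an
# "energy" value G tied to per-compound potential variables mu by
# G = sum_i S[i,j] mu[i].  Flux sign and energy sign are coupled with
# big-M constraints so that flux can only run "downhill"; any internal
# cycle would need potentials strictly decreasing around the cycle, which
# is impossible, so unsupported circulation is forced to zero.

build_fba_problem <- function(mv, loop_removal = "none", internal = NULL,
                              M = 1000) {
  p <- steady_state_problem(mv)
  if (loop_removal == "tfba") {
    cpds <- mv$compounds
    for (ck in cpds) lp_add_variable(p, paste0("mu:", ck), -1000, 1000)
    for (rid in internal) {
      j <- match(rid, mv$reactions)
      lp_add_variable(p, paste0("y:", rid), 0, 1, type = "binary")
      lp_add_variable(p, paste0("G:", rid), -1000, 1000)
      # G = S^T mu for this column
      col <- mv$S[, j]
      nz <- which(col != 0)
      lp_add_constraint(p, stats::setNames(c(as.numeric(col[nz]), -1),
                                           c(paste0("mu:", cpds[nz]),
                                             paste0("G:", rid))), "=", 0)
      # y = 1 -> v in [0, M];  y = 0 -> v in [-M, 0]
      lp_add_constraint(p, stats::setNames(c(1, -M), c(rid, paste0("y:", rid))),
                        "<=", 0)
      lp_add_constraint(p, stats::setNames(c(1, -M), c(rid, paste0("y:", rid))),
                        ">=", -M)
      # y = 1 -> G in [-1000, -1];  y = 0 -> G in [1, 1000]
      lp_add_constraint(p, stats::setNames(c(1, 1001), paste0(c("G:", "y:"), rid)),
                        "<=", 1000)
      lp_add_constraint(p, stats::setNames(c(1, 1001), paste0(c("G:", "y:"), rid)),
                        ">=", 1)
    }
  }
  p
}

#' Flux balance analysis
#'
#' Maximizes the flux of the objective reaction subject to steady state
#' (`S v = 0`) and the resolved flux bounds.  With
#' `loop_removal = "tfba"` thermodynamic loop-law constraints additionally
#' forbid flux through internal cycles that are not supported by
#' exchanges.
#'
#' @param model A [gem_model()].
#' @param objective Objective reaction id; defaults to the model's
#'   biomass reaction.
#' @param loop_removal `"none"` or `"tfba"`.
#' @param solver Solver backend name.
#' @return An object of class `gem_flux_solution`: `objective_reaction`,
#'   `objective_value`, `flux` (named vector), `status`, `loop_removal`.
#'   On an infeasible or unbounded problem the status says so and the
#'   values are `NA` -- no error is thrown.
#' @export
fba <- function(model, objective = model$biomass,
                loop_removal = c("none", "tfba"),
                solver = default_solver()) {
  loop_removal <- match.arg(loop_removal)
  if (is.null(objective)) gem_stop("no objective reaction (no biomass set)")
  if (!objective %in% model_reactions(model))
    gem_stop("objective reaction '", objective, "' not in model")
  mv <- matrix_view(model)
  internal <- setdiff(mv$reactions, exchange_reactions(model))
  p <- build_fba_problem(mv, loop_removal, internal,
                         M = model$default_flux_limit)
  lp_set_objective(p, stats::setNames(1, objective), "max")
  sol <- lp_solve(p, solver)
  flux <- if (sol$status == "optimal") sol$assignment[mv$reactions]
          else stats::setNames(rep(NA_real_, length(mv$reactions)),
                               mv$reactions)
  if (sol$status == "unbounded")
    gem_warn("objective '", objective, "' is unbounded")
  structure(list(objective_reaction = objective,
                 objective_value = if (sol$status == "optimal")
                   sol$objective else NA_real_,
                 flux = flux, status = sol$status,
                 loop_removal = loop_removal),
            class = "gem_flux_solution")
}

#' Flux variability analysis
#'
#' Maximizes the objective, constrains it to stay within
#' `optimum_fraction` of the optimum, and then reports each reaction's
#' attainable flux range over the constrained polytope.  The LP is built
#' once and only the objective is mutated per reaction.
#'
#' @inheritParams fba
#' @param optimum_fraction Fraction of the optimum the objective must
#'   retain, in `(0, 1]`.
#' @return A data frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, objective = model$biomass, optimum_fraction = 1,
                loop_removal = c("none", "tfba"),
                solver = default_solver()) {
  loop_removal <- match.arg(loop_removal)
  stopifnot(optimum_fraction > 0, optimum_fraction <= 1)
  if (is.null(objective)) gem_stop("no objective reaction (no biomass set)")
  mv <- matrix_view(model)
  internal <- setdiff(mv$reactions, exchange_reactions(model))
  p <- build_fba_problem(mv, loop_removal, internal,
                         M = model$default_flux_limit)
  lp_set_objective(p, stats::setNames(1, objective), "max")
  sol <- lp_solve(p, solver)
  if (sol$status != "optimal")
    gem_stop("objective optimization reported status '", sol$status, "'")
  opt <- sol$objective
  lp_add_constraint(p, stats::setNames(1, objective), ">=",
                    optimum_fraction * opt)
  out <- data.frame(reaction = mv$reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(mv$reactions)) {
    rid <- mv$reactions[j]
    lp_set_objective(p, stats::setNames(1, rid), "min")
    out$min[j] <- lp_solve(p, solver)$objective
    lp_set_objective(p, stats::setNames(1, rid), "max")
    out$max[j] <- lp_solve(p, solver)$objective
  }
  attr(out, "objective") <- objective
  attr(out, "optimum") <- opt
  out
}

#' Robustness analysis
#'
#' Sweeps one reaction's flux over its feasible range in `steps` evenly
#' spaced points; at each point the flux is fixed and the objective
#' re-maximized on the same mutated problem.  Infeasible points are
#' recorded (not errors), so the curve always has `steps` entries.
#'
#' @inheritParams fba
#' @param varied Reaction id to sweep.
#' @param steps Number of grid points (at least 2).
#' @return An object of class `gem_robustness`: a data frame with columns
#'   `flux`, `objective`, `status`, plus attributes `varied` and
#'   `objective_reaction`.
#' @export
robustness <- function(model, objective = model$biomass, varied,
                       steps = 10, loop_removal = c("none", "tfba"),
                       solver = default_solver()) {
  loop_removal <- match.arg(loop_removal)
  stopifnot(steps >= 2)
  if (is.null(objective)) gem_stop("no objective reaction (no biomass set)")
  mv <- matrix_view(model)
  if (!varied %in% mv$reactions)
    gem_stop("varied reaction '", varied, "' not in model")
  internal <- setdiff(mv$reactions, exchange_reactions(model))
  p <- build_fba_problem(mv, loop_removal, internal,
                         M = model$default_flux_limit)
  # feasible range of the varied reaction (no objective constraint)
  lp_set_objective(p, stats::setNames(1, varied), "min")
  lo_sol <- lp_solve(p, solver)
  lp_set_objective(p, stats::setNames(1, varied), "max")
  hi_sol <- lp_solve(p, solver)
  if (lo_sol$status != "optimal" || hi_sol$status != "optimal")
    gem_stop("varied reaction range could not be computed")
  lo <- lo_sol$objective
  hi <- hi_sol$objective
  if (hi - lo < 1e-9) {
    gem_warn("varied reaction '", varied, "' is blocked; single-point curve")
    grid <- lo
  } else {
    grid <- lo + (seq_len(steps) - 1) * (hi - lo) / (steps - 1)
  }
  j <- match(varied, mv$reactions)
  orig <- c(mv$bounds[j, 1], mv$bounds[j, 2])
  out <- data.frame(flux = grid, objective = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  lp_set_objective(p, stats::setNames(1, objective), "max")
  for (k in seq_along(grid)) {
    lp_set_bounds(p, varied, grid[k], grid[k])
    sol <- lp_solve(p, solver)
    out$status[k] <- sol$status
    if (sol$status == "optimal") out$objective[k] <- sol$objective
  }
  lp_set_bounds(p, varied, orig[1], orig[2])
  attr(out, "varied") <- varied
  attr(out, "objective_reaction") <- objective
  class(out) <- c("gem_robustness", "data.frame")
  out
}

#' Random minimal network analysis
#'
#' Visits genes (or reactions) in a seeded random order and tentatively
#' deletes each one; a deletion is kept iff the re-optimized objective
#' stays at or above `threshold_fraction` times the wild-type optimum.
#' Because deletions only restrict the feasible set (gene rules are
#' monotone and/or trees), every retained element is essential in the
#' final network: the result is a minimal network.
#'
#' @inheritParams fba
#' @param threshold_fraction Fraction of the wild-type optimum that must
#'   be preserved, in `(0, 1]`.
#' @param mode Delete `"reactions"` or `"genes"`.
#' @param seed Integer seed controlling the deletion order (the only
#'   stochastic element).
#' @return An object of class `gem_minimal_network`: `mode`, `retained`,
#'   `deleted` (in deletion order), `seed`, `objective_value` of the
#'   final network, `threshold`.
#' @export
randomsparse <- function(model, objective = model$biomass,
                         threshold_fraction = 1,
                         mode = c("reactions", "genes"), seed = 1L,
                         solver = default_solver()) {
  mode <- match.arg(mode)
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  if (is.null(objective)) gem_stop("no objective reaction (no biomass set)")
  mv <- matrix_view(model)
  p <- steady_state_problem(mv)
  lp_set_objective(p, stats::setNames(1, objective), "max")
  wt <- lp_solve(p, solver)
  if (wt$status != "optimal" || wt$objective <= 1e-9)
    gem_stop("wild-type objective flux is zero; nothing to minimize")
  threshold <- threshold_fraction * wt$objective
  slack <- 1e-6 * max(1, abs(threshold))

  rids <- mv$reactions
  if (mode == "reactions") {
    candidates <- setdiff(rids, objective)
    order_ids <- with_seed(seed, sample(candidates))
    deleted <- character(0)
    for (rid in order_ids) {
      j <- match(rid, rids)
      lp_set_bounds(p, rid, 0, 0)
      sol <- lp_solve(p, solver)
      if (sol$status == "optimal" && sol$objective >= threshold - slack) {
        deleted <- c(deleted, rid)
      } else {
        lp_set_bounds(p, rid, mv$bounds[j, 1], mv$bounds[j, 2])
      }
    }
    retained <- setdiff(rids, deleted)
  } else {
    genes <- unique(unlist(lapply(model$reactions[rids], function(r)
      if (!is.null(r$genes)) genes_in_rule(r$genes))))
    if (length(genes) == 0) gem_stop("model has no gene associations")
    order_ids <- with_seed(seed, sample(genes))
    deleted <- character(0)
    apply_deletions <- function(del) {
      for (rid in rids) {
        g <- model$reactions[[rid]]$genes
        j <- match(rid, rids)
        if (!is.null(g) && !evaluate_genes(g, del))
          lp_set_bounds(p, rid, 0, 0)
        else
          lp_set_bounds(p, rid, mv$bounds[j, 1], mv$bounds[j, 2])
      }
    }
    for (g in order_ids) {
      trial <- c(deleted, g)
      apply_deletions(trial)
      sol <- lp_solve(p, solver)
      if (sol$status == "optimal" && sol$objective >= threshold - slack)
        deleted <- trial
      else
        apply_deletions(deleted)
    }
    retained <- setdiff(genes, deleted)
  }
  # final network objective
  sol <- lp_solve(p, solver)
  structure(list(mode = mode, retained = retained, deleted = deleted,
                 seed = seed, objective_value = sol$objective,
                 threshold = threshold, wild_type = wt$objective),
            class = "gem_minimal_network")
}

#' @export
print.gem_flux_solution <- function(x, ...) {
  cat("FBA solution (", x$status,
      if (x$loop_removal != "none") ", loop removal: tfba", ")\n", sep = "")
  cat("  objective ", x$objective_reaction, " = ",
      num_fmt(x$objective_value %||% NA_real_), "\n", sep = "")
  invisible(x)
}

#' @export
print.gem_minimal_network <- function(x, ...) {
  cat("Random minimal network (", x$mode, " mode, seed ", x$seed, ")\n",
      sep = "")
  cat("  deleted:  ", length(x$deleted), "\n", sep = "")
  cat("  retained: ", length(x$retained), "\n", sep = "")
  cat("  objective: ", num_fmt(x$objective_value), " (threshold ",
      num_fmt(x$threshold), ")\n", sep = "")
  invisible(x)
}
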