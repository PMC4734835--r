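# Stoichiometric (mass) consistency checking.
#
# A model is mass consistent when strictly positive compound masses m
# exist with S^T m = 0 over the internal reactions.  Two LP variants are
# provided: a compound-based check that locates compounds unable to take
# a positive mass, and a reaction-based check that introduces a signed
# mass residual per reaction and minimizes the total residual bound,
# localizing the unbalanced equations directly.

default_check_exclusions <- function(model) {
  ex <- intersect(exchange_reactions(model), model_reactions(model))
  unique(c(model$biomass, ex))
}

#' Compound-based stoichiometric consistency check
#'
#' Solves: maximize sum(z) subject to `S^T m = 0` over the non-excluded
#' reactions, `m >= z`, `z` in `[0, 1]`, `m >= 0`.  Compounds whose
#' optimal mass stays below 1 cannot carry a positive mass and are the
#' sources of stoichiometric inconsistency.  Compounds in `zero_mass_ok`
#' (used for photons or electrons) carry no positivity requirement and
#' are never flagged.
#'
#' @param model A [gem_model()].
#' @param exclude Reaction ids excluded from the balance requirement;
#'   `NULL` means the default exclusion of the biomass and all exchange
#'   reactions.
#' @param zero_mass_ok Compound keys (e.g. `"photon[c]"`) allowed to have
#'   zero mass.
#' @param tol Classification tolerance on masses.
#' @param solver Solver backend name.
#' @return An object of class `gem_masscheck` with elements `m`, `z`
#'   (named vectors), `flagged` (compound keys with mass below 1),
#'   `objective` (the attained sum of z) and `consistent`.
#' @export
masscheck_compounds <- function(model, exclude = NULL,
                                zero_mass_ok = character(),
                                tol = 1e-6, solver = default_solver()) {
  if (is.null(exclude)) exclude <- default_check_exclusions(model)
  mv <- matrix_view(model)
  rids <- setdiff(mv$reactions, exclude)
  if (length(rids) == 0) gem_stop("no reactions left after exclusions")
  S <- mv$S[, rids, drop = FALSE]
  keep <- Matrix::rowSums(S != 0) > 0
  S <- S[keep, , drop = FALSE]
  cpds <- rownames(S)
  p <- lp_problem()
  for (ck in cpds) lp_add_variable(p, paste0("m:", ck), 0, Inf)
  zc <- setdiff(cpds, zero_mass_ok)
  for (ck in zc) {
    lp_add_variable(p, paste0("z:", ck), 0, 1)
    lp_add_constraint(p, stats::setNames(c(1, -1), paste0(c("m:", "z:"), ck)),
                      ">=", 0)
  }
  for (j in rids) {
    col <- S[, j]
    nz <- which(col != 0)
    if (length(nz) == 0) next    # degenerate all-zero column
    lp_add_constraint(p, stats::setNames(as.numeric(col[nz]),
                                         paste0("m:", cpds[nz])), "=", 0)
  }
  lp_set_objective(p, stats::setNames(rep(1, length(zc)), paste0("z:", zc)),
                   "max")
  sol <- lp_solve(p, solver)
  if (sol$status != "optimal")
    gem_stop("mass-consistency LP reported status '", sol$status, "'",
             class = "gem_solver_error")
  m <- stats::setNames(sol$assignment[paste0("m:", cpds)], cpds)
  z <- stats::setNames(sol$assignment[paste0("z:", zc)], zc)
  flagged <- names(m)[m < 1 - tol & !(names(m) %in% zero_mass_ok)]
  structure(list(type = "compound", m = m, z = z, flagged = flagged,
                 objective = sol$objective, excluded = exclude,
                 consistent = length(flagged) == 0),
            class = "gem_masscheck")
}

#' Reaction-based stoichiometric consistency check
#'
#' Introduces a signed mass residual `r[j]` into every checked reaction,
#' `S^T m = r` with all masses `m >= 1`, bounds the residuals by
#' `|r[j]| <= z[j]` and minimizes `sum(z)`.  Reactions left with a
#' non-zero residual are candidates of inconsistency.  Reactions in
#' `checked` are constrained to a zero residual (the `--checked`
#' workflow: confirm balanced reactions iteratively to converge on the
#' faulty set).
#'
#' The internal residual `r` is oriented as net production
#' (`r = S^T m`); the report also carries `left_minus_right = -r`, the
#' "how many mass units does the left side exceed the right" reading used
#' when comparing hydrogen counts by hand.
#'
#' @inheritParams masscheck_compounds
#' @param checked Reaction ids whose residual is fixed at zero.
#' @return An object of class `gem_masscheck` with elements `m`, `r`,
#'   `z`, `left_minus_right`, `flagged` (reaction ids with `|r| > tol`,
#'   ordered by decreasing `|r|`), `objective` and `consistent`.
#' @export
masscheck_reactions <- function(model, exclude = NULL,
                                checked = character(),
                                zero_mass_ok = character(),
                                tol = 1e-6, solver = default_solver()) {
  if (is.null(exclude)) exclude <- default_check_exclusions(model)
  mv <- matrix_view(model)
  rids <- setdiff(mv$reactions, exclude)
  if (length(rids) == 0) gem_stop("no reactions left after exclusions")
  bad <- setdiff(checked, rids)
  if (length(bad))
    gem_stop("checked reactions not among checked-candidate set: ",
             paste(bad, collapse = ", "))
  S <- mv$S[, rids, drop = FALSE]
  keep <- Matrix::rowSums(S != 0) > 0
  S <- S[keep, , drop = FALSE]
  cpds <- rownames(S)
  p <- lp_problem()
  for (ck in cpds) {
    lo <- if (ck %in% zero_mass_ok) 0 else 1
    lp_add_variable(p, paste0("m:", ck), lo, Inf)
  }
  for (j in rids) {
    fixed <- j %in% checked
    lp_add_variable(p, paste0("r:", j), if (fixed) 0 else -Inf,
                    if (fixed) 0 else Inf)
    lp_add_variable(p, paste0("z:", j), 0, Inf)
    col <- S[, j]
    nz <- which(col != 0)
    lp_add_constraint(p, stats::setNames(c(as.numeric(col[nz]), -1),
                                         c(paste0("m:", cpds[nz]),
                                           paste0("r:", j))), "=", 0)
    # r in [-z, z]
    lp_add_constraint(p, stats::setNames(c(1, -1), paste0(c("r:", "z:"), j)),
                      "<=", 0)
    lp_add_constraint(p, stats::setNames(c(1, 1), paste0(c("r:", "z:"), j)),
                      ">=", 0)
  }
  lp_set_objective(p, stats::setNames(rep(1, length(rids)),
                                      paste0("z:", rids)), "min")
  sol <- lp_solve(p, solver)
  if (sol$status != "optimal")
    gem_stop("reaction-based mass check is infeasible; the 'checked' ",
             "constraints (", paste(checked, collapse = ", "),
             ") contradict the positive-mass requirement",
             class = "gem_solver_error")
  m <- stats::setNames(sol$assignment[paste0("m:", cpds)], cpds)
  r <- stats::setNames(sol$assignment[paste0("r:", rids)], rids)
  z <- stats::setNames(sol$assignment[paste0("z:", rids)], rids)
  flagged <- names(r)[abs(r) > tol]
  flagged <- flagged[order(-abs(r[flagged]), match(flagged, rids))]
  structure(list(type = "reaction", m = m, r = r, z = z,
                 left_minus_right = -r, flagged = flagged,
                 objective = sol$objective, excluded = exclude,
                 checked = checked, consistent = length(flagged) == 0),
            class = "gem_masscheck")
}

#' @export
print.gem_masscheck <- function(x, ...) {
  cat("Stoichiometric consistency check (", x$type, "-based)\n", sep = "")
  if (x$consistent) {
    cat("  model is mass consistent\n")
  } else if (x$type == "compound") {
    cat("  compounds unable to take positive mass:\n")
    for (ck in x$flagged) cat("    ", ck, "\tm=", num_fmt(x$m[[ck]]), "\n",
                              sep = "")
  } else {
    cat("  candidate unbalanced reactions (residual = net production,",
        "lmr = left-minus-right):\n")
    for (rid in x$flagged)
      cat("    ", rid, "\tresidual=", num_fmt(x$r[[rid]]),
          "\tlmr=", num_fmt(x$left_minus_right[[rid]]), "\n", sep = "")
  }
  invisible(x)
}

#' Chemical formula balance check
#'
#' Compares the stoichiometry-weighted total element composition of the
#' two sides of every checked reaction.  Reactions whose compounds lack a
#' formula are skipped (counted in the result).
#'
#' @inheritParams masscheck_compounds
#' @return An object of class `gem_balancecheck`: a list with `results`
#'   (per-reaction list of left/right compositions and their difference),
#'   `flagged` (ids of unbalanced reactions), `skipped` (ids lacking
#'   formulas).
#' @export
formulacheck <- function(model, exclude = NULL) {
  if (is.null(exclude)) exclude <- default_check_exclusions(model)
  balance_check(model, exclude, mode = "formula")
}

#' Charge balance check
#'
#' Like [formulacheck()] but over integer compound charges; the imbalance
#' is the net charge of right minus left.
#'
#' @inheritParams masscheck_compounds
#' @return An object of class `gem_balancecheck` (see [formulacheck()]);
#'   per-reaction results carry the signed net-charge `imbalance`.
#' @export
chargecheck <- function(model, exclude = NULL) {
  if (is.null(exclude)) exclude <- default_check_exclusions(model)
  balance_check(model, exclude, mode = "charge")
}

balance_check <- function(model, exclude, mode) {
  rids <- setdiff(model_reactions(model), exclude)
  results <- list()
  flagged <- character(0)
  skipped <- character(0)
  for (rid in rids) {
    eq <- model$reactions[[rid]]$equation
    ok <- TRUE
    side_total <- function(side) {
      if (mode == "formula") {
        tot <- numeric(0)
        for (i in seq_len(nrow(side))) {
          f <- model$compounds[[side$compound[i]]]$formula
          if (is.null(f)) { ok <<- FALSE; return(NULL) }
          comp <- tryCatch(parse_formula(f), gem_parse_error = function(e) {
            gem_warn("reaction '", rid, "': unparseable formula '", f,
                     "' for compound '", side$compound[i], "'")
            NULL
          })
          if (is.null(comp)) { ok <<- FALSE; return(NULL) }
          tot <- composition_add(tot, composition_scale(comp, side$coef[i]))
        }
        tot
      } else {
        tot <- 0
        for (i in seq_len(nrow(side))) {
          ch <- model$compounds[[side$compound[i]]]$charge
          if (is.null(ch)) { ok <<- FALSE; return(NULL) }
          tot <- tot + ch * side$coef[i]
        }
        tot
      }
    }
    left <- side_total(eq$left)
    right <- if (ok) side_total(eq$right) else NULL
    if (!ok) {
      skipped <- c(skipped, rid)
      next
    }
    if (mode == "formula") {
      diff <- composition_diff(right, left)
      bal <- length(diff) == 0
    } else {
      diff <- right - left
      bal <- diff == 0
    }
    results[[rid]] <- list(reaction = rid, left = left, right = right,
                           imbalance = diff, balanced = bal)
    if (!bal) flagged <- c(flagged, rid)
  }
  structure(list(mode = mode, results = results, flagged = flagged,
                 skipped = skipped, excluded = exclude,
                 consistent = length(flagged) == 0),
            class = "gem_balancecheck")
}

#' @export
print.gem_balancecheck <- function(x, ...) {
  cat(if (x$mode == "formula") "Formula" else "Charge", "balance check\n")
  if (length(x$skipped))
    cat("  skipped (missing ", x$mode, "): ", length(x$skipped),
        " reaction(s)\n", sep = "")
  if (x$consistent) cat("  all checked reactions balanced\n")
  else for (rid in x$flagged) {
    imb <- x$results[[rid]]$imbalance
    txt <- if (x$mode == "formula") render_formula(abs(imb)) else num_fmt(imb)
    cat("    ", rid, "\timbalance (right-left): ", txt, "\n", sep = "")
  }
  invisible(x)
}
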