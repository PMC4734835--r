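# Mutable linear/mixed-integer problem objects and the solver-backend
# registry.  A problem is an environment, so objectives and bounds can be
# modified in place and the problem re-solved without rebuilding -- the
# pattern that makes FVA sweeps and robustness curves cheap.

#' Create an empty linear programming problem
#'
#' Problems are mutable: [lp_add_variable()], [lp_add_constraint()],
#' [lp_set_objective()] and [lp_set_bounds()] modify them in place, and
#' [lp_solve()] can be called repeatedly between modifications.
#'
#' @return An object of class `gem_lp` (an environment).
#' @export
lp_problem <- function() {
  p <- new.env(parent = emptyenv())
  p$vars <- character(0)
  p$lb <- numeric(0)
  p$ub <- numeric(0)
  p$vtype <- character(0)
  p$constraints <- list()
  p$objective <- numeric(0)      # named sparse coefficient vector
  p$direction <- "max"
  class(p) <- "gem_lp"
  p
}

#' Add a variable to a problem
#'
#' @param p A [lp_problem()].
#' @param name Unique variable name.
#' @param lower,upper Bounds (may be `-Inf`/`Inf`).
#' @param type `"continuous"` or `"binary"`.
#' @return The problem, invisibly.
#' @export
lp_add_variable <- function(p, name, lower = -Inf, upper = Inf,
                            type = c("continuous", "binary")) {
  type <- match.arg(type)
  if (name %in% p$vars)
    gem_stop("duplicate variable '", name, "'")
  p$vars <- c(p$vars, name)
  p$lb <- c(p$lb, lower)
  p$ub <- c(p$ub, upper)
  p$vtype <- c(p$vtype, if (type == "binary") "B" else "C")
  invisible(p)
}

#' Add a linear constraint
#'
#' @param p A [lp_problem()].
#' @param coefs Named numeric vector of coefficients over existing
#'   variables.
#' @param rel One of `"<="`, `">="`, `"="`.
#' @param rhs Right-hand-side constant.
#' @return The problem, invisibly.
#' @export
lp_add_constraint <- function(p, coefs, rel, rhs) {
  stopifnot(rel %in% c("<=", ">=", "="))
  unknown <- setdiff(names(coefs), p$vars)
  if (length(unknown))
    gem_stop("constraint references unknown variable(s): ",
             paste(unknown, collapse = ", "))
  p$constraints[[length(p$constraints) + 1L]] <-
    list(coefs = coefs, rel = rel, rhs = rhs)
  invisible(p)
}

#' Set or replace the objective
#'
#' @param p A [lp_problem()].
#' @param coefs Named numeric vector (variables absent get coefficient 0).
#' @param direction `"max"` or `"min"`.
#' @return The problem, invisibly.
#' @export
lp_set_objective <- function(p, coefs, direction = c("max", "min")) {
  direction <- match.arg(direction)
  unknown <- setdiff(names(coefs), p$vars)
  if (length(unknown))
    gem_stop("objective references unknown variable(s): ",
             paste(unknown, collapse = ", "))
  p$objective <- coefs
  p$direction <- direction
  invisible(p)
}

#' Change the bounds of one variable in place
#'
#' @param p A [lp_problem()].
#' @param name Variable name.
#' @param lower,upper New bounds.
#' @return The problem, invisibly.
#' @export
lp_set_bounds <- function(p, name, lower, upper) {
  i <- match(name, p$vars)
  if (is.na(i)) gem_stop("unknown variable '", name, "'")
  if (lower > upper)
    gem_stop("lower bound exceeds upper bound for '", name, "'")
  p$lb[i] <- lower
  p$ub[i] <- upper
  invisible(p)
}

lp_get_bounds <- function(p, name) {
  i <- match(name, p$vars)
  if (is.na(i)) gem_stop("unknown variable '", name, "'")
  c(p$lb[i], p$ub[i])
}

# assemble dense matrices in variable insertion order
lp_assemble <- function(p) {
  n <- length(p$vars)
  m <- length(p$constraints)
  A <- matrix(0, m, n, dimnames = list(NULL, p$vars))
  rel <- character(m)
  b <- numeric(m)
  for (i in seq_len(m)) {
    con <- p$constraints[[i]]
    A[i, names(con$coefs)] <- con$coefs
    rel[i] <- con$rel
    b[i] <- con$rhs
  }
  cvec <- numeric(n)
  names(cvec) <- p$vars
  cvec[names(p$objective)] <- p$objective
  list(cvec = cvec, A = A, rel = rel, b = b, lb = p$lb, ub = p$ub,
       vtype = p$vtype, maximize = p$direction == "max")
}

# --- backend registry -----------------------------------------------------

.gem_solvers <- new.env(parent = emptyenv())

#' Register a solver backend
#'
#' A backend is a function taking the assembled problem pieces
#' (`cvec, A, rel, b, lb, ub, vtype, maximize`) and returning
#' `list(status, x, objective)`.
#'
#' @param name Backend name used with the `solver` argument of analysis
#'   functions and the `--solver` command-line flag.
#' @param fun Solver function.
#' @param milp Whether the backend supports binary variables.
#' @export
register_solver <- function(name, fun, milp = FALSE) {
  assign(name, list(fun = fun, milp = milp), envir = .gem_solvers)
  invisible(name)
}

#' List registered solver backends
#' @return Character vector of backend names.
#' @export
list_solvers <- function() sort(ls(.gem_solvers))

default_solver <- function() getOption("gemflux.solver", "bb")

#' Solve a problem
#'
#' @param p A [lp_problem()].
#' @param solver Backend name (default the bundled simplex/branch-and-bound
#'   backend `"bb"`; see [list_solvers()]).
#' @return A solution: `list(status, objective, assignment)` where
#'   `assignment` is a named numeric vector present when the status is
#'   `"optimal"`.
#' @export
lp_solve <- function(p, solver = default_solver()) {
  if (!exists(solver, envir = .gem_solvers))
    gem_stop("unknown solver backend '", solver, "'; registered: ",
             paste(list_solvers(), collapse = ", "))
  backend <- get(solver, envir = .gem_solvers)
  parts <- lp_assemble(p)
  if (any(parts$vtype == "B") && !backend$milp)
    gem_stop("solver backend '", solver,
             "' does not support binary (MILP) variables",
             class = "gem_solver_error")
  res <- backend$fun(parts$cvec, parts$A, parts$rel, parts$b, parts$lb,
                     parts$ub, parts$vtype, parts$maximize)
  out <- list(status = res$status, objective = res$objective)
  if (identical(res$status, "optimal")) {
    out$assignment <- stats::setNames(res$x, p$vars)
    out$objective <- res$objective
  }
  class(out) <- "gem_lp_solution"
  out
}

solver_bb <- function(cvec, A, rel, b, lb, ub, vtype, maximize) {
  if (any(vtype != "C"))
    milp_solve(cvec, A, rel, b, lb, ub, vtype, maximize = maximize)
  else
    simplex_solve(cvec, A, rel, b, lb, ub, maximize = maximize)
}

# LP-only backend delegating to pracma::linprog; mainly useful as an
# independent cross-check of the bundled simplex.  linprog is only
# dependable in its standard form (x >= 0, A x <= b, Aeq x = beq), so the
# problem is shifted: x = z + lb with z >= 0, upper bounds become rows.
solver_pracma <- function(cvec, A, rel, b, lb, ub, vtype, maximize) {
  if (!requireNamespace("pracma", quietly = TRUE))
    gem_stop("the 'pracma' package is not installed",
             class = "gem_solver_error")
  n <- length(cvec)
  big <- 1e6
  lb2 <- pmax(lb, -big)
  ub2 <- pmin(ub, big)
  shift <- lb2
  b2 <- b - as.numeric(A %*% shift)
  le <- rel == "<="
  ge <- rel == ">="
  eq <- rel == "="
  Ain <- rbind(A[le, , drop = FALSE], -A[ge, , drop = FALSE])
  bin <- c(b2[le], -b2[ge])
  ubrow <- which(is.finite(ub2))
  if (length(ubrow)) {
    U <- matrix(0, length(ubrow), n)
    U[cbind(seq_along(ubrow), ubrow)] <- 1
    Ain <- rbind(Ain, U)
    bin <- c(bin, ub2[ubrow] - shift[ubrow])
  }
  res <- tryCatch(
    pracma::linprog(cc = cvec,
                    A = if (nrow(Ain)) Ain else NULL,
                    b = if (nrow(Ain)) bin else NULL,
                    Aeq = if (any(eq)) A[eq, , drop = FALSE] else NULL,
                    beq = if (any(eq)) b2[eq] else NULL,
                    maxiter = 2000, maximize = maximize),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$x))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  x <- res$x + shift
  list(status = "optimal", x = x, objective = sum(cvec * x))
}

.onLoad <- function(libname, pkgname) {
  register_solver("bb", solver_bb, milp = TRUE)
  register_solver("pracma", solver_pracma, milp = FALSE)
}
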