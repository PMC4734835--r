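# Bounded-variable two-phase primal simplex and a branch-and-bound MILP
# layer on top of it.  Dense linear algebra: the problems built by this
# package are small (tens to a few hundred variables), so robustness and
# determinism are preferred over sparse revised-simplex machinery.  All
# pivot rules are index-deterministic, so repeated solves of the same
# problem give byte-identical answers.

# minimize (or maximize) c'x  subject to  A x <rel> b,  lb <= x <= ub.
# rel is a character vector over {"<=", ">=", "="}.  Returns
# list(status = "optimal"|"infeasible"|"unbounded", x, objective).
simplex_solve <- function(cvec, A, rel, b, lb, ub, maximize = FALSE,
                          tol = 1e-9, max_iter = 50000L) {
  n <- length(cvec)
  m <- length(b)
  if (m == 0L) {
    # bounds-only problem: optimum at the favourable bound of each variable
    cc <- if (maximize) -cvec else cvec
    x <- ifelse(cc > 0, lb, ifelse(cc < 0, ub, ifelse(is.finite(lb), lb,
                                            ifelse(is.finite(ub), ub, 0))))
    if (any(!is.finite(x) & cc != 0))
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x,
                objective = sum(cvec * x)))
  }
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, nrow(A) == m, length(rel) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  cc <- if (maximize) -cvec else cvec

  # slack variables turn every row into an equality
  nslack <- sum(rel != "=")
  Aext <- cbind(A, matrix(0, m, nslack + m))
  slb <- c(lb, numeric(nslack + m))
  sub <- c(ub, numeric(nslack + m))
  k <- n
  for (i in seq_len(m)) {
    if (rel[i] == "<=") {
      k <- k + 1L
      Aext[i, k] <- 1
      slb[k] <- 0; sub[k] <- Inf
    } else if (rel[i] == ">=") {
      k <- k + 1L
      Aext[i, k] <- -1
      slb[k] <- 0; sub[k] <- Inf
    } else if (rel[i] != "=") gem_stop("unknown relation '", rel[i], "'")
  }
  nall <- n + nslack           # structural + slack
  art0 <- nall + 1L            # artificial columns start here

  # initial nonbasic point: finite bound nearest zero, or 0 for free vars
  x <- numeric(nall + m)
  for (j in seq_len(nall)) {
    x[j] <- if (is.finite(slb[j])) slb[j] else if (is.finite(sub[j])) sub[j] else 0
  }
  stat <- integer(nall + m)    # 1 at-lb, 2 at-ub, 3 free-at-zero, 0 basic
  stat[seq_len(nall)] <- ifelse(is.finite(slb[seq_len(nall)]), 1L,
                                ifelse(is.finite(sub[seq_len(nall)]), 2L, 3L))
  resid <- b - as.numeric(Aext[, seq_len(nall), drop = FALSE] %*%
                            x[seq_len(nall)])
  for (i in seq_len(m)) {
    j <- nall + i
    Aext[i, j] <- if (resid[i] >= 0) 1 else -1
    slb[j] <- 0; sub[j] <- Inf
    x[j] <- abs(resid[i])
  }
  basis <- art0:(nall + m)
  stat[basis] <- 0L

  run_phase <- function(cost, basis, stat, x, phase1) {
    ntot <- length(cost)
    iter <- 0L
    bland_after <- 200L * (m + 10L)
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        gem_stop("simplex iteration limit reached", class = "gem_solver_error")
      B <- Aext[, basis, drop = FALSE]
      sol <- tryCatch({
        nb <- which(stat != 0L)
        rhs <- b - as.numeric(Aext[, nb, drop = FALSE] %*% x[nb])
        xb <- solve(B, rhs)
        y <- solve(t(B), cost[basis])
        list(xb = xb, y = y)
      }, error = function(e)
        gem_stop("singular basis in simplex: ", conditionMessage(e),
                 class = "gem_solver_error"))
      x[basis] <- sol$xb
      y <- sol$y
      nb <- which(stat != 0L)
      d <- cost[nb] - as.numeric(crossprod(Aext[, nb, drop = FALSE], y))
      sgn <- stat[nb]
      elig_up <- (sgn == 1L | sgn == 3L) & d < -tol   # enter increasing
      elig_dn <- (sgn == 2L | sgn == 3L) & d > tol    # enter decreasing
      elig <- elig_up | elig_dn
      if (!any(elig)) {
        return(list(basis = basis, stat = stat, x = x,
                    objective = sum(cost * x), status = "optimal",
                    iterations = iter))
      }
      cand <- which(elig)
      if (iter <= bland_after) {
        q_i <- cand[which.max(abs(d[cand]))]
      } else {
        q_i <- cand[which.min(nb[cand])]   # Bland's rule: anti-cycling
      }
      q <- nb[q_i]
      dir <- if (elig_up[q_i]) 1 else -1
      w <- solve(B, Aext[, q])
      # ratio test with stability-aware tie-break
      tvals <- rep(Inf, m)
      for (i in seq_len(m)) {
        delta <- -dir * w[i]
        bi <- basis[i]
        if (delta > 1e-10) {
          room <- sub[bi] - x[bi]
          tvals[i] <- max(room, 0) / delta
        } else if (delta < -1e-10) {
          room <- x[bi] - slb[bi]
          tvals[i] <- max(room, 0) / (-delta)
        }
      }
      t_flip <- if (is.finite(slb[q]) && is.finite(sub[q])) sub[q] - slb[q] else Inf
      t_leave <- min(tvals)
      t_step <- min(t_leave, t_flip)
      if (!is.finite(t_step)) {
        if (phase1)
          gem_stop("phase-1 ray (should not happen)",
                   class = "gem_solver_error")
        return(list(status = "unbounded", x = x, basis = basis, stat = stat,
                    objective = NA_real_, iterations = iter))
      }
      if (t_flip <= t_leave + 1e-12 && is.finite(t_flip)) {
        # bound flip: entering variable moves to its other bound
        x[q] <- x[q] + dir * t_flip
        x[basis] <- x[basis] - t_flip * dir * w
        stat[q] <- if (stat[q] == 1L) 2L else 1L
        next
      }
      near <- which(tvals <= t_leave + 1e-9)
      r <- near[which.max(abs(w[near]))]
      lv <- basis[r]
      x[q] <- x[q] + dir * t_step
      x[basis] <- x[basis] - t_step * dir * w
      # leaving variable lands on one of its bounds
      if (abs(x[lv] - slb[lv]) <= abs(x[lv] - sub[lv])) {
        x[lv] <- slb[lv]; stat[lv] <- 1L
      } else {
        x[lv] <- sub[lv]; stat[lv] <- 2L
      }
      basis[r] <- q
      stat[q] <- 0L
    }
  }

  # phase 1: minimize total artificial infeasibility
  cost1 <- c(numeric(nall), rep(1, m))
  p1 <- run_phase(cost1, basis, stat, x, phase1 = TRUE)
  if (p1$objective > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  # freeze artificials at zero and optimize the real objective
  sub[art0:(nall + m)] <- 0
  x <- p1$x
  x[art0:(nall + m)][x[art0:(nall + m)] < 1e-9] <- 0
  cost2 <- c(cc, numeric(nslack + m))
  p2 <- run_phase(cost2, p1$basis, p1$stat, x, phase1 = FALSE)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  xs <- p2$x[seq_len(n)]
  obj <- sum(cvec * xs)
  list(status = "optimal", x = xs, objective = obj,
       iterations = p2$iterations)
}

# branch-and-bound on top of simplex_solve.  vtype: "C" continuous,
# "B" binary, "I" general integer.  Depth-first, most-fractional
# branching, best-bound pruning.  Deterministic.
milp_solve <- function(cvec, A, rel, b, lb, ub, vtype = NULL,
                       maximize = FALSE, int_tol = 1e-6,
                       max_nodes = 200000L) {
  n <- length(cvec)
  if (is.null(vtype)) vtype <- rep("C", n)
  intv <- which(vtype %in% c("B", "I"))
  lb <- ifelse(vtype == "B", pmax(lb, 0), lb)
  ub <- ifelse(vtype == "B", pmin(ub, 1), ub)
  if (length(intv) == 0)
    return(simplex_solve(cvec, A, rel, b, lb, ub, maximize = maximize))

  sign <- if (maximize) -1 else 1
  best <- NULL
  best_obj <- Inf   # in minimization sense
  nodes <- list(list(lb = lb, ub = ub))
  visited <- 0L
  root_unbounded <- FALSE
  while (length(nodes) > 0) {
    visited <- visited + 1L
    if (visited > max_nodes)
      gem_stop("branch-and-bound node limit reached",
               class = "gem_solver_error")
    node <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    rel_sol <- simplex_solve(cvec, A, rel, b, node$lb, node$ub,
                             maximize = maximize)
    if (rel_sol$status == "infeasible") next
    if (rel_sol$status == "unbounded") {
      if (visited == 1L) root_unbounded <- TRUE
      # an unbounded relaxation cannot be pruned soundly; treat the whole
      # problem as unbounded (integers cannot bound a continuous ray here)
      root_unbounded <- TRUE
      break
    }
    node_obj <- sign * rel_sol$objective
    if (node_obj >= best_obj - 1e-9) next
    frac <- abs(rel_sol$x[intv] - round(rel_sol$x[intv]))
    if (all(frac <= int_tol)) {
      xi <- rel_sol$x
      xi[intv] <- round(xi[intv])
      best <- xi
      best_obj <- node_obj
      next
    }
    j <- intv[which.max(frac)]
    xv <- rel_sol$x[j]
    lo_node <- node; lo_node$ub[j] <- floor(xv)
    hi_node <- node; hi_node$lb[j] <- ceiling(xv)
    # explore the branch nearer the relaxation value first (pushed last)
    if (xv - floor(xv) > 0.5) {
      nodes <- c(nodes, list(lo_node), list(hi_node))
    } else {
      nodes <- c(nodes, list(hi_node), list(lo_node))
    }
  }
  if (root_unbounded)
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  if (is.null(best))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  list(status = "optimal", x = best, objective = sum(cvec * best))
}
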