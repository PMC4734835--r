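# Shared test helpers: random object generators and independent oracles.

# random equation with awkward-but-legal compound names
random_equation <- function() {
  pool <- c("A", "B2", "H+", "D-Glucose 1-phosphate", "co a", "NAD+",
            "x_y", "2-Oxoglutarate")
  cmpts <- c("", "c", "e")
  side <- function(k) {
    if (k == 0) return(NULL)
    nm <- sample(pool, k)
    eq_side(nm, sample(cmpts, k, replace = TRUE),
            sample(c(1, 2, 3, 0.5), k, replace = TRUE))
  }
  nl <- sample(0:3, 1)
  nr <- if (nl == 0) sample(1:3, 1) else sample(0:3, 1)
  equation(side(nl), side(nr),
           direction = sample(c("forward", "reverse", "both"), 1))
}

eq_side <- gemflux:::eq_side
equation <- gemflux::equation

# random gene-rule tree of bounded depth over the given genes
random_gene_tree <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4)
    return(list(op = "id", id = sample(genes, 1)))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  list(op = op, args = replicate(k, random_gene_tree(genes, depth - 1),
                                 simplify = FALSE))
}

# independent gene-rule oracle: textual substitution into an R logical
# expression
eval_rule_text_oracle <- function(text, deleted, genes) {
  expr <- text
  for (g in genes) {
    val <- if (g %in% deleted) "FALSE" else "TRUE"
    expr <- gsub(paste0("\\b", g, "\\b"), val, expr)
  }
  expr <- gsub("\\band\\b", "&", expr)
  expr <- gsub("\\bor\\b", "|", expr)
  eval(parse(text = expr))
}

# dense LP oracle via pracma::linprog (independent of the bundled
# simplex).  linprog is dependable only in standard form, so the oracle
# does its own shift x = z + lb, z >= 0, with upper bounds as rows.
pracma_lp <- function(cvec, A, rel, b, lb, ub, maximize = FALSE) {
  n <- length(cvec)
  lb2 <- pmax(lb, -1e6)
  ub2 <- pmin(ub, 1e6)
  b2 <- b - as.numeric(A %*% lb2)
  le <- rel == "<="
  ge <- rel == ">="
  eq <- rel == "="
  Ain <- rbind(A[le, , drop = FALSE], -A[ge, , drop = FALSE], diag(n))
  bin <- c(b2[le], -b2[ge], ub2 - lb2)
  res <- pracma::linprog(cc = cvec,
                         A = Ain, b = bin,
                         Aeq = if (any(eq)) A[eq, , drop = FALSE] else NULL,
                         beq = if (any(eq)) b2[eq] else NULL,
                         maxiter = 2000, maximize = maximize)
  if (!is.null(res$x)) res$x <- res$x + lb2
  res
}

# check a flux vector against steady state and bounds by direct
# substitution, independently of any solver
expect_steady_state <- function(model, flux, tol = 1e-6) {
  mv <- matrix_view(model)
  v <- flux[mv$reactions]
  imbalance <- as.numeric(mv$S %*% v)
  expect_lt(max(abs(imbalance)), tol)
  expect_true(all(v >= mv$bounds[, "lower"] - tol))
  expect_true(all(v <= mv$bounds[, "upper"] + tol))
}

# directed compound graph of the internal reactions that carry flux;
# loop-free solutions must make it acyclic
flux_graph_is_acyclic <- function(model, flux, tol = 1e-6) {
  edges <- character(0)
  internal <- setdiff(model_reactions(model), exchange_reactions(model))
  for (rid in internal) {
    v <- flux[[rid]]
    if (is.na(v) || abs(v) <= tol) next
    eq <- model$reactions[[rid]]$equation
    from <- gemflux:::compound_key(eq$left$compound, eq$left$compartment)
    to <- gemflux:::compound_key(eq$right$compound, eq$right$compartment)
    if (v < 0) { tmp <- from; from <- to; to <- tmp }
    for (f in from) for (t in to) edges <- c(edges, f, t)
  }
  if (length(edges) == 0) return(TRUE)
  g <- igraph::make_graph(edges, directed = TRUE)
  igraph::is_dag(g)
}

# tiny two-chain model: objective chain plus an independent side chain,
# used for decoupling tests
two_chain_model <- function() {
  gem_model(
    name = "two_chain",
    reactions = list(
      reaction_entry("EX_A", "A[e] <==>"),
      reaction_entry("R_AB", "A[e] --> B[e]"),
      reaction_entry("BIO", "B[e] -->"),
      reaction_entry("EX_C", "C[e] <==>"),
      reaction_entry("R_CD", "C[e] --> D[e]"),
      reaction_entry("EX_D", "D[e] <==>")),
    biomass = "BIO",
    limits = list(list(reaction = "EX_A", lower = -10),
                  list(reaction = "EX_C", lower = -5)))
}
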