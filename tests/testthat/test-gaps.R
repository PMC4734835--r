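test_that("dead-end compounds are found, viable chains are clean", {
  rep_blocked <- gapfind(make_fixture("blocked"))
  expect_true(all(c("C[c]", "D[c]") %in% rep_blocked$blocked_compounds))
  expect_equal(rep_blocked$root_gaps, "C[c]")
  expect_true(all(rep_blocked$root_gaps %in% rep_blocked$blocked_compounds))
  rep_chain <- gapfind(make_fixture("chain"))
  expect_equal(rep_chain$blocked_compounds, character(0))
})

test_that("gapfind agrees with a per-compound LP sweep on random models", {
  # independent oracle: a compound is producible iff some reaction can
  # push at least epsilon of it under the relaxed balance S v >= 0
  sweep_blocked <- function(model, epsilon) {
    mv <- matrix_view(model)
    base <- gemflux:::steady_state_problem(mv)
    # relax the equalities: rebuild with >= 0 rows
    p <- lp_problem()
    for (j in seq_along(mv$reactions))
      lp_add_variable(p, mv$reactions[j], mv$bounds[j, 1], mv$bounds[j, 2])
    for (i in seq_along(mv$compounds)) {
      row <- mv$S[i, ]
      nz <- which(row != 0)
      lp_add_constraint(p, setNames(as.numeric(row[nz]), mv$reactions[nz]),
                        ">=", 0)
    }
    blocked <- character(0)
    for (i in seq_along(mv$compounds)) {
      producible <- FALSE
      for (j in seq_along(mv$reactions)) {
        s <- mv$S[i, j]
        if (s == 0) next
        if (!((s > 0 && mv$bounds[j, 2] > 0) ||
              (s < 0 && mv$bounds[j, 1] < 0))) next
        lp_set_objective(p, setNames(s, mv$reactions[j]), "max")
        sol <- lp_solve(p)
        if (sol$status == "optimal" && sol$objective >= epsilon - 1e-9) {
          producible <- TRUE
          break
        }
      }
      if (!producible) blocked <- c(blocked, mv$compounds[i])
    }
    blocked
  }
  for (seed in c(3, 8, 21, 30)) {
    m <- make_fixture("random", seed = seed, n_compounds = 7,
                      n_reactions = 7)
    found <- gapfind(m)$blocked_compounds
    oracle <- sweep_blocked(m, gemflux:::gap_epsilon(m))
    expect_setequal(found, oracle)
  }
})

test_that("a unique single-reaction fix is proposed for the orphan chain", {
  m <- make_fixture("blocked")
  db <- gem_model(reactions = list(
    reaction_entry("EX_C_db", "C[c] <=>")))
  prop <- gapfill(m, database = db, targets = c("C[c]", "D[c]"),
                  allow_reversals = FALSE)
  expect_equal(prop$added$id, "EX_C_db")
  expect_equal(prop$added$origin, "database")
  expect_equal(prop$objective, 1)
  # closure: after applying the proposal nothing targeted stays blocked
  fixed <- apply_gap_proposal(m, prop)
  expect_equal(intersect(gapfind(fixed)$blocked_compounds,
                         c("C[c]", "D[c]")), character(0))
})

test_that("already-producible targets need no additions", {
  m <- make_fixture("chain")
  prop <- gapfill(m, targets = character(0))
  expect_equal(nrow(prop$added), 0)
  prop2 <- gapfill(m, targets = "B[c]")
  expect_equal(nrow(prop2$added), 0)
  expect_equal(prop2$objective, 0)
})

test_that("the cheaper of two alternative fixes wins", {
  base <- gem_model(name = "gap", reactions = list(
    reaction_entry("EX_A", "A[c] <=>"),
    reaction_entry("r1", "[c]: A => B"),
    reaction_entry("sink_D", "D[c] -->")))
  db <- gem_model(reactions = list(
    reaction_entry("db1", "[c]: B => D")))
  cheap_db <- gapfill(base, database = db, targets = "D[c]",
                      allow_reversals = FALSE,
                      penalties = list(database = 1, reversal = 5,
                                       exchange = 10))
  expect_equal(cheap_db$added$id, "db1")
  # flip the penalties: the artificial exchange becomes the cheaper fix
  cheap_ex <- gapfill(base, database = db, targets = "D[c]",
                      allow_reversals = FALSE,
                      penalties = list(database = 20, reversal = 5,
                                       exchange = 2))
  expect_equal(cheap_ex$added$origin, "exchange")
  expect_equal(cheap_ex$objective, 2)
})

test_that("reversal candidates can close gaps when enabled", {
  # D is consumed by an irreversible reaction; reversing it produces D
  base <- gem_model(name = "revgap", reactions = list(
    reaction_entry("EX_A", "A[c] <=>"),
    reaction_entry("r1", "[c]: A => B"),
    reaction_entry("r2", "[c]: D => B"),
    reaction_entry("sink_D", "D[c] -->")))
  with_rev <- gapfill(base, targets = "D[c]", allow_reversals = TRUE,
                      penalties = list(database = 1, reversal = 5,
                                       exchange = 10))
  expect_equal(with_rev$added$origin, "reversal")
  without <- gapfill(base, targets = "D[c]", allow_reversals = FALSE,
                     penalties = list(database = 1, reversal = 5,
                                      exchange = 10))
  expect_equal(without$added$origin, "exchange")
})

test_that("proposals match brute-force minimal subsets on small databases", {
  # enumerate all candidate subsets and find the minimum total penalty
  # that makes every target producible (feasibility via plain LP)
  brute_min_penalty <- function(model, db, targets, penalties) {
    cand_ids <- names(db$reactions)
    pen <- rep(penalties$database, length(cand_ids))
    best <- Inf
    for (mask in 0:(2^length(cand_ids) - 1)) {
      pick <- cand_ids[bitwAnd(mask, 2^(seq_along(cand_ids) - 1)) > 0]
      cost <- sum(pen[match(pick, cand_ids)])
      if (cost >= best) next
      ext <- suppressWarnings(gem_model(
        name = "ext",
        reactions = c(unname(model$reactions),
                      lapply(pick, function(id) db$reactions[[id]])),
        compounds = unname(model$compounds)))
      mv <- matrix_view(ext)
      p <- lp_problem()
      for (j in seq_along(mv$reactions))
        lp_add_variable(p, mv$reactions[j], mv$bounds[j, 1],
                        mv$bounds[j, 2])
      for (i in seq_along(mv$compounds)) {
        row <- mv$S[i, ]
        nz <- which(row != 0)
        rhs <- if (mv$compounds[i] %in% targets)
          gemflux:::gap_epsilon(model) else 0
        lp_add_constraint(p, setNames(as.numeric(row[nz]),
                                      mv$reactions[nz]), ">=", rhs)
      }
      lp_set_objective(p, setNames(1, mv$reactions[1]), "max")
      if (lp_solve(p)$status == "optimal") best <- min(best, cost)
    }
    best
  }
  base <- gem_model(name = "multi_gap", reactions = list(
    reaction_entry("EX_A", "A[c] <=>"),
    reaction_entry("r1", "[c]: A => B"),
    reaction_entry("sink_D", "D[c] -->"),
    reaction_entry("sink_F", "F[c] -->")))
  db <- gem_model(reactions = list(
    reaction_entry("db1", "[c]: B => D"),
    reaction_entry("db2", "[c]: B => E"),
    reaction_entry("db3", "[c]: E => F"),
    reaction_entry("db4", "[c]: B => D + F")))
  pen <- list(database = 1, reversal = 5, exchange = 1000)
  prop <- gapfill(base, database = db, targets = c("D[c]", "F[c]"),
                  allow_reversals = FALSE, penalties = pen)
  expect_equal(prop$objective,
               brute_min_penalty(base, db, c("D[c]", "F[c]"), pen))
  expect_equal(prop$added$id, "db4")   # the single two-product fix
  fixed <- apply_gap_proposal(base, prop)
  expect_equal(intersect(gapfind(fixed)$blocked_compounds,
                         c("D[c]", "F[c]")), character(0))
})

test_that("targets that exist nowhere are rejected with their names", {
  m <- gem_model(name = "nofix", reactions = list(
    reaction_entry("EX_A", "A[c] <=>"),
    reaction_entry("r1", "[c]: A => B")))
  expect_error(gapfill(m, targets = "Z[q]", allow_reversals = FALSE),
               "Z\\[q\\]")
})
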