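# The reaction-based check minimizes the total residual bound sum(z)
# subject to S^T m = r, m >= 1, |r| <= z; the compound-based check
# maximizes sum(z) subject to S^T m = 0, m >= z, z in [0,1].

test_that("the glucose-phosphate pair localizes a two-proton residual", {
  m <- make_fixture("table3_pair")
  res <- masscheck_reactions(m, exclude = character(0),
                             checked = "RR08939")
  expect_equal(res$flagged, "RR00610")
  expect_equal(unname(res$left_minus_right["RR00610"]), 2)
  expect_equal(unname(res$r["RR08939"]), 0)
  expect_equal(res$objective, 2)
  # the proton carries unit mass at the optimum
  expect_equal(unname(res$m["H+[c]"]), 1)
})

test_that("the uroporphyrinogen pair localizes a seven-proton residual", {
  m <- make_fixture("table3_uro_pair")
  res <- masscheck_reactions(m, exclude = character(0),
                             checked = "IR01815")
  expect_equal(res$flagged, "IR04287")
  expect_equal(unname(res$left_minus_right["IR04287"]), -7)
  expect_equal(unname(res$r["IR01815"]), 0)
})

test_that("a lone balanced reaction carries zero residual", {
  m <- gem_model(reactions = list(reaction_entry(
    "RR08939", "[c]: D-Glucose 1-phosphate <==> D-Glucose 6-phosphate")))
  res <- masscheck_reactions(m, exclude = character(0))
  expect_equal(res$flagged, character(0))
  expect_equal(unname(res$r["RR08939"]), 0)
  expect_equal(res$objective, 0)
})

test_that("the compound check flags the proton in the printed pair", {
  m <- make_fixture("table3_pair")
  res <- masscheck_compounds(m, exclude = character(0))
  expect_equal(res$flagged, "H+[c]")
  expect_equal(res$objective, 2)     # two of three compounds attain z = 1
  expect_lt(unname(res$m["H+[c]"]), 1e-6)
})

test_that("balanced single reactions pass the compound check", {
  m <- gem_model(reactions = list(reaction_entry("r", "[c]: A + B => C")))
  res <- masscheck_compounds(m, exclude = character(0))
  expect_equal(res$flagged, character(0))
  expect_equal(res$objective, 3)
})

test_that("default exclusions hide biomass imbalance; empty exclusions reveal it", {
  # the biomass drain consumes A and emits A + H+: unbalanced by one
  # proton, and the internal A <=> B reaction pins the masses so the
  # imbalance cannot be absorbed
  m <- gem_model(reactions = list(
    reaction_entry("EX_A", "A[c] <=>"),
    reaction_entry("r1", "[c]: A <==> B"),
    reaction_entry("bio", "[c]: A => A + H+")),
    biomass = "bio")
  def <- masscheck_reactions(m)                  # excludes bio + EX_A
  expect_equal(def$flagged, character(0))
  all_in <- masscheck_reactions(m, exclude = character(0))
  expect_true("bio" %in% all_in$flagged)
})

test_that("zero-mass-allowed compounds are never flagged", {
  # photon-driven reaction: A + photon -> B is only balanced with a
  # massless photon
  m <- gem_model(reactions = list(
    reaction_entry("r1", "[c]: A + photon => B"),
    reaction_entry("r2", "[c]: B => A")))
  plain <- masscheck_compounds(m, exclude = character(0))
  expect_true("photon[c]" %in% plain$flagged)
  relaxed <- masscheck_compounds(m, exclude = character(0),
                                 zero_mass_ok = "photon[c]")
  expect_equal(relaxed$flagged, character(0))
  relaxed_r <- masscheck_reactions(m, exclude = character(0),
                                   zero_mass_ok = "photon[c]")
  expect_equal(relaxed_r$flagged, character(0))
})

test_that("contradictory checked constraints give a clear diagnostic", {
  m <- gem_model(reactions = list(
    reaction_entry("r1", "[c]: A => B"),
    reaction_entry("r2", "[c]: A + H+ => B")))
  expect_error(masscheck_reactions(m, exclude = character(0),
                                   checked = c("r1", "r2")),
               "checked")
})

test_that("residual objective matches an independent LP solve on tiny models", {
  skip_if_not_installed("pracma")
  # assemble the LP directly from the equations, independently of the
  # package's problem construction, and solve with pracma
  oracle_sumz <- function(model, checked = character(0)) {
    mv <- matrix_view(model)
    S <- as.matrix(mv$S)
    nc <- nrow(S); nr <- ncol(S)
    # variables: m (nc), r (nr), z (nr)
    cvec <- c(rep(0, nc), rep(0, nr), rep(1, nr))
    A <- rbind(
      cbind(t(S), -diag(nr), matrix(0, nr, nr)),       # S^T m - r = 0
      cbind(matrix(0, nr, nc), diag(nr), -diag(nr)),   # r - z <= 0
      cbind(matrix(0, nr, nc), -diag(nr), -diag(nr)))  # -r - z <= 0
    rel <- c(rep("=", nr), rep("<=", 2 * nr))
    b <- rep(0, 3 * nr)
    lb <- c(rep(1, nc), rep(-1e6, nr), rep(0, nr))
    ub <- rep(1e6, nc + 2 * nr)
    fix <- match(checked, mv$reactions)
    lb[nc + fix] <- 0; ub[nc + fix] <- 0
    res <- pracma_lp(cvec, A, rel, b, lb, ub, maximize = FALSE)
    sum(cvec * res$x)
  }
  pair <- make_fixture("table3_pair")
  expect_equal(masscheck_reactions(pair, exclude = character(0),
                                   checked = "RR08939")$objective,
               oracle_sumz(pair, "RR08939"), tolerance = 1e-6)
  uro <- make_fixture("table3_uro_pair")
  expect_equal(masscheck_reactions(uro, exclude = character(0),
                                   checked = "IR01815")$objective,
               oracle_sumz(uro, "IR01815"), tolerance = 1e-6)
  m3 <- gem_model(reactions = list(
    reaction_entry("a", "[c]: A + H+ => B"),
    reaction_entry("b", "[c]: B => C"),
    reaction_entry("c", "[c]: C => A")))
  expect_equal(masscheck_reactions(m3, exclude = character(0))$objective,
               oracle_sumz(m3), tolerance = 1e-6)
})

test_that("single injected imbalances are localized when the rest is checked", {
  # the published failure mode: a balanced reaction and its proton-shifted
  # variant coexist, making the pair mutually exclusive.  The balanced
  # copy pins the compound masses, so the faulted copy must carry the
  # whole residual.
  for (seed in c(2, 4, 6)) {
    m <- make_fixture("random", seed = seed)
    internal <- setdiff(model_reactions(m), exchange_reactions(m))
    target <- internal[1]
    dup <- reaction_entry(paste0(target, "_bal"),
                          m$reactions[[target]]$equation)
    paired <- gem_model(name = m$name,
                        reactions = c(unname(m$reactions), list(dup)),
                        compounds = unname(m$compounds))
    bad <- inject_fault(paired, list(kind = "add_protons",
                                     reaction = target, k = 2,
                                     side = "left"))
    res <- masscheck_reactions(bad,
                               checked = setdiff(c(internal,
                                                   paste0(target, "_bal")),
                                                 target))
    expect_equal(res$flagged, target, info = paste("seed", seed))
    expect_equal(unname(res$left_minus_right[target]), 2,
                 info = paste("seed", seed))
    # the compound check sees the inconsistency too, the clean model not
    expect_false(masscheck_compounds(bad)$consistent,
                 info = paste("seed", seed))
    expect_true(masscheck_compounds(m)$consistent,
                info = paste("seed", seed))
  }
})

test_that("flag sets are invariant under reordering and renaming", {
  m <- make_fixture("table3_pair")
  res1 <- masscheck_reactions(m, exclude = character(0),
                              checked = "RR08939")
  # reorder reactions
  m2 <- gem_model(name = m$name,
                  reactions = rev(unname(m$reactions)),
                  compounds = unname(m$compounds))
  res2 <- masscheck_reactions(m2, exclude = character(0),
                              checked = "RR08939")
  expect_setequal(res1$flagged, res2$flagged)
  expect_equal(res1$objective, res2$objective)
  # rename compounds consistently
  ren <- function(eq) {
    f <- function(side) { side$compound <- paste0("X_", side$compound); side }
    equation(f(eq$left), f(eq$right), eq$direction)
  }
  m3 <- gem_model(reactions = lapply(unname(m$reactions), function(r)
    reaction_entry(r$id, ren(r$equation))))
  res3 <- masscheck_reactions(m3, exclude = character(0),
                              checked = "RR08939")
  expect_equal(res3$flagged, res1$flagged)
  expect_equal(res3$objective, res1$objective)
})
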