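# Deterministic generators of toy and randomized models, including
# deliberately broken ones, so every algorithm can be exercised without
# any external dataset.  Random models are built by rearranging conserved
# pseudo-element pools, so fault-free instances are elementally balanced
# by construction and carry a known mass certificate.

#' Generate a toy or randomized model
#'
#' Available kinds:
#' \describe{
#'   \item{`chain`}{`EX_A` exchange (uptake limited to 10), transport
#'     `A[e] <=> A[c]`, conversion `A -> B`, biomass sink `B ->`.}
#'   \item{`blocked`}{The chain plus an orphan internal reaction
#'     `C -> D` with no inlet or outlet.}
#'   \item{`loop`}{The chain plus a `B -> A` return reaction forming an
#'     internal 2-cycle with `A -> B`.}
#'   \item{`branched`}{The chain plus a second, redundant route
#'     `A -> C -> B` (two parallel pathways to biomass).}
#'   \item{`table3_pair`}{The glucose-phosphate isomerisation pair
#'     RR00610/RR08939 that differs only by two protons on one side.}
#'   \item{`table3_uro_pair`}{The uroporphyrinogen-III methylation pair
#'     IR04287/IR01815 that differs by six protons and one product
#'     proton.}
#'   \item{`random`}{A random model over `n_elements` conserved
#'     pseudo-elements: every reaction rearranges element pools, so the
#'     model is mass consistent by construction.  Includes exchange
#'     reactions for a few compounds.}
#' }
#'
#' @param kind Fixture kind (see Details).
#' @param seed Integer seed (used by `random`).
#' @param n_compounds,n_reactions,n_elements Size parameters for `random`.
#' @return A [gem_model()].
#' @export
make_fixture <- function(kind = c("chain", "blocked", "loop", "branched",
                                  "table3_pair", "table3_uro_pair",
                                  "random"),
                         seed = 1L, n_compounds = 8L, n_reactions = 10L,
                         n_elements = 4L) {
  kind <- match.arg(kind)
  switch(kind,
         chain = fixture_chain(),
         blocked = fixture_blocked(),
         loop = fixture_loop(),
         branched = fixture_branched(),
         table3_pair = fixture_table3_pair(),
         table3_uro_pair = fixture_table3_uro_pair(),
         random = fixture_random(seed, n_compounds, n_reactions, n_elements))
}

chain_reactions <- function() {
  list(
    reaction_entry("EX_A", "A[e] <==>"),
    reaction_entry("TP_A", "A[e] <==> A[c]", genes = "gT"),
    reaction_entry("R_AB", "A[c] --> B[c]", genes = "g1 or g2"),
    reaction_entry("BIO", "B[c] -->")
  )
}

chain_compounds <- function() {
  list(compound_entry("A", formula = "C2H4O2", charge = 0),
       compound_entry("B", formula = "C2H4O2", charge = 0))
}

fixture_chain <- function() {
  gem_model(name = "toy_chain",
            reactions = chain_reactions(),
            compounds = chain_compounds(),
            biomass = "BIO",
            limits = list(list(reaction = "EX_A", lower = -10)))
}

fixture_blocked <- function() {
  gem_model(name = "toy_blocked",
            reactions = c(chain_reactions(), list(
              reaction_entry("R_CD", "C[c] --> D[c]"))),
            compounds = c(chain_compounds(), list(
              compound_entry("C", formula = "CH2O", charge = 0),
              compound_entry("D", formula = "CH2O", charge = 0))),
            biomass = "BIO",
            limits = list(list(reaction = "EX_A", lower = -10)))
}

fixture_loop <- function() {
  gem_model(name = "toy_loop",
            reactions = c(chain_reactions(), list(
              reaction_entry("R_BA", "B[c] --> A[c]"))),
            compounds = chain_compounds(),
            biomass = "BIO",
            limits = list(list(reaction = "EX_A", lower = -10)))
}

fixture_branched <- function() {
  gem_model(name = "toy_branched",
            reactions = c(chain_reactions(), list(
              reaction_entry("R_AC", "A[c] --> C[c]", genes = "g3"),
              reaction_entry("R_CB", "C[c] --> B[c]", genes = "g4"))),
            compounds = c(chain_compounds(), list(
              compound_entry("C", formula = "C2H4O2", charge = 0))),
            biomass = "BIO",
            limits = list(list(reaction = "EX_A", lower = -10)))
}

# the printed glucose-phosphate pair: the reactions differ only by two
# protons, which makes the pair mutually exclusive in a consistent model
fixture_table3_pair <- function() {
  gem_model(
    name = "table3_pair",
    reactions = list(
      reaction_entry("RR00610",
        "[c]: D-Glucose 1-phosphate + (2) H+ <==> D-Glucose 6-phosphate"),
      reaction_entry("RR08939",
        "[c]: D-Glucose 1-phosphate <==> D-Glucose 6-phosphate")),
    compounds = list(
      compound_entry("D-Glucose 1-phosphate", formula = "C6H13O9P"),
      compound_entry("D-Glucose 6-phosphate", formula = "C6H13O9P"),
      compound_entry("H+", formula = "H", charge = 1)))
}

fixture_table3_uro_pair <- function() {
  gem_model(
    name = "table3_uro_pair",
    reactions = list(
      reaction_entry("IR04287",
        paste0("[c]: Uroporphyrinogen III + (2) S-Adenosyl-L-methionine",
               " --> Precorrin 2 + (2) S-Adenosyl-L-homocysteine + H+")),
      reaction_entry("IR01815",
        paste0("[c]: Uroporphyrinogen III + (6) H+ + (2) ",
               "S-Adenosyl-L-methionine --> Precorrin 2 + (2) ",
               "S-Adenosyl-L-homocysteine"))),
    compounds = list(
      compound_entry("Uroporphyrinogen III"),
      compound_entry("S-Adenosyl-L-methionine"),
      compound_entry("Precorrin 2"),
      compound_entry("S-Adenosyl-L-homocysteine"),
      compound_entry("H+", formula = "H", charge = 1)))
}

# Random balanced model.  Compounds are multisets over a small conserved
# element pool; "monomer" compounds (one element each) guarantee that any
# leftover pool can be expressed, so generated reactions balance exactly.
fixture_random <- function(seed, n_compounds, n_reactions, n_elements) {
  stopifnot(n_elements >= 2, n_compounds >= n_elements, n_reactions >= 1)
  elements <- c("C", "H", "N", "O", "P", "S")[seq_len(min(n_elements, 6L))]
  with_seed(seed, {
    comps <- list()
    vecs <- list()
    # monomers
    for (e in elements) {
      id <- paste0("m", e)
      v <- stats::setNames(numeric(length(elements)), elements)
      v[e] <- 1
      vecs[[id]] <- v
      comps[[id]] <- compound_entry(id, formula = render_formula(v[v > 0]))
    }
    # composite compounds
    for (i in seq_len(n_compounds - length(elements))) {
      id <- paste0("cpd", i)
      v <- stats::setNames(sample(0:3, length(elements), replace = TRUE),
                           elements)
      if (sum(v) == 0) v[sample(length(elements), 1)] <- 1
      vecs[[id]] <- v
      comps[[id]] <- compound_entry(id, formula = render_formula(v[v > 0]))
    }
    ids <- names(vecs)
    # left sides draw from composite compounds only; monomers act as
    # right-side fillers, so a reaction can never cancel to an empty
    # net stoichiometry
    composites <- grep("^cpd", ids, value = TRUE)
    rxns <- list()
    for (r in seq_len(n_reactions)) {
      nl <- min(sample(1:2, 1), length(composites))
      left_ids <- sample(composites, nl)
      left_coef <- sample(1:2, nl, replace = TRUE)
      pool <- Reduce(`+`, Map(function(id, k) vecs[[id]] * k,
                              left_ids, left_coef))
      # draw right-side compounds that fit in the remaining pool
      right_ids <- character(0)
      right_coef <- numeric(0)
      for (attempt in seq_len(3)) {
        cand <- sample(setdiff(ids, left_ids))
        for (id in cand) {
          if (all(vecs[[id]] <= pool) && sum(vecs[[id]]) > 0 &&
              length(right_ids) < 2) {
            right_ids <- c(right_ids, id)
            right_coef <- c(right_coef, 1)
            pool <- pool - vecs[[id]]
          }
        }
      }
      # leftover pool goes to monomers, exactly balancing the reaction
      for (e in elements) {
        if (pool[e] > 0) {
          mid <- paste0("m", e)
          k <- match(mid, right_ids)
          if (!is.na(k)) right_coef[k] <- right_coef[k] + pool[e]
          else {
            right_ids <- c(right_ids, mid)
            right_coef <- c(right_coef, pool[e])
          }
          pool[e] <- 0
        }
      }
      dir <- sample(c("forward", "both"), 1)
      eq <- equation(eq_side(left_ids, "c", left_coef),
                     eq_side(right_ids, "c", right_coef),
                     direction = dir)
      rxns[[length(rxns) + 1L]] <-
        reaction_entry(paste0("r", r), eq,
                       subsystem = sample(c("core", "peripheral"), 1))
    }
    # exchanges for a few compounds keep part of the network flux viable
    ex_for <- sample(ids, min(3L, length(ids)))
    for (id in ex_for) {
      rxns[[length(rxns) + 1L]] <-
        reaction_entry(paste0("EX_", id),
                       equation(eq_side(id, "c"), NULL, "both"))
    }
    gem_model(name = paste0("random_", seed), reactions = rxns,
              compounds = comps)
  })
}

#' Inject a deliberate fault into a model
#'
#' Produces a modified copy; the original model is untouched.  Fault
#' kinds mirror inconsistencies observed in published models:
#' \describe{
#'   \item{`add_protons`}{Add `k` protons to one side of a reaction
#'     (stoichiometric imbalance; caught by the mass-consistency check).}
#'   \item{`shift_compartment`}{Relabel the compartment of one compound in
#'     one reaction (disconnects the network; caught by the
#'     flux-consistency check).}
#'   \item{`duplicate_compound`}{Copy a left-side compound onto the right
#'     side of a reaction (caught by model validation).}
#'   \item{`close_exchange`}{Set an exchange reaction's bounds to zero
#'     (caught by the flux-consistency check).}
#' }
#'
#' @param model A [gem_model()].
#' @param fault A list with `kind` and `reaction`, plus kind-specific
#'   fields: `k` and `side` for `add_protons`; `compound` and
#'   `compartment` for `shift_compartment`; `compound` for
#'   `duplicate_compound`.
#' @return A modified [gem_model()].
#' @export
inject_fault <- function(model, fault) {
  stopifnot(is.list(fault), !is.null(fault$kind))
  rid <- fault$reaction
  if (is.null(rid) || !rid %in% names(model$reactions))
    gem_stop("fault target reaction '", rid %||% "<missing>",
             "' not in model")
  rxns <- model$reactions
  limits <- unname(model$limits)
  eq <- rxns[[rid]]$equation
  if (fault$kind == "add_protons") {
    k <- fault$k %||% 2
    side <- fault$side %||% "left"
    cmpt <- if (nrow(eq$left)) eq$left$compartment[1]
            else eq$right$compartment[1]
    extra <- eq_side("H+", cmpt, k)
    if (side == "left") eq <- equation(rbind(eq$left, extra), eq$right, eq$direction)
    else eq <- equation(eq$left, rbind(eq$right, extra), eq$direction)
  } else if (fault$kind == "shift_compartment") {
    target <- fault$compound
    newc <- fault$compartment %||% "x"
    fix <- function(side) {
      hit <- side$compound == target
      if (!any(hit)) return(side)
      side$compartment[hit] <- newc
      side
    }
    eq <- equation(fix(eq$left), fix(eq$right), eq$direction)
    if (!any(c(eq$left$compartment, eq$right$compartment) == newc))
      gem_stop("fault compound '", target, "' not in reaction '", rid, "'")
  } else if (fault$kind == "duplicate_compound") {
    target <- fault$compound %||% eq$left$compound[1]
    row <- eq$left[eq$left$compound == target, , drop = FALSE]
    if (nrow(row) == 0)
      gem_stop("fault compound '", target, "' not on left of '", rid, "'")
    eq <- equation(eq$left, rbind(eq$right, row[1, ]), eq$direction)
  } else if (fault$kind == "close_exchange") {
    limits <- Filter(function(le) !identical(le$reaction, rid), limits)
    limits <- c(limits, list(list(reaction = rid, lower = 0, upper = 0)))
  } else {
    gem_stop("unknown fault kind '", fault$kind, "'")
  }
  rxns[[rid]] <- reaction_entry(rid, eq, genes = rxns[[rid]]$genes,
                                name = rxns[[rid]]$name,
                                subsystem = rxns[[rid]]$subsystem,
                                ec = rxns[[rid]]$ec,
                                extra = rxns[[rid]]$extra)
  suppressWarnings(
    gem_model(name = model$name, reactions = unname(rxns),
              compounds = unname(model$compounds), biomass = model$biomass,
              media = model$media, limits = limits,
              model_subset = model$model_subset,
              default_flux_limit = model$default_flux_limit))
}
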