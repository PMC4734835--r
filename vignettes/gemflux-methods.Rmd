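---
title: "gemflux: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gemflux: models, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemflux)
```

This vignette is the package's account of the science it implements:
the optimization problems behind each analysis, the assumptions they
make, the tunable parameters and why their defaults are what they are,
and the numerical decisions that make results reproducible.

## The model container

A genome-scale metabolic model (GEM) is a set of reactions over
compartmentalized compounds, with optional gene-protein-reaction (GPR)
boolean rules, a designated biomass reaction, a growth medium (bounds on
exchange reactions), and explicit flux limits.  The stoichiometric
matrix view `matrix_view()` maps it to a sparse matrix $S$
(compounds × reactions), negative entries for consumed compounds,
positive for produced.  Flux bounds default to $[-x, x]$ for reversible
and $[0, x]$ for irreversible reactions with $x$ the
`default_flux_limit` (1000 by convention; the unit is whatever flux
unit the model's bounds are written in, conventionally
mmol·gDW⁻¹·h⁻¹).  Explicit limit entries override per side; media
entries configure exchange-reaction bounds and are overridden by
explicit limits.

Stoichiometric coefficients are stored as R doubles rather than exact
rationals: every coefficient a curated model prints (small integers and
short decimals) is exactly representable in binary-scaled doubles or
within $10^{-15}$ of it, far below the $10^{-6}$ classification
tolerances used throughout.  Equation text follows the grammar
`[c]: A + (2) B <==> C`, with `-->`/`<--`/`<==>` canonical arrows,
per-compound `[x]` suffixes when compartments differ, and compound
names that may contain spaces and `+` (terms are split on a
space-delimited `+` only).

## Mass consistency

A model is *stoichiometrically (mass) consistent* when strictly
positive compound masses $m$ exist with $S^T m = 0$ over the internal
reactions.  Exchange and biomass reactions are excluded by default:
they are unbalanced by design, which is also why they are the default
`exclude` set of every checker.

**Compound-based check** (`masscheck_compounds`):

$$\max \sum_i z_i \quad \text{s.t.}\quad S^T m = 0,\; m_i \ge z_i,\;
z_i \in [0,1],\; m \ge 0.$$

Compounds whose optimal mass stays below 1 cannot carry positive mass
in any consistent assignment; they are the *sources* of inconsistency.

**Reaction-based check** (`masscheck_reactions`) introduces a signed
residual $r_j$ per reaction:

$$\min \sum_j z_j \quad \text{s.t.}\quad S^T m = r,\; m_i \ge 1,\;
r_j \in [-z_j, z_j],\; z_j \ge 0.$$

At the optimum $z_j = |r_j|$, so the objective is the total absolute
mass leak, and the flagged reactions are the unbalanced equations
themselves.  One formulation choice deserves a note: a maximization of
$\sum z$ under these constraints would be unbounded (any $z$ can grow
freely), so the residual bounds are minimized — the only reading under
which the program has an optimum.  Residuals are reported in two
orientations to avoid sign confusion: `r` is net production ($S^T m$)
and `left_minus_right = -r` matches the "hydrogens on the left minus
hydrogens on the right" reading used when checking equations by hand.

Degenerate optima are real: when two mutually exclusive reactions
differ by two protons, the LP may put the residual on either.  The
intended workflow is the `checked` argument — fix reactions confirmed
balanced at zero residual and re-run, converging on the faulty set.  On
top of that, the bundled simplex uses fixed, index-deterministic pivot
rules, so repeated runs of the same model give identical flag sets; a
lexicographic secondary objective was considered and dropped as
redundant given solver determinism (one LP instead of $n$).

Compounds modelling photons or electrons legitimately carry no mass;
the `zero_mass_ok` argument exempts them (their lower bound drops to 0
and they are never flagged).  No name-based heuristics are applied —
the user says which compounds qualify.

`formulacheck` and `chargecheck` are the complementary annotations-based
checks: stoichiometry-weighted element totals (or integer charges) per
side, flagged when unequal, skipped (and counted) where annotation is
missing.  They localize faults precisely but only work when formulas or
charges are curated; the mass checks need nothing beyond stoichiometry.

## Flux consistency

A reaction is *blocked* (flux inconsistent) when no solution of
$Sv = 0$ within bounds gives it non-zero flux.  `fluxcheck_fva` builds
the steady-state LP once and sweeps objectives: maximize $v_j$, and for
reactions that may run backwards also minimize; consistent iff either
optimum exceeds `tol` ($10^{-6}$) in magnitude.  Re-using one problem
and mutating only the objective is what keeps the sweep cheap, and the
same pattern backs FVA and robustness.

`fluxcheck_fastcc` computes the same partition with fewer LPs: one
block LP pushes all irreversible reactions jointly toward a flux of at
least `epsilon`, certifying everything in the support of the solution
at once, then rescues remaining candidates one at a time with a
direction flip for reversibles.  `epsilon` defaults to $10^{-4}$: small
enough that any reaction able to carry meaningful flux under bounds of
order 1–1000 reaches it, large enough to sit far above solver
tolerance.  The partition equality of the two methods is asserted on
100 randomized models in the test suite.

The `unrestricted_exchanges` flag widens all exchange bounds to
$[-x, x]$ before the sweep, removing the influence of a particular
growth medium; use it to separate "topologically blocked" from "blocked
under this medium".  `blocked_fraction_by_subsystem` aggregates a
result over subsystem annotations of the internal reactions, grouping
unmapped subsystems under `"other"`.

## Constraint-based simulation

`fba` maximizes the objective flux under $Sv = 0$ and bounds.
Infeasibility or unboundedness is reported as an explicit status on the
returned object, never as a silently wrong optimum.

`loop_removal = "tfba"` adds thermodynamic loop-law constraints.  The
formulation (a choice of this package; standard in the field but with
several equivalent variants) gives every internal reaction a binary
direction indicator $y_j$ and an energy $G_j$ tied to per-compound
potentials $\mu$ by $G_j = \sum_i S_{ij}\mu_i$, with big-$M$ coupling
($M$ = `default_flux_limit`):

$$v_j \le M y_j,\quad v_j \ge -M(1-y_j),\quad
G_j \in [-1000, -1] \text{ if } y_j = 1,\quad
G_j \in [1, 1000] \text{ if } y_j = 0.$$

Flux must run down a potential gradient, and since potentials cannot
strictly decrease around a cycle, internal circulation unsupported by
exchanges is forced to zero.  Exchange reactions are exempt.  The
constraint applies a non-zero energy to zero-flux reactions too
(their indicator is still free), which is the usual benign degeneracy
of this formulation; pathological inputs such as a reaction paired with
its exact duplicate in opposite orientation are handled because one
indicator of the pair can take each sign.

`fva` maximizes the objective, constrains it to
`optimum_fraction` × optimum, then reports each reaction's flux range
over the constrained polytope, mutating one problem throughout.
`robustness` computes the varied reaction's feasible range by min/max
LP, fixes it at `steps` evenly spaced values and re-maximizes; an
infeasible grid point is recorded in the curve, not raised, so the
curve always has the requested number of entries (a blocked varied
reaction degenerates to a single point, with a warning).

`randomsparse` visits genes (or reactions) once, in an order drawn from
the integer `seed` — the only stochastic element — and keeps a deletion
iff the re-optimized objective stays at or above
`threshold_fraction` × wild type.  Because deletions only shrink the
feasible set and GPR trees are and/or-monotone, an element that failed
its deletion test can never become deletable later; the result is
therefore a minimal network, which the tests re-verify by exhaustive
single-deletion probing.

## Gap analysis

`gapfind` and `gapfill` run on a relaxed balance $Sv \ge 0$
(accumulation allowed), as in the original formulations: a compound is
*producible* when some reaction can push at least `epsilon` of it into
its pool.  `epsilon` defaults to $10^{-3}$ × `default_flux_limit` — a
production of 1 flux unit under default bounds — and big-$M$ constants
scale with the largest stoichiometric coefficient so indicator
constraints never clip a feasible flux.  `gapfind` maximizes the number
of produced compounds with per-(compound, reaction) production
indicators; `root_gaps` is the topological subset with no producing
reaction at all.

`gapfill` selects a minimum-penalty subset of candidates so that one
flux vector produces every target.  Candidates and default penalties:
database reactions outside the model subset (1), reversals of
irreversible model reactions (5, behind `allow_reversals`, on by
default), artificial uptake exchanges for target compounds (10).  The
ordering encodes a curation preference — real biochemistry first,
directionality changes second, topology patches last — and is fully
configurable.  Artificial exchanges are only offered for compounds that
occur somewhere in the model or database; a target known to neither is
an error, not a proposal.

## Solver layer

No LP solver is assumed on the system.  The package bundles a dense
bounded-variable two-phase primal simplex (Dantzig pricing with a
Bland's-rule fallback for anti-cycling, Harris-style ratio-test
tie-break toward large pivots) and a depth-first best-bound
branch-and-bound for binaries.  Primal feasibility tolerance is
$10^{-9}$ at the simplex level; MILP integrality tolerance is
$10^{-6}$.  Problems in this package are small (tens to a few hundred
variables), so dense linear algebra is both simpler and fast enough;
determinism was the design priority, because flag sets and minimal
networks must be reproducible across runs.

Backends are a registry (`register_solver`); every analysis takes
`solver` and the CLI takes `--solver`.  A second, LP-only backend wraps
`pracma::linprog` and refuses binary variables with an explicit error —
the same restriction an exact rational LP solver would have — and the
test suite uses it as an independent cross-check of the bundled
simplex.

## Synthetic fixtures: what they do and do not show

`make_fixture` provides the toy models the tests run on: a linear
growth chain, a chain with an orphaned two-reaction fragment, a chain
with an internal 2-cycle, a two-route branched variant, the two printed
reaction pairs of the worked example, and seeded random models.  Random
models are built by rearranging conserved pseudo-element pools
(formulas over C, H, N, O): left sides draw composite compounds, right
sides are completed with monomers so that every generated reaction
balances exactly.  This gives each clean model a known mass certificate
(soundness tests) while fault injection (`inject_fault`: proton
imbalances, compartment mislabeling, duplicated compounds, closed
exchanges) produces controlled violations with a known culprit.

Deliberate limits of the generator: models are tiny (default 8
compounds, 10 reactions plus exchanges) and fully connected only by
chance; they have no compartment topology beyond labels, no realistic
degree distribution, no biomass composition, and GPR rules only where
fixtures define them.  Passing tests therefore certify algorithmic
correctness — LP formulations, partitions, minimality, round trips —
not performance or curation behaviour on organism-scale
reconstructions.  Test problem sizes (100 random models for the
partition-equality property, 2⁴ deletion subsets for GPR truth tables,
4-candidate databases for brute-force gap comparisons) were chosen so
the whole suite certifies every property in about a minute on one CPU.

## Formats

The YAML layout is line-oriented on purpose: one scalar field per line,
fixed key order, records in model order, so a one-field edit changes
exactly one line and Git diffs stay readable.  Sections may be inlined
in `model.yaml` or split across `include`d YAML or tab-delimited files;
both spellings parse to the same model, includes resolve relative to
the including file, and cycles are errors.  Reading uses the `yaml`
package; writing uses the package's own emitter because generic YAML
serializers re-flow output and void the diff-minimality contract.

SBML import accepts levels 1–3 (including the level-1 `specie`
spelling) in two modes.  `strict` fails on any deviation; `lax` applies
four repairs, each recorded in the import report: decimal stoichiometry
at integer-only levels, boundary species marked by an `_b` id suffix
(an exchange reaction is created), references to undefined species
(dropped), and irreversible reactions with a negative COBRA
`LOWER_BOUND` (the stated bounds win, the conflict is recorded).  A
strictly valid file produces zero repairs in either mode, which the
tests assert.  Export targets level 2 with COBRA-dialect kineticLaw
bound parameters — the dialect the bulk of published models use —
writing `boundaryCondition` attributes rather than id suffixes;
species ids are sanitized to SBML's identifier alphabet, so round-trip
equivalence is up to that renaming (exact for alphanumeric ids), with
original ids kept in each entry's `extra` data for traceability.

## Known limitations

* The mass checks localize faults; they do not propose corrected
  stoichiometry — correction is a curation decision.
* The loop-law MILP is one of several equivalent formulations; other
  implementations' flux distributions may differ on degenerate optima
  even where objectives agree.
* `fastgapfill`-style consistency-based gap filling is not implemented;
  the CLI name is reserved and reports so.
* The bundled solver is dense; organism-scale models (thousands of
  reactions) would want a sparse external backend via
  `register_solver()`.
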