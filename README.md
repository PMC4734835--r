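# gemflux

Constraint-based analysis and quality checking of genome-scale metabolic
models (GEMs) in R, with a modular, version-control-friendly YAML model
format.

Curated metabolic reconstructions accumulate inconsistencies: reactions
that are not mass balanced, compounds mislabeled across compartments,
pathways disconnected from the rest of the network, SBML files that bend
the specification.  These faults silently corrupt flux balance analysis
— an unbalanced reaction pair can create or destroy matter at no cost —
and they are hard to find by eye among thousands of reactions.  gemflux
is for model curators and modelers who need to import a published model,
localize its faults, and simulate it, each with a single function call
or shell command.

## What it computes

With stoichiometric matrix `S` (compounds × reactions) and flux vector
`v`:

* **Stoichiometric (mass) consistency.**  A model is mass consistent
  when strictly positive compound masses `m` exist with `Sᵀm = 0` over
  the internal reactions.  The *compound-based* check solves
  `max Σᵢ zᵢ` s.t. `Sᵀm = 0`, `mᵢ ≥ zᵢ`, `zᵢ ∈ [0,1]`: compounds whose
  optimal mass stays below 1 are the sources of inconsistency.  The
  *reaction-based* check introduces a signed mass residual per reaction,
  `Sᵀm = r` with `m ≥ 1`, `|rⱼ| ≤ zⱼ`, and minimizes `Σⱼ zⱼ`: reactions
  left with non-zero residual are the unbalanced equations themselves,
  and the residual value says how much mass (e.g. how many hydrogens)
  one side is missing.  A `checked` set fixes confirmed-balanced
  reactions at zero residual so the procedure converges on the faulty
  set.
* **Flux consistency.**  A reaction is blocked when no solution of
  `Sv = 0` within bounds gives it non-zero flux; detected either by an
  FVA sweep (maximize, then minimize, each reaction on one reused LP) or
  by the FASTCC block-elimination scheme, which certifies many reactions
  per LP.
* **Simulation.**  FBA (`max v_obj` s.t. `Sv = 0`, bounds), optionally
  with thermodynamic loop-law constraints that forbid internal cycles;
  FVA; robustness curves; and random minimal networks in which every
  remaining gene (or reaction) is essential.
* **Gap analysis.**  GapFind/GapFill MILPs that locate unproducible
  compounds and propose a minimum-penalty set of database reactions,
  reaction reversals, or artificial exchanges that restores production.
* **Formats.**  A line-oriented YAML model layout with `include`
  support (diff-minimal under Git), SBML import for levels 1–3 in strict
  or repairing mode, SBML level-2 export with COBRA-dialect bounds, and
  delimited-table import/export.

All LPs and MILPs run on a bundled bounded-variable simplex with
branch-and-bound; other backends can be registered (`register_solver()`),
and every analysis takes a `solver` argument / `--solver` flag.

## Worked example

The classic failure mode is a pair of reactions that differ only by
stray protons.  `make_fixture("table3_pair")` builds a two-reaction
model of glucose-phosphate isomerisation:

```
RR00610  [c]: D-Glucose 1-phosphate + (2) H+ <==> D-Glucose 6-phosphate
RR08939  [c]: D-Glucose 1-phosphate <==> D-Glucose 6-phosphate
```

Both cannot be true at once — together they make two protons from
nothing.  Run the reaction-based mass check, telling it RR08939 is the
trusted version:

```r
library(gemflux)
m <- make_fixture("table3_pair")
res <- masscheck_reactions(m, exclude = character(0), checked = "RR08939")
res
#> Stoichiometric consistency check (reaction-based)
#>   candidate unbalanced reactions (residual = net production, lmr = left-minus-right):
#>     RR00610	residual=-2	lmr=2
```

The same from the shell (`inst/cli/gemflux-model`):

```
$ gemflux-model masscheck --model demo_pair --type=reaction --checked RR08939
# model: table3_pair
# objective: <none>
# sum z: 2
RR00610	-2	2	[c]: D-Glucose 1-phosphate + (2) H+ <==> D-Glucose 6-phosphate
```

Reading: RR00610 carries the whole residual; its left side has **2**
hydrogens too many (`lmr = 2`, i.e. net production −2), exactly the
H-count difference between the two printed equations, and `sum z: 2` is
the minimized total residual.  A flux simulation on a toy growth model:

```
$ gemflux-model fba --model demo_chain
# model: toy_chain
# objective: BIO
# objective value: 10
EX_A	-10	A[e] <==>
TP_A	10	A[e] <==> A[c]
R_AB	10	[c]: A --> B
BIO	10	B[c] -->
```

Uptake of A is capped at 10, so biomass flux is 10 and each step of the
pathway carries it.

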