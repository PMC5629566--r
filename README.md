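# pessknock

Robust reaction-knockout strain design for targeted biochemical
overproduction on stoichiometric metabolic models, by **pessimistic
bi-level optimization**.

## The problem

Given a metabolic network at steady state (fluxes `v` with mass balance
`S v = 0`, bounds `v_min ≤ v ≤ v_max`, fixed substrate uptake
`v_glc = v_glc_uptake`, viability threshold `v_biom ≥ v_biomass_target`),
which ≤ K reactions should be knocked out so that the surviving mutant
overproduces a target chemical?

Classical designs are *optimistic* bi-level programs:

* **OptKnock** — `max_z v_chem` subject to the mutant solving
  `max_v v_biom` over the knockout-constrained flux space
  (`v_min_j z_j ≤ v_j ≤ v_max_j z_j`, `Σ(1 − z_j) ≤ K`, `z` binary);
* **ROOM** (LP variant) — the same outer problem, with the mutant instead
  minimizing `Σ y_j` over relaxed change indicators `y ∈ [0,1]` that bound
  each flux's deviation from the wild-type reference `w`.

Both silently assume that when the mutant's own optimum is not unique, it
picks the response most favorable to the engineer.  `pessknock`
implements the *pessimistic* counterparts, **P-OptKnock** and **P-ROOM**:
maximize the **worst-case** target flux over every response whose inner
objective lies within a multiplicative tolerance band of optimal —
`v_biom ≥ (1 − ε)·φ*(z)` for the biomass model, `Σ y_j ≤ (1 + ε)·φ*(z)`
for ROOM.  At `ε = 0` only adversarial tie-breaking is allowed; growing
`ε` also covers error in the survival model itself.  The reported
objective is a flux the design *guarantees*, not a prediction.

Each three-level program is collapsed to a single mixed-integer linear
program by applying LP strong duality twice (inner survival LP → dual;
adversarial min-LP → dual again), with feasibility witnesses excluding
designs that kill the mutant outright and exact big-M linearization of
binary-by-dual products.  MILPs are solved with HiGHS via SciPy; every
returned design's objective is re-certified with an exact two-stage LP,
and an independent brute-force enumeration oracle referees the MILPs in
the tests.

## Worked example

The bundled `toy7` fixture (4 metabolites, 9 reactions, substrate uptake
fixed at 10 mmol/gDW/hr, biomass minimum 1) has an uncredited sink `R5`
competing with the target secretion `CHEM`, so the biomass-optimal face
leaves the target flux undetermined — exactly the situation in which
optimistic designs overpromise.

```r
library(pessknock)

m <- make_fixture("toy7")
solve_optknock(m, K = 2)
#> OptKnock (optimistic) design on 'toy7'
#>   knockouts (K = 2): R1, R3
#>   predicted (cooperative) CHEM flux: 5 mmol/gDW/hr [optimal]

epsilon_extreme_flux(m, c("R1", "R3"), "biomass", epsilon = 0)
#> Worst-case evaluation (inner model: biomass, epsilon = 0)
#>   knockouts: R1, R3
#>   inner optimum phi* = 5; target flux in [0, 5] mmol/gDW/hr
```

OptKnock predicts 5 mmol/gDW/hr — but among biomass-optimal responses the
mutant may just as well secrete everything through the sink, so the
guaranteed flux is 0.  The pessimistic design closes the sink:

```r
solve_p_optknock(m, K = 3, epsilon = 0)
#> P-OptKnock (pessimistic) design on 'toy7', epsilon = 0
#>   knockouts (K = 3): R1, R3, R5
#>   guaranteed worst-case CHEM flux: 5 mmol/gDW/hr [optimal]

run_epsilon_sweep(m, methods = "p_optknock", K = 3, epsilons = c(0, 0.25, 0.5))
#> Epsilon/K sweep on 'toy7' (4 metabolites, 9 reactions)
#>       method K epsilon objective  knocked  status
#> 1 p_optknock 3    0.00      5.00 R1,R3,R5 optimal
#> 2 p_optknock 3    0.25      3.75 R1,R3,R5 optimal
#> 3 p_optknock 3    0.50      2.50 R1,R3,R5 optimal
```

With knockouts `{R1, R3, R5}` production is growth-coupled: 5 mmol/gDW/hr
is guaranteed even against an adversarial response, degrading gracefully
(`5·(1 − ε)`) as the tolerance band widens.

A command-line interface wraps the same functions
(`fixture`, `validate`, `fba`, `design`, `evaluate`, `sweep`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pessknock", package = "pessknock"))')
$CLI fixture --name toy7 --out toy7.json
$CLI design --method p-optknock --K 3 --eps 0 --model toy7.json --out design.json
```

## Package layout

* `design_strain()` / `solve_optknock()`, `solve_room_design()`,
  `solve_p_optknock()`, `solve_p_room()` — the four design MILPs.
* `solve_fba()`, `wild_type_fluxes()` — FBA and the parsimonious
  wild-type reference.
* `inner_optimum()`, `epsilon_extreme_flux()`, `worst_case_table()`,
  `pessimistic_enumeration_oracle()` — evaluation of fixed designs and
  the brute-force referee.
* `make_fixture()`, `load_model()`, `save_model()`, `validate_model()` —
  fixtures, SBML (Level 3 FBC) and a JSON tabular dialect.
* `run_epsilon_sweep()`, `cli_main()` — sweep experiments and the CLI.

See the vignette (`vignettes/pessimistic-strain-design.Rmd`) for the
model, the double-dualization, big-M auditing, and all numerical choices.
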