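---
title: "Robust knockout strain design by pessimistic bi-level optimization"
author: "pessknock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust knockout strain design by pessimistic bi-level optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Computational strain design asks which set of reaction knockouts will force a
microbe to overproduce a target chemical.  In the flux balance analysis (FBA)
framework, the cell's steady-state fluxes $v$ satisfy mass balance $Sv = 0$,
bounds $v^{\min} \le v \le v^{\max}$, a fixed substrate uptake
$v_{glc} = v_{glc\_uptake}$, and a viability threshold
$v_{biom} \ge v_{biomass}^{target}$.  A knockout design is a binary vector
$z$ with $v_j^{\min} z_j \le v_j \le v_j^{\max} z_j$ and at most $K$ zeros.

Classical methods are *optimistic* bi-level programs.  OptKnock maximizes the
target flux over designs subject to the mutant maximizing biomass; the ROOM
family instead assumes the mutant minimizes the number of regulatory flux
changes relative to the wild type.  Both implicitly assume that when the
cellular response is not unique, the cell picks the response most favorable
to the engineer.  That assumption is fragile twice over: the inner survival
model is itself an approximation, and among equally good responses nothing
forces the favorable one.  A design whose predicted production relies on the
cooperative tie-break may produce nothing at all in practice.

`pessknock` implements the *pessimistic* counterparts, P-OptKnock and P-ROOM:
choose the design maximizing the **worst-case** target flux over every
response whose inner objective is within a multiplicative tolerance band of
optimal.  The reported objective is a guarantee, not a prediction.

## Models and the epsilon band

Two inner (cell survival) models are supported:

* **biomass** (OptKnock's): the response maximizes $v_{biom}$.  The band at
  tolerance $\varepsilon \in [0, 1]$ admits any feasible $v$ with
  $v_{biom} \ge (1 - \varepsilon)\,\varphi^*(z)$, where $\varphi^*(z)$ is the
  design's maximal biomass.  The viability threshold
  $v_{biom} \ge v_{biomass}^{target}$ applies throughout, so the effective
  constraint is the larger of the two.
* **room** (the LP variant of ROOM): relaxed change indicators
  $y_j \in [0,1]$ bound each flux's deviation from the wild-type reference
  $w$ through
  $v_j - y_j (v_j^{\max} - w_j) \le w_j$ and
  $v_j - y_j (v_j^{\min} - w_j) \ge w_j$; the response minimizes
  $\sum_j y_j$.  The band admits responses with
  $\sum_j y_j \le (1 + \varepsilon)\,\varphi^*(z)$.  The change constraints
  compare fluxes to $w_j$ exactly; no relative significance thresholds are
  layered on top.  When $\varphi^*(z) = 0$ (the wild type itself survives
  the design) the band degenerates to $\sum y_j \le 0$ and is handled
  exactly, not padded by an additive floor.

$\varepsilon = 0$ is the pure pessimistic problem — the inner model is taken
at face value but ties resolve adversarially.  Growing $\varepsilon$ models
growing distrust in the inner model itself.  By construction the guaranteed
flux is non-increasing in $\varepsilon$ and the optimistic objective is an
upper bound for the pessimistic one at every $\varepsilon$; both facts are
asserted as tests.

## From three levels to one MILP

For a fixed $z$ the inner problem is an LP, so the three-level structure
(outer knockouts → adversarial response → inner-optimal certificate)
collapses by applying strong duality twice:

1. The inner LP is replaced by its dual, and the band constraint ties the
   response's inner objective to the *dual objective*.  Any dual-feasible
   point bounds $\varphi^*$ from the safe side, and the adversary — who
   controls the dual variables and wants the band as permissive as the
   formulation allows — drives the dual objective exactly to $\varphi^*$.
   This encodes the band without knowing $\varphi^*$ in advance.
2. The resulting adversarial min-LP is dualized again; the outer
   maximization then absorbs the second dual, giving a single-level MIP.

Two modeling details matter:

* **Feasibility witnesses.**  Some $z$ leave the mutant with no feasible
  flux distribution at all, which makes the second dual unbounded.  A
  witness copy of the inner primal constraints (variables $s$, and $r$ for
  the ROOM change indicators) is kept in the MIP so only designs with a
  live mutant are eligible.
* **Big-M linearization.**  Products of binaries with duals ($z_j$ times
  bound duals in the objective, $z_j$ times the band dual $t$ in
  constraints) are linearized exactly with
  $\xi \le M z$, $\xi \ge -M z$, $\xi \le x + M(1-z)$, $\xi \ge x - M(1-z)$.
  Flux-by-binary couplings need no products at all
  ($v_j^{\min} z_j \le v_j \le v_j^{\max} z_j$ is linear), and products are
  only created for knockable reactions — for permanently active reactions
  $z_j \equiv 1$ and the product *is* the dual variable.

The optimistic baselines use the standard single-dualization route: inner
primal feasibility + inner dual feasibility + equality of the two
objectives.  When the inner optimum is degenerate the MILP inherently picks
the cooperative response; that selection is the optimistic assumption
itself, so it is documented rather than "fixed".

## Choosing big M, and auditing it

Duals of degenerate LPs are unbounded in general, so no a-priori dual bound
exists.  The package uses a working bound `M_dual = 1e4` (fluxes are
bounded by the model, typically at 100 mmol/gDW/hr) and audits every
linearized product after solving: if a continuous factor sits within
`audit_margin` (default 0.95) of its $M$ *while its binary is active*, the
relaxation may have truncated the optimum; $M$ is escalated tenfold and the
program re-solved (twice at most, then the result is flagged
`big_m_unsafe`).  Factors at large values while their binary is zero are
ignored deliberately: with $z_j = 0$ the product is exactly zero whatever
the factor, and such excursions are just degenerate rays of the dual
polyhedron.  Escalating on them is not only unnecessary — pushing $M$
toward $10^6$ and beyond genuinely degrades MILP numerics (feasibility
tolerances scale with the coefficients), which is why the audit is
z-aware.

## Certifying the returned objective

MILP solvers declare a binary integral within an integrality tolerance
(about $10^{-6}$ for HiGHS).  In a big-M model that slack is not free: a
binary at $1 - 10^{-6}$ relaxes a big-M row by $M \cdot 10^{-6}$, which the
adversarial dual can convert into a spurious objective contribution of
order $10^{-2}$ when $M = 10^4$ — easily visible next to guarantees of
order 1.  The package therefore treats the MILP as the design *selector*
only: once the knockout set is read off (binaries rounded), the design's
objective is recomputed exactly with the two-stage band LP at fixed,
integral $z$, and that certified value is what `design_strain()` reports
(the raw MILP value is kept in `solver_stats$milp_objective`).  The
certified value is exact for the returned design; the selection itself is
optimal up to the same $M \cdot 10^{-6}$ leakage, which the
oracle-equivalence tests bound empirically at below $10^{-4}$ across the
whole grid.

## The wild-type reference

ROOM-type models need wild-type fluxes $w$.  "Maximize biomass" alone does
not pin $w$ down — genome-scale FBA optima are notoriously degenerate — and
every downstream ROOM/P-ROOM number inherits that ambiguity.  The package
therefore fixes a parsimonious tie-break: among biomass-optimal solutions,
$w$ minimizes total absolute flux (a second LP with split positive/negative
parts).  This makes $w$, and everything built on it, reproducible across
solvers and runs.  On networks where even the parsimonious optimum is not
unique, determinism still holds for a fixed solver and ordering, which is
what the tests assert.

## Fixtures and what they do (not) show

All tests and the acceptance script run on self-contained fixtures:

* `toy7` — 4 metabolites, 9 reactions, uptake fixed at 10 mmol/gDW/hr,
  biomass minimum 1.  Its defining feature is an uncredited sink (`R5`)
  competing with the target secretion, so the biomass-optimal face leaves
  the target flux undetermined: the optimistic prediction at $K = 2$ is 5
  while the guaranteed flux is 0.  Knocking `R1`, `R3`, `R5` ($K = 3$)
  growth-couples production and guarantees 5.  All of these values are
  hand-derivable and are frozen in the tests.
* `diamond` — two symmetric arms, a deliberately degenerate biomass
  optimum for exercising the parsimonious tie-break.
* `random` — seed-reproducible networks with 3–5 internal metabolites, a
  conversion DAG with mixed stoichiometric yields (0.5/1/2), occasional
  reversible steps, an uncredited sink competing with the target, and at
  most 8 knockable reactions so exhaustive enumeration stays cheap.  A
  draw is accepted only if wild-type FBA is feasible at the configured
  uptake (10) and biomass minimum (1).

These fixtures reproduce the *structural* causes of non-cooperative
failure (fixed uptake, viability threshold, competing secretion routes,
degenerate optima) but not the scale or biochemical realism of
genome-scale reconstructions: no cofactor coupling, no compartments, no
thousands-of-reactions degeneracy.  Passing tests certify the optimization
machinery — they do not certify biological predictions on real networks,
which additionally depend on the quality of the reconstruction and on the
unknown knockable set.

## Validation strategy

The MILPs are never trusted on their own:

* an independent brute-force referee enumerates every design of size
  $\le K$ and scores it with the two-stage band LP
  (`pessimistic_enumeration_oracle()`); on the full grid — 21 fixtures,
  $K \in \{1,2,3\}$, $\varepsilon \in \{0, 0.1, 0.5, 1\}$, both methods —
  MILP and oracle must agree to $10^{-4}$;
* inner ROOM primal and dual optima are compared on 50 random
  (fixture, design) pairs to $10^{-5}$;
* upper-bound, $\varepsilon$-monotonicity and $K$-monotonicity hold across
  the same grid;
* at $\varepsilon = 1$ the biomass-model evaluator must coincide with an
  independently coded flux-variability computation under the viability
  threshold alone.

The grid sizes above were chosen to exercise every code path (both inner
models, reversible reactions, infeasible designs, degenerate optima) while
keeping the default suite a few minutes on one CPU; the enumeration oracle
is exponential in $K$ by design and is the reason fixtures cap knockable
reactions at 8.

## Numerical choices

* LP/MILP solving: HiGHS through `scipy.optimize.milp`, single problem
  batch protocol over JSON; relative MILP gap $10^{-6}$; problems are
  batched so the Python interpreter start-up (~0.5 s) is paid once per
  batch, not per LP.
* Solver feasibility/optimality tolerances are at their HiGHS defaults
  ($\sim 10^{-7}$); package-level comparisons use $10^{-4}$ for objectives
  and $10^{-6}$ for constraint residuals.
* The two-stage evaluator adds an absolute slack of $10^{-7}$ to the band
  so stage 2 is never spuriously infeasible at $\varepsilon = 0$ from LP
  round-off.
* The parsimonious stage of the wild-type reference fixes biomass to its
  optimum minus $10^{-9}$; resulting fluxes below $10^{-9}$ are snapped to
  zero so $w$ is a clean reference.
* Ties among optimal designs are broken by the solver in the MILPs and by
  enumeration order (smaller sets first, then lexicographic) in the
  oracle; the two can legitimately return different argmax designs with
  equal objectives, so tests compare objectives, and knockout sets only
  where the optimum is unique.

## Design decisions that were genuinely open

* **Knockability policy.**  Published studies rarely state their knockable
  set.  Default: only `internal` reactions are knockable; uptake, biomass,
  target and exchange reactions are not, unless explicitly whitelisted
  (`set_knockable()`).
* **Fixed uptake.**  Implemented by setting both bounds of the uptake
  reaction for plain FBA, but kept as an explicit equality row in the
  embedded duals so the uptake dual appears exactly as in the inner-dual
  structure.
* **Reversible reactions** are a single flux variable with a negative
  lower bound; no forward/backward splitting.
* **External metabolites** are dropped from mass balance; exchange
  reactions appear as single-sided stoichiometries.
* **Epsilon semantics** are multiplicative on the inner optimum,
  $(1+\varepsilon)$ for minimized and $(1-\varepsilon)$ for maximized
  inner objectives, applied only through the band — never by perturbing
  bounds.

## Worked example

```{r example}
library(pessknock)

m <- make_fixture("toy7")
w <- wild_type_fluxes(m)

# optimistic prediction vs pessimistic guarantee
solve_optknock(m, K = 2)                      # predicts 5 via {R1, R3}
epsilon_extreme_flux(m, c("R1", "R3"),
                     "biomass", epsilon = 0)  # guarantees [0, 5]

solve_p_optknock(m, K = 3, epsilon = 0)       # guarantees 5 via {R1, R3, R5}

run_epsilon_sweep(m, methods = c("p_optknock", "optknock_eval"),
                  K = 3, epsilons = seq(0, 0.5, 0.25))
```

## Limitations

* Gene–protein–reaction mappings are out of scope: knockouts are at the
  reaction level.
* The monolithic MILP scales with $|I| + 7|J|$ rows; genome-scale networks
  are expected to be solvable (the structure is only modestly larger than
  the classical OptKnock MILP) but no decomposition scheme is provided.
* Only the extreme target fluxes of the band are computed; the band's
  interior (e.g. flux samples) is not characterized.
* The quadratic-inner-model family (minimization of squared adjustment)
  has no pessimistic counterpart here.
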