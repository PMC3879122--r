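---
title: "Dual-semantics simulation of reagent-centric reaction networks and the (M,R) system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-semantics simulation of reagent-centric reaction networks and the (M,R) system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopepa)
```

## The model class

`biopepa` simulates mass-action biochemical reaction networks written in a
*reagent-centric* style: instead of listing reactions with left and right
sides, each species declares, per named reaction, its role — reactant
(`<<`), product (`>>`), activator (`(+)`) or inhibitor (`(-)`) — and its
stoichiometric coefficient.  The conventional reaction-centric form
(reactants, products, modifiers, signed net change) is derived from those
declarations by `reaction_views()` and `net_stoichiometry()`; the two views
are interchangeable and the package tests that they always agree.

Every model carries one more piece of structure: a set of
*environment-held* (constant) species.  Such a species contributes its
quantity to every kinetic law that mentions it, but its own amount never
changes — its row of the net-stoichiometry matrix is forced to zero.  This
is the natural encoding of a nutrient source replenished by the
environment, and it is deliberately a model-level annotation rather than a
use of the activator role: the source can then appear as a formal reactant
of a binding reaction (so the law is the usual bimolecular product) while
the unbinding reaction simply does not return it, and no bookkeeping of
the environment's amount is ever needed.

Both semantics consume the same compiled form:

* **Deterministic (ODE).**  d*x*/d*t* = *S v*(*x*), where *S* is the net
  stoichiometry matrix and *v* the vector of kinetic-law values; mass-action
  laws are *c* · Π *x*ᵢ^(mᵢ) over the rate-contributing species.  Integration
  uses `deSolve::lsoda` (adaptive, stiff-capable) at `rel_tol = 1e-8`,
  `abs_tol = 1e-10` by default: the networks studied here mix rate
  constants spanning four orders of magnitude (binding at 0.01, unbinding
  at 100), which is moderately stiff.  Undershoots below zero within the
  absolute tolerance are clamped in reported series; anything larger
  raises a warning.
* **Stochastic (CTMC).**  The exact Gillespie direct method: exponential
  waiting time at the total propensity, next reaction drawn proportionally
  to its propensity, state updated by the net change.  Mass-action
  propensities use the combinatorial falling-factorial form
  *c* · *n*(*n* − 1)···(*n* − *m* + 1), which counts distinct molecular
  encounters; for the networks here every reactant is distinct so this
  reduces to the plain product.  Trajectories are recorded onto a uniform
  grid by last-value-carried-forward.  The inner loop is C++ (via Rcpp),
  drawing from R's RNG so that `set.seed()` makes runs bit-reproducible;
  replicate *r* of a sweep uses seed `base_seed + r - 1`.

## The (M,R) instantiation

Rosen's Metabolism-Replacement system is the smallest network that is
*closed to efficient causation*: every catalyst is itself a product of the
network.  Read as a single metabolic pathway, a source A is turned into B
by the enzyme f, B is turned into f by the enzyme p, and f is turned into
p by B itself — the catalytic cycle f → B → p → f with only A supplied
from outside.  `build_mr_model()` expands each of the three catalytic
steps into the standard enzymatic triple (binding, unbinding, catalysis)
with explicit enzyme–substrate complexes fA, pB and Bf:

| step | reactions | constants |
|------|-----------|-----------|
| A → B by f | A + f → fA; fA → f; fA → f + B | k1, k2, k3 |
| B → f by p | B + p → pB; pB → p + B; pB → p + f | l1, l2, l3 |
| f → p by B | f + B → Bf; Bf → B + f; Bf → B + p | m1, m2, m3 |
| turnover | B → ∅; f → ∅; p → ∅ | d1, d2, d3 |

A is environment-held, so the binding law k1·A·f sees a constant A and
the unbinding reaction fA → f does not return an A unit.  All twelve laws
are pure mass action; rate constants are per time unit (unimolecular) or
per molecule per time unit (bimolecular).

Three named regimes (`mr_preset()`) cover the studied behaviours, all
starting from A = f = 1000 and everything else at zero:

* **fig3** — k1 = l1 = m1 = 0.01, k2 = l2 = m2 = 100, k3 = l3 = m3 = 1,
  d1 = 0, d2 = 0.05, d3 = 0.02426.  Converges to a live steady state with
  roughly 577 p, 495 B, 286 f, 28 pB, 28 fA and 14 Bf.
* **fig6** — identical except d2 = 0.07: the ~40% increase in f turnover
  collapses the cycle; f, p and the complexes decay towards zero.
* **fig7** — k1 = l1 = m1 = 1, k2 = l2 = m2 = 100, k3 = m3 = 10, l3 = 20,
  d1 = 0, d2 = 60, d3 = 19.2666666.  Deterministically this regime also
  reaches a steady state (all free species positive), but its f and p
  levels are small enough that stochastic fluctuation can exhaust the
  species a reaction needs: individual replicates reach *deadlock* — every
  propensity zero, "death" — at random times while others live out the
  whole horizon.

```{r steady-state}
m <- build_mr_model(mr_preset("fig3")$params)
find_steady_state(m)
```

## Steady-state detection

`find_steady_state()` integrates in chunks and declares convergence when
the largest absolute derivative over the non-constant species falls below
`abs_tol` (default `1e-4` molecules per time unit).  That default deserves
a note.  The live regime's Jacobian at its plateau has one eigenvalue
within ~5·10⁻⁸ of zero: after the fast transients die away the state
creeps along a slow quasi-steady manifold, and the residual plateaus near
2.5·10⁻⁵ — reaching, say, 10⁻⁶ would take on the order of 10⁸ time units
and is numerically meaningless next to gross one-way fluxes of order 10³.
A tolerance of 10⁻⁴ is seven orders of magnitude below those fluxes,
accepts the plateau as the steady state (as any practitioner reading the
time course would), and still rejects genuinely moving states by a wide
margin.  Non-convergence within `t_max` is reported, not raised.  Counts
are additionally reported rounded to integers, matching how molecule
numbers are conventionally quoted.

## Volume scaling

`scale_model(model, f)` multiplies all initial quantities by `f` and
divides every mass-action constant by `f^(order-1)`, where the order
counts rate-contributing quantity factors (constant species included).
Mass-action ODEs are exactly equivariant under this map — the scaled
trajectory is the unscaled one magnified pointwise by `f` — which the
tests verify at factors 10 and 10⁴ (the latter giving the
10⁷-molecule configuration with k1 = l1 = m1 = 10⁻⁶).  The operation
refuses models with non-mass-action laws, where the order of a reaction
is not inferable.

## Verification strategy

The stochastic engine is checked against independent exact references,
not against itself:

* **Uniformization oracle.**  `ctmc_transient_oracle()` enumerates the
  reachable state space (breadth-first, truncated at `state_cap` states;
  transitions beyond the truncation feed an absorbing overflow state whose
  mass is reported as *leaked*), assembles the sparse generator, and
  computes the exact transient distribution by uniformization, with the
  Poisson series cut at a 10⁻¹² tail.  A miniature (M,R) instance (A held
  at 2, one enzyme molecule, all constants 1, no turnover) is small enough
  for the oracle; 2·10⁴ Gillespie replicates are compared to it with a
  chi-squared goodness-of-fit test at α = 0.01, pooling states with
  expectation below 5.
* **Closed forms.**  A pure-death chain X → ∅ at rate *c* has
  P(extinct by *t*) = 1 − e^(−*ct*) and a binomial transient law; the
  empirical extinction fraction and the oracle are both checked against
  these.
* **Law of large numbers.**  The mean of 50 replicates is compared to the
  ODE curve at native scale and at 10× volume; the relative deviation must
  shrink with scale.  These runs use 200 time units — enough to cover the
  transient and the entry into the steady state, where the comparison is
  most informative — with 100 grid points.
* **Determinism.**  Identical (model, horizon, seed) must give
  bit-identical trajectories.

Extinction is *defined* as total propensity zero — the simulation halting
— rather than any particular pattern of zeros among species, and the
tests assert it is absorbing.  The empirical extinction probability over a
seed sweep is reported with a 95% Wilson score interval.

## The text format

Models can be written in a small semicolon-terminated language
(`parse_biopepa()` / `write_biopepa()`): parameter assignments, kinetic
laws (`kineticLawOf r : expr;` with `+ - * /` and parentheses), species
declarations built from the four role operators with optional
stoichiometry, an optional `constant` annotation, and a final composition
line `A[1000] <*> B[0] <*> ...` carrying initial quantities.  The parser
is total over this grammar and reports line/column on failure; the
pretty-printer emits a canonical form that re-parses to a structurally
identical model, and parsing recognises pure mass-action laws
structurally (the expression must be one declared parameter times exactly
the reaction's rate-contributing species).  A ready-made model file for
the live regime ships as
`system.file("extdata", "mr_fig3.biopepa", package = "biopepa")`.
`write_sbml()` exports the reaction-centric view as SBML Level 3 core
with constant species flagged as boundary conditions.

## What the generator does and does not emulate

The presets are the exact published parameter regimes; nothing about
them is fitted.  What the package demonstrates on them — convergence,
collapse under a single degradation-constant change, and the life/death
dichotomy of identical-parameter stochastic replicates — are properties
of the idealized mass-action network: a well-mixed volume, a literally
constant source, integer molecule counts, no compartments, no transport,
no resource limits on the environment.  Real pathways violate all of
these to some degree, so passing tests certify the kernel's semantics and
the published regimes' behaviour, not biological realism.  The inhibitor
role is parsed and carried through the data model, but no built-in
inhibition rate law is supplied: a law touching an inhibitor must be
written out explicitly.

## Numerical choices and limitations

* ODE tolerances `1e-8`/`1e-10` (`1e-10`/`1e-12` inside the steady-state
  finder, which needs accurate derivatives near the plateau); `lsoda`
  switches between stiff and non-stiff methods automatically.
* The chi-squared comparison uses the oracle's exact probabilities as the
  null, so its degrees of freedom are the bin count minus one; leaked
  oracle mass is pooled into the remainder bin.
* Replicate sweeps reseed R's generator per replicate
  (`base_seed + r - 1`), so any replicate can be reproduced in isolation;
  batch helpers that draw many replicates from one stream are used only
  where a single distribution is being accumulated.
* Uniformization is exponential in horizon times uniformization rate
  (the Poisson series length) and linear in enumerated states; it is a
  verification tool for small instances, not a production engine.
* No tau-leaping or hybrid acceleration is provided; at the molecule
  counts studied here the exact method is fast enough, and exactness is
  the point.
* Bistability is demonstrated by direct simulation from the published
  initial condition only; no continuation or attractor-basin analysis is
  attempted, and the collapsed regime's long-run values are not asserted
  beyond "not the live steady state".
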