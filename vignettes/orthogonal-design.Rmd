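---
title: "Orthogonal pathway design: models, scores and valves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal pathway design: models, scores and valves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodesign)
```

## Motivation

Cellular metabolism is shaped for growth, while industrial fermentation
wants carbon routed to a product. Coupling the two — forcing product
secretion as a by-product of growth — wastes substrate on biomass and ties
productivity to the growth rate. The alternative studied here is an
*orthogonal* topology: substrate enters a branch point from which one limb
feeds biomass and the other converts carbon to the product, sharing as few
reactions as possible. A single shared reaction on the biomass limb then
acts as a *metabolic valve*: open during the growth phase, closed during
the production phase, when essentially all uptake is forced into product
at the guaranteed yield.

This vignette describes the models and procedures the package implements,
the parameters that matter, the numerical choices, and what the test suite
does and does not establish.

## Network model

A model (`sto_model()`) is a stoichiometry matrix over *internal*
metabolites (external metabolites are excluded from the mass balance, so
uptake and drain reactions appear as unbalanced columns), with per-reaction
reversibility, finite flux bounds in mmol gDW⁻¹ h⁻¹, and role tags. Three
roles anchor every analysis: the substrate **uptake** reaction, the
**biomass** drain, and the **target**-product secretion. SBML Level 3 +
`fbc` files carry no such semantics, so the loader takes the biomass
reaction from the active flux objective and everything else from an
explicit sidecar config (`read_roles_config()`); explicitness beats
inference here. A JSON dialect mirroring the in-memory types round-trips
models exactly.

Role-tagged reactions are non-deletable by default — cut sets should name
enzymes, not the substrate port or the drains — and the set is
configurable per analysis because exchange handling legitimately varies
case by case.

Defaults follow standard practice for sugar substrates: uptake capped at
20 mmol gDW⁻¹ h⁻¹, internal bounds 1000, product-yield demand
1 mol mol⁻¹, valve admission at 90% of wild-type growth.

## Elementary flux modes

All downstream quantities are functions of the network's elementary flux
modes: minimal-support nonnegative steady-state flux vectors, unique up to
scaling. `enumerate_efms()` implements the classic tableau
(double-description) iteration: reversible reactions are first split into
irreversible pairs, candidate rays start as the identity, each mass-balance
row is imposed by combining positive/negative ray pairs, and a
support-minimality sweep removes non-elementary rays at every step. Futile
two-cycles created by the splitting are discarded at the end.

Numerical choices: rays are renormalised to a unit maximum coefficient at
each step and entries below 10⁻⁹ (relative) are treated as zero; supports,
not magnitudes, are the fragile quantity, and at fixture scale (small
integer or simple fractional stoichiometries) this is exact in practice.
Mode order is lexicographic by support, so outputs are identical run to
run. A `max_modes` guard (default 500 000) aborts with a resource error
rather than exhausting memory on large networks.

The test suite checks the enumerator against an *exhaustive subset oracle*:
for every reaction subset of every fixture, the restricted stoichiometry is
tested for a one-dimensional, strictly one-signed null space, followed by a
minimality filter. On networks of ≤ 12 reactions this enumerates the exact
EFM set by construction and is entirely independent of the tableau code.

## The orthogonality score

Modes are partitioned into `S_x` (biomass flux, no target flux) and `S_t`
(target flux, no biomass flux); coupled and idle modes fall outside both.
For each pair the similarity `s(t, x) = |supp(t) ∩ supp(x)| / |supp(x)|`
is the shared fraction of the *biomass* mode's reactions — supports are
binary, flux values do not enter, and all reactions of the split network
(including uptake and drains) count. The per-pair orthogonality values
`1 − s` form a distribution; the score is their mean (`OS = 1 − AS`)
unless the distribution is multimodal, in which case the location of its
highest-density mode is reported instead. Multimodality is flagged by
Sarle's sample-corrected bimodality coefficient at the conventional 5/9
threshold; the mode location uses a Freedman–Diaconis histogram with ties
broken toward the higher bin (no canonical estimator exists, so the
package documents and fixes this one).

Interpretation: `OS = 1` iff every product mode is support-disjoint from
every biomass mode; `OS = 0` iff every biomass support is contained in
every product support. With `m = 0` (no product-only modes) or `n = 0`
(strong growth coupling) the score is *undefined*, and the package raises
a typed `od_undefined_score` error rather than inventing a number.

Two supporting metrics quantify the residual entanglement of production
with growth: the total and per-mode counts of support reactions in `S_t`
modes that *produce* a biomass-precursor metabolite. The package ships the
canonical twelve precursors (`canonical_precursors()`) as a default
configuration — the standard central-carbon list (G6P, F6P, R5P, E4P, GAP,
3PG, PEP, PYR, AcCoA, AKG, SucCoA, OAA) — flagged as an assumption to be
remapped per model.

## ValveFind

The design demand is: after deletions, *any* surviving steady-state flux
must achieve at least the yield threshold (default 1 mol product per mol
substrate), with no demand on growth. The modes to eliminate are therefore
exactly those with product yield below the threshold — all biomass-only
modes and low-yield product modes; high-yield growth-coupled modes may
survive. Minimal cut sets are the minimal hitting sets of the targeted
modes' supports restricted to deletable reactions, enumerated by the Berge
transversal iteration with minimalisation at each step (the contract is
algorithm-agnostic; brute-force hitting-set search verifies the family on
fixtures). Order is cardinality, then lexicographic.

Within each cut set, every member is probed as a valve: all other members
stay deleted, the candidate is restored, and FBA asks what fraction of
wild-type growth returns. Candidates at or above the growth fraction
(default 0.9) qualify; ties are broken toward fewer precursors
synthesizable with the valve closed, then lexicographically. Each design's
orthogonality score is computed on the *reduced* network — cut set
applied, valve on — and designs are ranked by score, then cardinality,
then lexicographically; designs whose reduced network cannot be scored are
flagged and ranked last. The valve-off audit attaches a temporary drain to
each precursor and maximises it by FBA, counting those with positive
attainable flux, and reports the maximum product yield with the valve
closed.

## Linear programming

FBA, FVA, envelopes and the audits all reduce to small dense LPs
(`S v = 0`, box bounds). These are solved by an in-package two-phase
primal simplex with Bland's anti-cycling rule. Flux-balance problems are
maximally degenerate (every right-hand side is zero), which defeats
naive pivoting; Bland's rule guarantees termination, and determinism
follows from its fixed index order. Upper bounds become slack rows,
variables are shifted to be nonnegative, and fixed (deleted) reactions are
eliminated from the basis entirely. The solver is dense and intended for
fixture-to-core scale, which is the package's scope.

Production envelopes define "percent open" as a fraction of the valve's
reference flux, taken as the FVA maximum of the valve at the wild-type
growth optimum (the natural operating flux; no other reference is
canonical). For each fraction the biomass axis is swept on a uniform grid
(default 50 points) from zero to its constrained maximum, recording the
product flux range at each point; axes are reported as yields per mol
substrate by default, and the area between the product bounds summarises
envelope size. Nested fractions give nested envelopes, which the tests
verify both pointwise and via strictly decreasing areas.

## Protein cost

The cost of running a pathway at unit input flux is
`Σ_r flux_r · mass_r / (kcat_r · η_sat,r · η_therm,r)` in g s mol⁻¹, with
`η_therm = 1 − exp(ΔG′/RT)` (the capacity fraction lost to backward flux;
requires ΔG′ < 0) and `η_sat` the multiplicative Michaelis–Menten
saturation over substrates, `Π (c/Km)/(1 + c/Km)`. Product inhibition
terms are deliberately omitted (substrate-side saturation only);
concentrations live in a physiological window of 1 µM–10 mM by default,
at 298.15 K (RT = 2.479 kJ mol⁻¹). All are configurable.

Feasibility is decided first by the max–min driving force linear program:
maximise the smallest `−ΔG′` over log-concentrations within bounds. A
non-positive optimum means no concentration assignment can drive every
step forward, and the package reports the bottleneck reactions. The cost
itself is *not* linear in log-concentrations — the saturation terms see to
that — so the minimisation proceeds by deterministic multistart local
descent: the MDF optimum plus a coarse interior lattice (5 points per
dimension) seed `L-BFGS-B` within the bounds, and the thermodynamic
barrier (cost diverging as ΔG′ → 0⁻) keeps iterates feasible. The tests
bound the optimizer against a dense 50-points-per-dimension grid scan on
two- to four-metabolite toy pathways: the optimizer must match or beat the
grid minimum and agree within 1%. The thermodynamic contribution reported
is the share of the optimal cost attributable to `η_therm`:
`(total − total with η_therm ≡ 1)/total × 100%`.

Absolute costs for real pathways depend on curated kcat/Km/ΔG′° values
supplied by the user (`read_kinetics_tsv()`); the package does not fetch
them from databases.

## Fixtures: what they emulate and what they do not

The generator (`build_fixture()`) provides five deterministic networks:
the normative `branched_toy` (two biomass routes, one independent product
branch; three EFMs; score 0.8), `branched_toy_redundant` (adds a shunt
that shares a biomass reaction, adding a fourth mode and lowering the
score to 0.7833 — the redundancy penalty the score is designed to
capture), `linear_chain` (no product route; `S_t` empty),
`diamond_coupled` (a shared trunk forcing ≥ 2 shared internal reactions
per pair), and `mini_glycolysis` (a lumped glycolysis-like network with a
reversible isomerase, fractional biomass coefficients and precursor tags).
Uptake is 20 mmol gDW⁻¹ h⁻¹ throughout, matching the standard operating
assumption.

These fixtures exercise every code path — branching, redundancy,
reversibility, coupling, undefined scores — at a size where exhaustive
oracles are feasible. They do **not** emulate genome-scale redundancy,
cofactor and energy metabolism, or the combinatorial growth of EFM counts
(real core models reach 10⁵ modes); passing tests establish correctness
of the algorithms, not scalability claims beyond core scale, nor
biological conclusions about any particular organism.

## Design choices where the design was open

- **Direction of the score.** The score is defined so that *higher = more
  orthogonal* (`OS = 1 − AS`); every ranking and comparison in the package
  assumes orthogonal designs score higher.
- **Supports include exchange/drain columns.** No exclusion rule is
  canonical; including all split-network columns is the documented
  convention and callers can restrict supports upstream if desired.
- **Unweighted intersections.** Similarity counts shared reactions
  (Boolean supports), not shared flux; weighting by flux would make the
  score scale-dependent across modes.
- **Valve reference flux** for envelopes is the wild-type FVA maximum, as
  the natural operating point of the reaction being throttled.
- **Exact arithmetic vs doubles.** Coefficients are doubles with per-step
  renormalisation and a 10⁻⁹ zero tolerance rather than exact rationals;
  the oracle-equivalence tests confirm exactness at the scales supported.
- **Problem sizes in tests.** Oracles run exhaustively on ≤ 12-reaction
  networks, cost grids at 50 points per dimension on ≤ 4 metabolites —
  sizes chosen so every expected value is independently computable.

## Known limitations

- The EFM enumerator and simplex are dense and single-threaded; they are
  built for fixture-to-core scale, not genome scale.
- Gene–protein–reaction mapping is out of scope: cut sets name reactions,
  not genes, and enzyme promiscuity is not modelled.
- The protein-cost optimizer is a local method with deterministic
  multistart; pathological non-convex landscapes could in principle evade
  it, which is why the grid oracle bound is part of the acceptance tests.
- Score comparisons across models with different exchange conventions are
  only meaningful if the support convention is held fixed.
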