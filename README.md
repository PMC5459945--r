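# orthodesign

Tools for designing microbial production strains in which chemical synthesis
is *orthogonal* to growth: carried by a branch of the metabolic network that
shares as few reactions as possible with biomass formation, and gated by a
single controllable "valve" reaction instead of being coupled to growth.

The package targets metabolic engineers and systems biologists working with
small to core-scale stoichiometric models. It covers:

- **Elementary flux mode (EFM) enumeration** (`enumerate_efms()`), with
  partitioning of modes into biomass-only (`S_x`) and product-only (`S_t`)
  sets.
- **An orthogonality score** (`orthogonality_score()`) quantifying how
  separable production is from growth.
- **ValveFind** (`select_target_modes()`, `enumerate_mcs()`,
  `find_valves()`, `rank_designs()`): minimal cut sets that guarantee a
  product yield at zero growth, plus identification of a valve reaction
  whose reactivation restores near-wild-type growth.
- **FBA / FVA and valve-throttled production envelopes**
  (`fba()`, `fva()`, `production_envelope()`).
- **Pathway protein cost** (`minimize_pathway_cost()`): minimum enzyme
  demand of a pathway with thermodynamic and saturation decomposition.

## The score

Let `S_t` be the set of EFMs that secrete the target chemical without
producing biomass, and `S_x` the set that produce biomass without the
target. For a product mode `t` and a biomass mode `x`, the similarity is
the shared fraction of the biomass mode's reactions,

```
s(t, x) = |supp(t) ∩ supp(x)| / |supp(x)|
```

and the average similarity over all m·n pairs is

```
AS = (1 / m n) Σ_{t∈S_t} Σ_{x∈S_x} s(t, x).
```

The orthogonality score is `OS = 1 − AS` (per-pair values `1 − s` are
averaged when their distribution is unimodal; when Sarle's bimodality
coefficient exceeds 5/9 the location of the highest-density mode is used
instead). `OS = 1` means production and growth share no reactions;
`OS = 0` means every biomass route is contained in every production route;
with no product-only modes (m = 0) or under strong growth coupling (n = 0)
the score is undefined and the package raises a typed error.

## Worked example

The built-in `branched_toy` network converts substrate A either through
two biomass routes (A→B→C→E, A→B→D→E, E drained by `v_bio`) or through an
independent product branch (A→P, drained by `v8`):

```r
library(orthodesign)

m <- build_fixture("branched_toy")
efms <- partition_modes(enumerate_efms(m))
efms
#> <od_efm_set: 3 modes over 9 reactions>
#>   partition: 2 biomass-only (S_x), 1 product-only (S_t), 0 coupled, 0 neither

orthogonality_score(efms)
#> Orthogonality score: 0.8  (average similarity 0.2; m = 1, n = 2)
```

Each biomass mode has 5 reactions and shares exactly one (the uptake) with
the product mode, so `AS = 1/5` and `OS = 0.8`. ValveFind then asks: which
minimal deletion sets force every surviving flux to a product yield of at
least 1 mol/mol, and which deleted reaction can serve as a growth valve?

```r
targets <- select_target_modes(efms, yield_threshold = 1)
mcs <- enumerate_mcs(targets, efms,
                     deletable = setdiff(m$reactions$id, c("R_up", "v_bio", "v8")))
rank_designs(m, mcs, precursors = c("B", "C", "D", "E"))
#> <od_design_list: 5 valve designs>
#>   {v1} valve=v1 growth=1 score=0.8 precursors_off=0
#>   {v2,v3} valve=v2 growth=1 score=0.8 precursors_off=1
#>   {v2,v5} valve=v2 growth=1 score=0.8 precursors_off=2
#>   {v3,v4} valve=v3 growth=1 score=0.8 precursors_off=2
#>   {v4,v5} valve=v4 growth=1 score=0.8 precursors_off=3
```

The top design deletes only `v1` and uses it as the valve: closed, growth
is zero, no biomass precursor is reachable and all carbon goes to product
at yield 1; open, the strain grows at 100% of the wild-type rate.
Throttling the valve shrinks the production envelope toward the high-yield
zero-growth edge:

```r
production_envelope(m, "v1")
#> <od_envelope_set>
#>   valve 100% open: 50 points, area 0.5
#>   valve  50% open: 50 points, area 0.375
#>   valve  20% open: 50 points, area 0.18
#>   valve  10% open: 50 points, area 0.095
#>   valve   5% open: 50 points, area 0.04875
```

A thin command-line wrapper over the same functions ships in
`inst/cli/orthodesign.R` (subcommands `score`, `valvefind`, `envelope`,
`fixtures`).

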