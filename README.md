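# heterogame

Game-theoretic models of phenotypic heterogeneity in microbial
competition.

Marine microbe communities harbor enormous phenotypic heterogeneity, and
vast numbers of species coexist in seemingly unstructured environments —
at odds with classical theory in which selection narrows traits around an
optimum and competitive exclusion prunes species sharing a niche.
`heterogame` implements a non-cooperative game for asexually reproducing
microbes that links individual-level cell-to-cell competition to
species-level population dynamics, and shows how *maximal* trait
variability is itself a coexistence mechanism. It is aimed at theoretical
ecologists and modellers who want to compute with the model: evaluate its
payoffs, classify and verify equilibrium strategies, design
counter-strategies, and run the individual-based tournament experiments.

## The model

A species is a *strategy*: a distribution of a scalar competitive ability
(CA) on [0, 1], scaled by population abundance. In the discrete model a
strategy is a map `B` on the grid `x_j = j/M` with weights `B(x_j) ≥ 0`,
abundance `|B| = Σ_j B(x_j) > 0`, and mean competitive ability

    MCA(B) = (1/|B|) Σ_j x_j B(x_j) ≤ 1/2,

the bound reflecting that individuals are not perfect. The continuous
model replaces weights with a density `f` on [0, 1] (`F(1) > 0`,
`MCA(f) ≤ 1/2`). Individuals meet pairwise; the higher CA wins (+1: it
replicates), the lower loses (−1: it dies), equal CAs draw (0). With all
`n` species competing at once, the payoff to species `A_k` is

    ℘(A_k) = (1/Σ_ℓ |A_ℓ|) Σ_j A_k(x_j) [ Σ_{i<j} P(x_i) − Σ_{i>j} P(x_i) ],

where `P` pools all species' weights; payoffs are zero-sum and give the
expected change in population abundance. The equilibrium strategies —
those from which no species can unilaterally improve — are completely
characterized: positive constant weights for odd `M`; for even `M` the
alternating two-level pattern with `MCA = 1/2`; positive constant
densities in the continuous model. They are maximally heterogeneous,
neutral towards any strategy of equal MCA (hence unlimited coexistence),
and dominant over any lower-MCA strategy. Every non-equilibrium strategy
can be defeated by an equally-fit designer distribution; the package
constructs one (`design_counter_strategy()`), the "Lake Wobegon"
two-point distribution that eliminates the invariant strategy being the
canonical example.

## Worked example

```r
library(heterogame)

comm <- community(
  make_invariant(0.5, 1000, label = "invariant"),
  make_lake_wobegon(1000, 0.5, 1000, label = "lake_wobegon")
)
payoff_discrete(comm)
#> # A tibble: 2 × 3
#>   species      abundance payoff
#>   <chr>            <dbl>  <dbl>
#> 1 invariant         1000   -499
#> 2 lake_wobegon      1000    499
```

Both strategies have MCA exactly 0.5 and abundance 1000, yet the
invariant strategy (all individuals at CA 0.5) is expected to lose 499
individuals per round: Lake Wobegon concedes one individual in a
thousand at CA 0 and places everyone else just above 0.5, winning 99.9%
of cross-species contests. The tournament simulator realizes the
prediction:

```r
run_simulation(comm, rounds = 50, seed = 42)
#> <competition_sim> 2 species, 50 rounds, seed 42
#> final counts:
#>    invariant lake_wobegon
#>            0         2000
#> extinctions:
#>     species round
#> 1 invariant     4
```

The designer itself, for any non-equilibrium target:

```r
design_counter_strategy(make_invariant(0.5, 1000))
#> <counter_strategy> expected score 0.998049 (two-point mixture x = (0, 0.500488) at mean 0.5)
#> <discrete_strategy> counter_invariant: 2 support points, abundance 1000, MCA 0.5
```

while equilibrium strategies are flagged as undefeatable, and any
collection of them is verified as an equilibrium point:

```r
design_counter_strategy(make_uniform(8))$equilibrium
#> [1] TRUE
verify_equilibrium_point(
  community(make_uniform(5, 1), make_uniform(5, 10), make_uniform(5, 100))
)$is_equilibrium
#> [1] TRUE
```

The figure-level experiments (elimination of the invariant strategy,
coexistence of equal-MCA strategies, persistence of a rare equilibrium
population, competitive exclusion, small-population breakdown,
many-species coexistence) are registered scenarios:

```r
list_scenarios()
run_scenario("s1", seed = 1)   # lower-MCA competitor excluded
```

A command-line front end over the same functions ships in
`inst/cli/heterogame` (`payoff`, `equilibrium-check`, `counter`,
`simulate`, `reproduce`), with communities described in YAML or JSON.

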