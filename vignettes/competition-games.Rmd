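---
title: "Competition games with phenotypic heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition games with phenotypic heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterogame)
```

This vignette is the package's account of the science it implements: the
competition game, its equilibrium structure, the numerical choices
behind the payoff engine and the best-response oracle, what the
individual-based simulator does and does not emulate, and the design
decisions that were genuinely open.

## The game

A species plays a *mixed strategy over competitive abilities*: a
distribution on $[0,1]$ scaled by its population abundance. Discrete
strategies put weights $B(x_j) \ge 0$ on a finite support (canonically
the grid $x_j = j/M$) with abundance $|B| = \sum_j B(x_j) > 0$;
continuous strategies are densities $f \ge 0$ with $F(1) = \int_0^1 f >
0$. Both are constrained by the mean competitive ability,
$\mathrm{MCA} \le 1/2$ — a biological bound expressing that individuals
are not perfect. Abundances are nonnegative reals; they need not be
integers (only the simulator maintains integer head-counts).

Individuals meet pairwise and the higher ability wins: the winner's
species replicates, the loser dies, ties draw. Summing the win/lose
kernel over all ordered pairs of atoms and dividing by the community's
total abundance gives the multi-species payoff (the expected abundance
change per round); it is zero-sum by the antisymmetry of the kernel, and
a species' interactions with itself cancel, so internal competition
never moves its own abundance.

## Equilibrium structure and the oracle

Equilibrium strategies — members of communities in which no species can
improve by a unilateral change — have a closed-form characterization on
the grid: constant positive weights when $M$ is odd; when $M$ is even,
even-index weights equal to $B(x_0) > 0$, odd-index weights equal to
$B(x_1) > 0$, and $\mathrm{MCA} = 1/2$ (implied by the pattern, but
checked explicitly as stated). In the continuous model the equilibrium
strategies are exactly the positive constant densities. Equilibria are
closed under addition, neutral towards any equal-MCA strategy, and
dominant over any lower-MCA strategy.

`verify_equilibrium_point()` checks the definition directly rather than
the characterization: because self-interaction cancels, a deviator's
payoff is *linear* in its normalized weights, so the best deviation over
$\{w \ge 0,\ \sum w = a,\ \mathrm{MCA} \le 1/2\}$ is attained at a
vertex of that polytope — a single support point at or below $1/2$, or a
two-point mixture straddling $1/2$ held at mean exactly $1/2$.
`best_response()` enumerates all $O(M^2)$ vertices exactly; no iterative
optimizer, no tolerance beyond the $10^{-9}$ gain threshold.

Three methodological points deserve emphasis:

* **The characterization is a grid statement.** An atom placed just
  above a grid point (or just above any atom of a finite-support
  strategy) wins every contest that the grid point itself would only
  draw. A two-point mixture $(0,\ 1/2 + \delta)$ with mean held at $1/2$
  obtains a strictly positive expected score against the uniform grid
  strategy whenever $\delta < 1/(2M)$. Deviations in
  `best_response()`/`verify_equilibrium_point()` are therefore
  restricted to the community's shared canonical grid, which is the
  setting in which the characterization holds; off-grid supports raise a
  domain error in the classifier.
* **Classifying a single strategy via the oracle** uses a community of
  *two copies* of the strategy: a one-species community is trivially an
  equilibrium point (every deviation against an empty opponent pool
  scores zero), whereas the pair community is an equilibrium point
  exactly when the strategy is an equilibrium strategy.
* **Boundary cases with zero weights.** A strategy such as $(0, 1, 0)$
  on the $M = 2$ grid is rejected by the classifier (weights must be
  positive) yet admits no *strictly* improving on-grid deviation, so the
  weak-inequality oracle calls it an equilibrium. The discrepancy lives
  on a measure-zero boundary; the randomized concordance suites draw
  strictly positive weights, and the package documents rather than hides
  the edge.

## Counter-strategy design

For a non-equilibrium target the package constructs an equally-fit
defeater: mean competitive ability **equal to the target's** (not the
looser $1/2$ bound), expected pairwise score strictly positive. The
search space is the same vertex geometry as the best response, but over
a candidate set adapted to the target: ability $0$, the target's own
atoms (exploiting draws), and points just above each atom (converting
draws and losses into wins), offset by a $2^{-10}$ fraction of the gap
to the next candidate. Against the invariant strategy at $0.5$ this
reproduces the Lake Wobegon construction — one individual conceded at
ability $0$, the rest just above the mean. On-grid targets are first
classified in closed form, and equilibrium strategies return an explicit
flag: no defeating strategy exists. A target with $\mathrm{MCA} = 0$
(all mass at ability $0$) is undefeatable under the equal-MCA bound and
is also flagged; defeating it requires the $1/2$ bound instead, which
the best-response oracle covers.

## The simulator

The tournament realizes the discrete game at the individual level. Each
round: every individual draws a fresh ability from its species'
normalized strategy (no heritability — prior outcomes never bias the
draw), the pooled community is paired by a uniform-random perfect
matching, and each pair is resolved by the win/lose/draw kernel, moving
one head-count per decisive pair. Declared conventions, where the
underlying description leaves freedom:

* the *whole* community competes each round (the competing fraction is
  maximal); an odd pooled count sits one uniformly chosen individual
  out;
* intra-species pairs are resolved like any other (their net effect is
  zero by construction);
* extinction is exactly zero individuals, recorded at the first round it
  occurs; extinct species are never resampled;
* one seedable RNG stream; a trajectory is bit-reproducible from
  (community, rounds, seed), and replicate batches derive per-replicate
  seeds from the batch seed.

With an even pooled count $N$ the expected one-round change per species
equals the analytic payoff times $N/(N-1)$ (an individual is matched
with one of $N-1$ others, never itself); `estimate_expected_change()`
exposes the Monte Carlo side of that identity and the test suite holds
the two within three standard errors.

**Grid coarseness versus designer offsets.** The Lake Wobegon strategy
for population size $n$ places its upper atom at $1/2 + 1/(2(n-1))$ —
an offset of $5 \times 10^{-4}$ at $n = 1000$. If the "uniform" species
is discretized on a grid coarser than this offset, the atom tie-snipes
the grid (it beats the grid point it should effectively tie with) and
the equal-MCA neutrality that the theory guarantees is lost: at $M = 10$
the uniform species loses about $0.09$ per cross contest instead of $0$.
The simulator therefore samples continuous strategies directly
(inverse-CDF; exact `runif()` draws for constant densities), and the
registered experiments represent maximal heterogeneity by the continuous
uniform, which is neutral to machine precision against any equal-MCA
competitor. Users composing their own discrete experiments should keep
$1/M$ small relative to any designer atom's offset.

## Payoff engine numerics

Finite supports are merged to the union grid with zero padding before
the payoff sum is evaluated; ties arising from merged supports score
exactly zero. Continuous payoffs prefer exact piecewise-polynomial
antiderivatives (`continuous_constant()`,
`continuous_piecewise_linear()`, or explicit segment coefficients);
arbitrary callables fall back to adaptive quadrature at absolute
tolerance $10^{-10}$, and a non-converging quadrature raises an error
carrying the estimated error rather than returning silently. The MCA
constraint carries a $10^{-9}$ tolerance to absorb floating-point
construction error; weight-equality checks in the classifier are
relative at $10^{-9}$.

## The experiment registry

Each registered scenario fixes a community, a round count, a replicate
count (default 100) and a success criterion computable from trajectories
alone. Sizes follow the simulated regimes of the underlying experiments
($10^2$–$10^3$ individuals per species); where the source runs were
single exemplars, the registry runs replicate batches and reports
frequencies. Declared choices:

* **fig4** invariant vs Lake Wobegon, 1000 each, 100 rounds; criterion:
  invariant extinct in $\ge 90\%$ of replicates.
* **fig5/fig6** equal-MCA pairs at 1000 each, 50 rounds; both extant in
  $\ge 90\%$.
* **fig7** uniform plus four equal-MCA competitors; uniform extant in
  $\ge 90\%$.
* **fig8** the rare-invader setting: uniform at 200 individuals — 1% of
  each competitor (invariant and Lake Wobegon at 20,000) — for 30
  rounds. The sizes were chosen by a hitting-time argument: the rare
  neutral species' per-round change has standard deviation
  $\approx \sqrt{0.9\, n_u}$, so 200 individuals sit
  $200/\sqrt{30 \cdot 180} \approx 2.7$ standard deviations from
  absorption over the run — far enough that persistence, the claim under
  test, is the expected outcome rather than a coin flip.
* **fig9** scaled to 25 equilibrium species $\times$ 200 individuals
  $\times$ 50 rounds (the full-size hundreds-of-species setting is the
  same code at larger `counts`); criterion: $\ge 90\%$ of species extant
  on average. "Fewer than a handful of extinctions" is not a precise
  number; the threshold is a declared interpretation.
* **s1** uniform vs invariant at MCA 0.3; the lower-MCA species extinct
  in $\ge 95\%$ — the competitive-exclusion check.
* **s2** uniform vs Lake Wobegon at matched $n \in \{10, 100, 1000\}$,
  100 rounds; criterion: uniform extinction frequency strictly
  decreasing in $n$. At $n = 10$ a ten-draw sample cannot represent a
  uniform distribution faithfully, and chance dominates.

## What the synthetic experiments do and do not show

The generator draws iid abilities from exactly the stated strategy
distributions, pairs individuals uniformly, and conserves total
head-count. Passing scenarios therefore demonstrate the *model's*
internal predictions — neutrality, dominance, designer defeat, drift at
small $n$ — under clean sampling. They do not emulate real microbial
data: no environmental fluctuation or resource dynamics, no spatial or
network structure in pairing, no overlapping generations, no mutation or
heritability of abilities, and abundances capped only by memory. The
MCA $\le 1/2$ bound is a modelling constraint, not an empirical
calibration.

## Known limitations

* The equilibrium machinery for communities requires a shared canonical
  grid; arbitrary mixed finite supports are handled by the payoff engine
  but not by the equilibrium verifier.
* The weak-inequality boundary cases with zero weights (above) mean
  classifier and oracle can disagree on measure-zero inputs.
* The counter-strategy designer guarantees a strictly positive expected
  score, not the *maximal* one; its candidate offsets are finite, so the
  supremum (approached as the offset shrinks) is not attained.
* Continuous strategies enter the simulator through a 2049-point
  inverse-CDF lattice except for constant densities, which are exact.

## Problem sizes

The shipped test and experiment sizes — communities up to $4 \times 10^4$
individuals, batches of 100 replicates, randomized suites of a few
hundred cases per grid size — were chosen as comfortable desk-scale runs;
all of the package's claims are insensitive to scaling these up, and the
registry exposes `replicates`, `rounds` and abundances as overrides.
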