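---
title: "Models of selection on vitality and longevity under eusocial reproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of selection on vitality and longevity under eusocial reproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(eusim)
```

## The scientific question

Eusocial animals — ants, bees, termites, naked mole-rats — channel all
reproduction through a single queen, and they are conspicuously long-lived.
`eusim` implements a modeling stack for one candidate explanation: the
*reproductive structure itself* changes which component of mortality
selection acts on.

Mortality is modeled by the Gompertz–Makeham hazard

$$h(n) = \alpha e^{\beta n} + \gamma,$$

where $\alpha$ is the baseline hazard at age 0, $\beta$ the exponential
rate at which hazard grows with age, and $\gamma$ an age-independent term.
We call the inverse of $\alpha$ **vitality** ($V$) and the inverse of
$\beta$ **longevity** ($L$): an allele of high vitality protects the young,
an allele of high longevity slows aging. A heritable allele carries a
$(V, L)$ pair; competing alleles trade one against the other
(antagonistic pleiotropy). The question is which trait wins under
*exponential* reproduction (every female breeds) versus *linear*
reproduction (only the queen breeds).

## The (V, L) to (alpha, beta) mapping

The mapping is the package's own calibration, exposed in
`mapping_config()`:

* $\beta = \ln 2 / L$ — $L$ is the mortality-doubling half-life, about 9
  years in humans, and the standard allele pairs use $L$ of 9 and 10.
* $\alpha = \alpha_\mathrm{ref}\, V_\mathrm{ref} / V$ — inverse
  proportionality anchored at $V_\mathrm{ref} = 1000$.

Both choices follow the qualitative definition of the traits (vitality
inverse to $\alpha$, longevity inverse to $\beta$); any monotone-inverse
alternative can be substituted through the `rule` extension point. The
default $\alpha_\mathrm{ref} = 0.005$ puts the reference allele's median
lifespan near 32 ticks, i.e. a tick is roughly a quarter-year of a human
scale life. This value was fixed once, jointly with the default life-history
parameters below, so that the standard allele competition reproduces the
qualitative regime of interest (a linear population that is old enough for
longevity to pay; see "Calibration" below), and is not adjusted per
experiment.

With hazard integrated exactly over a step, the probability of dying
between ages $n$ and $n + dt$ is

$$D_n = 1 - \exp\!\left[-\frac{\alpha}{\beta} e^{\beta n}
  \left(e^{\beta\,dt} - 1\right) - \gamma\,dt\right],$$

with an exact constant-hazard branch at $\beta = 0$ (not a small-$\beta$
approximation). Survival products therefore telescope to
$\exp(-\int h)$ exactly, which the test suite exploits as an oracle.

## The analytical age-structured model

`step_age_structured()` advances abundance-by-age vectors for two alleles:
survival first, then the birth law fills age 0 from the abundances at the
previous tick. Two birth laws are provided (`growth_law()`):

* **linear**: a queen contributes $g$ offspring per interval, split by
  allele frequency;
* **exponential**: each allele receives
  $g\,N_s X / (2 (N_s + N - 2))$ births — all females breed, saturating
  at scale $N_s$ ($S(2) = 2$ so a founding pair is unconstrained).

Both laws have the form $X_i = p_i H(A, B)$ with a shared factor $H$, and
under that form only competitive-exclusion steady states are attainable;
the winner is decided by the sign of the summed-survivorship difference

$$\Delta F = \sum_{n\ge 1} \prod_{k=0}^{n-1} (1 - D_k)
           - \sum_{n\ge 1} \prod_{k=0}^{n-1} (1 - d_k),$$

computed by `delta_F()`. The series is truncated when survivorship falls
below $10^{-12}$; because the terms decay superexponentially the truncated
tail is bounded by the geometric tail $l_n (1-D_n)/D_n < 10^{-11}$ for any
admissible parameters, which is below double-precision noise for the sums
involved. The same threshold caps the number of age classes carried by the
state vectors.

```{r delta-f}
m <- mapping_config()
pV <- allele_to_gompertz(allele("vitality", 1000, 9), m)
pL <- allele_to_gompertz(allele("longevity", 900, 10), m)
delta_F(pV, pL)
```

### Carrying-capacity matching and nullclines

Comparing growth modes fairly requires equal carrying capacities. With
identical mortality the exponential population equilibrates larger, so
`match_gamma()` raises the age-independent hazard of the exponential
population to $\gamma' \ge \gamma$ (scalar root solve on the single-allele
steady-state size, computed by iterating the update map) until the two
steady states agree. The matched exponential population is younger on
average — the analytical footprint of the resource-pressure argument. Note
the feasibility constraint: the exponential steady state has the lower
bound $N_s (g/2 - 1) + 2$ even under extreme mortality, so $N_s$ must be
comparable to the linear carrying capacity for a match to exist; the
function reports an explicit error otherwise.

`nullcline()` then maps tradeoff space: the competitor's hazard is
$(1-x)\,\alpha\, e^{(1-y)\beta n} + \gamma$, with $x$ (vitality change)
and $y$ (longevity change) of opposite signs, and for each $x$ a
bracketed root solve in $y$ finds the neutral curve $\Delta F = 0$ through
the origin. $\Delta F$ is monotone in $y$, so the bracket is certified by a
sign change before refinement; grid points without a sign change are
returned as `NA` rather than extrapolated. The slope magnitude at the
origin measures how much longevity must be paid for vitality: it is
several-fold larger for the $\gamma'$-matched exponential population
(about $-5.4$ versus $-0.56$ for the defaults used in the tests), i.e. the
linear population is relatively more sensitive to longevity.

## The colony-site competition ODE

At the colony level, allele-typed colonies compete for $M$ sites:

$$\frac{dA}{dt} = (k_A r - D_A)\,A, \qquad
  \frac{dB}{dt} = (k_B r - D_B)\,B, \qquad r = M - A - B.$$

Each colony seeds empty sites at per-colony rate $k\,r$ and collapses at
rate $D$. (The per-colony multiplication is required for the stated
steady-state structure — the empty landscape as a fixed point and the
invasion-stability rule below — and matches the verbal definition of the
rates.) The three steady states are the empty landscape and two exclusion
states with $r_i = D_i / k_i$; the exclusion state with the *lower* $r$ is
stable, because a state with more free sites can be invaded by the other
type. `colony_steady_states()` labels these (ties are reported as neutral,
not broken), and `integrate_colony_ode()` integrates explicitly with
adaptive step halving on sign violations — the system is non-stiff at
these scales, and site conservation holds identically because $r$ is
recomputed from the state. If a monotone map sends larger steady colony
size to larger $k$ and smaller $D$, the allele that wins within colonies
also wins the site competition — colony-level exponential growth does not
overturn individual-level selection.

## The agent-based simulator

`run_competition()` competes two alleles in a diploid, two-sex,
individual-based population. Each tick:

1. every individual dies with probability
   $1 - (1 - D_\mathrm{age})(1 - d(N))$, combining its phenotype's
   Gompertz risk with the logistic density risk
   $d(N) = 1/(1 + e^{-(N - K)/w})$ as independent hazards;
2. in linear mode a dead queen is replaced by a female drawn uniformly at
   random (an immature successor holds the position but breeds only once
   mature);
3. births: in linear mode the (mature) queen breeds with probability
   `p_repro` with a uniformly drawn mature male; in exponential mode every
   mature female does so independently. Offspring get one uniformly chosen
   gene copy per parent and a uniformly random sex;
4. survivors age by one tick. Newborns enter at age 0 and neither die nor
   reproduce in their birth tick.

This update order (deaths, succession, births, aging) is fixed; the main
consequence of the choice is that newborns are first exposed to mortality
one tick after birth, so age-0 mortality is experienced exactly once.

The Makeham term defaults to zero in the simulator: density mortality
plays the age-independent role. Density dependence uses the simplest
monotone saturating form consistent with a "logistic increase of mortality
with population size"; midpoint `K` and width `w` are config-exposed. The
density risk multiplies survival rather than adding to the hazard, which
makes crowding deaths allele-blind — a conservative choice that weakens,
never mimics, selection (see "Calibration").

Heterozygote phenotype follows the `dominance` rule: the flagged dominant
allele masks the other, or `"codominant"` averages $V$ and $L$.

Founding populations are homozygous adults at the target allele frequency,
with genotypes balanced **within** each sex — otherwise the first queen's
genotype would be biased, which is easily detectable as a departure from
neutrality in identical-allele competitions (the suite tests this).

### Calibration and what the defaults mean

The default configuration — `maturity_age = 5`, `p_repro = 1`,
`litter_size = 1`, `K = 400`, `w = 40`, `init_size = 100`,
$\alpha_\mathrm{ref} = 0.005$ — defines the package's study conditions for
the standard competition of a dominant vitality allele $(V{=}1000, L{=}9)$
against a recessive longevity allele $(V{=}900, L{=}10)$ from a 50/50
start:

* In **linear** mode the population equilibrates near 30 individuals
  (far below `K`), the queen succession chain dominates inheritance, and
  the longevity allele fixes in roughly 55–58% of replicates. Drift is
  strong — the queen bottleneck keeps the effective population size near
  ten regardless of census size — so the preference is a shifted coin, not
  a deterministic sweep.
* In **exponential** mode the population grows to the density ceiling,
  most deaths are crowding deaths at young ages, and the longevity allele
  fixes in well under half of replicates (about 0.44 at `K = 400`,
  about 0.35 at `K = 600`; the selection intensity scales with how much of
  total mortality is age-structured, hence with `K`).

Two caveats documented deliberately: first, because the density risk is
allele-blind by construction, exponential-mode selection against longevity
is weaker here than it would be if crowding interacted with frailty, and
the exponential fixation fraction does not drop to the few-percent range
at these population scales — only the direction, not the magnitude,
is scale-independent. Second, all stochastic results above are study
conditions chosen once; the test suite measures them at fixed seeds and
replicate counts and asserts directions and calibrated bands, never
re-tuned per run.

## Colony reproduction (ant and mole-rat modes)

`metapop_run()` superimposes exponential colony reproduction on linear
within-colony reproduction. Shared machinery: a colony is a linear-mode
population; founding succeeds with probability
$1/(1 + e^{(C - C_\mathrm{cap})/w_c})$ in the current colony count $C$
(the logistic cap on colony numbers); a colony at or above
`threshold_colony_size` may attempt founding each `flight_interval` ticks.

* **Ant mode**: a founding event creates a lone daughter queen of the
  source queen, mated on a "mating flight" with a male drawn from all
  threshold-size colonies (the simplest faithful reading of intermittent
  population-wide flights); she stores his genotype as an inexhaustible
  sperm supply and breeds from it. The colony dies with its queen.
* **Mole-rat mode**: founding sends `pioneers_per_event` members (capped
  to leave the source one member); a random pioneer female becomes queen,
  and mating happens within the colony. Failed foundings lose the
  pioneers. Dead queens are replaced after
  `ticks_to_queen_replacement`; each colony faces a per-tick disaster
  probability that kills each member with `p_disaster_kill`.

A founding ant queen enters at `maturity_age` — she is a mated adult, not
an egg — so new colonies begin producing immediately; without this, most
ant colonies would die with a queen that never filled them.

The disaster probability defaults to 0.045 per tick, the typical literature
rate. One scaling note: at this package's tick scale an individual lifespan
is only ~30 ticks, so 0.045 makes colony lifetime comparable to an
individual lifetime and almost all deaths colony-wide and allele-blind. The
mole-rat experiments in the tests therefore run at `p_disaster = 0.01`
(colony lifetime of ~100 ticks, a few individual generations), which keeps
colony turnover while letting within-colony inheritance operate; this is a
tick-scale alignment, exposed in the config like every other rate.

Colony-level selection in this simulator expresses only through
differential *time above the founding threshold*: colonies must be
mortality-limited (their equilibrium below the density ceiling `K`), or
every colony pins at the same size and colony selection vanishes. The
ant-mode experiments use a larger litter so that the time to threshold is
short and queen lifespan dominates colony output; the mole-rat experiments
use spaced founding events so colonies can grow past the threshold.

## The queen-effects-only model

To isolate the effect of channeling reproduction through one female,
`match_populations()` makes a linear and an exponential population
demographically equivalent: it raises the queen's fecundity (linear) and
tunes the per-female reproduction probability (exponential) until long-run
mean sizes agree within 5% and the pooled age distributions agree
(maximum absolute ECDF difference below 0.05 — a two-sample sup-distance
on ages). Matching the per-tick *birth flows* is the control signal: equal
sizes, equal inflows and identical mortality configuration force the same
stationary age structure. Verification runs on fresh seeds.

`invasion_experiment()` then introduces a few invader homozygotes into a
burned-in resident population (burn-in defaults to ten times the
resident's 1%-survivorship age) and estimates the fixation probability
$f$; the **fixation bias** $FB = f/p_0 - 1$ is zero for a neutral invader.
Burn-ins are shared across blocks of replicates (a fresh resident
population every 25 replicates) purely to bound cost; introduction and all
subsequent dynamics are per-replicate. Invaders enter as mature adults at
`maturity_age`, which is age-advantaged relative to the stationary
population; this shifts $f$ equally for every invader allele in a given
population type, and the quantity of interest — the *sign change* of FB
along a vitality grid — compares alleles within a type.
`neutral_threshold_scan()` locates that sign change by linear
interpolation, with a CI envelope interpolated from the Wald bounds.

In the linear population the FB curve is strongly drift-flattened (the
queen bottleneck again): resolving its crossing takes thousands of
replicates per grid point, and the scan reports censored results rather
than extrapolating when the grid does not bracket a sign change. The
queen-effects contrast in this package is correspondingly a
statistically delicate measurement, and the acceptance experiment runs it
at the largest replicate counts that fit its time budget.

## Known limitations

* One biallelic locus; no mutation, recombination, or multi-locus
  genetics.
* The $(V, L)\to(\alpha,\beta)$ mapping is a calibration, not a measured
  quantity; all headline percentages depend on it, only directions are
  robust to it.
* Density mortality is allele-blind by construction (see above).
* Colony sites have no spatial structure; founding and collapse rates are
  global.
* The synthetic populations are demographically idealized (even sex
  ratios, uniform mating); passing tests show internal consistency of the
  selection mechanisms, not fit to any empirical colony data.
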