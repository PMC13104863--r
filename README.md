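# eusim

Simulation and analysis toolkit for a question from life-history theory:
**does eusocial (single-queen) reproduction select for longevity?**

Mortality follows the Gompertz–Makeham law, `h(n) = α·e^{βn} + γ`. Two
heritable traits trade off against each other:

* **Vitality** `V ∝ 1/α` — robustness at young ages;
* **Longevity** `L ∝ 1/β` — the mortality-doubling half-life, i.e. how
  slowly risk grows with age.

An allele carries a `(V, L)` pair; a high-vitality allele competes against
a high-longevity allele in populations that reproduce either
**exponentially** (every female breeds) or **linearly** (only the queen
breeds). The package provides, in idiomatic base R:

* a deterministic age-structured competition model with the
  summed-survivorship fitness difference
  `ΔF = Σₙ Πₖ (1 − Dₖ) − Σₙ Πₖ (1 − dₖ)` whose sign decides competitive
  exclusion (`delta_F()`, `steady_state()`), carrying-capacity matching via
  the Makeham term (`match_gamma()`), and fitness nullclines in tradeoff
  space (`nullcline()`);
* a colony-site competition ODE `dA/dt = (k_A r − D_A)A` with
  competitive-exclusion steady states and stability labels
  (`colony_steady_states()`, `integrate_colony_ode()`);
* a diploid agent-based simulator of allele competition with Mendelian
  genetics, dominance, density-dependent mortality, and single-queen or
  all-female reproduction (`run_competition()`, `fixation_experiment()`);
* colony-level metapopulation simulators in **ant** mode (mating flights,
  stored sperm, colony dies with its queen) and **mole-rat** mode
  (pioneer groups, in-colony queen replacement, disasters)
  (`metapop_run()`, `metapop_experiment()`);
* a queen-effects-only invasion model on demographically matched
  populations, measuring the fixation bias `FB = f/p₀ − 1` of invading
  alleles (`match_populations()`, `invasion_experiment()`,
  `neutral_threshold_scan()`).

See the vignette (`vignettes/eusocial-longevity-models.Rmd`) for the
models, their assumptions, and the calibration choices.

## Worked example

Compete the standard dominant vitality allele `(V=1000, L=9)` against the
recessive longevity allele `(V=900, L=10)`, both starting at 50%:

```r
library(eusim)
aV <- allele("vitality", 1000, 9, dominant = TRUE)
aL <- allele("longevity", 900, 10)

# deterministic fitness difference (positive: vitality wins)
m <- mapping_config()
delta_F(allele_to_gompertz(aV, m), allele_to_gompertz(aL, m))
#> [1] -0.8801557

# stochastic fixation experiment, single-queen (linear) mode
e <- fixation_experiment(abm_config("linear"), aV, aL,
                         n_reps = 200, seed = 1)
e
#> Fixation experiment: 200 replicates (0 undecided), config a964cd88
#>     allele n_fixed prop_all ci_low ci_high prop_decided ci_low_decided ci_high_decided
#>   vitality      77    0.385 0.3176  0.4524        0.385         0.3176          0.4524
#>  longevity     123    0.615 0.5476  0.6824        0.615         0.5476          0.6824
```

The negative `ΔF` says the longevity allele is deterministically fitter at
these parameters, and the experiment shows it fixing in ~60% of linear-mode
replicates — a modest majority, because the queen bottleneck keeps the
effective population size (and hence the efficacy of selection) low. The
same pair in `abm_config("exponential")` fixes the longevity allele in well
under half of replicates: exponential populations are younger and
resource-pressed, and prefer vitality.

A thin CLI over the same functions lives at `inst/cli/eusim.R`
(subcommands `delta-f`, `nullcline`, `match-gamma`, `colony-ode`,
`simulate`, `experiment`, `colony-sim`, `queen-effects`), writing TSV
tables.

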