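# divshift

Episodic birth-death diversification analysis on time-calibrated
phylogenies, with incomplete sampling, shift-time search, model selection,
diversity back-projection, and ancestral reconstruction of a binary
habitat character.

## What it is for

Darkling beetles (Tenebrionidae) number ~20,000 extant species, but the
available time-calibrated trees sample only a few hundred of them; their
lineage-through-time curve flattens conspicuously near the Early/Late
Cretaceous boundary. `divshift` asks the question behind that pattern in a
reusable, tested form: given a (posterior sample of) chronograms and a
clade's standing richness, did speciation (λ) and extinction (μ) shift
through time, when, and in which direction? It is aimed at
phylogeneticists who want the full analysis chain —

1. read/validate chronograms (newick, NEXUS with translate tables) and
   reconstruct lineage-through-time curves with a pointwise median over a
   tree sample;
2. truncate branching times at an analysis horizon (default 50 Ma) and
   derive the sampling fraction ρ there from a method-of-moments net
   diversification rate and the back-projection
   `N_horizon = N_present / (horizon × r)`;
3. fit birth-death models with piecewise-constant rates and m = 0, 1, 2,
   … shifts by maximum likelihood (1 Myr shift-time grid, negative net
   diversification allowed), conditioning on the crown age and the
   survival of both crown lineages;
4. select the shift count by sequential likelihood-ratio tests
   (χ², df = 3 per added shift) and AICc, decompose each interval's net
   diversification r = λ − μ and turnover τ = μ/λ back into λ = r/(1−τ)
   and μ = rτ/(1−τ), and replicate the whole fit over a posterior tree
   sample;
5. reconstruct ancestral states of a binary habitat character
   (arid/semi-arid vs other) under the one-parameter symmetric Mk model,
   calling a node significant when one state beats the other by ≥ 2
   log-likelihood units.

The likelihood core evaluates the two birth-death propagators p0(u) (no
sampled descendants) and q(u) (reconstructed-lineage kernel) in closed
form per rate interval, with an independent ODE integration path as an
internal cross-check, and assembles
`log L = Σ[log λ(x_i) + log q(x_i)] + 2 log q(x_1) − 2 log(1 − p0(x_1))`
over the branching times. A forward (Gillespie-style) birth-death
simulator with ρ-sampling generates synthetic chronogram samples matching
the study conditions (crown ~180 Ma, one shift at 103 Ma, ~3% of lineages
at the 50 Ma horizon represented, ~250 tips), so every stage is testable
without any download. See `vignettes/episodic-diversification.Rmd` for the
model, its assumptions, and all numerical choices.

## Worked example

Published desk-scale arithmetic — decomposing the one-shift model's
estimates (older interval r = 0.085, τ = 0.305; younger r = 0.022,
τ = 0.935) and testing one shift against constant rates from the per-model
−log L values:

```r
library(divshift)
decompose_rates(r = c(0.085, 0.022), tau = c(0.305, 0.935))
#>        r   tau    lambda         mu
#> 1  0.085 0.305 0.1223022 0.03730216
#> 2  0.022 0.935 0.3384615 0.31646154

cmp <- compare_models(list(fit_result(0, 1051.096, 500),
                           fit_result(1, 1042.438, 500)))
cmp$p_value[2]
#> [1] 0.0006084736

project_diversity(n_present = 20000, horizon = 50, r = 0.0529)
#> [1] 7561.437
```

Speciation rises ~2.8-fold across the shift (0.122 → 0.338 events/lineage
Myr⁻¹) but extinction rises ~8.5-fold (0.037 → 0.316), so net
diversification collapses; the one-shift model beats constant rates at
p ≈ 6 × 10⁻⁴; and a clade of 20,000 species diversifying at 0.0529 Myr⁻¹
back-projects to ~7,561 species at the 50 Ma horizon.

End-to-end on a synthetic chronogram (truth: shift at 30 Ma, young
interval r = 0.02, τ = 0.9; old interval r = 0.09, τ = 0.3; ρ = 0.5):

```r
set.seed(1)
truth <- episodic_bd_model(shift_times = 30, r = c(0.02, 0.09),
                           tau = c(0.9, 0.3), rho = 0.5)
tree <- simulate_bd_tree(truth, crown_age = 80)   # 526 tips
bt <- branching_times(tree)
f0 <- fit_episodic(bt, 0, rho = 0.5)
f1 <- fit_episodic(bt, 1, grid = list(start = 2, end = 78, step = 1),
                   rho = 0.5, prev = f0)
compare_models(list(f0, f1))
#>   m k neg_loglik aicc lrt_stat df   p_value accepted best_aicc
#> 1 0 2       2002 4008       NA NA        NA     TRUE     FALSE
#> 2 1 5       1981 3973    40.92  3 6.806e-09     TRUE      TRUE
f1
#> Episodic BD fit: m = 1 shift(s), -logL = 1981.2814, AICc = 3972.6784 (k = 5, n = 525)
#> Episodic birth-death model: 1 shift(s), rho = 0.5
#>   interval 1 [0, 30) Myr: lambda=0.198 mu=0.1796 r=0.0184 tau=0.9071
#>   interval 2 [30, crown) Myr: lambda=0.1039 mu=1e-10 r=0.1039 tau=9.623e-10
```

The shift is recovered exactly on the grid (30 Ma) and the interval net
diversification rates land near their truths (0.018 vs 0.02; 0.104 vs
0.09); the old-interval extinction rate sits on its lower boundary, a
common feature of single-tree extinction estimates.

The numbered scripts under `analysis/` run the same chain narratively —
`01_simulate_fixture.R` (synthetic posterior sample), `02_ltt.R`,
`03_sampling_fraction.R`, `04_fit_shifts.R`, `05_ancestral_states.R` —
each writing its tables under `results/`. `run_pipeline(run_config(...))`
does all stages in one call with a machine-readable JSON report.

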