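# modonset

Modular-network models of complex-disease onset and incidence.

Complex genetic disorders — Crohn's disease is the motivating example —
arise from many small genetic effects, environmental exposures and chance,
with onset typically in young adulthood. `modonset` models such a disease
as the failure of a network of N functional modules: each module matures
from a naive state after an Exponential(τ) time, stabilizes in a
disease-*permissive* state with probability Φ (its **module disease
propensity**, MDP) or a *protective* state otherwise, and a stabilized
protective module may still fail to the permissive state at the slow rate
1/T (T ≫ τ). Disease begins at the first age when **all** N modules are
permissive. The homogenized (geometric-mean) model has just four
parameters (N, τ, T, Φ); its onset probability by age x is

    Pr(onset ≤ x) = [ (1 − a)(1 − e^(−x/τ)) + a(1 − e^(−x/T)) ]^N,
    a = (1 − Φ)/(1 − τ/T),

and the age-specific incidence I(x) = d/dx Pr(onset ≤ x) reproduces the
registry-typical shape: near-exponential rise, a peak around ages 20–30,
then slow decline.

The package provides, per module of the analysis pipeline:

* **Core model** — closed-form module/network onset CDFs (general and
  homogenized) and the analytic incidence rate (`module_permissive_cdf`,
  `cdf_general`, `cdf_homogenized`, `incidence_rate`, `incidence_curve`).
* **Registry fitting** — seeded multi-start box-constrained quasi-Newton
  least squares with integer-N profiling (`fit_incidence`, `profile_N`,
  `variance_explained`).
* **Environmental transitions** — secular incidence change while a risk
  factor spreads through the population: logistic exposure rollout,
  propensity chosen at module stabilization, and a transient
  destabilization era with failure time T* (`transition_scenario`,
  `birth_cohort_cdf`, `secular_curves`, `detect_second_peak`).
* **Genetics** — the exact mapping between carrier-contrast GWAS odds
  ratios and MDPs, the induced MDP density across loci, and inverse-power
  correction of OR histograms for GWAS detection bias (`or_from_mdp`,
  `mdp_from_or`, `mdp_density`, `gwas_power`, `correct_or_distribution`).
* **Synthetic data** — seeded Monte-Carlo cohorts, Poisson registries and
  locus catalogues so every stage is testable offline
  (`simulate_onset_ages`, `generate_registry`, `generate_locus_catalogue`).
* **IO / pipeline** — CSV/JSON/YAML formats and a one-call pipeline
  (`read_incidence_csv`, `read_pipeline_config`, `run_pipeline`).

## Worked example

Simulate a registry from known parameters, fit it back, and look at the
secular trend a spreading risk factor would produce:

```r
library(modonset)

p <- homogenized_params(N = 12, tau = 8, T = 1240, Phi = 0.63)
reg <- generate_registry(p, person_years = 5e6, seed = 42)  # Poisson noise
head(reg, 3)
#>   age_lo age_hi incidence person_years cases
#> 1      0      5      0.00        5e+06     0
#> 2      5     10      1.20        5e+06    60
#> 3     10     15     10.18        5e+06   509

fit_incidence(reg, fit_config(N_grid = 12, n_starts = 16, seed = 1))
#> Incidence fit: N = 12, tau = 7.95 y, T = 1158 y, Phi = 0.6288
#>   SSE = 1.97386, variance explained = 0.9969
```

The fit recovers the generating maturation time (7.95 vs 8 y) and
propensity (0.629 vs 0.63); `T` is weakly identified by incidence curves
and is recovered to order of magnitude, a property the multi-start
profiling makes explicit.

```r
sc <- transition_scenario()     # Phi 0.51 -> 0.63 around t50, T* = 350 y
ann <- secular_curves(sc)$annual
ann$year_offset[which.max(ann$incidence_per_100k)]
#> [1] 40
round(ann$incidence_per_100k[ann$year_offset == 0] / max(ann$incidence_per_100k), 3)
#> [1] 0.218
```

Annual population incidence keeps climbing for four decades after half the
population is exposed — and at the exposure midpoint itself the wave is
still below a quarter of its eventual maximum, which is why environmental
outbreaks of such diseases are recognized late.

```r
mdp_from_or(1.3, raf = 0.25, phi = 0.63)
#> [1] 0.7239779
```

A locus with odds ratio 1.3 at 25% risk-allele frequency implies a carrier
MDP of 0.72 against a population mean of 0.63: even relatively strong GWAS
hits barely move a module's propensity.

See the vignette (`vignettes/modular-network-incidence.Rmd`) for the model
assumptions, the transition-model reconstruction, and numerical choices.

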