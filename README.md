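# nettemp

Network temperature estimation for longitudinal binary symptom networks.

## The problem

Psychometric network models treat psychiatric symptoms as interacting
nodes rather than reflections of a single latent cause. For binarized
symptom data the canonical model is the Ising model: the probability of a
symptom configuration `x` (each item present/absent, encoded −1/+1 or
0/1) is

    P(X = x) = exp(−β·H(x)) / Z,
    H(x)     = −(τᵀx + ½ xᵀΩx),

where `Ω` is the symmetric edge-weight matrix (pairwise symptom
interactions), `τ` the thresholds (external fields pushing individual
symptoms toward or away from endorsement), `Z` the partition function, and
`β` the **inverse temperature**: a single global parameter scaling how
strongly the configuration probabilities depend on the energy `H`. High
`β` (low temperature `T = 1/β`) means aligned, stable, low-entropy
symptom states — the system settles into a healthy or a symptomatic
basin. Low `β` means noisy, fluctuating, high-entropy states.

`nettemp` estimates how `T` changes across repeated measurement occasions
(waves) of a cohort. The scale of `β` is not identified from a single
cross-section, so models at several waves are fitted **jointly** with
equality constraints: with a shared `Ω` across waves and `β` fixed to 1
at the first wave, the later `β_g` become identified and the temperature
trajectory `T_g = 1/β_g` is interpretable relative to the first occasion.
Cooling (`T` falling with age) means symptom states are becoming more
aligned and predictable.

The package is aimed at researchers with panels of binarized
questionnaire data (5–13 items, thousands of individuals per wave) who
want temperature, entropy, and connectivity trajectories with honest
model selection and uncertainty — plus a fully seedable synthetic cohort
generator, so every stage is testable without access-restricted cohort
data.

## What it does

- **Exact small-p Ising machinery** — enumeration-based probabilities,
  log-likelihood via sufficient statistics, Gibbs entropy
  `S = −Σ P(x)·ln P(x)`, global strength `Σ|ω_ij|`, and the exact
  parameter transform between the −1/+1 and 0/1 encodings.
- **Multigroup maximum likelihood** across four nested constraint levels
  (saturated; equal edges; equal edges + thresholds; all equal) × dense or
  Wald-pruned sparse structures, with analytic gradients, Newton
  polishing, standard errors, and case-bootstrap CIs.
- **Model selection** over the 8-model grid with AIC, BIC, χ² against the
  saturated reference, and RMSEA; default rule: lowest BIC subject to
  RMSEA < 0.05.
- **Trajectories** — temperature with delta-method and bootstrap 95% CIs,
  per-wave entropy, β-scaled connectivity, observed sum-score summaries,
  sex/stratum-stratified fits, and an age × stratum mixed-model
  interaction test.
- **IO + CLI** — long/wide CSV readers with listwise-deletion policy,
  Likert collapsing, YAML/JSON design configs, deterministic result
  writers, and a `simulate / fit / select / temperature / bootstrap /
  stratify` command-line surface (`inst/cli/nettemp.R`).

## Worked example

Simulate an 8-wave, six-item cohort whose temperature cools from 1.0 to
0.6 across ages 10–17, pick the best of the eight candidate models, and
extract the temperature trajectory:

```r
library(nettemp)
library(dplyr)

design <- abcd_like_design(n_per_wave = 1500, seed = 42)
cohort <- generate_cohort(design)

sel <- select_model(cohort)
glance(sel)
#> # A tibble: 1 × 6
#>   n_models chosen_model chosen_structure chosen_bic chosen_rmsea rmsea_pass
#>      <int> <chr>        <chr>                 <dbl>        <dbl> <lgl>
#> 1        8 equal_edges  dense                74585.            0 TRUE

fit  <- sel$chosen
traj <- temperature_trajectory(fit,
          bootstrap = bootstrap_beta(fit, B = 200, seed = 43))
traj %>% select(wave, age, beta, temperature, ci_lo, ci_hi,
                entropy_nats, mean_score)
#> # A tibble: 8 × 8
#>    wave   age  beta temperature ci_lo ci_hi entropy_nats mean_score
#>   <dbl> <dbl> <dbl>       <dbl> <dbl> <dbl>        <dbl>      <dbl>
#> 1     1    10  1          1     1     1             3.08       1.44
#> 2     2    11  1.02       0.976 0.894 1.07          3.12       1.50
#> 3     3    12  1.17       0.853 0.787 0.924         3.09       1.61
#> 4     4    13  1.12       0.894 0.824 0.970         3.25       1.77
#> 5     5    14  1.28       0.778 0.721 0.840         3.16       1.91
#> 6     6    15  1.41       0.707 0.657 0.761         3.05       2.05
#> 7     7    16  1.48       0.678 0.630 0.729         3.07       2.38
#> 8     8    17  1.67       0.598 0.557 0.642         2.82       3.17

autoplot(traj)   # error-bar plot of T across age
```

Reading the output: the selection grid fitted all eight
constraint-by-structure combinations and chose the dense equal-edges
model (shared network structure, wave-specific thresholds and
temperature) — the generating model class — with RMSEA 0 against the
saturated reference. The trajectory recovers the simulated cooling: `T`
is anchored at 1 at age 10 (identification) and falls to 0.598 (95% CI
0.557–0.642) at age 17, against a design value of 0.6. Temperature and
the observed mean sum-score move independently — the score rises while
the network cools — which is exactly why the dependence parameter carries
information that raw symptom counts do not.

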