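# melprotect

Autoimmunity and cancer sit at two ends of one axis of immune reactivity:
class I HLA alleles that predispose to skin autoimmune conditions
(psoriasis, vitiligo) may also sharpen immune surveillance of nascent
melanomas.  `melprotect` provides the computational machinery to study that
hypothesis in cohort data: do carriers of these alleles get diagnosed
later, is the delay a delay of tumour *onset* rather than a longer
detection lag, and do the alleles present melanoma antigens unusually well?

The package implements, end to end:

* **Two-stage clonal-expansion (TSCE) carcinogenesis model** — closed-form
  age-specific hazard `h(t) = νX(1 − φ(t − τ))`, where `φ` solves the
  Riccati equation `φ′ = αφ² − (α+β+μ)φ + β` of the initiated-cell
  birth-death-conversion process and `τ` is the tumour sojourn time;
  Poisson-likelihood random-walk Metropolis calibration to registry
  incidence tables; a numerical-ODE cross-check and an exact Gillespie
  branching simulator; and the desk sojourn estimate from tumour doubling
  times (`ln N_det / (ln 2 / T_d)`).
* **UV-corrected SBS1 molecular clock** — counts C>T mutations at ApCpG and
  GpCpG contexts (excluding the SBS7-overlapping CpCpG and TpCpG),
  calibrates years-per-mutation by regression, and converts sex-specific
  population sojourns into personalized sojourn and onset ages via
  `onset = age_dx − (sojourn_sex + (burden − median) · β)`.
* **Cohort association statistics** — autoimmune-allele carrier
  stratification (seven- and eight-allele definitions), Mann-Whitney age
  comparisons, leave-one-out robustness, OLS with covariates, polygenic
  risk scores with effect-allele orientation, PRS×carrier interaction,
  logistic odds ratios, Cliff's delta, Fisher's exact, Benjamini-Hochberg.
* **Driver-mutation filter** — caller support, protein-altering SNVs,
  DNA+RNA co-occurrence, median VAF-percentile ≤ 40%, recurrence in ≥ 4
  tumours or CHASM ≥ 0.9.
* **Stably-expressed-gene (conserved antigen) scoring** — per-gene
  gamma-Gaussian mixture EM (`λ·Γ(α,β) + (1−λ)·N(µ,σ)`), composite
  percentile-rank score over mixing proportion, CV and zero fraction,
  tissue-specific set derivation at the 0.69 threshold.
* **MHC-I presentation metrics** — 8-11-mer enumeration, neoepitope sets,
  best ranks, coverage curves, repertoires (≤ cutoff), fraction of gene
  presentable (FGP, < 0.5), population envelopes over common alleles, and
  the FGP cost of HLA loss of heterozygosity (copy number < 0.5 with
  p < 0.05).
* **Synthetic-data generators** for every input format with planted,
  recoverable structure, plus TSV/FASTA/JSON readers and writers and a
  `run_pipeline()` orchestrator.

## Worked example

Calibrate the TSCE model on simulated registry incidence and recover a
planted 9-year sojourn, then test a planted carrier effect:

```r
library(melprotect)

p <- tsce_params(X = 1e7, nu = 1e-7, alpha = 9, beta = 8.7, mu = 1e-6,
                 tau = 9)
tsce_hazard(p, 60)
#> [1] 0.03326138
sojourn_from_doubling(144, 1e8)
#> [1] 10.47737

design <- data.frame(age_lo = seq(20, 80, 5), age_hi = seq(25, 85, 5),
                     person_years = 5e6)
inc <- gen_incidence(p, design, seed = 1)
fit_mcmc(inc, p, free = c("nu", "tau"), n_cycles = 20000, burn_in = 800,
         seed = 2)
#> Two-stage model MCMC fit: 20000 cycles (800 burn-in), 43.1% accepted
#>  parameter         mean        q2.5        q97.5      ess rhat_split
#>         nu 9.995404e-08 9.97796e-08 1.001258e-07 1941.333    1.00236
#>        tau 8.988731e+00 8.95836e+00 9.018055e+00 1473.038    1.00388

cfg <- sim_config(n_individuals = 2000, seed = 3, ai_effect_years = 2.6)
coh <- gen_cohort(cfg)
mw <- mw_age_comparison(coh$age_dx[coh$ai_carrier],
                        coh$age_dx[!coh$ai_carrier])
mw$median_diff; mw$p_value
#> [1] 4.399773
#> [1] 1.699e-08
ols_age_model(coh, exposure = "ai_count")
#>      term estimate    ci_lo    ci_hi      p_value   (ai_count row)
#>  ai_count 2.417339 1.565602 3.269077 2.957937e-08
```

The posterior sojourn interval covers the planted 9 years; carriers of the
autoimmune alleles are diagnosed a median 4.4 years later and the
per-allele OLS coefficient recovers the planted 2.6-year delay within its
confidence interval.

## Package layout

```
R/                  model, clock, cohort, drivers, seg, antigen, sim, io
src/branching.cpp   Gillespie simulator for the TSCE process
tests/testthat/     unit, property and acceptance suites with
                    independent oracles in helper-oracles.R
vignettes/          methods vignette (model, assumptions, design choices)
scripts/acceptance.R
```
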