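---
title: "Modelling melanoma onset, sojourn time and MHC-I antigen presentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling melanoma onset, sojourn time and MHC-I antigen presentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melprotect)
```

# Scope

`melprotect` studies how class I HLA alleles linked to skin autoimmunity
(psoriasis and vitiligo) relate to the timing of melanoma: whether carriers
are diagnosed later, whether the delay reflects delayed tumour initiation or
a longer tumour sojourn, and whether the alleles' peptide-presentation
repertoires can explain a protective effect.  The package supplies the
complete computational chain — carcinogenesis model, molecular clock, cohort
statistics, driver filter, stable-expression scoring, and presentation
metrics — together with a synthetic-data module that generates every input
with known planted structure, so the whole pipeline is testable without
access to restricted human data.

# The two-stage clonal-expansion model

The carcinogenesis model is the classical two-stage clonal-expansion (TSCE)
process: `X` normal stem cells acquire a first hit at rate `nu` per
cell-year; initiated cells divide at `alpha` and die at `beta` per year
(a linear birth-death process); each initiated cell converts to a malignant
cell at rate `mu` per cell-year; detection follows the first persistent
malignant cell after a deterministic lag `tau`, the tumour sojourn time.

Writing `phi(t)` for the probability that a clone founded by one initiated
cell has produced no malignant cell within `t` years, `phi` satisfies the
Riccati equation

$$\phi' = \alpha\phi^2 - (\alpha+\beta+\mu)\phi + \beta,\qquad \phi(0)=1,$$

whose constant-coefficient solution is expressed through the roots
`r1 < 1 < r2` of `alpha*z^2 - (alpha+beta+mu)*z + beta`.  Because
initiations form a Poisson process, the age-specific hazard is

$$h(t) = \nu X\,\bigl(1 - \phi(t-\tau)\bigr),\qquad t \ge \tau,$$

and 0 before `tau`.  `tsce_hazard()` implements this closed form using only
the decaying exponential `exp(-alpha (r2-r1) t)`, so it is overflow-safe at
any age; `tsce_hazard_ode()` integrates the Riccati equation numerically
(deSolve, `rtol = 1e-12`) as an independent cross-check, and
`simulate_branching()` is an exact event-driven (Gillespie) simulation of
the same process.  The test suite verifies the three formulations against
each other — the "equivalence triangle" — over a grid of parameter sets with
plausible initiation fluxes (`nu*X` up to a few events per year).  The
simulator's cost scales with the clone size at which conversion typically
fires, about `1/mu` cells, so simulation-based checks use moderate `mu`;
regimes with `mu ~ 1e-6` (conversion at million-cell clones) are covered by
the closed-form/ODE pair instead.

Two further modelling choices are deliberate simplifications, recorded here
as the package's own design decisions:

* **Birth trends.** Registry incidence drifts across birth cohorts.  This is
  modelled as a log-linear multiplier
  `exp(cohort_slope * (birth_year - ref_birth_year))` on the hazard —
  the simplest monotone parametric form; tabular period-cohort adjustment is
  out of scope.
* **Lag.** The sojourn is a deterministic shift `tau`, not a distributed
  lag.

## Calibration

`fit_mcmc()` calibrates the model to incidence tables (age bin, cases,
person-years) under a Poisson likelihood with person-year offsets evaluated
at bin midpoints — SEER-style 5-year bins are the intended resolution.
Sampling is random-walk Metropolis: rates are proposed on the log scale with
log-uniform priors (default six decades around the start), `tau` on the
natural scale with a Uniform(0, 30) year prior.  Proposal scales adapt
toward ~30% acceptance during burn-in only; at the end of burn-in a
covariance-informed joint proposal (scaled `2.38^2/d`) is frozen from the
late burn-in draws, so the post-burn-in chain satisfies detailed balance.
The default chain length is 100,000 cycles with a 4,000-cycle burn-in;
recovery experiments in the tests use 20,000 cycles with the same 4%
burn-in fraction, which keeps the whole experiment around half a minute
while leaving tau's effective sample size in the thousands.

Only the parameter combinations `nu*X*mu`, `alpha - beta - mu` and
`alpha*mu` (plus `tau`) are identifiable from incidence alone, so the
sensible use of `fit_mcmc()` frees a minimal subset (for example `nu` and
`tau` with the clonal parameters fixed by convention); raw rates quoted
from such a fit are conventions, not estimates.

Independently of the incidence fit, `sojourn_from_doubling()` gives the
desk estimate of sojourn implied by an exponentially growing tumour: with a
144-day doubling time the growth rate is about 1.76/year, hence about 10.5
years to reach 1e8 cells and 11.8 years to reach 1e9.

# The UV-corrected SBS1 molecular clock

Melanomas are dominated by UV mutagenesis (signature SBS7), which swamps
the clock-like SBS1 signal.  The package therefore counts C>T mutations at
CpG sites while excluding CpCpG and TpCpG trinucleotide contexts (which
overlap SBS7), keeping ApCpG and GpCpG.  Records reported on the purine
strand (G>A) are strand-collapsed by reverse complement before the rule is
applied, and counting is invariant to record order and strand
representation.  Individuals without usable mutation data receive the
cohort median burden (lower median, for determinism) and are flagged
`imputed`.

A linear model of age at diagnosis on this burden gives the years-per-
mutation coefficient `beta`; personalized sojourn then anchors the median
individual at the sex-specific population sojourn from the TSCE fit and
shifts others proportionally to their burden deviation:

$$\text{sojourn}_i = \text{sojourn}_{\text{sex}(i)} +
  (\text{burden}_i - \text{median}) \cdot \beta,\qquad
  \text{onset}_i = \text{agedx}_i - \text{sojourn}_i.$$

The onset identity holds to machine precision by construction, and imputed
individuals sit exactly at the sex baseline.  `compare_wgd_sojourn()` is a
one-sided sanity check (the single deliberately one-sided test in the
package): tumours that underwent whole-genome duplication must have been
growing for years, so their personalized sojourns should be longer.

# Cohort association analyses

The exposure of interest is carriage of the seven autoimmune alleles
B\*27:05, B\*57:01, C\*12:03, B\*13:02, C\*06:02, B\*39:06 and B\*51:01;
A\*02:01 (common, presentation-atypical) is included only under the
eight-allele definition, and individuals carrying only A\*02:01 are
non-carriers under the default.  Homozygous autoimmune alleles count as two
copies in the allele-count exposure; this is a documented convention, and
carrier status (any copy) is always available as the alternative coding.

All comparisons are two-sided: Mann-Whitney for group ages, OLS with
covariates for adjusted effects (years per allele), linear
PRS-by-carrier-status interaction, logistic regression for case-control
odds ratios, Cliff's delta for rank effect sizes, Fisher's exact for 2x2
flags, and Benjamini-Hochberg adjustment within each analysis family.
Polygenic risk scores are weighted sums of effect-allele dosages with the
flip `d -> 2 - d` when the genotype table counts the other allele; missing
dosages are mean-imputed per SNP by default, with subset scoring (dropping
the SNP) available.  Cohorts are filtered to ages 20 and above before
association analysis, since younger cases are enriched for rare germline
predisposition.

# The driver-mutation filter

Somatic calls are reduced to a driver set by a cascade: per-sample records
need at least two callers; only protein-altering single-nucleotide variants
are considered; a mutation must be seen in both DNA and RNA
(`dna_vaf > 0` and `rna_vaf > 0`) in at least one sample; and its median
per-sample VAF percentile must be at most 40% in both DNA and RNA.  The
percentile is computed per sample over that sample's records with rank 0 at
the *highest* VAF (descending), so the cut keeps the high-VAF, clonal —
hence early — mutations, which is the biologically coherent reading for
drivers; the ascending orientation is available behind a flag for
sensitivity analysis.  Survivors are drivers if recurrent in at least four
distinct tumours, or, failing recurrence, if their melanoma-specific CHASM
pathogenicity score is at least 0.9 (both boundaries inclusive).  The two
subsets are disjoint by construction and their union is the driver set.

# Stably expressed genes (conserved antigens)

Candidate conserved antigens are genes expressed stably across samples of a
tissue.  After a prefilter (genes at or below 0.5 expression units, or
below 6 counts in more than 93% of samples, or in excluded classes such as
ribosomal RNA, Y-chromosomal and histone genes), each gene's nonzero
expression is fitted with a gamma-Gaussian mixture

$$f(x) = \lambda\,\Gamma(\alpha,\beta) + (1-\lambda)\,N(\mu,\sigma),$$

where the gamma component captures low-expressing samples (enforced by
seeding it on the lowest 30% of values) and the zero fraction `omega` is a
separate metric, not part of the mixture.  The EM uses an exact weighted
gamma M-step (Newton solution of the profile shape equation), so the
observed log-likelihood is monotone non-decreasing — asserted in the tests
at every iteration.  Numerical guards: 200 iterations maximum, relative
tolerance 1e-8, a 1e-6 floor on `sigma`, and constant-value vectors short-
circuit to a degenerate Gaussian with `lambda = 0`.

A two-component fit is weakly identifiable on unimodal data because a
high-shape gamma mimics a Gaussian; after EM the mixture is therefore
compared with a single Gaussian by BIC and collapsed to `lambda = 0` when
the extra components are unsupported (the observed likelihood gains differ
by three orders of magnitude between the two cases, so the decision is not
delicate).

Genes are scored by the percentile ranks, across genes, of `lambda`, the
coefficient of variation `sigma/mu`, and `omega`:
`score = 1 - mean(ranks)` with average-tie ranks `(rank - 0.5)/n`, so
stable genes score high and `score > 0.69` selects them.  Genes with too
few nonzero samples to fit receive the worst rank on all three metrics.
Tissue-specific stable genes are the target tissue's stable set minus the
union of stable sets across background tissues; adding background tissues
can only shrink the result.

# Presentation metrics

Peptide space is the set of 8- to 11-mers of a protein.  All metrics
consume allele-by-peptide percentile ranks (NetMHCpan-style; lower =
stronger, 0.5/2 the conventional strong/weak cutoffs) supplied as input
tables.  A mutation's neoepitopes are the mutant peptides absent from the
wild-type peptide set (38 for one interior substitution); its per-allele
summary is the best (minimum) rank.  Derived quantities: coverage curves
(fraction of mutations with best rank at or below a threshold),
repertoire fractions (inclusive cutoff, "at or below"), position-wise best
ranks, and the fraction of a gene presentable (FGP; *strictly* below 0.5 —
the inclusive/strict asymmetry between repertoire and FGP is intentional
and preserved).  Population envelopes take pointwise maxima/minima of
per-allele curves over common alleles (population frequency at least 1%).

HLA loss of heterozygosity calls require both a copy number below 0.5 and a
supporting p value below 0.05.  Genotype-level FGP uses the union rule — a
peptide counts as presented if any carried allele binds it below the
cutoff — so duplicate alleles contribute once and removing one copy of a
homozygous pair changes nothing.  The presentation cost of losing an allele
is the relative FGP decrease after its removal, compared across allele
classes (autoimmune-lost, other-lost, retained) by Mann-Whitney with FDR
control.

# The synthetic-data module

`sim_config()` fixes the study conditions: NMDP-like European class I
allele frequencies covering the autoimmune alleles at realistic population
frequencies (residual mass per locus goes to a catch-all `*other` allele);
a Gaussian age at diagnosis centred at 58 with SD 13, typical of melanoma
cohorts, shifted additively by 2.6 years per autoimmune allele copy by
default; an optional sex effect (default 0); negative-binomial clock
mutation counts with mean `clock_rate * age` (dispersion 0 degenerates to
Poisson); per-gene gamma-Gaussian expression with a planted 10% stable
fraction; rank matrices Uniform(0, 100] with an optional planted strong-
binding block; and Poisson incidence drawn from the TSCE hazard.  The same
configuration (including its seed) always reproduces byte-identical
outputs.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: the real left-skewed onset distribution
(ages are Gaussian, adequate for the rank-based and linear estimators under
test), linkage disequilibrium between PRS SNPs and HLA alleles, and somatic
mutational processes beyond context labels.  Parameter-recovery results on
synthetic data validate the estimators, not the biology.

# Problem sizes in the tests

The suite fixes its own scales: MCMC recovery uses 13 five-year age bins at
5e6 person-years each, 20 seeded replicates of 20,000-cycle chains;
branching-process checks use 1e5 subjects in a moderate-`mu` regime; EM
recovery uses n = 2000 observations; cohort recovery uses n = 5000
(per-allele effect) and n = 450 (carrier shift); null calibration uses
1000 seeded Mann-Whitney replicates.  `scripts/acceptance.R` recomputes the
same quantities at similar sizes from a single command-line seed.

# Known limitations

* The incidence fit exposes raw rate parameters; the user must respect the
  identifiability structure noted above when interpreting them.
* The percentile direction in the driver filter's VAF rule is a documented
  convention (descending), selectable but not externally validated.
* Percentile ranks in the SEG score use `(rank - 0.5)/n`; genes near the
  0.69 threshold can move under the alternative `rank/n` convention.
* The NetMHCpan reader covers the tab-separated "xls" export with
  `EL_Rank` columns only; the long `allele/peptide/rank` TSV is the
  canonical interchange format.
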