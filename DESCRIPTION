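Package: melprotect
Title: Modelling the Effect of MHC-I Autoimmune Alleles on Melanoma Onset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how class I HLA alleles linked to skin
    autoimmunity relate to the timing of melanoma. Implements a two-stage
    clonal-expansion carcinogenesis model with closed-form hazard,
    Poisson-likelihood MCMC calibration to registry incidence tables and an
    event-driven branching-process simulator; a UV-corrected SBS1 molecular
    clock that personalizes tumour sojourn and onset estimates; cohort
    association statistics for autoimmune-allele carrier status and polygenic
    risk scores; a multi-criterion somatic driver-mutation filter; a
    gamma-Gaussian mixture scorer for stably expressed genes; and peptide
    presentation metrics over allele-by-peptide percentile-rank tables,
    including the impact of HLA loss of heterozygosity. A synthetic-data
    module generates every input format with known planted structure so the
    whole pipeline is testable without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
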