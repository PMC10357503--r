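#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' population HLA allele frequencies (NMDP-like defaults), a planted
#' additive delay of age at diagnosis per autoimmune allele, a Gaussian
#' baseline age model, a negative-binomial clock-mutation process whose
#' mean grows linearly with age, per-gene gamma-Gaussian expression
#' mixtures with a planted stable fraction, a uniform rank matrix with a
#' planted strong-binding block, and weighted-SNP PRS structure.
#'
#' @param n_individuals number of simulated individuals (at least 2, or 0
#'   for empty outputs).
#' @param seed integer seed; identical configurations give identical
#'   outputs.
#' @param ai_effect_years planted additive delay of age at diagnosis per
#'   autoimmune allele copy (years; default 2.6).
#' @param baseline_age_median,baseline_age_sd Gaussian baseline age at
#'   diagnosis (years; defaults 58 and 13, typical of melanoma cohorts).
#' @param sex_effect_years additive age shift for males (default 0).
#' @param allele_freqs named list with elements `A`, `B`, `C`, each a named
#'   numeric vector of allele frequencies summing to at most 1 per locus;
#'   residual mass goes to a catch-all `<locus>*other` allele.
#' @param prs_weights data frame with columns `snp`, `effect_allele`,
#'   `weight`.
#' @param clock_rate clock mutations per year of age (default 1).
#' @param clock_dispersion negative-binomial overdispersion; 0 degenerates
#'   to Poisson.
#' @param seg_fraction_stable fraction of genes planted as stably expressed
#'   (default 0.1).
#' @param rank_block list `(alleles, peptides, ceiling)` describing the
#'   planted strong-binding block of the rank matrix, or `NULL`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500, seed = 1,
                       ai_effect_years = 2.6,
                       baseline_age_median = 58, baseline_age_sd = 13,
                       sex_effect_years = 0,
                       allele_freqs = default_allele_freqs(),
                       prs_weights = default_prs_weights(),
                       clock_rate = 1, clock_dispersion = 0.2,
                       seg_fraction_stable = 0.1,
                       rank_block = NULL) {
  if (n_individuals != 0 && n_individuals < 2)
    stop("'n_individuals' must be 0 or at least 2", call. = FALSE)
  for (locus in c("A", "B", "C")) {
    f <- allele_freqs[[locus]]
    if (is.null(f) || length(f) == 0L)
      stop("allele frequencies required for locus ", locus, call. = FALSE)
    if (any(f < 0) || any(f > 1))
      stop("allele frequencies must lie in [0, 1]", call. = FALSE)
    if (sum(f) > 1 + 1e-9)
      stop("allele frequencies at locus ", locus, " sum above 1",
           call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed),
                 ai_effect_years = ai_effect_years,
                 baseline_age_median = baseline_age_median,
                 baseline_age_sd = baseline_age_sd,
                 sex_effect_years = sex_effect_years,
                 allele_freqs = allele_freqs,
                 prs_weights = prs_weights,
                 clock_rate = clock_rate,
                 clock_dispersion = clock_dispersion,
                 seg_fraction_stable = seg_fraction_stable,
                 rank_block = rank_block),
            class = "sim_config")
}

#' NMDP-like default allele frequencies
#'
#' European-ancestry-flavoured class I allele frequencies covering the
#' autoimmune alleles at their approximate population frequencies plus a
#' few common fillers; residual mass per locus is absorbed by a catch-all
#' allele at draw time.
#' @return Named list of named frequency vectors for loci A, B, C.
#' @export
default_allele_freqs <- function() {
  list(
    A = c("A*02:01" = 0.27, "A*01:01" = 0.16, "A*03:01" = 0.13,
          "A*24:02" = 0.09),
    B = c("B*07:02" = 0.13, "B*08:01" = 0.11, "B*44:02" = 0.09,
          "B*57:01" = 0.035, "B*27:05" = 0.02, "B*13:02" = 0.015,
          "B*39:06" = 0.01, "B*51:01" = 0.055),
    C = c("C*07:01" = 0.15, "C*07:02" = 0.14, "C*04:01" = 0.12,
          "C*06:02" = 0.09, "C*12:03" = 0.03, "C*03:04" = 0.08)
  )
}

#' Default PRS weight table
#'
#' A small melanoma-style weight table: 20 SNPs with effects on both the
#' risk and protective side, magnitudes like published melanoma PRS
#' weights.
#' @return Data frame with columns `snp`, `effect_allele`, `weight`.
#' @export
default_prs_weights <- function() {
  set.seed(20260930)  # fixed: part of the configuration, not the draws
  n <- 20
  out <- data.frame(snp = sprintf("rs%06d", sample.int(999999, n)),
                    effect_allele = sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE),
                    weight = round(stats::rnorm(n, 0, 0.15), 4),
                    stringsAsFactors = FALSE)
  out
}

#' Generate HLA genotypes
#'
#' Draws two alleles per locus per individual independently from the
#' configured locus frequencies; residual probability mass goes to the
#' catch-all `<locus>*other` allele.
#'
#' @param config a [sim_config()] object.
#' @return Data frame with columns `id`, `A1`, `A2`, `B1`, `B2`, `C1`,
#'   `C2`.
#' @export
gen_hla_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  set.seed(config$seed)
  cols <- list(id = if (n > 0) sprintf("ind%04d", seq_len(n))
               else character())
  for (locus in c("A", "B", "C")) {
    f <- config$allele_freqs[[locus]]
    resid <- max(0, 1 - sum(f))
    alleles <- c(names(f), paste0(locus, "*other"))
    probs <- c(f, resid)
    draw <- function() if (n > 0)
      sample(alleles, n, replace = TRUE, prob = probs) else character()
    cols[[paste0(locus, "1")]] <- draw()
    cols[[paste0(locus, "2")]] <- draw()
  }
  do.call(data.frame, c(cols, stringsAsFactors = FALSE))
}

#' Generate a cohort with a planted autoimmune-allele age effect
#'
#' Age at diagnosis is Gaussian with the configured centre and spread plus
#' `ai_effect_years` per autoimmune allele copy carried (seven-allele
#' definition) and `sex_effect_years` for males.  Ages below 20 are
#' permitted so the cohort age filter can be exercised.
#'
#' @param config a [sim_config()] object.
#' @param genotypes output of [gen_hla_genotypes()] for the same `n`.
#' @return Cohort data frame: `id`, `age_dx`, `sex`, `status`, genotype
#'   columns, `ai_carrier`, `ai_count`.
#' @export
gen_cohort <- function(config, genotypes = gen_hla_genotypes(config)) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes)
  set.seed(config$seed + 1L)
  cs <- if (n > 0) carrier_status(genotypes, ai_allele_set())
  else data.frame(carrier = logical(), count = integer())
  sex <- if (n > 0) sample(c("male", "female"), n, replace = TRUE)
  else character()
  age <- stats::rnorm(n, config$baseline_age_median,
                      config$baseline_age_sd) +
    config$ai_effect_years * cs$count +
    config$sex_effect_years * (sex == "male")
  out <- data.frame(id = genotypes$id, age_dx = age, sex = sex,
                    status = rep("case", n), stringsAsFactors = FALSE)
  out <- cbind(out, genotypes[, genotype_cols, drop = FALSE])
  out$ai_carrier <- cs$carrier
  out$ai_count <- cs$count
  out
}

#' Generate a mutation table with clock and driver structure
#'
#' Per individual, a clock-mutation count is drawn with mean
#' `clock_rate * age` (negative binomial with the configured dispersion;
#' dispersion 0 gives Poisson) and emitted as C>T records at qualifying
#' ApCpG/GpCpG contexts; UV-context background records (CpCpG/TpCpG and
#' non-C>T) are added as noise.  Optional recurrent drivers are planted in
#' a chosen number of samples with two-caller support and high DNA/RNA
#' VAFs.
#'
#' @param config a [sim_config()] object.
#' @param cohort output of [gen_cohort()].
#' @param drivers optional data frame with columns `gene`,
#'   `protein_change`, `n_samples`, `chasm` describing planted drivers.
#' @param background_per_indiv mean count of non-clock background
#'   mutations per individual (default 30).
#' @return Mutation data frame with columns `sample`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `context`, `callers`, `dna_vaf`, `rna_vaf`,
#'   `protein_change`, `chasm`.
#' @export
gen_mutation_table <- function(config, cohort, drivers = NULL,
                               background_per_indiv = 30) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  set.seed(config$seed + 2L)
  n <- nrow(cohort)
  mean_clock <- pmax(config$clock_rate * cohort$age_dx, 0)
  counts <- if (config$clock_dispersion > 0)
    stats::rnbinom(n, size = 1 / config$clock_dispersion, mu = mean_clock)
  else stats::rpois(n, mean_clock)
  counts[mean_clock == 0] <- 0L

  rows <- list()
  pos_counter <- 0L
  emit <- function(sample, gene, ref, alt, context, callers, dv, rv, pc,
                   chasm = NA_real_, pos = NULL) {
    pos_counter <<- pos_counter + length(sample)
    data.frame(sample = sample, gene = gene,
               chrom = "chr1",
               pos = if (is.null(pos))
                 seq.int(pos_counter, length.out = length(sample)) else pos,
               ref = ref, alt = alt, context = context, callers = callers,
               dna_vaf = dv, rna_vaf = rv, protein_change = pc,
               chasm = chasm, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    k <- counts[i]
    if (k > 0) {
      ctx <- sample(c("ACG", "GCG"), k, replace = TRUE)
      rows[[length(rows) + 1L]] <- emit(
        rep(cohort$id[i], k), sprintf("CLK%03d", sample.int(999, k,
                                                            replace = TRUE)),
        "C", "T", ctx, "muse,mutect",
        stats::runif(k, 0.05, 0.6), stats::runif(k, 0, 0.6), "")
    }
    b <- stats::rpois(1, background_per_indiv)
    if (b > 0) {
      ctx <- sample(c("CCG", "TCG", "ACA", "TCT"), b, replace = TRUE)
      alt <- ifelse(substr(ctx, 2, 2) == "C", "T", "A")
      rows[[length(rows) + 1L]] <- emit(
        rep(cohort$id[i], b), sprintf("BG%03d", sample.int(999, b,
                                                           replace = TRUE)),
        substr(ctx, 2, 2), alt, ctx, "muse,mutect",
        stats::runif(b, 0.05, 0.6), stats::runif(b, 0, 0.6),
        ifelse(stats::runif(b) < 0.5, "p.X1Y", ""))
    }
  }
  if (!is.null(drivers)) {
    for (j in seq_len(nrow(drivers))) {
      ids <- sample(cohort$id, min(drivers$n_samples[j], n))
      rows[[length(rows) + 1L]] <- emit(
        ids, drivers$gene[j], "C", "A", "ACA",
        "muse,mutect,varscan",
        stats::runif(length(ids), 0.4, 0.6),
        stats::runif(length(ids), 0.3, 0.6),
        drivers$protein_change[j],
        chasm = drivers$chasm[j],
        pos = rep(1e6 + j, length(ids)))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      context = character(), callers = character(),
                      dna_vaf = numeric(), rna_vaf = numeric(),
                      protein_change = character(), chasm = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate an expression matrix with planted stable genes
#'
#' Stable genes get a low mixing proportion, low coefficient of variation
#' and few zeros; unstable genes the opposite, following the
#' gamma-Gaussian mixture the scorer assumes.  Ground-truth labels are
#' attached as attribute `"stable"`.
#'
#' @param config a [sim_config()] object.
#' @param n_genes,n_samples matrix dimensions (defaults 200 x 100;
#'   `n_genes >= 2`, `n_samples >= 10`).
#' @return Numeric matrix genes x samples with attribute `stable`
#'   (logical per gene).
#' @export
gen_expression_matrix <- function(config, n_genes = 200, n_samples = 100) {
  stopifnot(inherits(config, "sim_config"))
  if (n_genes < 2 || n_samples < 10)
    stop("need n_genes >= 2 and n_samples >= 10", call. = FALSE)
  set.seed(config$seed + 3L)
  n_stable <- round(config$seg_fraction_stable * n_genes)
  stable <- rep(FALSE, n_genes)
  if (n_stable > 0) stable[sample.int(n_genes, n_stable)] <- TRUE
  mat <- matrix(0, n_genes, n_samples,
                dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
  for (g in seq_len(n_genes)) {
    if (stable[g]) {
      lam <- 0.05; mu <- stats::runif(1, 40, 80); cv <- 0.1; om <- 0
    } else {
      lam <- stats::runif(1, 0.3, 0.6)
      mu <- stats::runif(1, 20, 60)
      cv <- stats::runif(1, 0.4, 0.8)
      om <- stats::runif(1, 0.05, 0.3)
    }
    from_gamma <- stats::runif(n_samples) < lam
    x <- numeric(n_samples)
    x[from_gamma] <- stats::rgamma(sum(from_gamma), shape = 2, rate = 0.5)
    x[!from_gamma] <- pmax(stats::rnorm(sum(!from_gamma), mu, cv * mu), 0)
    x[stats::runif(n_samples) < om] <- 0
    mat[g, ] <- x
  }
  attr(mat, "stable") <- stable
  mat
}

#' Generate an allele x peptide rank matrix
#'
#' Percentile ranks drawn Uniform(0, 100] for every (allele, peptide)
#' pair, except a planted block (from `config$rank_block`) whose ranks are
#' Uniform(0, ceiling] — a strong-binding region recoverable downstream.
#'
#' @param config a [sim_config()] object.
#' @param alleles,peptides non-empty character vectors; peptides must be
#'   unique.
#' @return Numeric matrix alleles x peptides.
#' @export
gen_rank_matrix <- function(config, alleles, peptides) {
  stopifnot(inherits(config, "sim_config"))
  if (length(alleles) == 0L || length(peptides) == 0L)
    stop("alleles and peptides must be non-empty", call. = FALSE)
  if (anyDuplicated(peptides))
    stop("duplicate peptide identifiers", call. = FALSE)
  set.seed(config$seed + 4L)
  m <- matrix(100 * (1 - stats::runif(length(alleles) * length(peptides))),
              nrow = length(alleles),
              dimnames = list(alleles, peptides))
  blk <- config$rank_block
  if (!is.null(blk)) {
    ba <- intersect(blk$alleles, alleles)
    bp <- intersect(blk$peptides, peptides)
    if (length(ba) && length(bp))
      m[ba, bp] <- blk$ceiling * (1 - stats::runif(length(ba) * length(bp)))
  }
  m
}

#' Simulate an incidence table from the two-stage model
#'
#' Case counts per stratum drawn Poisson with mean `person_years` times
#' the cohort-adjusted model hazard at the bin midpoints — forward
#' simulation for parameter-recovery experiments.
#'
#' @param params a [tsce_params()] object.
#' @param design data frame with columns `age_lo`, `age_hi`,
#'   `person_years` and optionally `sex`, `birth_lo`, `birth_hi`.
#' @param seed optional integer seed.
#' @return The design with a `cases` column appended.
#' @export
gen_incidence <- function(params, design, seed = NULL) {
  stopifnot(inherits(params, "tsce_params"))
  if (any(design$person_years <= 0))
    stop("'person_years' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mid_age <- (design$age_lo + design$age_hi) / 2
  mid_by <- if (all(c("birth_lo", "birth_hi") %in% names(design)))
    (design$birth_lo + design$birth_hi) / 2 else params$ref_birth_year
  h <- cohort_adjusted_hazard(params, mid_age, mid_by)
  if (any(!is.finite(h)))
    stop("non-finite hazard in design bin ", which(!is.finite(h))[1],
         call. = FALSE)
  design$cases <- stats::rpois(nrow(design), design$person_years * h)
  design
}

#' Generate a PRS dosage matrix
#'
#' Independent SNP dosages drawn Binomial(2, maf) per SNP, with the
#' counted allele equal to the effect allele (no orientation flips needed
#' unless requested).
#'
#' @param config a [sim_config()] object.
#' @param mafs optional numeric vector of allele frequencies per SNP
#'   (default Uniform(0.1, 0.5) draws).
#' @return Matrix individuals x SNPs with attribute `counted_allele`.
#' @export
gen_prs_dosages <- function(config, mafs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$prs_weights
  set.seed(config$seed + 5L)
  if (is.null(mafs)) mafs <- stats::runif(nrow(w), 0.1, 0.5)
  n <- config$n_individuals
  d <- vapply(mafs, function(p) stats::rbinom(n, 2, p), numeric(n))
  d <- matrix(d, nrow = n,
              dimnames = list(sprintf("ind%04d", seq_len(n)), w$snp))
  attr(d, "counted_allele") <- stats::setNames(w$effect_allele, w$snp)
  d
}
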