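#' Autoimmune MHC-I allele set definitions
#'
#' Returns the set of class I HLA alleles linked to skin autoimmunity used
#' to stratify melanoma cohorts.  The seven-allele definition comprises
#' psoriasis-linked B*27:05, B*57:01 and C*12:03, vitiligo-linked B*13:02,
#' the dual psoriasis/vitiligo allele C*06:02, plus B*39:06 and B*51:01.
#' The eight-allele definition adds the vitiligo-linked but common and
#' presentation-atypical A*02:01; under the seven-allele definition,
#' individuals carrying only A*02:01 are non-carriers.
#'
#' @param definition `"seven_allele"` (default) or `"eight_allele"`.
#' @return Character vector of allele names with attribute `definition`.
#' @export
ai_allele_set <- function(definition = c("seven_allele", "eight_allele")) {
  definition <- match.arg(definition)
  seven <- c("B*27:05", "B*57:01", "C*12:03", "B*13:02", "C*06:02",
             "B*39:06", "B*51:01")
  out <- if (definition == "seven_allele") seven else c(seven, "A*02:01")
  structure(out, definition = definition)
}

genotype_cols <- c("A1", "A2", "B1", "B2", "C1", "C2")

#' Apply the cohort age filter
#'
#' Removes individuals younger than 20 years at diagnosis (young patients
#' are enriched for rare germline predisposition) and individuals whose age
#' is missing.  The number removed is reported as a message.
#'
#' @param individuals cohort data frame with an `age_dx` column.
#' @return Filtered data frame.
#' @export
filter_cohort <- function(individuals) {
  if (nrow(individuals) == 0L) return(individuals)
  keep <- !is.na(individuals$age_dx) & individuals$age_dx >= 20
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " individual(s) removed (< 20 years or missing age)")
  individuals[keep, , drop = FALSE]
}

#' Autoimmune-allele carrier status and copy count
#'
#' @param ind one-row cohort data frame (or a full cohort; vectorized) with
#'   genotype columns `A1, A2, B1, B2, C1, C2`.
#' @param ai allele set from [ai_allele_set()] (or any character vector of
#'   normalized allele names).
#' @return For one row, a list `(carrier, count)`; for several rows, a data
#'   frame with columns `carrier`, `count`.  `count` counts genotype slots
#'   (with multiplicity) matching the set, so homozygotes count twice.
#' @export
carrier_status <- function(ind, ai = ai_allele_set()) {
  g <- as.matrix(ind[, genotype_cols, drop = FALSE])
  present <- !is.na(g) & g != ""
  ok <- !present | grepl("^[ABC]\\*(\\d{2,3}:\\d{2,3}|[Oo][Tt][Hh][Ee][Rr])$", g)
  if (!all(ok))
    stop("unresolvable allele format: '", g[!ok][1], "'", call. = FALSE)
  count <- rowSums(matrix(g %in% ai & present, nrow = nrow(g)))
  if (nrow(g) == 1L) list(carrier = count >= 1, count = count)
  else data.frame(carrier = count >= 1, count = count)
}

#' Mann-Whitney comparison of two age distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test plus group medians, the
#' workhorse comparison for carrier versus non-carrier ages at diagnosis.
#'
#' @param group_a,group_b numeric vectors of ages.
#' @param exact passed to [stats::wilcox.test()]; default lets R choose.
#' @return List with `p_value`, `median_a`, `median_b`, `median_diff`
#'   (a minus b), group sizes and the `htest` object.
#' @export
mw_age_comparison <- function(group_a, group_b, exact = NULL) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            exact = exact))
  list(p_value = ht$p.value,
       median_a = stats::median(group_a),
       median_b = stats::median(group_b),
       median_diff = stats::median(group_a) - stats::median(group_b),
       n_a = length(group_a), n_b = length(group_b), test = ht)
}

#' Leave-one-out robustness over the autoimmune allele set
#'
#' For each allele in the set, repeats the carrier-versus-non-carrier age
#' comparison with that allele removed from the definition (mode
#' `"drop_allele"`), or with all carriers of that allele removed from the
#' cohort while keeping the full definition (mode `"drop_carriers"`).
#'
#' @param cohort cohort data frame (ages + genotype columns).
#' @param ai allele set, normally the seven-allele definition.
#' @param mode `"drop_allele"` or `"drop_carriers"`.
#' @return Data frame with one row per held-out allele: `held_out`,
#'   `p_value`, `median_diff`, `n_carrier`, `n_noncarrier`, `degenerate`.
#' @export
leave_one_out <- function(cohort, ai = ai_allele_set(),
                          mode = c("drop_allele", "drop_carriers")) {
  mode <- match.arg(mode)
  res <- lapply(seq_along(ai), function(i) {
    held <- ai[i]
    if (mode == "drop_allele") {
      sub_ai <- ai[-i]
      dat <- cohort
    } else {
      sub_ai <- ai
      dat <- cohort[carrier_status(cohort, held)$count == 0, , drop = FALSE]
    }
    if (length(sub_ai) == 0L || nrow(dat) == 0L)
      return(data.frame(held_out = held, p_value = NA_real_,
                        median_diff = NA_real_, n_carrier = 0L,
                        n_noncarrier = nrow(dat), degenerate = TRUE))
    st <- carrier_status(dat, sub_ai)
    a <- dat$age_dx[st$carrier]
    b <- dat$age_dx[!st$carrier]
    if (length(a) == 0L || length(b) == 0L)
      return(data.frame(held_out = held, p_value = NA_real_,
                        median_diff = NA_real_, n_carrier = length(a),
                        n_noncarrier = length(b), degenerate = TRUE))
    mw <- mw_age_comparison(a, b)
    data.frame(held_out = held, p_value = mw$p_value,
               median_diff = mw$median_diff, n_carrier = length(a),
               n_noncarrier = length(b), degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' OLS model of age at diagnosis with covariates
#'
#' Ordinary least squares of age at diagnosis on the autoimmune-allele
#' exposure (carrier flag or copy count) plus covariates, with Wald 95%
#' confidence intervals per coefficient.
#'
#' @param cohort cohort data frame; must contain `age_dx`, the exposure
#'   column and all covariates.
#' @param exposure name of the exposure column (e.g. `"ai_carrier"` or
#'   `"ai_count"`).
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return Data frame with one row per coefficient: `term`, `estimate`,
#'   `ci_lo`, `ci_hi`, `p_value`; the `lm` fit is attached as attribute
#'   `"fit"`.
#' @export
ols_age_model <- function(cohort, exposure = "ai_carrier",
                          covariates = character()) {
  vars <- c(exposure, covariates)
  miss <- setdiff(c("age_dx", vars), names(cohort))
  if (length(miss))
    stop("cohort missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (v in vars) {
    x <- cohort[[v]]
    if (is.numeric(x) && stats::var(x, na.rm = TRUE) == 0)
      stop("covariate '", v, "' has zero variance", call. = FALSE)
  }
  form <- stats::reformulate(vars, response = "age_dx")
  fit <- stats::lm(form, data = cohort)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    ci_lo = ci[, 1], ci_hi = ci[, 2],
                    p_value = cf[, 4], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Polygenic risk score from SNP dosages
#'
#' Weighted sum of effect-allele dosages:
#' `score_i = sum_j w_j * d_ij` after orienting each dosage to the effect
#' allele (`d -> 2 - d` when the table's counted allele is the non-effect
#' allele).  Missing dosages are mean-imputed per SNP by default, or the SNP
#' can be dropped for that individual (`missing = "drop"`, i.e. subset
#' scoring).
#'
#' @param dosages numeric matrix, individuals x SNPs, entries in \[0, 2\];
#'   the counted allele per SNP is taken from attribute
#'   `"counted_allele"` (named character) or the `counted` argument.
#' @param weights data frame with columns `snp`, `effect_allele`, `weight`.
#' @param counted optional named character vector of counted alleles,
#'   overriding the matrix attribute.
#' @param missing `"mean"` (impute the per-SNP mean dosage) or `"drop"`.
#' @return Named numeric vector of scores per individual.
#' @export
prs_score <- function(dosages, weights, counted = NULL,
                      missing = c("mean", "drop")) {
  missing <- match.arg(missing)
  if (is.null(counted)) counted <- attr(dosages, "counted_allele")
  snps <- intersect(colnames(dosages), weights$snp)
  if (length(snps) == 0L) stop("no scored SNPs in dosage table",
                               call. = FALSE)
  w <- weights[match(snps, weights$snp), ]
  d <- dosages[, snps, drop = FALSE]
  if (is.null(counted))
    stop("counted allele unknown for dosage table; supply 'counted'",
         call. = FALSE)
  cnt <- counted[snps]
  if (any(is.na(cnt)))
    stop("counted allele unknown for SNP(s): ",
         paste(snps[is.na(cnt)], collapse = ", "), call. = FALSE)
  flip <- cnt != w$effect_allele
  d[, flip] <- 2 - d[, flip, drop = FALSE]
  if (anyNA(d)) {
    if (missing == "mean") {
      for (j in seq_len(ncol(d))) {
        nas <- is.na(d[, j])
        if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
      }
    } else {
      d[is.na(d)] <- 0  # dropped SNPs contribute nothing
    }
  }
  drop(d %*% w$weight)[seq_len(nrow(d))]
}

#' PRS-by-carrier-status interaction model
#'
#' OLS of age at diagnosis on the polygenic risk score, autoimmune carrier
#' status, and their product; the interaction coefficient measures how much
#' steeper the PRS-age slope is in carriers.
#'
#' @param cohort data frame with `age_dx` and a logical/0-1 `ai_carrier`
#'   column.
#' @param scores numeric PRS vector aligned with `cohort` rows.
#' @return As [ols_age_model()]; the interaction row is labelled
#'   `"prs:ai_carrier"`.
#' @export
prs_interaction_model <- function(cohort, scores) {
  d <- data.frame(age_dx = cohort$age_dx,
                  prs = as.numeric(scores),
                  ai_carrier = as.numeric(cohort$ai_carrier))
  if (all(d$ai_carrier == 0) || all(d$ai_carrier == 1))
    stop("need both carriers and non-carriers", call. = FALSE)
  if (stats::var(d$prs) == 0) stop("PRS has zero variance", call. = FALSE)
  fit <- stats::lm(age_dx ~ prs * ai_carrier, data = d)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    ci_lo = ci[, 1], ci_hi = ci[, 2], p_value = cf[, 4],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Logistic odds ratio for case status
#'
#' Logistic regression of case/control status on an exposure (carrier flag
#' or allele count), reporting the odds ratio `exp(coef)` with a Wald 95%
#' confidence interval.  On a 2x2 design this equals the cross-product
#' ratio.
#'
#' @param cohort data frame with a `status` column coded `"case"`/
#'   `"control"` (or logical/0-1) and the exposure column.
#' @param exposure exposure column name.
#' @return List with `or`, `ci_lo`, `ci_hi`, `beta`, `p_value`, `n`, and
#'   the `glm` fit.
#' @export
logistic_or <- function(cohort, exposure = "ai_carrier") {
  y <- cohort$status
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "case"
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  x <- as.numeric(cohort[[exposure]])
  fit <- stats::glm(y ~ x, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop("logistic fit did not converge (possible complete separation)",
         call. = FALSE)
  cf <- summary(fit)$coefficients["x", ]
  beta <- cf[["Estimate"]]; se <- cf[["Std. Error"]]
  list(or = exp(beta),
       ci_lo = exp(beta - stats::qnorm(0.975) * se),
       ci_hi = exp(beta + stats::qnorm(0.975) * se),
       beta = beta, p_value = cf[["Pr(>|z|)"]],
       n = length(y), fit = fit)
}

#' Cliff's delta effect size
#'
#' `(#\{a > b\} - #\{a < b\}) / (n_a * n_b)` over all pairs; ranges over
#' \[-1, 1\] with 0 meaning stochastic equality.  Computed from the
#' rank-sum statistic so it scales to large groups.
#'
#' @param group_a,group_b numeric vectors.
#' @return Scalar in \[-1, 1\].
#' @export
cliffs_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("groups must be non-empty", call. = FALSE)
  r <- rank(c(group_a, group_b))
  # U = #{a>b} + 0.5 #{a==b}; D = (2U - na*nb)/(na*nb)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  (2 * u - na * nb) / (na * nb)
}

#' Fisher's exact association between two carrier flags
#'
#' Two-sided Fisher's exact test (hypergeometric tail) of the 2x2 table of
#' e.g. HLA-proximal risk-SNP carriage against autoimmune-allele carriage.
#'
#' @param snp_carrier,ai_carrier logical vectors of equal length, or a 2x2
#'   matrix passed as `table`.
#' @param table optional 2x2 matrix overriding the flag vectors.
#' @return List with `p_value`, `odds_ratio` (conditional MLE from
#'   `fisher.test`), and the table.
#' @export
fisher_carrier_assoc <- function(snp_carrier = NULL, ai_carrier = NULL,
                                 table = NULL) {
  if (is.null(table)) {
    table <- base::table(factor(as.logical(snp_carrier),
                                levels = c(TRUE, FALSE)),
                         factor(as.logical(ai_carrier),
                                levels = c(TRUE, FALSE)))
  }
  table <- as.matrix(table)
  ht <- stats::fisher.test(table)
  list(p_value = ht$p.value, odds_ratio = unname(ht$estimate),
       table = table, test = ht)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up false-discovery-rate adjustment; monotone and capped at
#' 1.  Thin wrapper over [stats::p.adjust()] with input validation.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Carrier-age comparison within HLA supertypes
#'
#' For each supertype in a user-supplied allele-to-supertype map, compares
#' ages of individuals carrying any allele of that supertype against the
#' rest, Mann-Whitney with Benjamini-Hochberg adjustment across supertypes.
#' Genotype alleles absent from the map fall into `"unassigned"`.
#'
#' @param cohort cohort data frame (ages + genotype columns).
#' @param supertype_map data frame with columns `allele`, `supertype`.
#' @return Data frame per supertype: `supertype`, `n_carrier`,
#'   `n_noncarrier`, `median_diff`, `p_value`, `p_adj`.
#' @export
supertype_compare <- function(cohort, supertype_map) {
  g <- as.matrix(cohort[, genotype_cols, drop = FALSE])
  st_of <- function(al) {
    i <- match(al, supertype_map$allele)
    ifelse(is.na(i), "unassigned", supertype_map$supertype[i])
  }
  sts <- sort(unique(st_of(g[!is.na(g) & g != ""])))
  rows <- lapply(sts, function(s) {
    alleles <- c(supertype_map$allele[supertype_map$supertype == s],
                 if (s == "unassigned")
                   setdiff(unique(g[!is.na(g) & g != ""]),
                           supertype_map$allele))
    cs <- carrier_status(cohort, alleles)
    a <- cohort$age_dx[cs$carrier]; b <- cohort$age_dx[!cs$carrier]
    if (length(a) == 0L || length(b) == 0L) {
      message("supertype '", s, "' skipped (empty comparison group)")
      return(NULL)
    }
    mw <- mw_age_comparison(a, b)
    data.frame(supertype = s, n_carrier = length(a),
               n_noncarrier = length(b), median_diff = mw$median_diff,
               p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out)) out$p_adj <- bh_adjust(out$p_value)
  out
}

#' Age-group labels for stratified displays
#'
#' Labels ages as `young` (< 50 years), `old` (>= 69 years) or
#' `intermediate` — the bottom and top ~30% of the discovery-age
#' distribution and the band in between.
#'
#' @param age numeric vector of ages.
#' @return Character vector of labels.
#' @export
assign_age_groups <- function(age) {
  ifelse(age < 50, "young", ifelse(age >= 69, "old", "intermediate"))
}
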