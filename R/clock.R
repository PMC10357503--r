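#' Count UV-corrected SBS1 clock mutations
#'
#' Counts, per individual, C>T mutations at CpG sites whose trinucleotide
#' context (pyrimidine strand) is ApCpG or GpCpG; CpCpG and TpCpG contexts
#' are excluded because they overlap the UV signature (SBS7).  Records
#' written on the purine strand (G>A) are first strand-collapsed: the
#' alleles are complemented and the context reverse-complemented.  The
#' result is the UV-corrected SBS1 burden used as a molecular clock.
#'
#' Individuals listed in `individuals` but absent from the mutation table
#' are flagged `imputed` and assigned the cohort median burden (lower median
#' over non-imputed individuals, for determinism).
#'
#' @param muts mutation data frame with columns `sample`, `ref`, `alt`,
#'   `context` (3-mer centred on the mutated base).
#' @param individuals optional character vector of individual ids defining
#'   the full cohort; defaults to the samples present in `muts`.
#' @return Data frame with columns `individual`, `c_to_t_burden`, `imputed`.
#' @examples
#' muts <- data.frame(sample = "s1", ref = "C", alt = "T",
#'                    context = c("ACG", "CCG", "TCG", "ACT"))
#' count_uv_corrected_sbs1(muts)  # burden 1: only ApCpG qualifies
#' @export
count_uv_corrected_sbs1 <- function(muts, individuals = NULL) {
  req <- c("sample", "ref", "alt", "context")
  miss <- setdiff(req, names(muts))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(individuals)) individuals <- unique(as.character(muts$sample))

  n <- nrow(muts)
  qual <- logical(n)
  if (n > 0L) {
    ref <- toupper(as.character(muts$ref))
    alt <- toupper(as.character(muts$alt))
    ctx <- toupper(as.character(muts$context))
    # strand-collapse purine-strand records to the pyrimidine strand
    pur <- ref %in% c("G", "A")
    ref[pur] <- .revcomp(ref[pur])
    alt[pur] <- .revcomp(alt[pur])
    ctx[pur] <- .revcomp(ctx[pur])
    snv <- nchar(ref) == 1L & nchar(alt) == 1L
    ct <- snv & ref == "C" & alt == "T"
    bad <- ct & (nchar(ctx) != 3L | substr(ctx, 2, 2) != "C")
    if (any(bad))
      stop("malformed trinucleotide context in mutation record ",
           which(bad)[1], ": '", muts$context[which(bad)[1]], "'",
           call. = FALSE)
    qual <- ct & substr(ctx, 3, 3) == "G" &
      substr(ctx, 1, 1) %in% c("A", "G")
  }
  counted <- table(factor(as.character(muts$sample)[qual],
                          levels = individuals))
  observed <- individuals %in% as.character(muts$sample)
  burden <- as.integer(counted[individuals])
  med <- .lower_median(burden[observed])
  burden[!observed] <- med
  data.frame(individual = individuals, c_to_t_burden = burden,
             imputed = !observed, stringsAsFactors = FALSE)
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s)
           paste(rev(s), collapse = ""), character(1)))
}

# lower median: middle value, or the lower of the two middle values
.lower_median <- function(x) {
  x <- sort(x)
  if (length(x) == 0L) return(NA_integer_)
  x[ceiling(length(x) / 2)]
}

#' Fit the clock-to-age linear model
#'
#' Ordinary least squares of age at diagnosis on the UV-corrected SBS1
#' burden over non-imputed individuals.  The slope is the per-mutation
#' calendar-time increment of the clock (years per mutation).
#'
#' @param cohort data frame with columns `id` and `age_dx`.
#' @param counts output of [count_uv_corrected_sbs1()].
#' @return Object of class `clock_model`: list with `beta_c_to_t`
#'   (years/mutation), `intercept`, `pearson_r`, `spearman_rho`, `n`, and
#'   the underlying `lm` fit.
#' @export
fit_clock_model <- function(cohort, counts) {
  d <- merge(cohort[, c("id", "age_dx")], counts,
             by.x = "id", by.y = "individual")
  d <- d[!d$imputed & is.finite(d$age_dx), ]
  if (nrow(d) < 3L)
    stop("need at least 3 non-imputed individuals with ages", call. = FALSE)
  if (stats::var(d$c_to_t_burden) == 0)
    stop("zero variance in clock burden; slope is not identifiable",
         call. = FALSE)
  fit <- stats::lm(age_dx ~ c_to_t_burden, data = d)
  structure(list(beta_c_to_t = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(d$c_to_t_burden, d$age_dx),
                 spearman_rho = stats::cor(d$c_to_t_burden, d$age_dx,
                                           method = "spearman"),
                 n = nrow(d), fit = fit),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Clock model (n = %d): %.3f years/mutation, r = %.3f, rho = %.3f\n",
              x$n, x$beta_c_to_t, x$pearson_r, x$spearman_rho))
  invisible(x)
}

#' Personalized sojourn and onset estimates
#'
#' Combines the sex-specific population sojourn time with the individual's
#' clock deviation:
#' `sojourn_i = sojourn[sex_i] + (burden_i - median(burden)) * beta` and
#' `onset_i = age_dx_i - sojourn_i`.  Individuals with imputed burden sit at
#' the median, so their sojourn is exactly the sex-specific baseline.
#'
#' @param cohort data frame with columns `id`, `age_dx`, `sex`.
#' @param counts output of [count_uv_corrected_sbs1()].
#' @param sojourn_by_sex named numeric vector mapping each sex label present
#'   in `cohort` to a baseline sojourn time in years (e.g.
#'   `c(male = 8.35, female = 9.64)`).
#' @param model a [fit_clock_model()] object supplying `beta_c_to_t`.
#' @return Data frame with columns `id`, `age_dx`, `personalized_sojourn`,
#'   `onset_age`; the identity `onset_age + personalized_sojourn == age_dx`
#'   holds exactly.
#' @export
personalized_onset <- function(cohort, counts, sojourn_by_sex, model) {
  stopifnot(inherits(model, "clock_model"))
  d <- merge(cohort[, c("id", "age_dx", "sex")], counts,
             by.x = "id", by.y = "individual")
  sexes <- unique(as.character(d$sex))
  missing_sex <- setdiff(sexes, names(sojourn_by_sex))
  if (length(missing_sex))
    stop("no sojourn baseline for sex: ",
         paste(missing_sex, collapse = ", "), call. = FALSE)
  med <- .lower_median(d$c_to_t_burden[!d$imputed])
  dev <- ifelse(d$imputed, 0, d$c_to_t_burden - med)
  psoj <- unname(sojourn_by_sex[as.character(d$sex)]) +
    dev * model$beta_c_to_t
  data.frame(id = d$id, age_dx = d$age_dx,
             personalized_sojourn = psoj,
             onset_age = d$age_dx - psoj,
             stringsAsFactors = FALSE)
}

#' Compare personalized sojourns by whole-genome-duplication status
#'
#' One-sided Mann-Whitney test of whether tumours with a whole-genome
#' duplication (which must precede detection by years) have longer
#' personalized sojourn times than tumours without one — a sanity check on
#' the clock-based estimates.
#'
#' @param onsets output of [personalized_onset()].
#' @param wgd_status logical vector (or named logical) of WGD calls aligned
#'   with `onsets$id`.
#' @return List with `p_value` (one-sided, WGD+ greater), `median_wgd`,
#'   `median_no_wgd`, group sizes, and the `htest` object.
#' @export
compare_wgd_sojourn <- function(onsets, wgd_status) {
  if (!is.null(names(wgd_status)))
    wgd_status <- wgd_status[as.character(onsets$id)]
  wgd_status <- as.logical(wgd_status)
  a <- onsets$personalized_sojourn[wgd_status]
  b <- onsets$personalized_sojourn[!wgd_status]
  if (length(a) == 0L || length(b) == 0L)
    stop("both WGD groups must be non-empty", call. = FALSE)
  ht <- stats::wilcox.test(a, b, alternative = "greater", exact = FALSE)
  list(p_value = ht$p.value,
       median_wgd = stats::median(a), median_no_wgd = stats::median(b),
       n_wgd = length(a), n_no_wgd = length(b), test = ht)
}
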