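#' Enumerate 8- to 11-mer peptides of a protein
#'
#' All substrings of the given lengths across the full protein, with start
#' positions.  The MHC class I groove accommodates peptides of 8-11
#' residues, so these windows are the candidate epitope space.
#'
#' @param sequence amino-acid string over the 20-letter alphabet (`X`
#'   tolerated with a warning).
#' @param lengths integer vector of window lengths (default `8:11`).
#' @return Data frame with columns `peptide`, `start`, `length`; zero rows
#'   if the protein is shorter than the minimum length.
#' @examples
#' nrow(enumerate_peptides(strrep("A", 10)))  # 3 + 2 + 1 = 6 windows
#' @export
enumerate_peptides <- function(sequence, lengths = 8:11) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty protein sequence", call. = FALSE)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop("invalid amino-acid letter in sequence", call. = FALSE)
  if (grepl("X", sequence, fixed = TRUE))
    warning("sequence contains 'X' (unknown residue)", call. = FALSE)
  L <- nchar(sequence)
  out <- lapply(lengths, function(k) {
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.frame(peptide = substring(sequence, starts, starts + k - 1L),
               start = starts, length = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(peptide = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  out
}

#' Neoepitope peptides of a mutant protein
#'
#' The unique 8- to 11-mers of the mutant protein that occur nowhere in the
#' wild-type peptide set — the novel peptide space a mutation exposes.  For
#' a single interior substitution this is 8 + 9 + 10 + 11 = 38 peptides
#' minus any coincidental wild-type matches.
#'
#' @param wild,mutant amino-acid strings; must differ.
#' @param lengths window lengths (default `8:11`).
#' @return Character vector of unique mutant-only peptides.
#' @export
mutant_peptides <- function(wild, mutant, lengths = 8:11) {
  if (identical(toupper(wild), toupper(mutant)))
    stop("wild-type and mutant sequences are identical", call. = FALSE)
  wt <- unique(enumerate_peptides(wild, lengths)$peptide)
  mt <- unique(enumerate_peptides(mutant, lengths)$peptide)
  setdiff(mt, wt)
}

# look up ranks for (allele, peptides); error on any missing pair
rank_lookup <- function(ranks, allele, peptides) {
  if (!allele %in% rownames(ranks))
    stop("allele '", allele, "' not in rank matrix", call. = FALSE)
  miss <- setdiff(peptides, colnames(ranks))
  if (length(miss))
    stop("missing rank for (", allele, ", ", miss[1], ")",
         if (length(miss) > 1L) paste0(" and ", length(miss) - 1L,
                                       " more pair(s)"),
         call. = FALSE)
  ranks[allele, peptides]
}

#' Best (minimum) percentile rank over a peptide set
#'
#' The allele-specific binding summary of a mutation: the minimum
#' percentile rank across its unique 8- to 11-mers (lower = stronger).
#'
#' @param allele allele name (row of `ranks`).
#' @param peptides character vector of peptides.
#' @param ranks rank matrix, alleles x peptides (see [read_rank_table()]).
#' @return Scalar minimum rank.
#' @export
best_rank <- function(allele, peptides, ranks) {
  if (length(peptides) == 0L) stop("empty peptide set", call. = FALSE)
  min(rank_lookup(ranks, allele, peptides))
}

#' Mutation coverage curve per allele
#'
#' For each allele, the fraction of mutations whose best rank is at or
#' below each threshold — the presentation coverage of a driver set as a
#' function of binding stringency.
#'
#' @param alleles character vector of alleles.
#' @param peptide_sets named list mapping mutation id to its peptide set.
#' @param ranks rank matrix.
#' @param thresholds numeric vector of rank thresholds.
#' @return Matrix alleles x thresholds of fractions in \[0, 1\],
#'   non-decreasing along each row.
#' @export
coverage_curve <- function(alleles, peptide_sets, ranks, thresholds) {
  if (length(peptide_sets) == 0L) stop("no mutations", call. = FALSE)
  br <- sapply(alleles, function(a)
    vapply(peptide_sets, function(p) best_rank(a, p, ranks), numeric(1)))
  br <- matrix(br, nrow = length(peptide_sets),
               dimnames = list(names(peptide_sets), alleles))
  out <- vapply(thresholds, function(t) colMeans(br <= t),
                numeric(length(alleles)))
  matrix(out, nrow = length(alleles),
         dimnames = list(alleles, as.character(thresholds)))
}

#' Presented fraction of a peptide repertoire
#'
#' Fraction of a gene's peptides presented by an allele at or below a rank
#' threshold (inclusive cut, matching the "at or below" repertoire
#' definition; contrast [fgp()], which is strict).
#'
#' @param allele allele name.
#' @param peptides peptide set of the gene.
#' @param ranks rank matrix.
#' @param threshold rank cutoff; 0.5 and 2 are the conventional strong and
#'   weak binding cuts.
#' @return Fraction in \[0, 1\].
#' @export
repertoire_fraction <- function(allele, peptides, ranks, threshold = 0.5) {
  if (length(peptides) == 0L) stop("empty peptide set", call. = FALSE)
  mean(rank_lookup(ranks, allele, peptides) <= threshold)
}

#' Position-wise best rank along a protein
#'
#' For every residue position, the minimum rank among all 8- to 11-mer
#' windows covering that position — a per-position presentability profile.
#' Positions covered by no window (protein shorter than 8) are `NA`.
#'
#' @param allele allele name.
#' @param sequence protein sequence.
#' @param ranks rank matrix.
#' @param lengths window lengths (default `8:11`).
#' @return Numeric vector of length `nchar(sequence)`.
#' @export
positionwise_best_rank <- function(allele, sequence, ranks, lengths = 8:11) {
  peps <- enumerate_peptides(sequence, lengths)
  L <- nchar(sequence)
  out <- rep(NA_real_, L)
  if (nrow(peps) == 0L) return(out)
  r <- rank_lookup(ranks, allele, peps$peptide)
  for (i in seq_len(nrow(peps))) {
    span <- peps$start[i]:(peps$start[i] + peps$length[i] - 1L)
    out[span] <- pmin(out[span], r[i], na.rm = TRUE)
  }
  out
}

#' Fraction of a gene presentable (FGP)
#'
#' Fraction of a protein's 8- to 11-mers bound by an allele at a percentile
#' rank strictly below the cutoff (default 0.5).  Note the strict
#' inequality, versus the inclusive cut of [repertoire_fraction()].
#'
#' @param allele allele name.
#' @param sequence protein sequence.
#' @param ranks rank matrix.
#' @param cutoff strict rank cutoff (default 0.5).
#' @param lengths window lengths (default `8:11`).
#' @return Fraction in \[0, 1\].
#' @export
fgp <- function(allele, sequence, ranks, cutoff = 0.5, lengths = 8:11) {
  peps <- unique(enumerate_peptides(sequence, lengths)$peptide)
  if (length(peps) == 0L) stop("protein yields no peptides", call. = FALSE)
  mean(rank_lookup(ranks, allele, peps) < cutoff)
}

#' Population coverage envelope over common alleles
#'
#' Pointwise maximum and minimum of per-allele metric curves across the
#' common alleles (population frequency at least 1%): the best- and
#' worst-case presentation attainable within the common allele pool at each
#' threshold.
#'
#' @param curves matrix alleles x thresholds (e.g. from
#'   [coverage_curve()]), restricted to common alleles.
#' @return List with `max` and `min` numeric vectors over thresholds.
#' @export
population_envelope <- function(curves) {
  if (is.null(dim(curves)) || nrow(curves) == 0L)
    stop("no common-allele curves supplied", call. = FALSE)
  list(max = apply(curves, 2, max), min = apply(curves, 2, min))
}

#' Classify HLA alleles as lost by LOH
#'
#' An allele is called lost when its tumour copy number is below 0.5 and
#' the supporting p value is below 0.05 (quality-control conjunction).
#' Negative copy numbers (which allele-specific copy-number tools can emit)
#' are accepted with a warning; a missing p value means not lost.
#'
#' @param copy_number numeric vector of allele copy numbers.
#' @param pvalue numeric vector of supporting p values (NA allowed).
#' @param cn_cutoff copy-number threshold (default 0.5).
#' @param p_cutoff p-value threshold (default 0.05).
#' @return Logical vector of lost flags.
#' @export
classify_lost <- function(copy_number, pvalue, cn_cutoff = 0.5,
                          p_cutoff = 0.05) {
  if (any(copy_number < 0, na.rm = TRUE))
    warning("negative copy number(s) accepted as < cutoff", call. = FALSE)
  !is.na(copy_number) & copy_number < cn_cutoff &
    !is.na(pvalue) & pvalue < p_cutoff
}

# genotype-level FGP under the union rule: a peptide counts as presented
# when any carried allele binds it strictly below the cutoff
genotype_fgp <- function(alleles, peptides, ranks, cutoff = 0.5) {
  alleles <- unique(alleles)
  if (length(alleles) == 0L) return(0)
  pres <- Reduce(`|`, lapply(alleles, function(a)
    rank_lookup(ranks, a, peptides) < cutoff))
  mean(pres)
}

#' FGP impact of removing alleles from a genotype
#'
#' For each carried allele, the relative decrease in the genotype-level
#' fraction of a gene presented when that allele is removed:
#' `(FGP_full - FGP_without) / FGP_full`.  Genotype-level FGP uses the
#' union rule (a peptide is presented if any carried allele binds it below
#' the cutoff), so removing one copy of a duplicated allele changes
#' nothing.
#'
#' @param alleles character vector of carried alleles (up to six, with
#'   possible duplicates).
#' @param sequence protein sequence of the gene.
#' @param ranks rank matrix.
#' @param cutoff strict rank cutoff (default 0.5).
#' @param lengths window lengths (default `8:11`).
#' @return Data frame per carried allele slot: `allele`, `fgp_full`,
#'   `fgp_without`, `rel_decrease` (`NA` with a flag when the full FGP is
#'   0).
#' @export
loh_fgp_impact <- function(alleles, sequence, ranks, cutoff = 0.5,
                           lengths = 8:11) {
  peps <- unique(enumerate_peptides(sequence, lengths)$peptide)
  if (length(peps) == 0L) stop("protein yields no peptides", call. = FALSE)
  full <- genotype_fgp(alleles, peps, ranks, cutoff)
  rows <- lapply(seq_along(alleles), function(i) {
    without <- genotype_fgp(alleles[-i], peps, ranks, cutoff)
    data.frame(allele = alleles[i], fgp_full = full,
               fgp_without = without,
               rel_decrease = if (full == 0) NA_real_
               else (full - without) / full,
               undefined = full == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare FGP loss between allele classes
#'
#' Groups per-allele relative FGP decreases by class (e.g. autoimmune
#' alleles lost to LOH, other lost alleles, retained alleles) and compares
#' classes pairwise by Mann-Whitney with Benjamini-Hochberg adjustment.
#'
#' @param decreases numeric vector of relative FGP decreases.
#' @param classes character vector of class labels, same length.
#' @return List with `medians` (named), and `tests` data frame of pairwise
#'   comparisons (`class_a`, `class_b`, `p_value`, `p_adj`).
#' @export
fgp_class_comparison <- function(decreases, classes) {
  ok <- !is.na(decreases)
  decreases <- decreases[ok]; classes <- classes[ok]
  med <- tapply(decreases, classes, stats::median)
  cls <- names(med)
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    ht <- suppressWarnings(stats::wilcox.test(decreases[classes == p[1]],
                                              decreases[classes == p[2]]))
    data.frame(class_a = p[1], class_b = p[2], p_value = ht$p.value,
               stringsAsFactors = FALSE)
  }))
  tests$p_adj <- bh_adjust(tests$p_value)
  list(medians = med, tests = tests)
}
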