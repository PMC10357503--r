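#' Candidate driver-mutation filter
#'
#' Reduces a somatic mutation table to candidate drivers by the
#' multi-criterion cascade: (a) per-sample records must be called by at
#' least two mutation callers; (b) only single-nucleotide,
#' protein-altering mutations are considered; (c) at the mutation level,
#' the variant must be observed in both DNA and RNA (`dna_vaf > 0` and
#' `rna_vaf > 0`) in at least one sample and have a median (across samples)
#' per-sample VAF percentile of at most 40% in both DNA and RNA.
#'
#' The VAF percentile of a record is its rank among the VAFs of all
#' filtered records of the same sample, scaled to \[0, 100\].  With
#' `direction = "descending"` (default) the highest VAF in a sample has
#' percentile near 0, so the 40% cut keeps the top-VAF (clonal, early)
#' mutations; `"ascending"` inverts this.
#'
#' Mutation identity is `chrom:pos:ref>alt` when those columns are present,
#' otherwise `gene|protein_change`.
#'
#' @param muts mutation data frame with columns `sample`, `gene`,
#'   `protein_change`, `callers` (comma-separated names), `dna_vaf`,
#'   `rna_vaf` and optionally `chrom`, `pos`, `ref`, `alt`, `chasm`.
#' @param min_callers per-sample caller support required (default 2).
#' @param vaf_percentile_max median VAF percentile cut (default 40).
#' @param direction percentile orientation, see Details.
#' @return The candidate subset of `muts` with an added `mutation_id`
#'   column.
#' @export
candidate_filter <- function(muts, min_callers = 2, vaf_percentile_max = 40,
                             direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  muts <- add_mutation_id(muts)
  if (nrow(muts) == 0L) return(muts)

  # (a) caller support per sample record
  n_call <- vapply(strsplit(as.character(muts$callers), ","),
                   function(x) length(unique(trimws(x[nzchar(trimws(x))]))),
                   integer(1))
  keep <- n_call >= min_callers
  # (b) protein-altering SNVs
  keep <- keep & !is.na(muts$protein_change) & nzchar(muts$protein_change)
  if (all(c("ref", "alt") %in% names(muts)))
    keep <- keep & nchar(as.character(muts$ref)) == 1L &
      nchar(as.character(muts$alt)) == 1L
  m <- muts[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(m)

  # per-sample VAF percentiles over the surviving records
  pct <- function(v) {
    n <- sum(!is.na(v))
    if (n == 0L) return(rep(NA_real_, length(v)))
    r <- rank(if (direction == "descending") -v else v,
              ties.method = "average", na.last = "keep")
    100 * (r - 0.5) / n
  }
  dna_pct <- stats::ave(m$dna_vaf, m$sample, FUN = pct)
  rna_pct <- stats::ave(m$rna_vaf, m$sample, FUN = pct)

  # mutation-level criteria
  both <- !is.na(m$dna_vaf) & m$dna_vaf > 0 &
    !is.na(m$rna_vaf) & m$rna_vaf > 0
  med_na <- function(x) if (all(is.na(x))) NA_real_ else
    stats::median(x, na.rm = TRUE)
  by_mut <- split(seq_len(nrow(m)), m$mutation_id)
  ok_ids <- names(by_mut)[vapply(by_mut, function(i) {
    any(both[i]) &&
      isTRUE(med_na(dna_pct[i]) <= vaf_percentile_max) &&
      isTRUE(med_na(rna_pct[i]) <= vaf_percentile_max)
  }, logical(1))]
  m[m$mutation_id %in% ok_ids, , drop = FALSE]
}

add_mutation_id <- function(muts) {
  if ("mutation_id" %in% names(muts)) return(muts)
  muts$mutation_id <- if (all(c("chrom", "pos", "ref", "alt") %in%
                              names(muts)))
    paste0(muts$chrom, ":", muts$pos, ":", muts$ref, ">", muts$alt)
  else paste0(muts$gene, "|", muts$protein_change)
  muts
}

#' Recurrence filter
#'
#' Keeps candidate mutations detected in at least `min_tumors` distinct
#' samples (default 4; duplicate records within a sample count once).
#'
#' @param candidates output of [candidate_filter()].
#' @param min_tumors recurrence threshold, inclusive.
#' @return Character vector of recurrent `mutation_id`s.
#' @export
recurrence_filter <- function(candidates, min_tumors = 4) {
  if (nrow(candidates) == 0L) return(character())
  candidates <- add_mutation_id(candidates)
  n_tum <- tapply(candidates$sample, candidates$mutation_id,
                  function(s) length(unique(s)))
  names(n_tum)[n_tum >= min_tumors]
}

#' CHASM score filter for non-recurrent candidates
#'
#' Among candidates that failed the recurrence criterion, keeps mutations
#' with a melanoma-specific CHASM pathogenicity score of at least
#' `min_score` (default 0.9, inclusive).  Non-recurrent candidates with no
#' score are excluded with a warning.
#'
#' @param candidates output of [candidate_filter()] (needs a `chasm`
#'   column).
#' @param recurrent character vector from [recurrence_filter()].
#' @param min_score CHASM threshold, inclusive.
#' @return Character vector of `mutation_id`s, disjoint from `recurrent`.
#' @export
chasm_filter <- function(candidates, recurrent, min_score = 0.9) {
  if (nrow(candidates) == 0L) return(character())
  candidates <- add_mutation_id(candidates)
  singles <- candidates[!candidates$mutation_id %in% recurrent, ,
                        drop = FALSE]
  if (nrow(singles) == 0L) return(character())
  score <- tapply(singles$chasm, singles$mutation_id,
                  function(s) suppressWarnings(max(s, na.rm = TRUE)))
  unscored <- !is.finite(score)
  if (any(unscored))
    warning(sum(unscored), " non-recurrent candidate(s) without a CHASM ",
            "score excluded", call. = FALSE)
  names(score)[is.finite(score) & score >= min_score]
}

#' Assemble the driver set
#'
#' Runs the candidate, recurrence and CHASM filters and returns the driver
#' set as the disjoint union of recurrent mutations and high-CHASM
#' singletons.
#'
#' @param muts mutation data frame (see [candidate_filter()]).
#' @param min_callers,vaf_percentile_max,direction passed to
#'   [candidate_filter()].
#' @param min_tumors passed to [recurrence_filter()].
#' @param min_chasm passed to [chasm_filter()].
#' @return Object of class `driver_set`: list with `recurrent`, `chasm`,
#'   `union` (mutation id vectors), `counts`, and the candidate table.
#' @export
build_driver_set <- function(muts, min_callers = 2, vaf_percentile_max = 40,
                             direction = "descending", min_tumors = 4,
                             min_chasm = 0.9) {
  cand <- candidate_filter(muts, min_callers, vaf_percentile_max, direction)
  rec <- recurrence_filter(cand, min_tumors)
  chs <- chasm_filter(cand, rec, min_chasm)
  structure(list(recurrent = rec, chasm = chs, union = c(rec, chs),
                 counts = c(candidates =
                              length(unique(cand$mutation_id)),
                            recurrent = length(rec), chasm = length(chs),
                            union = length(rec) + length(chs)),
                 candidates = cand),
            class = "driver_set")
}

#' @export
print.driver_set <- function(x, ...) {
  cat(sprintf(
    "Driver set: %d candidates -> %d recurrent + %d CHASM = %d drivers\n",
    x$counts["candidates"], x$counts["recurrent"], x$counts["chasm"],
    x$counts["union"]))
  invisible(x)
}
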