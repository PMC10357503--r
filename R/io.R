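#' Normalize an HLA allele name
#'
#' Canonical form is `LOCUS*GG:PP` (e.g. `B*57:01`).  Accepts compact
#' (`B5701`), starred-unseparated (`B*5701`), colon-only (`B57:01`) and
#' lower-case spellings; `NA` and empty strings pass through unchanged.
#'
#' @param allele character vector of allele spellings.
#' @return Character vector of normalized names; unparseable entries raise
#'   an error naming the string.
#' @export
normalize_hla <- function(allele) {
  out <- as.character(allele)
  idx <- !is.na(out) & nzchar(out)
  x <- toupper(gsub("\\s", "", out[idx]))
  keep_other <- grepl("^[ABC]\\*OTHER$", x)
  m <- regmatches(x, regexec("^([ABC])\\*?(\\d{2,3}):?(\\d{2,3})$", x))
  bad <- !keep_other & vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("unresolvable allele format: '", x[bad][1], "'", call. = FALSE)
  x[!keep_other] <- vapply(m[!keep_other], function(g)
    paste0(g[2], "*", g[3], ":", g[4]), character(1))
  x[keep_other] <- paste0(substr(x[keep_other], 1, 1), "*other")
  out[idx] <- x
  out
}

#' Read a cohort table
#'
#' Tab-separated cohort file with header columns `id`, `age_dx`, `sex`,
#' `status`, `A1`, `A2`, `B1`, `B2`, `C1`, `C2` plus arbitrary covariate
#' columns.  Allele spellings are normalized via [normalize_hla()]; rows
#' with missing ages are retained (flagged by `NA`) and removed later by
#' [filter_cohort()].
#'
#' @param path file path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  req <- c("id", "age_dx", "sex", "status", genotype_cols)
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in genotype_cols) d[[col]] <- normalize_hla(d[[col]])
  d$age_dx <- suppressWarnings(as.numeric(d$age_dx))
  d
}

#' Write a cohort table
#' @param cohort cohort data frame.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mutation table
#'
#' Tab-separated file with header columns `sample`, `gene`, `chrom`,
#' `pos`, `ref`, `alt`, `context`, `callers`, `dna_vaf`, `rna_vaf`,
#' `protein_change` and optionally `chasm`.
#'
#' @param path file path.
#' @return Mutation data frame.
#' @export
read_mutation_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  req <- c("sample", "gene", "ref", "alt", "context", "callers",
           "dna_vaf", "rna_vaf", "protein_change")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("mutation file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !is.na(d$dna_vaf) & (d$dna_vaf < 0 | d$dna_vaf > 1)
  if (any(bad))
    stop("DNA VAF outside [0, 1] at line ", which(bad)[1] + 1L,
         call. = FALSE)
  d$protein_change[is.na(d$protein_change)] <- ""
  d
}

#' Write a mutation table
#' @param muts mutation data frame.
#' @param path output file path.
#' @export
write_mutation_table <- function(muts, path) {
  utils::write.table(muts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an incidence table
#'
#' Tab-separated file with header `age_lo`, `age_hi`, `sex`, `birth_lo`,
#' `birth_hi`, `cases`, `person_years` (`sex` and birth columns optional).
#'
#' @param path file path.
#' @return Validated incidence data frame.
#' @export
read_incidence <- function(path) {
  validate_incidence(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write an incidence table
#' @param table incidence data frame.
#' @param path output file path.
#' @export
write_incidence <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated genes x samples table; first column holds gene ids.
#'
#' @param path file path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(d[[1]]))
    stop("duplicate gene ids in expression file", call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix
#' @param mat numeric matrix genes x samples.
#' @param path output file path.
#' @export
write_expression_matrix <- function(mat, path) {
  d <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele x peptide rank table
#'
#' Canonical dialect is long-format TSV with header columns `allele`,
#' `peptide`, `rank`.  The `"netmhcpan"` dialect parses the tab-separated
#' NetMHCpan-4.1 "xls" export: a first line carrying allele names above
#' their column blocks, a second line of per-block column names including
#' `EL_Rank`, then one row per peptide.
#'
#' @param path file path.
#' @param dialect `"long"` (default) or `"netmhcpan"`.
#' @return Numeric matrix alleles x peptides with attribute `provenance`.
#' @export
read_rank_table <- function(path, dialect = c("long", "netmhcpan")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("allele", "peptide", "rank"), names(d))
    if (length(miss))
      stop("rank file missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    key <- paste(d$allele, d$peptide)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("duplicate (allele, peptide) pair: ", dup, call. = FALSE)
    }
    alleles <- unique(d$allele); peptides <- unique(d$peptide)
    m <- matrix(NA_real_, length(alleles), length(peptides),
                dimnames = list(alleles, peptides))
    m[cbind(match(d$allele, alleles), match(d$peptide, peptides))] <- d$rank
  } else {
    lines <- readLines(path)
    head1 <- strsplit(lines[1], "\t")[[1]]
    head2 <- strsplit(lines[2], "\t")[[1]]
    rank_cols <- which(head2 == "EL_Rank")
    alleles <- head1[head1 != "" & !is.na(head1)]
    if (length(alleles) != length(rank_cols))
      stop("cannot align allele names with EL_Rank columns", call. = FALSE)
    body <- utils::read.delim(text = lines[-(1:2)], header = FALSE,
                              stringsAsFactors = FALSE)
    pep_col <- which(head2 == "Peptide")[1]
    peptides <- body[[pep_col]]
    if (anyDuplicated(peptides))
      stop("duplicate peptide identifiers", call. = FALSE)
    m <- t(as.matrix(body[, rank_cols, drop = FALSE]))
    dimnames(m) <- list(alleles, peptides)
    storage.mode(m) <- "double"
  }
  attr(m, "provenance") <- basename(path)
  m
}

#' Write a rank matrix in long format
#' @param ranks numeric matrix alleles x peptides.
#' @param path output file path.
#' @export
write_rank_table <- function(ranks, path) {
  d <- data.frame(allele = rep(rownames(ranks), times = ncol(ranks)),
                  peptide = rep(colnames(ranks), each = nrow(ranks)),
                  rank = as.vector(ranks), stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Minimal FASTA reader for protein records: returns a named character
#' vector keyed by the first token of each header.
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(toupper(seqs), names_)
}

#' Write protein sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line wrap width.
#' @export
write_protein_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}
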