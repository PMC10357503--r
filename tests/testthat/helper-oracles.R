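# Independent oracles used across the suite; deliberately naive
# implementations kept separate from the package code paths.

# Cliff's delta by exhaustive pair enumeration
brute_cliffs <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# two-sided Fisher exact p by hypergeometric tail summation
brute_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + cc; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by the definitional arithmetic
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# AUC of score against binary label via the rank-sum identity
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small deterministic rank matrix for antigen tests
toy_ranks <- function(alleles, peptides, seed = 1) {
  set.seed(seed)
  matrix(100 * (1 - runif(length(alleles) * length(peptides))),
         nrow = length(alleles),
         dimnames = list(alleles, peptides))
}

# random protein sequence
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# hand-checkable driver-filter fixtures: per sample the target mutation has
# the top VAF (descending percentile 25 with two records) and a filler the
# bottom one (percentile 75)
driver_fixture_row <- function(sample, gene, pc, callers = "muse,mutect",
                               dna = 0.5, rna = 0.5, chasm = NA_real_) {
  data.frame(sample = sample, gene = gene, protein_change = pc,
             callers = callers, dna_vaf = dna, rna_vaf = rna,
             chasm = chasm, stringsAsFactors = FALSE)
}

# one sample with six mutations of which exactly two survive all rules:
#   m1 vaf .50/.50  descending pct 12.5  -> candidate
#   m2 vaf .40/.40  descending pct 37.5  -> candidate
#   m3 vaf .10/.10  descending pct 62.5  -> fails VAF percentile
#   m4 vaf .05/.02  descending pct 87.5  -> fails VAF percentile
#   m5 silent       -> fails protein rule
#   m6 one caller   -> fails caller rule
hand_fixture <- function() {
  rbind(driver_fixture_row("s1", "G1", "p.A1B", dna = 0.50, rna = 0.50),
        driver_fixture_row("s1", "G2", "p.C2D", dna = 0.40, rna = 0.40),
        driver_fixture_row("s1", "G3", "p.E3F", dna = 0.10, rna = 0.10),
        driver_fixture_row("s1", "G4", "p.G4H", dna = 0.05, rna = 0.02),
        driver_fixture_row("s1", "G5", "",      dna = 0.60, rna = 0.60),
        driver_fixture_row("s1", "G6", "p.I5K", dna = 0.70, rna = 0.70,
                           callers = "muse"))
}

# n_samp samples each holding the target mutation at the top VAF plus a
# low-VAF filler so percentiles are 25 (target) and 75 (filler)
recurrent_fixture <- function(gene, pc, n_samp, chasm = NA_real_,
                              prefix = "t") {
  do.call(rbind, lapply(seq_len(n_samp), function(i) {
    rbind(driver_fixture_row(paste0(prefix, i), gene, pc, dna = 0.5,
                             rna = 0.5, chasm = chasm),
          driver_fixture_row(paste0(prefix, i), paste0("FILL", prefix, i),
                             "p.F1L", dna = 0.01, rna = 0.01))
  }))
}
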