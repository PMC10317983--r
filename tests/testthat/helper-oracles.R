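# Independent scalar oracles, coded from the textbook formulas rather than
# from the package internals, plus small fixture builders shared by tests.

# Tajima's D for a complete-data dosage matrix (sites x individuals),
# via per-site heterozygosity n/(n-1) * 2pq and freshly computed constants.
oracle_tajima_D <- function(dosage) {
  n <- 2L * ncol(dosage)
  ca <- rowSums(dosage)
  seg <- ca > 0 & ca < n
  S <- sum(seg)
  p <- ca / n
  pi_w <- sum((n / (n - 1)) * 2 * p * (1 - p))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_w - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Per-site Weir & Cockerham (1984) theta for two populations, written
# scalar from the published equations with the r*nbar form of n_c.
oracle_wc_theta <- function(xA, xB) {
  xA <- xA[!is.na(xA)]
  xB <- xB[!is.na(xB)]
  n1 <- length(xA); n2 <- length(xB); r <- 2
  p1 <- sum(xA) / (2 * n1); p2 <- sum(xB) / (2 * n2)
  h1 <- mean(xA == 1); h2 <- mean(xB == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  A <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
  B <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) * hbar / (4 * nbar))
  C <- hbar / 2
  if (A + B + C == 0) return(NA_real_)
  A / (A + B + C)
}

# quick genotype_matrix builder with sane defaults
h_gm <- function(dosage, chrom = "chr1", pos = NULL, ids = NULL,
                 qual = 100, gq = 99, individuals = NULL, is_indel = FALSE) {
  dosage <- as.matrix(dosage)
  ns <- nrow(dosage); ni <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1000L, by = 100L, length.out = ns)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(ns))
  if (is.null(individuals)) individuals <- sprintf("I%02d", seq_len(ni))
  sites <- data.frame(chrom = rep_len(chrom, ns), pos = pos, id = ids,
                      ref = "A", alt = "G", qual = rep_len(qual, ns),
                      is_indel = rep_len(is_indel, ns),
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, individuals, dosage,
                  gq = matrix(rep_len(gq, ns * ni), ns, ni))
}

# two-population map for h_gm-style individuals
h_popmap <- function(n_per_pop = c(PopA = 6L, PopB = 6L),
                     continents = NULL, subsistence = NULL) {
  pops <- names(n_per_pop)
  if (is.null(continents)) continents <- rep("X", length(pops))
  if (is.null(subsistence)) {
    subsistence <- rep(c("agriculturalist", "forager"), length.out = length(pops))
  }
  data.frame(
    individual = sprintf("I%02d", seq_len(sum(n_per_pop))),
    population = rep(pops, n_per_pop),
    continent = rep(continents, n_per_pop),
    subsistence = rep(subsistence, n_per_pop),
    stringsAsFactors = FALSE
  )
}

# one-row annotation record with overridable fields
h_ann <- function(variant_id = "v1", gene = "OR001",
                  gene_type = "protein_coding", gene_family = "OR",
                  consequence = "missense_variant", transcript_id = "T1",
                  transcript_length = 1000, is_rna_gene = FALSE,
                  is_ancient_pseudogene = FALSE) {
  data.frame(variant_id = variant_id, gene = gene, gene_type = gene_type,
             gene_family = gene_family, consequence = consequence,
             transcript_id = transcript_id,
             transcript_length = transcript_length,
             is_rna_gene = is_rna_gene,
             is_ancient_pseudogene = is_ancient_pseudogene,
             stringsAsFactors = FALSE)
}
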