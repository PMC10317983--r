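#' Default simulated cohort design
#'
#' Six populations mirroring the study design: three from Uganda (BaKiga
#' agriculturalists; Sua and Twa foragers) and three from the Philippines
#' (Manobo agriculturalists; Agta and Mamanwa foragers), with the
#' published post-QC sample sizes.
#'
#' @return data.frame: `label`, `continent`, `subsistence`, `n`.
#' @export
default_populations <- function() {
  data.frame(
    label = c("Agta", "Mamanwa", "Manobo", "BaKiga", "Sua", "Twa"),
    continent = c("Philippines", "Philippines", "Philippines",
                  "Uganda", "Uganda", "Uganda"),
    subsistence = c("forager", "forager", "agriculturalist",
                    "agriculturalist", "forager", "forager"),
    n = c(21L, 18L, 24L, 26L, 21L, 23L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic cohort generator. Defaults emulate the study
#' design: a 133-individual, six-population cohort; 4913 chemosensory
#' exonic SNPs over 378 OR + 2 TAS1R + 24 TAS2R genes and 1704 putatively
#' neutral intergenic SNPs over 51 targeted regions; hierarchical
#' Balding-Nichols drift with continental differentiation ~0.10 and
#' within-continent population differentiation ~0.03; ~5% of chemosensory
#' sites carrying LOF alleles (a handful with reference-pseudogene rescue
#' polarity) calibrated to continent-level homozygous-load targets of
#' 11.78 (Philippines) and 8.22 (Uganda) lost genes per individual; and 20
#' selected sites with a +0.5 focal-branch frequency shift.
#'
#' @param seed RNG seed.
#' @param populations data.frame as [default_populations()].
#' @param F_cont,F_pop Balding-Nichols drift at the continent and
#'   population branches.
#' @param n_chemosensory_sites,n_neutral_sites SNP counts for the two
#'   datasets.
#' @param n_selected number of selected chemosensory sites.
#' @param delta focal-branch allele-frequency shift at selected sites.
#' @param selected_pop population receiving the shift.
#' @param lof_fraction fraction of chemosensory sites that are LOF.
#' @param rescue_fraction fraction of LOF sites with rescue (reference
#'   broken) polarity.
#' @param frameshift_fraction fraction of LOF sites simulated as
#'   frameshift indels (excluded from the SNP datasets, retained for load
#'   analysis).
#' @param target_load named numeric: expected homozygous-LOF gene load per
#'   individual, per continent.
#' @param sfs_mode `"neutral"` (allele count i with probability
#'   proportional to 1/i) or `"expansion"` (extra singleton mass).
#' @param sfs_skew extra singleton mass weight under `"expansion"`.
#' @param genes named integer vector of functional gene counts per family.
#' @param site_spacing bp between sites within a gene.
#' @param n_neutral_regions number of targeted intergenic regions.
#' @param neutral_spacing bp between neutral sites within a region.
#' @param missing_rate per-genotype missingness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       populations = default_populations(),
                       F_cont = 0.10, F_pop = 0.03,
                       n_chemosensory_sites = 4913L,
                       n_neutral_sites = 1704L,
                       n_selected = 20L, delta = 0.5,
                       selected_pop = "BaKiga",
                       lof_fraction = 0.05, rescue_fraction = 0.06,
                       frameshift_fraction = 0.30,
                       target_load = c(Philippines = 11.78, Uganda = 8.22),
                       sfs_mode = c("neutral", "expansion"),
                       sfs_skew = 0.3,
                       genes = c(OR = 378L, TAS1R = 2L, TAS2R = 24L),
                       site_spacing = 150L,
                       n_neutral_regions = 51L,
                       neutral_spacing = 5000L,
                       missing_rate = 0.02) {
  sfs_mode <- match.arg(sfs_mode)
  cfg <- list(
    seed = as.integer(seed), populations = populations,
    F_cont = F_cont, F_pop = F_pop,
    n_chemosensory_sites = as.integer(n_chemosensory_sites),
    n_neutral_sites = as.integer(n_neutral_sites),
    n_selected = as.integer(n_selected), delta = delta,
    selected_pop = selected_pop,
    lof_fraction = lof_fraction, rescue_fraction = rescue_fraction,
    frameshift_fraction = frameshift_fraction,
    target_load = target_load, sfs_mode = sfs_mode, sfs_skew = sfs_skew,
    genes = genes, site_spacing = as.integer(site_spacing),
    n_neutral_regions = as.integer(n_neutral_regions),
    neutral_spacing = as.integer(neutral_spacing),
    missing_rate = missing_rate
  )
  fracs <- c(F_cont, F_pop, lof_fraction, rescue_fraction,
             frameshift_fraction, missing_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (any(populations$n < 2L)) stop("each population needs >= 2 individuals")
  if (cfg$n_selected > cfg$n_chemosensory_sites) {
    stop("more selected sites than chemosensory sites")
  }
  if (n_selected > 0L && !selected_pop %in% populations$label) {
    stop("unknown selected_pop")
  }
  structure(cfg, class = "sim_config")
}

# Ancestral alt-allele frequency from the configured site frequency
# spectrum: derived-allele count i out of 2N with P(i) proportional to 1/i
# (standard neutral), optionally with extra singleton mass (expansion).
sample_sfs <- function(n_sites, n_chrom, mode, skew) {
  i <- seq_len(n_chrom - 1L)
  w <- 1 / i
  if (mode == "expansion") {
    w <- w / sum(w)
    w[1] <- w[1] + skew
  }
  counts <- sample(i, n_sites, replace = TRUE, prob = w)
  counts / n_chrom
}

# Balding-Nichols drift: daughter frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F).
bn_drift <- function(p, F) {
  if (F <= 0) return(p)
  out <- stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  # beta draws at machine 0/1 would make a site monomorphic everywhere
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Inject LOF and rescue sites into a truth table
#'
#' Marks one site in each of a sample of distinct genes as
#' loss-of-function and overwrites its population frequencies so that the
#' expected per-individual homozygous load (sum over sites of the squared
#' broken-allele frequency, one LOF site per gene) matches the configured
#' per-continent targets. Rescue-polarity sites have the *reference* as
#' the broken allele and the alternate as the rescue, and their gene
#' becomes a segregating pseudogene.
#'
#' @param cfg a [sim_config()].
#' @param truth truth table from the site-layout stage (chemosensory rows
#'   present, frequency columns `freq_<pop>` populated).
#' @return the updated truth table, with `is_lof`, `lof_allele`,
#'   `is_rescue` set.
#' @export
inject_lof <- function(cfg, truth) {
  chem <- which(truth$dataset == "chemosensory")
  if (length(chem) == 0L) stop("no chemosensory sites to inject LOF into")
  n_lof <- round(cfg$lof_fraction * length(chem))
  if (n_lof == 0L) return(truth)
  genes <- unique(truth$gene[chem])
  lof_genes <- sample(genes, min(n_lof, length(genes)))
  lof_rows <- vapply(lof_genes, function(g) {
    rows <- chem[truth$gene[chem] == g]
    rows[sample.int(length(rows), 1L)]
  }, integer(1))
  n_rescue <- round(cfg$rescue_fraction * length(lof_rows))
  rescue_rows <- lof_rows[seq_len(n_rescue)]

  pops <- cfg$populations
  freq_cols <- paste0("freq_", pops$label)
  # broken-allele base frequencies, scaled per continent to the target
  # expected load (sum of q^2 over sites)
  q_base <- stats::rbeta(length(lof_rows), 0.7, 2.0)
  for (cont in unique(pops$continent)) {
    target <- cfg$target_load[[cont]]
    s <- sqrt(target / sum(q_base^2))
    q_cont <- pmin(q_base * s, 0.98)
    for (lab in pops$label[pops$continent == cont]) {
      q_pop <- bn_drift(q_cont, cfg$F_pop)
      alt_freq <- ifelse(lof_rows %in% rescue_rows, 1 - q_pop, q_pop)
      truth[[paste0("freq_", lab)]][lof_rows] <- alt_freq
    }
  }
  truth$is_lof[lof_rows] <- TRUE
  truth$lof_allele[lof_rows] <- "alt"
  truth$is_lof[rescue_rows] <- FALSE
  truth$is_rescue[rescue_rows] <- TRUE
  truth$lof_allele[rescue_rows] <- "ref"
  truth
}

#' Simulate a full synthetic cohort
#'
#' Generates, deterministically for a given seed, a cohort with the
#' statistical structure the analysis assumes: per-site ancestral
#' frequencies from the configured SFS; hierarchical Balding-Nichols drift
#' (ancestral -> continent -> population); selected chemosensory sites
#' with a focal-branch frequency shift; LOF and rescue sites calibrated to
#' per-continent homozygous-load targets; and Hardy-Weinberg genotypes
#' drawn binomially from the population frequencies.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort`: `gm` (a [genotype_matrix()]),
#'   `annotations` (candidate annotation table), `popmap`, `truth`,
#'   `curated_rescue` (variant ids), `curated_lof` (empty; frameshift and
#'   stop consequences self-classify), `depth` (gene x individual matrix),
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pops <- cfg$populations
  N <- sum(pops$n)
  popmap <- data.frame(
    individual = sprintf("%s_%02d", rep(pops$label, pops$n),
                         unlist(lapply(pops$n, seq_len))),
    population = rep(pops$label, pops$n),
    continent = rep(pops$continent, pops$n),
    subsistence = rep(pops$subsistence, pops$n),
    stringsAsFactors = FALSE
  )

  layout <- site_layout(cfg)
  truth <- layout$truth
  n_total <- nrow(truth)

  truth$p_anc <- sample_sfs(n_total, 2L * N, cfg$sfs_mode, cfg$sfs_skew)
  cont_freq <- list()
  for (cont in unique(pops$continent)) {
    cont_freq[[cont]] <- bn_drift(truth$p_anc, cfg$F_cont)
  }
  for (k in seq_len(nrow(pops))) {
    lab <- pops$label[k]
    truth[[paste0("freq_", lab)]] <-
      bn_drift(cont_freq[[pops$continent[k]]], cfg$F_pop)
  }

  truth$is_lof <- FALSE
  truth$is_rescue <- FALSE
  truth$lof_allele <- NA_character_
  truth <- inject_lof(cfg, truth)

  truth$selected <- FALSE
  # selected sites are meant to be strongly differentiated: inject only
  # where the full focal-branch shift is realizable without clipping
  candidates <- which(truth$dataset == "chemosensory" & !truth$is_lof &
                        !truth$is_rescue & !truth$is_indel &
                        truth$p_anc <= 1 - cfg$delta)
  if (cfg$n_selected > 0L) {
    sel <- sample(candidates, min(cfg$n_selected, length(candidates)))
    truth$selected[sel] <- TRUE
    col <- paste0("freq_", cfg$selected_pop)
    truth[[col]][sel] <- pmin(1, truth[[col]][sel] + cfg$delta)
  }

  dosage <- matrix(NA_integer_, n_total, N)
  if (cfg$F_cont == 0 && cfg$F_pop == 0 && cfg$n_selected == 0L &&
      !any(truth$is_lof | truth$is_rescue)) {
    # no drift: the cohort IS the population, so realize the configured
    # sample SFS exactly -- place round(p * 2N) alternate alleles on a
    # random permutation of the 2N chromosomes (binomial resampling would
    # deplete singletons and push Tajima's D positive)
    counts <- round(truth$p_anc * 2L * N)
    for (s in seq_len(n_total)) {
      hap <- integer(2L * N)
      hap[sample.int(2L * N, counts[s])] <- 1L
      dosage[s, ] <- hap[c(TRUE, FALSE)] + hap[c(FALSE, TRUE)]
    }
  } else {
    for (k in seq_len(nrow(pops))) {
      cols <- which(popmap$population == pops$label[k])
      p <- truth[[paste0("freq_", pops$label[k])]]
      dosage[, cols] <- stats::rbinom(n_total * length(cols), 2L,
                                      rep(p, length(cols)))
    }
  }
  if (cfg$missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < cfg$missing_rate] <- NA_integer_
  }
  gq <- matrix(sample(30:99, n_total * N, replace = TRUE), n_total, N)

  sites <- data.frame(
    chrom = truth$chrom, pos = truth$pos, id = truth$id,
    ref = truth$ref, alt = truth$alt,
    qual = round(stats::runif(n_total, 60, 2000), 1),
    is_indel = truth$is_indel, stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(sites, popmap$individual, dosage, gq = gq)

  depth_genes <- unique(truth$gene)
  depth <- matrix(
    pmax(1, stats::rnorm(length(depth_genes) * N, mean = 97.4, sd = 15)),
    length(depth_genes), N, dimnames = list(depth_genes, popmap$individual)
  )

  out <- list(
    gm = gm,
    annotations = layout$build_annotations(truth),
    popmap = popmap,
    truth = truth,
    curated_rescue = truth$id[truth$is_rescue],
    curated_lof = character(0),
    depth = depth,
    config = cfg
  )
  class(out) <- "sim_cohort"
  out
}

# Gene/region coordinates and the pre-frequency truth skeleton.
site_layout <- function(cfg) {
  fam <- rep(names(cfg$genes), cfg$genes)
  gene_names <- unlist(lapply(names(cfg$genes), function(f) {
    sprintf("%s%03d", f, seq_len(cfg$genes[[f]]))
  }))
  n_genes <- length(gene_names)
  gene_chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% 22L + 1L)
  slot <- stats::ave(seq_len(n_genes), gene_chrom, FUN = seq_along)
  gene_start <- 1e6 * slot + 1

  site_gene <- sort(sample.int(n_genes, cfg$n_chemosensory_sites, replace = TRUE))
  within <- stats::ave(site_gene, site_gene, FUN = seq_along)
  chem <- data.frame(
    chrom = gene_chrom[site_gene],
    pos = as.integer(gene_start[site_gene] + (within - 1L) * cfg$site_spacing),
    gene = gene_names[site_gene],
    family = fam[site_gene],
    dataset = "chemosensory",
    stringsAsFactors = FALSE
  )

  region <- sort(sample.int(cfg$n_neutral_regions, cfg$n_neutral_sites,
                            replace = TRUE))
  within_n <- stats::ave(region, region, FUN = seq_along)
  reg_chrom <- paste0("chr", (seq_len(cfg$n_neutral_regions) - 1L) %% 22L + 1L)
  reg_slot <- stats::ave(seq_len(cfg$n_neutral_regions), reg_chrom,
                         FUN = seq_along)
  neu <- data.frame(
    chrom = reg_chrom[region],
    pos = as.integer(5e8 + 1e6 * reg_slot[region] + (within_n - 1L) * cfg$neutral_spacing),
    gene = sprintf("NEU%03d", region),
    family = "intergenic",
    dataset = "neutral",
    stringsAsFactors = FALSE
  )

  truth <- rbind(chem, neu)
  n_total <- nrow(truth)
  truth$id <- sprintf("snp%05d", seq_len(n_total))
  alleles <- c("A", "C", "G", "T")
  truth$ref <- sample(alleles, n_total, replace = TRUE)
  truth$alt <- vapply(truth$ref, function(r) sample(setdiff(alleles, r), 1L),
                      character(1))
  truth$is_indel <- FALSE

  # frameshift indels among the chemosensory sites are assigned after LOF
  # injection; the builder reads flags off the finished truth table
  build_annotations <- function(tr) {
    fs <- tr$is_lof & stats::runif(nrow(tr)) < cfg$frameshift_fraction
    conseq <- ifelse(tr$dataset == "neutral", "intergenic_variant",
              ifelse(tr$is_rescue, "missense_variant",
              ifelse(tr$is_lof & fs, "frameshift_variant",
              ifelse(tr$is_lof, "stop_gained",
                     sample(c("missense_variant", "synonymous_variant",
                              "3_prime_UTR_variant"),
                            nrow(tr), replace = TRUE,
                            prob = c(0.5, 0.4, 0.1))))))
    data.frame(
      variant_id = tr$id,
      gene = tr$gene,
      gene_type = ifelse(tr$dataset == "neutral", "pseudogene",
                  ifelse(tr$is_rescue, "segregating_pseudogene",
                         "protein_coding")),
      gene_family = tr$family,
      consequence = conseq,
      transcript_id = ifelse(tr$dataset == "neutral", NA_character_,
                             paste0(tr$gene, "-T1")),
      transcript_length = ifelse(tr$dataset == "neutral", NA_real_,
                                 900 + (as.integer(factor(tr$gene)) %% 21L) * 100),
      is_rna_gene = FALSE,
      is_ancient_pseudogene = FALSE,
      stringsAsFactors = FALSE
    )
  }
  list(truth = truth, build_annotations = build_annotations)
}

#' Mark frameshift LOF sites as indels in a simulated cohort
#'
#' The annotation builder labels a fraction of LOF sites as frameshift
#' indels; this helper keeps the genotype matrix's `is_indel` flags in
#' step with the emitted annotation table.
#'
#' @param sim a `sim_cohort`.
#' @return the updated `sim_cohort`.
#' @export
sync_indel_flags <- function(sim) {
  fs <- sim$annotations$variant_id[
    sim$annotations$consequence == "frameshift_variant"]
  rows <- match(fs, sim$gm$sites$id)
  sim$gm$sites$is_indel[rows] <- TRUE
  sim$gm$sites$ref[rows] <- paste0(sim$gm$sites$ref[rows], "C")
  sim$truth$is_indel[match(fs, sim$truth$id)] <- TRUE
  sim
}

#' Expected homozygous LOF load from a truth table
#'
#' With one LOF site per gene and Hardy-Weinberg genotypes, the expected
#' number of homozygous-broken genes per individual of a population is the
#' sum over LOF sites of the squared broken-allele frequency.
#'
#' @param truth a truth table from [simulate_cohort()].
#' @param populations character vector of population labels.
#' @return named numeric vector of expected loads.
#' @export
expected_hom_load <- function(truth, populations) {
  rows <- truth$is_lof | truth$is_rescue
  vapply(populations, function(lab) {
    f <- truth[[paste0("freq_", lab)]][rows]
    broken <- ifelse(truth$lof_allele[rows] == "ref", 1 - f, f)
    sum(broken^2)
  }, numeric(1))
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `annotations.tsv`, `popmap.tsv`, `truth.tsv`,
#' `depth.tsv` (long format) and `curated_rescue.txt` under `dir`.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$gm, file.path(dir, "cohort.vcf"))
  utils::write.table(sim$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$popmap, file.path(dir, "popmap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  depth_long <- data.frame(
    gene = rep(rownames(sim$depth), ncol(sim$depth)),
    individual = rep(colnames(sim$depth), each = nrow(sim$depth)),
    mean_depth = as.vector(sim$depth)
  )
  utils::write.table(depth_long, file.path(dir, "depth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$curated_rescue, file.path(dir, "curated_rescue.txt"))
  invisible(dir)
}

#' Generate the deterministic mini-fixture suite
#'
#' Writes the small named fixtures used across the test suite: a
#' quality-filter stress VCF with planned QUAL/GQ failures, a
#' two-population F_ST fixture, an LD fixture with engineered r-squared
#' structure, and a reduced paper-shaped scan cohort (six populations with
#' the published sample sizes, fewer sites). A README documents each file.
#' Regeneration is byte-deterministic apart from the VCF `fileDate` header
#' line.
#'
#' @param out_dir output directory.
#' @return named list of the fixture paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  filt <- filter_fixture_gm()
  write_vcf(filt, file.path(out_dir, "filter_fixture.vcf"))

  wc <- wc_fixture()
  write_vcf(wc$gm, file.path(out_dir, "wc_fixture.vcf"))
  utils::write.table(wc$popmap, file.path(out_dir, "wc_popmap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ld <- ld_fixture_gm()
  write_vcf(ld, file.path(out_dir, "ld_fixture.vcf"))

  scan_dir <- file.path(out_dir, "scan_cohort")
  sim <- simulate_cohort(sim_config(seed = 424242L,
                                    n_chemosensory_sites = 600L,
                                    n_neutral_sites = 300L))
  sim <- sync_indel_flags(sim)
  write_cohort(sim, scan_dir)

  writeLines(c(
    "Deterministic mini-fixtures:",
    "",
    "filter_fixture.vcf  10 sites x 8 samples; sites q30/q31 probe the strict",
    "                    QUAL cut, planned GQ<=20 failures drive one individual",
    "                    below 50% call rate and one site below 75% call rate.",
    "wc_fixture.vcf      5 sites, two 6-individual populations (wc_popmap.tsv):",
    "                    identical arrays, reciprocal fixation, shared fixation,",
    "                    and two intermediate-differentiation sites.",
    "ld_fixture.vcf      8 individuals, 4 sites: a pair in perfect LD, a",
    "                    partially linked pair, and an independent site.",
    "scan_cohort/        reduced paper-shaped cohort (6 populations, sizes",
    "                    21/26/18/24/21/23; 600 chemosensory + 300 neutral",
    "                    SNPs; seed 424242)."
  ), file.path(out_dir, "README.md"))

  invisible(list(
    filter = file.path(out_dir, "filter_fixture.vcf"),
    wc = file.path(out_dir, "wc_fixture.vcf"),
    ld = file.path(out_dir, "ld_fixture.vcf"),
    scan = scan_dir
  ))
}

# 10 sites x 8 samples with hand-planned failures (no RNG):
# - snp02 has QUAL exactly 30 (must fail the strict cut), snp03 QUAL 31
# - individual I8 has GQ <= 20 at 5 of the 9 surviving sites -> rate 4/9
# - snp10 has GQ <= 20 for 3 of the remaining 7 individuals -> rate 4/7
filter_fixture_gm <- function() {
  inds <- paste0("I", 1:8)
  sites <- data.frame(
    chrom = "chr1", pos = seq(1000L, by = 500L, length.out = 10L),
    id = sprintf("snp%02d", 1:10), ref = "A", alt = "G",
    qual = c(100, 30, 31, 200, 150, 90, 80, 70, 60, 50),
    is_indel = FALSE, stringsAsFactors = FALSE
  )
  dosage <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L), each = 10L), 10L, 8L)
  gq <- matrix(99, 10L, 8L)
  gq[c(1:4, 6:7), 8] <- 15   # I8 fails at 6 of the 9 surviving sites
  gq[10, 2:4] <- 10          # snp10 fails for I2..I4
  genotype_matrix(sites, inds, dosage, gq = gq)
}

# Two 6-individual populations over 5 sites with known differentiation.
wc_fixture <- function() {
  inds <- c(paste0("A", 1:6), paste0("B", 1:6))
  popmap <- data.frame(
    individual = inds, population = rep(c("PopA", "PopB"), each = 6L),
    continent = "X", subsistence = rep(c("agriculturalist", "forager"), each = 6L),
    stringsAsFactors = FALSE
  )
  sites <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    id = paste0("w", 1:5), ref = "A", alt = "T",
    qual = 100, is_indel = FALSE, stringsAsFactors = FALSE
  )
  dosage <- rbind(
    c(0, 1, 1, 2, 0, 1, 0, 1, 1, 2, 0, 1),   # identical arrays
    c(0, 0, 0, 0, 0, 0, 2, 2, 2, 2, 2, 2),   # reciprocal fixation
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # shared fixation (undefined)
    c(0, 0, 1, 0, 1, 0, 2, 1, 2, 2, 1, 2),   # strong differentiation
    c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 2, 0)    # mild differentiation
  )
  list(gm = genotype_matrix(sites, inds, dosage,
                            gq = matrix(99, 5L, 12L)),
       popmap = popmap)
}

# 8 individuals, 4 sites: s1 == s2 (perfect LD), s3 partially linked to s1,
# s4 unrelated.
ld_fixture_gm <- function() {
  inds <- paste0("L", 1:8)
  sites <- data.frame(
    chrom = "chr2", pos = c(1000L, 2000L, 3000L, 4000L),
    id = paste0("s", 1:4), ref = "C", alt = "T",
    qual = 100, is_indel = FALSE, stringsAsFactors = FALSE
  )
  s1 <- c(0, 0, 1, 1, 2, 2, 1, 0)
  dosage <- rbind(
    s1,
    s1,
    c(0, 1, 1, 1, 2, 2, 0, 0),
    c(2, 0, 1, 0, 0, 1, 2, 1)
  )
  genotype_matrix(sites, inds, dosage, gq = matrix(99, 4L, 8L))
}
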