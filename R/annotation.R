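#' @name annotation
#' @title Variant annotation resolution and dataset partitioning
#'
#' @description
#' Target-capture panels of chemosensory genes yield one VEP-style
#' annotation per transcript isoform, so a variant can carry several
#' candidate annotations. These helpers reduce them to one deterministic
#' annotation per variant, classify putative loss-of-function (LOF) and
#' reference-pseudogene "rescue" variants, and split SNPs into the
#' chemosensory (exon/UTR of functional OR/TAS1R/TAS2R genes) and
#' putatively neutral datasets used by the selection statistics.
NULL

CONSEQUENCE_VOCAB <- c(
  "stop_gained", "start_lost", "stop_lost", "frameshift_variant",
  "missense_variant", "synonymous_variant", "intron_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant", "upstream_gene_variant",
  "downstream_gene_variant", "regulatory_region_variant", "intergenic_variant"
)

LOF_CONSEQUENCES <- c("stop_gained", "start_lost", "stop_lost",
                      "frameshift_variant")

EXONIC_CONSEQUENCES <- c("stop_gained", "start_lost", "stop_lost",
                         "frameshift_variant", "missense_variant",
                         "synonymous_variant")

UTR_CONSEQUENCES <- c("5_prime_UTR_variant", "3_prime_UTR_variant")

SENSORY_FAMILIES <- c("OR", "TAS1R", "TAS2R")

#' Read a variant annotation table
#'
#' Tab-delimited, one row per (variant, transcript) candidate annotation,
#' with columns `variant_id`, `gene`, `gene_type`, `gene_family`,
#' `consequence`, `transcript_id`, `transcript_length`, `is_rna_gene`,
#' `is_ancient_pseudogene`.
#'
#' @param path TSV path.
#' @return data.frame of candidate annotations.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("variant_id", "gene", "gene_type", "gene_family",
                "consequence", "transcript_id", "transcript_length",
                "is_rna_gene", "is_ancient_pseudogene")
  if (!all(required %in% names(ann))) {
    stop("annotation table needs columns: ",
         paste(setdiff(required, names(ann)), collapse = ", "))
  }
  bad <- setdiff(unique(ann$consequence), CONSEQUENCE_VOCAB)
  if (length(bad) > 0L) {
    stop("consequence terms outside the controlled vocabulary: ",
         paste(bad, collapse = ", "))
  }
  ann$is_rna_gene <- as.logical(ann$is_rna_gene)
  ann$is_ancient_pseudogene <- as.logical(ann$is_ancient_pseudogene)
  ann
}

# Priority keys implementing the four-step single-annotation rule.
# Lower rank wins at each step; later keys break ties of earlier ones.
annotation_rank <- function(ann) {
  region <- ifelse(ann$consequence %in% EXONIC_CONSEQUENCES, 1L,
            ifelse(ann$consequence %in% c(UTR_CONSEQUENCES, "intron_variant"),
                   2L, 3L))
  sensory <- ifelse(ann$gene_family %in% SENSORY_FAMILIES, 1L,
             ifelse(ann$is_rna_gene, 3L, 2L))
  tl <- ann$transcript_length
  tl[is.na(tl)] <- 0
  list(region = region, sensory = sensory, neg_length = -tl,
       transcript = ann$transcript_id)
}

#' Resolve a single annotation per variant
#'
#' Applies, in order: (1) coding-region annotations (exonic, intronic, UTR)
#' over upstream/downstream/regulatory/intergenic; (2) exonic over
#' intronic/UTR; (3) sensory-family genes over RNA genes; (4) the longest
#' transcript; remaining ties break lexicographically on `transcript_id`,
#' so the result is invariant to the order of the candidates.
#'
#' @param candidates data.frame of candidate annotations for one or many
#'   variants (see [read_annotation_table()]).
#' @return data.frame with one row per `variant_id`.
#' @export
resolve_annotation <- function(candidates) {
  if (nrow(candidates) == 0L) stop("no candidate annotations")
  r <- annotation_rank(candidates)
  o <- order(candidates$variant_id, r$region, r$sensory, r$neg_length,
             r$transcript)
  sorted <- candidates[o, , drop = FALSE]
  out <- sorted[!duplicated(sorted$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify loss-of-function and rescue variants
#'
#' A variant is LOF (broken allele = alt) when its resolved consequence is
#' stop_gained, start_lost, stop_lost or frameshift_variant, or when it is
#' on a curated LOF list. A variant on the curated rescue list segregates
#' in a gene that is a pseudogene in the reference: its *reference* allele
#' is the broken state, and the alternate allele restores function.
#' Curated rescue status overrides a consequence-based LOF call (such
#' variants often carry stop-related consequence terms precisely because
#' the reference is the pseudogenized state).
#'
#' @param ann resolved annotation data.frame (one row per variant).
#' @param curated_lof character vector of variant ids (may be empty).
#' @param curated_rescue character vector of variant ids (may be empty).
#' @return data.frame (`lof_catalog`): `variant_id`, `gene`, `is_lof`,
#'   `is_rescue`, `lof_allele` (`"alt"`, `"ref"` or `NA`), `source`.
#' @export
classify_lof <- function(ann, curated_lof = character(),
                         curated_rescue = character()) {
  clash <- intersect(curated_lof, curated_rescue)
  if (length(clash) > 0L) {
    stop("variant(s) on both curated LOF and rescue lists: ",
         paste(clash, collapse = ", "))
  }
  by_conseq <- ann$consequence %in% LOF_CONSEQUENCES
  by_list <- ann$variant_id %in% curated_lof
  is_rescue <- ann$variant_id %in% curated_rescue
  is_lof <- (by_conseq | by_list) & !is_rescue
  data.frame(
    variant_id = ann$variant_id,
    gene = ann$gene,
    is_lof = is_lof,
    is_rescue = is_rescue,
    lof_allele = ifelse(is_rescue, "ref", ifelse(is_lof, "alt", NA_character_)),
    source = ifelse(is_rescue | (by_list & !by_conseq), "curated",
                    ifelse(by_conseq, "consequence", NA_character_)),
    stringsAsFactors = FALSE
  )
}

#' Partition SNPs into chemosensory and putatively neutral datasets
#'
#' The chemosensory dataset holds SNPs in exons and untranslated regions of
#' functional chemosensory genes (protein-coding or segregating-pseudogene
#' OR/TAS1R/TAS2R). The putatively neutral dataset holds SNPs from targeted
#' intergenic regions (LD-pruned at `r2_prune`) plus SNPs annotated as
#' intergenic, upstream/downstream, introns of pseudogenes, or in ancient
#' chemosensory pseudogenes. Indels never enter either dataset;
#' regulatory-region SNPs are excluded from both.
#'
#' @param ann resolved annotation data.frame (one row per variant).
#' @param gm a [genotype_matrix()]; supplies `is_indel` flags and the
#'   dosages used for LD pruning.
#' @param r2_prune squared-correlation threshold for pruning the targeted
#'   intergenic SNPs (default 0.5; a pair at or above the threshold loses
#'   its later member).
#' @param ld_pruner function `(gm, ids, r2_max) -> kept ids`; defaults to
#'   the package's greedy positional pruner [ld_prune()].
#' @return list of class `dataset_partition` with character vectors
#'   `chemosensory` and `neutral` (disjoint variant-id sets).
#' @export
partition_datasets <- function(ann, gm, r2_prune = 0.5, ld_pruner = ld_prune) {
  if (anyDuplicated(ann$variant_id)) {
    stop("annotations are not resolved: duplicated variant_id")
  }
  idx <- match(ann$variant_id, gm$sites$id)
  present <- !is.na(idx)
  ann <- ann[present, , drop = FALSE]
  is_snp <- !gm$sites$is_indel[idx[present]]

  chem <- is_snp &
    ann$gene_type %in% c("protein_coding", "segregating_pseudogene") &
    ann$gene_family %in% SENSORY_FAMILIES &
    ann$consequence %in% c(EXONIC_CONSEQUENCES, UTR_CONSEQUENCES)

  targeted_intergenic <- is_snp & !chem & ann$gene_family == "intergenic"
  neutral_by_class <- is_snp & !chem & !targeted_intergenic & (
    ann$consequence %in% c("intergenic_variant", "upstream_gene_variant",
                           "downstream_gene_variant") |
      (ann$consequence == "intron_variant" & ann$gene_type == "pseudogene") |
      ann$is_ancient_pseudogene
  )

  intergenic_ids <- ann$variant_id[targeted_intergenic]
  if (length(intergenic_ids) > 1L) {
    intergenic_ids <- ld_pruner(gm, intergenic_ids, r2_prune)
  }
  structure(
    list(
      chemosensory = ann$variant_id[chem],
      neutral = c(intergenic_ids, ann$variant_id[neutral_by_class])
    ),
    class = "dataset_partition"
  )
}

#' Greedy positional LD pruning
#'
#' Walks sites chromosome by chromosome in position order and drops any
#' site whose dosage r-squared with an already-kept site on the same
#' chromosome reaches `r2_max`.
#'
#' @param gm a [genotype_matrix()].
#' @param ids site ids to prune.
#' @param r2_max pruning threshold (site dropped when r^2 >= `r2_max`).
#' @return character vector of retained ids, in input (positional) order.
#' @export
ld_prune <- function(gm, ids, r2_max = 0.5) {
  idx <- match(ids, gm$sites$id)
  if (anyNA(idx)) stop("unknown site id in ld_prune")
  s <- gm$sites[idx, , drop = FALSE]
  kept <- character(0)
  for (chr in unique(s$chrom)) {
    rows <- which(s$chrom == chr)
    rows <- rows[order(s$pos[rows])]
    d <- gm$dosage[idx[rows], , drop = FALSE]
    kept_rows <- integer(0)
    for (j in seq_along(rows)) {
      ok <- TRUE
      if (length(kept_rows) > 0L) {
        r2 <- suppressWarnings(
          stats::cor(d[j, ], t(d[kept_rows, , drop = FALSE]),
                     use = "pairwise.complete.obs")^2
        )
        if (any(!is.na(r2) & r2 >= r2_max)) ok <- FALSE
      }
      if (ok) kept_rows <- c(kept_rows, j)
    }
    kept <- c(kept, s$id[rows][kept_rows])
  }
  kept[order(match(kept, ids))]
}
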