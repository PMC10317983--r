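#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via `VariantAnnotation::readVcf`) into the
#' package's dosage representation. Genotypes are diploid alternate-allele
#' counts; any missing allele (`./.` or `.`) yields a missing dosage.
#'
#' @param path path to a VCF file.
#' @param biallelic_only drop multi-allelic sites (default `TRUE`); the
#'   number of dropped sites is reported with a message. All downstream
#'   statistics assume biallelic sites.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) == 0L) stop("VCF has zero samples: ", path)
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  if (biallelic_only && any(n_alt != 1L)) {
    message(sum(n_alt != 1L), " multi-allelic site(s) dropped")
    vcf <- vcf[n_alt == 1L]
  }
  if (nrow(vcf) == 0L) stop("no sites left after multi-allelic filtering")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) as.character(a)[1], character(1))
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0("var", seq_along(rr))
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = ids,
    ref = ref,
    alt = alt,
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    is_indel = nchar(ref) != 1L | nchar(alt) != 1L,
    stringsAsFactors = FALSE
  )
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dosage <- gt_to_dosage(gt)
  gq <- VariantAnnotation::geno(vcf)$GQ
  if (!is.null(gq)) storage.mode(gq) <- "double"
  genotype_matrix(sites, colnames(gt), dosage, gq = gq, gt = unname(gt))
}

# GT strings -> {0,1,2,NA}; tolerates phased separators. Alleles other than
# 0/1 (possible only when multi-allelic sites are retained) become missing.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    al <- strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al) || any(al > 1L)) return(NA_integer_)
    sum(al)
  }, integer(1))
  d <- map[match(as.vector(gt), u)]
  matrix(d, nrow = nrow(gt), dimnames = NULL)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Round-trip property: `read_vcf(write_vcf(gm, path))` reproduces the
#' dosage matrix exactly. Genotype qualities are emitted as integers
#' (rounded) under the GQ FORMAT key.
#'
#' @param gm a [genotype_matrix()]; must be non-empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  if (n_sites(gm) == 0L || n_individuals(gm) == 0L) stop("empty genotype matrix")
  s <- gm$sites
  gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, width = nchar(s$ref)))
  names(gr) <- s$id
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$dosage + 1L],
                   nrow = n_sites(gm))
  gt_str[is.na(gt_str)] <- "./."
  geno_list <- list(GT = gt_str)
  geno_fmt <- data.frame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT", stringsAsFactors = FALSE
  )
  if (!is.null(gm$gq)) {
    gq <- round(gm$gq)
    storage.mode(gq) <- "integer"
    geno_list$GQ <- gq
    geno_fmt <- rbind(geno_fmt, data.frame(
      Number = "1", Type = "Integer", Description = "Genotype Quality",
      row.names = "GQ", stringsAsFactors = FALSE
    ))
  }
  hdr <- VariantAnnotation::VCFHeader(samples = gm$individuals)
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(geno_fmt)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat")
  )
  fx <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(s$ref),
    ALT = Biostrings::DNAStringSetList(as.list(s$alt)),
    QUAL = as.numeric(s$qual),
    FILTER = "."
  )
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = gm$individuals),
    fixed = fx,
    geno = S4Vectors::SimpleList(lapply(geno_list, function(m) {
      dimnames(m) <- list(s$id, gm$individuals); m
    })),
    exptData = list(header = hdr)
  )
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read a population map
#'
#' Tab-delimited file with a header row and columns `individual`,
#' `population`, `continent`, `subsistence` (values `forager` or
#' `agriculturalist`).
#'
#' @param path TSV path.
#' @return data.frame with those four character columns.
#' @export
read_population_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("individual", "population", "continent", "subsistence")
  if (!all(required %in% names(pm))) {
    stop("population map needs columns: ", paste(required, collapse = ", "))
  }
  validate_population_map(pm)
  pm[required]
}

validate_population_map <- function(pm) {
  bad <- setdiff(unique(pm$subsistence), c("forager", "agriculturalist"))
  if (length(bad) > 0L) {
    stop("unknown subsistence class(es): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(pm$individual)) stop("duplicated individuals in population map")
  per_pop <- unique(pm[c("population", "continent", "subsistence")])
  if (anyDuplicated(per_pop$population)) {
    stop("a population maps to more than one continent or subsistence class")
  }
  invisible(pm)
}

#' Read a gene x individual read-depth table
#'
#' Long-format TSV with header columns `gene`, `individual`, `mean_depth`.
#'
#' @param path TSV path.
#' @return numeric matrix, genes x individuals.
#' @export
read_depth_table <- function(path) {
  dt <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "individual", "mean_depth")
  if (!all(required %in% names(dt))) {
    stop("depth table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(dt$mean_depth < 0)) stop("read depths must be non-negative")
  genes <- unique(dt$gene)
  inds <- unique(dt$individual)
  m <- matrix(NA_real_, length(genes), length(inds), dimnames = list(genes, inds))
  m[cbind(match(dt$gene, genes), match(dt$individual, inds))] <- dt$mean_depth
  m
}

#' Apply site- and sample-level quality filters
#'
#' Three passes, in this order: (1) genotypes with GQ at or below `min_gq`
#' are masked to missing; (2) individuals whose call rate (over sites
#' passing the site-quality cut) is at or below `min_indiv_call_rate` are
#' removed; (3) sites whose call rate over the surviving individuals is at
#' or below `min_site_call_rate` are removed. Sites with QUAL at or below
#' `min_qual` (or missing QUAL) are removed first. All thresholds are
#' strict (a value exactly at the threshold fails).
#'
#' @param gm a [genotype_matrix()] with `qual` and `gq` populated.
#' @param min_qual site quality threshold (default 30).
#' @param min_gq genotype quality threshold (default 20).
#' @param min_indiv_call_rate per-individual fraction of called sites
#'   (default 0.50).
#' @param min_site_call_rate per-site fraction of called individuals
#'   (default 0.75).
#' @return filtered `genotype_matrix`.
#' @export
apply_quality_filters <- function(gm, min_qual = 30, min_gq = 20,
                                  min_indiv_call_rate = 0.50,
                                  min_site_call_rate = 0.75) {
  if (is.null(gm$gq)) stop("genotype matrix has no GQ values; cannot filter")
  keep_site <- !is.na(gm$sites$qual) & gm$sites$qual > min_qual
  gm <- gm_subset(gm, sites = keep_site)
  if (n_sites(gm) == 0L) stop("no sites left after site-quality filtering")
  mask <- !is.na(gm$gq) & gm$gq <= min_gq
  gm$dosage[mask] <- NA_integer_
  gm$gq[mask] <- NA_real_
  if (!is.null(gm$gt)) gm$gt[mask] <- "./."
  ind_rate <- colMeans(!is.na(gm$dosage))
  keep_ind <- ind_rate > min_indiv_call_rate
  if (!any(keep_ind)) stop("cohort empty after filtering")
  gm <- gm_subset(gm, individuals = keep_ind)
  site_rate <- rowMeans(!is.na(gm$dosage))
  gm_subset(gm, sites = site_rate > min_site_call_rate)
}

#' Read-depth quality control
#'
#' Removes (a) genes whose mean read-depth across individuals falls below
#' the `low_percentile` empirical quantile (type-7) of all gene mean depths
#' -- capture platforms consistently fail in segmental-duplication-rich
#' regions -- and (b) individuals whose mean depth across genes exceeds the
#' Tukey upper fence (Q3 + `high_fence_k` * IQR), the signature of a biased
#' capture step for that sample.
#'
#' @param dt numeric depth matrix (genes x individuals), see
#'   [read_depth_table()].
#' @param gm a [genotype_matrix()].
#' @param gene_map named character vector mapping site id to gene; sites
#'   without a gene entry are kept.
#' @param low_percentile gene-depth percentile cut (default 0.20).
#' @param high_fence_k Tukey fence multiplier (default 1.5).
#' @return list with elements `gm` (filtered matrix) and `report` (removed
#'   genes/individuals and the thresholds used).
#' @export
depth_qc <- function(dt, gm, gene_map, low_percentile = 0.20,
                     high_fence_k = 1.5) {
  if (length(dt) == 0L || nrow(dt) == 0L) stop("empty depth table")
  gene_means <- rowMeans(dt, na.rm = TRUE)
  depth_cut <- stats::quantile(gene_means, low_percentile, type = 7, names = FALSE)
  removed_genes <- names(gene_means)[gene_means < depth_cut]
  ind_means <- colMeans(dt, na.rm = TRUE)
  q <- stats::quantile(ind_means, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + high_fence_k * (q[2] - q[1])
  removed_inds <- names(ind_means)[ind_means > fence]
  site_gene <- unname(gene_map[gm$sites$id])
  keep_site <- is.na(site_gene) | !(site_gene %in% removed_genes)
  keep_ind <- !(gm$individuals %in% removed_inds)
  if (!any(keep_ind)) stop("cohort empty after depth filtering")
  out <- gm_subset(gm, sites = keep_site, individuals = keep_ind)
  list(
    gm = out,
    report = list(
      removed_genes = removed_genes,
      removed_individuals = intersect(removed_inds, gm$individuals),
      gene_depth_threshold = depth_cut,
      individual_depth_fence = fence
    )
  )
}
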