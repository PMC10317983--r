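#' Construct a genotype matrix
#'
#' The computational substrate for the whole package: a table of biallelic
#' variant sites together with a sites x individuals matrix of diploid
#' alternate-allele dosages (0, 1, 2 or `NA` for a missing call).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, `qual` and `is_indel`. One row per variant site.
#' @param individuals character vector of individual identifiers.
#' @param dosage integer matrix, `nrow(sites)` x `length(individuals)`,
#'   values in `{0, 1, 2, NA}`.
#' @param gq optional numeric matrix of per-genotype qualities, same
#'   dimensions as `dosage`.
#' @param gt optional character matrix of raw VCF GT strings (retained so
#'   phased LD can be computed when the source VCF was phased).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, individuals, dosage, gq = NULL, gt = NULL) {
  stopifnot(is.data.frame(sites))
  required <- c("chrom", "pos", "id", "ref", "alt", "qual", "is_indel")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L) {
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(sites$pos < 1L)) stop("positions must be >= 1 (1-based VCF convention)")
  if (any(!nzchar(sites$ref)) || any(!nzchar(sites$alt))) {
    stop("ref/alt alleles must be non-empty")
  }
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(sites) || ncol(dosage) != length(individuals)) {
    stop("dosage dimensions do not match sites/individuals")
  }
  bad <- !is.na(dosage) & !(dosage %in% c(0L, 1L, 2L))
  if (any(bad)) stop("dosage values must be in {0, 1, 2, NA}")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sites$id, individuals)
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    if (!all(dim(gq) == dim(dosage))) stop("gq dimensions must match dosage")
    dimnames(gq) <- dimnames(dosage)
  }
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    if (!all(dim(gt) == dim(dosage))) stop("gt dimensions must match dosage")
    dimnames(gt) <- dimnames(dosage)
  }
  rownames(sites) <- NULL
  structure(
    list(sites = sites, individuals = individuals, dosage = dosage,
         gq = gq, gt = gt),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d individuals\n",
              n_sites(x), n_individuals(x)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Number of individuals in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer
#' @export
n_individuals <- function(gm) length(gm$individuals)

#' Subset a genotype matrix by sites and/or individuals
#'
#' @param gm a `genotype_matrix`
#' @param sites logical/integer index, or character vector of site ids
#' @param individuals logical/integer index, or character vector of ids
#' @return a `genotype_matrix`
#' @export
gm_subset <- function(gm, sites = NULL, individuals = NULL) {
  si <- seq_len(n_sites(gm))
  ii <- seq_len(n_individuals(gm))
  if (!is.null(sites)) {
    si <- if (is.character(sites)) match(sites, gm$sites$id) else si[sites]
    if (anyNA(si)) stop("unknown site id in subset")
  }
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals)) match(individuals, gm$individuals) else ii[individuals]
    if (anyNA(ii)) stop("unknown individual id in subset")
  }
  genotype_matrix(
    sites = gm$sites[si, , drop = FALSE],
    individuals = gm$individuals[ii],
    dosage = gm$dosage[si, ii, drop = FALSE],
    gq = if (!is.null(gm$gq)) gm$gq[si, ii, drop = FALSE],
    gt = if (!is.null(gm$gt)) gm$gt[si, ii, drop = FALSE]
  )
}
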