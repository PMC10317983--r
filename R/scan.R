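#' Empirical p-values against a neutral null
#'
#' Ranks observed statistics against the neutral-SNP null distribution.
#' The default `mode = "ecdf"` is the one-minus-ECDF procedure,
#' `p = #(null > obs) / N`, which returns exact zeros for observations
#' beyond the null maximum; `mode = "add_one"` uses
#' `p = (1 + #(null >= obs)) / (N + 1)`, the permutation-style correction
#' guaranteeing `p > 0` (ties in the null count against the observation).
#' The ecdf form is the usable default here: with a null smaller than the
#' number of exonic tests, the add-one floor of `1/(N+1)` can never clear
#' a BH threshold of 0.05, so tail outliers would be undetectable by
#' construction.
#'
#' @param observed numeric vector of focal statistics (e.g. exonic PBS).
#' @param null numeric vector: the neutral null (need not be sorted).
#' @param mode `"ecdf"` (default) or `"add_one"`.
#' @return numeric vector of p-values.
#' @export
empirical_pvalues <- function(observed, null, mode = c("ecdf", "add_one")) {
  mode <- match.arg(mode)
  null <- null[!is.na(null)]
  if (length(null) == 0L) stop("empty neutral null")
  if (length(null) < 100L) {
    warning("neutral null has fewer than 100 values; percentiles are unstable")
  }
  ns <- sort(null)
  N <- length(ns)
  n_le <- findInterval(observed, ns)                   # null <= obs
  n_lt <- findInterval(observed, ns, left.open = TRUE) # null <  obs
  if (mode == "ecdf") {
    (N - n_le) / N
  } else {
    (1 + (N - n_lt)) / (N + 1)
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, as in
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Unphased mode (default) computes the squared Pearson correlation of
#' dosages (composite LD); phased mode computes haplotype r-squared from
#' gametic counts and requires the genotype matrix to retain phased GT
#' strings (`a|b`).
#'
#' @param gm a [genotype_matrix()].
#' @param snpA,snpB site ids.
#' @param phased use gametic counts from phased genotypes (default FALSE).
#' @param min_pairs minimum overlapping called individuals (default 5).
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either
#'   SNP is monomorphic among the shared called individuals.
#' @export
ld_r2 <- function(gm, snpA, snpB, phased = FALSE, min_pairs = 5L) {
  ia <- match(snpA, gm$sites$id)
  ib <- match(snpB, gm$sites$id)
  if (is.na(ia) || is.na(ib)) stop("unknown site id")
  if (phased) {
    if (is.null(gm$gt)) stop("phased r2 requires retained GT strings")
    ha <- split_haplotypes(gm$gt[ia, ])
    hb <- split_haplotypes(gm$gt[ib, ])
    ok <- !is.na(ha) & !is.na(hb)
    if (sum(ok) < 2L * min_pairs) stop("too few overlapping called gametes")
    pA <- mean(ha[ok]); pB <- mean(hb[ok]); pAB <- mean(ha[ok] * hb[ok])
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
      warning("monomorphic SNP; r2 undefined")
      return(NA_real_)
    }
    D <- pAB - pA * pB
    return(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  }
  x <- gm$dosage[ia, ]
  y <- gm$dosage[ib, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) stop("too few overlapping called individuals")
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    warning("monomorphic SNP; r2 undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])^2
}

split_haplotypes <- function(gt) {
  parts <- strsplit(gt, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L | !grepl("|", gt, fixed = TRUE)
  h <- suppressWarnings(
    matrix(as.integer(unlist(lapply(parts, function(p) {
      if (length(p) != 2L) c(NA, NA) else p
    }))), nrow = 2L)
  )
  h[, bad] <- NA_integer_
  as.vector(h)
}

#' PBS outlier scan against an empirical neutral null
#'
#' Runs the full per-comparison scan: computes the three pairwise
#' Weir-Cockerham F_ST sets and the focal-branch PBS for both the
#' chemosensory (exonic) and putatively neutral SNPs, drops sites that are
#' invariant across the two focal populations (focal + neighbor pooled; no
#' information about their divergence), builds the neutral null, assigns
#' empirical p-values and BH q-values to the exonic SNPs and flags
#' outliers at `q < q_threshold`. The neighbor may be a vector of
#' population labels, pooled as a single "population".
#'
#' @param gm a [genotype_matrix()].
#' @param partition a `dataset_partition` from [partition_datasets()].
#' @param pops population map data.frame.
#' @param focal focal population label (the branch tested for selection).
#' @param neighbor neighboring population label(s); pooled when length > 1.
#' @param outgroup distant population label.
#' @param gene_map optional named vector site id -> gene for the report.
#' @param q_threshold outlier FDR threshold (default 0.05).
#' @param p_mode passed to [empirical_pvalues()].
#' @param invariant_rule `"union"` (default: drop sites monomorphic in the
#'   pooled focal pair) or `"each"` (drop only sites monomorphic in both
#'   focal populations separately).
#' @return data.frame of class `outlier_table` with one row per exonic
#'   SNP: `chrom`, `pos`, `id`, `gene`, `pbs`, `p_emp`, `q_bh`, `outlier`;
#'   the sorted neutral null and the scan labels are attached as
#'   attributes `null` and `scan`.
#' @export
run_scan <- function(gm, partition, pops, focal, neighbor, outgroup,
                     gene_map = NULL, q_threshold = 0.05,
                     p_mode = c("ecdf", "add_one"),
                     invariant_rule = c("union", "each")) {
  p_mode <- match.arg(p_mode)
  invariant_rule <- match.arg(invariant_rule)
  if (any(focal %in% outgroup) || any(neighbor %in% outgroup) ||
      any(focal %in% neighbor)) {
    stop("focal, neighbor and outgroup populations must be distinct")
  }
  ids <- c(partition$chemosensory, partition$neutral)
  ids <- ids[ids %in% gm$sites$id]
  sub <- gm_subset(gm, sites = ids)
  # drop sites carrying no polymorphism within the focal pair
  pair_inds <- pops$individual[pops$population %in% c(focal, neighbor)]
  variant <- polymorphic_sites(sub, pair_inds, rule = invariant_rule,
                               pops = pops, groups = list(focal, neighbor))
  sub <- gm_subset(sub, sites = variant)

  fst_fn <- wc_fst(sub, pops, focal, neighbor)
  fst_fo <- wc_fst(sub, pops, focal, outgroup)
  fst_no <- wc_fst(sub, pops, neighbor, outgroup)
  pb <- pbs(fst_fn, fst_fo, fst_no)

  is_exonic <- sub$sites$id %in% partition$chemosensory
  null <- sort(pb$pbs[!is_exonic])
  obs <- pb$pbs[is_exonic]
  p <- empirical_pvalues(obs, null, mode = p_mode)
  q <- bh_fdr(p)
  genes <- if (is.null(gene_map)) NA_character_ else
    unname(gene_map[sub$sites$id[is_exonic]])
  out <- data.frame(
    chrom = sub$sites$chrom[is_exonic],
    pos = sub$sites$pos[is_exonic],
    id = sub$sites$id[is_exonic],
    gene = genes,
    pbs = obs, p_emp = p, q_bh = q,
    outlier = q < q_threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "null") <- null
  attr(out, "scan") <- list(focal = focal, neighbor = neighbor,
                            outgroup = outgroup, p_mode = p_mode,
                            q_threshold = q_threshold,
                            n_exonic = sum(is_exonic),
                            n_neutral = length(null))
  class(out) <- c("outlier_table", class(out))
  out
}

polymorphic_sites <- function(gm, pair_inds, rule, pops, groups) {
  poly <- function(inds) {
    d <- gm$dosage[, gm$individuals %in% inds, drop = FALSE]
    n <- 2L * rowSums(!is.na(d))
    ca <- rowSums(d, na.rm = TRUE)
    n > 0 & ca > 0 & ca < n
  }
  if (rule == "union") {
    poly(pair_inds)
  } else {
    res <- lapply(groups, function(g) {
      poly(pops$individual[pops$population %in% g])
    })
    Reduce(`|`, res)
  }
}

#' Cluster outlier SNPs into LD haploblocks
#'
#' Builds a graph over outlier SNPs with an edge between two SNPs on the
#' same chromosome within `max_gap` bp whose dosage r-squared exceeds
#' `r2_min`, and reports connected components with at least two members as
#' haploblocks (single linkage); singletons are listed separately.
#'
#' @param outliers an `outlier_table` (or any data.frame with `chrom`,
#'   `pos`, `id`), typically restricted to `outlier == TRUE` rows first.
#' @param gm a [genotype_matrix()] for the LD computation.
#' @param r2_min LD threshold on linking edges (default 0.65, strict >).
#' @param max_gap maximum pairwise distance in bp (default 1e6).
#' @return list: `blocks` (data.frame `block`, `chrom`, `start`, `end`,
#'   `n_snps`, `min_edge_r2`), `membership` (data.frame `id`, `block`),
#'   `singletons` (character vector of ids).
#' @export
cluster_haploblocks <- function(outliers, gm, r2_min = 0.65, max_gap = 1e6) {
  if ("outlier" %in% names(outliers)) {
    outliers <- outliers[outliers$outlier, , drop = FALSE]
  }
  n <- nrow(outliers)
  if (n == 0L) {
    return(list(blocks = data.frame(), membership = data.frame(),
                singletons = character(0)))
  }
  edges <- list()
  r2s <- numeric(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (outliers$chrom[i] != outliers$chrom[j]) next
        if (abs(outliers$pos[i] - outliers$pos[j]) > max_gap) next
        r2 <- suppressWarnings(ld_r2(gm, outliers$id[i], outliers$id[j]))
        if (!is.na(r2) && r2 > r2_min) {
          edges[[length(edges) + 1L]] <- c(outliers$id[i], outliers$id[j])
          r2s <- c(r2s, r2)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(outliers$id)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    igraph::E(g)$r2 <- r2s
  }
  comp <- igraph::components(g)
  member <- comp$membership
  sizes <- comp$csize
  block_ids <- which(sizes >= 2L)
  blocks <- lapply(seq_along(block_ids), function(k) {
    ids <- names(member)[member == block_ids[k]]
    rows <- match(ids, outliers$id)
    sg <- igraph::induced_subgraph(g, ids)
    data.frame(
      block = k, chrom = outliers$chrom[rows][1],
      start = min(outliers$pos[rows]), end = max(outliers$pos[rows]),
      n_snps = length(ids),
      min_edge_r2 = min(igraph::E(sg)$r2),
      stringsAsFactors = FALSE
    )
  })
  blocks <- if (length(blocks)) do.call(rbind, blocks) else data.frame()
  membership <- do.call(rbind, lapply(seq_along(block_ids), function(k) {
    data.frame(id = names(member)[member == block_ids[k]], block = k,
               stringsAsFactors = FALSE)
  }))
  if (is.null(membership)) membership <- data.frame()
  singles <- names(member)[member %in% which(sizes == 1L)]
  list(blocks = blocks, membership = membership, singletons = singles)
}

#' Write haploblocks as BED plus a membership table
#'
#' BED spans are 0-based half-open.
#'
#' @param hb result of [cluster_haploblocks()].
#' @param bed_path,membership_path output paths.
#' @return invisibly, the BED data.frame.
#' @export
write_haploblocks <- function(hb, bed_path, membership_path) {
  bed <- if (nrow(hb$blocks) > 0L) {
    data.frame(chrom = hb$blocks$chrom, start = hb$blocks$start - 1L,
               end = hb$blocks$end, name = paste0("block", hb$blocks$block))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  }
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(hb$membership, membership_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(bed)
}
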