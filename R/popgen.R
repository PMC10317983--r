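#' Per-site nucleotide diversity
#'
#' For a biallelic site with `c_ref` and `c_alt` called alleles
#' (`n = c_ref + c_alt` chromosomes), the expected pairwise difference is
#' `pi = 2 * c_ref * c_alt / (n * (n - 1))`. Sites with fewer than two
#' called chromosomes are undefined (`NA`) and excluded from means.
#'
#' @param gm a [genotype_matrix()] (biallelic sites).
#' @return data.frame: `chrom`, `pos`, `id`, `n_chr` (called chromosomes),
#'   `pi`.
#' @export
site_pi <- function(gm) {
  called <- !is.na(gm$dosage)
  n <- 2L * rowSums(called)
  c_alt <- rowSums(gm$dosage, na.rm = TRUE)
  c_ref <- n - c_alt
  pi <- ifelse(n >= 2, 2 * c_ref * c_alt / (n * (n - 1)), NA_real_)
  data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos, id = gm$sites$id,
    n_chr = n, pi = pi, stringsAsFactors = FALSE
  )
}

#' Mean per-site nucleotide diversity per population
#'
#' @param gm a [genotype_matrix()].
#' @param pops population map data.frame.
#' @param ids optional site ids to restrict to (e.g. the neutral dataset).
#' @return data.frame: `population`, `n_sites`, `mean_pi`.
#' @export
mean_pi_by_population <- function(gm, pops, ids = NULL) {
  if (!is.null(ids)) gm <- gm_subset(gm, sites = ids)
  res <- lapply(unique(pops$population), function(p) {
    inds <- intersect(pops$individual[pops$population == p], gm$individuals)
    sp <- site_pi(gm_subset(gm, individuals = inds))
    data.frame(population = p, n_sites = sum(!is.na(sp$pi)),
               mean_pi = mean(sp$pi, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Tajima (1989) normalizing constants
#'
#' @param n number of sampled chromosomes (>= 4).
#' @return named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima's D requires at least 4 chromosomes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# D from a window's summed per-site pi and segregating-site count.
tajima_d_value <- function(pi_sum, S, n) {
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tile 1 kb windows over gene spans
#'
#' Builds half-open `[start, start + width)` windows anchored at each
#' gene's first site and extending to cover its last site.
#'
#' @param gm a [genotype_matrix()].
#' @param gene_map named character vector site id -> gene; sites without an
#'   entry are ignored.
#' @param width window width in bp (default 1000).
#' @return data.frame: `chrom`, `start`, `end`, `gene`.
#' @export
make_windows <- function(gm, gene_map, width = 1000L) {
  g <- unname(gene_map[gm$sites$id])
  keep <- !is.na(g)
  s <- gm$sites[keep, , drop = FALSE]
  g <- g[keep]
  parts <- split(seq_len(nrow(s)), g)
  out <- lapply(names(parts), function(gene) {
    rows <- parts[[gene]]
    chrom <- s$chrom[rows][1]
    lo <- min(s$pos[rows])
    hi <- max(s$pos[rows])
    starts <- seq(lo, hi, by = width)
    data.frame(chrom = chrom, start = starts, end = starts + width,
               gene = gene, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Windowed Tajima's D
#'
#' Computes D per window as `(pi_w - S/a1) / sqrt(e1*S + e2*S*(S-1))` with
#' the Tajima (1989) constants evaluated at the window's number of called
#' chromosomes (the modal per-site count; with complete data this is twice
#' the sample size). Windows are half-open `[start, end)` in 1-based
#' positions. Windows with fewer than `min_snps` segregating sites are
#' omitted.
#'
#' @param gm a [genotype_matrix()].
#' @param windows data.frame with `chrom`, `start`, `end` and optionally
#'   `gene` (see [make_windows()]).
#' @param min_snps minimum segregating sites per window (default 3,
#'   i.e. "3 or more"; set 4 for a strict "more than 3" reading).
#' @return data.frame: window columns plus `S`, `pi_sum`, `n`, `D`.
#' @export
tajimas_d <- function(gm, windows, min_snps = 3L) {
  sp <- site_pi(gm)
  c_alt <- rowSums(gm$dosage, na.rm = TRUE)
  segregating <- !is.na(sp$pi) & c_alt > 0 & c_alt < sp$n_chr
  res <- lapply(seq_len(nrow(windows)), function(w) {
    inw <- segregating &
      sp$chrom == windows$chrom[w] &
      sp$pos >= windows$start[w] & sp$pos < windows$end[w]
    S <- sum(inw)
    if (S < min_snps) return(NULL)
    n_modal <- modal_value(sp$n_chr[inw])
    cbind(windows[w, , drop = FALSE],
          data.frame(S = S, pi_sum = sum(sp$pi[inw]), n = n_modal,
                     D = tajima_d_value(sum(sp$pi[inw]), S, n_modal)))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- cbind(windows[0, , drop = FALSE],
                 data.frame(S = integer(), pi_sum = numeric(),
                            n = numeric(), D = numeric()))
  }
  rownames(res) <- NULL
  res
}

#' Chromosome-level Tajima's D for neutral SNPs
#'
#' Pools the given (putatively neutral) sites per chromosome and computes
#' one D per chromosome, the neutral reference distribution the windowed
#' chemosensory values are compared against.
#'
#' @param gm a [genotype_matrix()].
#' @param ids neutral site ids.
#' @param min_snps minimum segregating sites per chromosome (default 3).
#' @return data.frame: `chrom`, `S`, `pi_sum`, `n`, `D`.
#' @export
tajimas_d_neutral <- function(gm, ids, min_snps = 3L) {
  gm <- gm_subset(gm, sites = ids)
  chroms <- unique(gm$sites$chrom)
  windows <- data.frame(chrom = chroms, start = 1L,
                        end = max(gm$sites$pos) + 1L,
                        stringsAsFactors = FALSE)
  out <- tajimas_d(gm, windows, min_snps = min_snps)
  out$start <- NULL
  out$end <- NULL
  out
}

modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Per-site Weir & Cockerham (1984) F_ST for two populations
#'
#' Computes the variance components a (between populations), b (between
#' individuals within populations) and c (within individuals) from the
#' per-site sample sizes, allele frequencies and observed heterozygote
#' frequencies of the two populations, and `theta = a / (a + b + c)`.
#' `defined` is `FALSE` where the denominator is zero (e.g. both
#' populations fixed for the same allele) or where a population has no
#' called genotype. Sample sizes are the per-site called genotype counts,
#' so missing data is handled site by site. The estimator is symmetric in
#' the two populations.
#'
#' @param gm a [genotype_matrix()].
#' @param pops population map data.frame.
#' @param popA,popB population labels, or character vectors of labels to
#'   pool as one "population".
#' @return data.frame: `chrom`, `pos`, `id`, `a`, `b`, `c`, `theta`,
#'   `defined`.
#' @export
wc_fst <- function(gm, pops, popA, popB) {
  colsA <- which(gm$individuals %in% pops$individual[pops$population %in% popA])
  colsB <- which(gm$individuals %in% pops$individual[pops$population %in% popB])
  if (length(colsA) == 0L || length(colsB) == 0L) {
    stop("population absent from genotype matrix / population map")
  }
  comp <- wc_components(gm$dosage[, colsA, drop = FALSE],
                        gm$dosage[, colsB, drop = FALSE])
  data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos, id = gm$sites$id,
    a = comp$a, b = comp$b, c = comp$c,
    theta = comp$theta, defined = comp$defined,
    stringsAsFactors = FALSE
  )
}

# Vectorized two-population W&C variance components over the site rows of
# two dosage matrices.
wc_components <- function(dA, dB) {
  nA <- rowSums(!is.na(dA))
  nB <- rowSums(!is.na(dB))
  pA <- rowSums(dA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(dB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(!is.na(dA) & dA == 1L) / nA
  hB <- rowSums(!is.na(dB) & dB == 1L) / nB
  r <- 2
  nbar <- (nA + nB) / 2
  nc <- (nA + nB) - (nA^2 + nB^2) / (nA + nB)
  pbar <- (nA * pA + nB * pB) / (nA + nB)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (nA + nB)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  usable <- nA > 0 & nB > 0 & nbar > 1 & nc > 0
  defined <- usable & !is.na(denom) & denom != 0
  theta <- ifelse(defined, a / denom, NA_real_)
  list(a = ifelse(usable, a, NA_real_), b = ifelse(usable, b, NA_real_),
       c = ifelse(usable, cc, NA_real_), theta = theta, defined = defined)
}

#' Weighted (multi-site) Weir & Cockerham F_ST
#'
#' The ratio-of-sums estimator `sum(a) / sum(a + b + c)` over all defined
#' sites. Unlike the mean of per-site ratios -- which is downward-biased
#' when the SFS is dominated by rare alleles -- this weighted form is the
#' standard unbiased genome-wide summary and is what parameter-recovery
#' checks against a Balding-Nichols drift parameter should use.
#'
#' @inheritParams wc_fst
#' @return a single numeric theta.
#' @export
wc_fst_global <- function(gm, pops, popA, popB) {
  per_site <- wc_fst(gm, pops, popA, popB)
  ok <- per_site$defined
  sum(per_site$a[ok]) / sum(per_site$a[ok] + per_site$b[ok] + per_site$c[ok])
}

#' Population branch statistic
#'
#' Transforms per-site F_ST triplets into branch lengths
#' `T = -log(1 - F_ST)` and computes the focal branch
#' `PBS = max(0, (T_fn + T_fo - T_no) / 2)` for focal (f), neighbor (n) and
#' outgroup (o). Handling rules: undefined F_ST is set to 0 (shared
#' fixation carries no differentiation signal); negative estimates are set
#' to 0 before the transform; estimates at or above 1 are clamped to
#' `1 - clamp_eps` so the branch length stays finite (outlier ranking only
#' needs order preservation); negative PBS is set to 0.
#'
#' @param fst_fn,fst_fo,fst_no numeric vectors of per-site theta (use `NA`
#'   for undefined), or `wc_fst()` data.frames (matched on `id`).
#' @param clamp_eps clamping distance below 1 (default 1e-9).
#' @return data.frame: `id` (when available), `T_fn`, `T_fo`, `T_no`,
#'   `pbs`.
#' @export
pbs <- function(fst_fn, fst_fo, fst_no, clamp_eps = 1e-9) {
  pull <- function(x) {
    if (is.data.frame(x)) {
      list(id = x$id, theta = ifelse(x$defined, x$theta, NA_real_))
    } else {
      list(id = NULL, theta = as.numeric(x))
    }
  }
  fn <- pull(fst_fn); fo <- pull(fst_fo); no <- pull(fst_no)
  if (length(fn$theta) != length(fo$theta) ||
      length(fn$theta) != length(no$theta)) {
    stop("mismatched site lists for the three F_ST inputs")
  }
  if (!is.null(fn$id) && !is.null(fo$id) &&
      (!identical(fn$id, fo$id) || !identical(fn$id, no$id))) {
    stop("mismatched site ids for the three F_ST inputs")
  }
  branch <- function(theta) {
    theta[is.na(theta)] <- 0
    theta[theta < 0] <- 0
    theta[theta >= 1] <- 1 - clamp_eps
    -log(1 - theta)
  }
  T_fn <- branch(fn$theta); T_fo <- branch(fo$theta); T_no <- branch(no$theta)
  out <- data.frame(T_fn = T_fn, T_fo = T_fo, T_no = T_no,
                    pbs = pmax(0, (T_fn + T_fo - T_no) / 2))
  if (!is.null(fn$id)) out <- cbind(data.frame(id = fn$id,
                                               stringsAsFactors = FALSE), out)
  out
}
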