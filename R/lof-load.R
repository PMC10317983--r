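#' Per-individual homozygous LOF gene load
#'
#' Under the recessive model, a gene counts as lost for an individual only
#' when at least one of its catalogued LOF sites is homozygous for the
#' broken allele: dosage 2 where the alternate allele breaks the gene, and
#' dosage 0 where the *reference* is the broken (pseudogenized) state and
#' the alternate allele is the rescue. Heterozygotes are not considered to
#' have lost gene function. Each gene is counted at most once per
#' individual. The offset denominator `n_called_lof_genes` counts genes
#' with at least one called genotype among their catalogued sites.
#'
#' @param gm a [genotype_matrix()].
#' @param catalog a `lof_catalog` data.frame from [classify_lof()]; only
#'   rows with `is_lof` or `is_rescue` participate.
#' @param pops optional population map data.frame (joined onto the result).
#' @param gene_map optional named character vector site id -> gene;
#'   defaults to the catalog's `gene` column.
#' @return data.frame with one row per individual: `individual`,
#'   `n_hom_lof_genes`, `n_called_lof_genes`, plus `population`,
#'   `continent`, `subsistence` when `pops` is given.
#' @export
hom_lof_load <- function(gm, catalog, pops = NULL, gene_map = NULL) {
  cat_sites <- catalog[catalog$is_lof | catalog$is_rescue, , drop = FALSE]
  idx <- match(cat_sites$variant_id, gm$sites$id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " catalogued site(s) absent from genotype matrix; skipped")
    cat_sites <- cat_sites[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  genes <- if (is.null(gene_map)) cat_sites$gene else unname(gene_map[cat_sites$variant_id])
  d <- gm$dosage[idx, , drop = FALSE]
  broken_dose <- ifelse(cat_sites$lof_allele == "ref", 0L, 2L)
  hom <- !is.na(d) & d == broken_dose
  called <- !is.na(d)
  gene_f <- factor(genes)
  # per gene x individual: any broken-hom site / any called site
  hom_gene <- rowsum(hom + 0L, gene_f) > 0L
  called_gene <- rowsum(called + 0L, gene_f) > 0L
  out <- data.frame(
    individual = gm$individuals,
    n_hom_lof_genes = colSums(hom_gene),
    n_called_lof_genes = colSums(called_gene),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(pops)) {
    m <- match(out$individual, pops$individual)
    if (anyNA(m)) stop("individual(s) missing from population map")
    out$population <- pops$population[m]
    out$continent <- pops$continent[m]
    out$subsistence <- pops$subsistence[m]
  }
  out
}

#' One-tailed Wilcoxon rank-sum contrast
#'
#' Thin wrapper over [stats::wilcox.test()] reporting the rank-sum
#' statistic W (rank sum of `x` minus n_x(n_x+1)/2), with exact enumeration
#' for small untied samples and the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param x,y numeric vectors (e.g. per-individual homozygous LOF loads of
#'   two groups).
#' @param alternative `"greater"` or `"less"` (direction of `x` vs `y`).
#' @param label optional test name carried into the result.
#' @return list of class `contrast_result`: `test`, `n_x`, `n_y`, `W`,
#'   `p`, `alternative`.
#' @export
wilcoxon_one_tailed <- function(x, y, alternative = c("greater", "less"),
                                label = "wilcoxon") {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical in both groups; p is the 0.5 boundary")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, correct = TRUE)
  )
  structure(
    list(test = label, n_x = length(x), n_y = length(y),
         W = unname(wt$statistic), p = wt$p.value, alternative = alternative),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s: W = %g, one-tailed p = %.4g (alternative: x %s y; n = %d vs %d)\n",
              x$test, x$W, x$p,
              if (x$alternative == "greater") ">" else "<", x$n_x, x$n_y))
  invisible(x)
}

#' Poisson mixed model for homozygous LOF load
#'
#' Fits `n_hom_lof_genes ~ subsistence + (1 | continent/population)` with a
#' Poisson response and `log(n_called_lof_genes)` as offset, so the fixed
#' effect estimates the log rate ratio of lost genes per called gene
#' between subsistence classes while population-within-continent structure
#' is absorbed by the random intercepts. Individuals with a zero offset
#' (no called LOF genes) are dropped with a warning. The reference level is
#' `forager`, so the coefficient is the agriculturalist log rate ratio.
#'
#' @param table output of [hom_lof_load()] including the population-map
#'   columns.
#' @return list: `coef` (subsistence log rate ratio), `se`, `p` (Wald),
#'   `ranef_var` (named random-intercept variances), `n`, `fit` (the
#'   underlying `glmerMod`).
#' @export
poisson_load_model <- function(table) {
  required <- c("n_hom_lof_genes", "n_called_lof_genes", "population",
                "continent", "subsistence")
  if (!all(required %in% names(table))) {
    stop("load table needs columns: ", paste(required, collapse = ", "))
  }
  zero <- table$n_called_lof_genes == 0
  if (any(zero)) {
    warning(sum(zero), " individual(s) with no called LOF genes dropped")
    table <- table[!zero, , drop = FALSE]
  }
  table$subsistence <- factor(table$subsistence,
                              levels = c("forager", "agriculturalist"))
  fit <- lme4::glmer(
    n_hom_lof_genes ~ subsistence + (1 | continent / population),
    offset = log(table$n_called_lof_genes),
    family = stats::poisson(), data = table,
    control = lme4::glmerControl(calc.derivs = FALSE)
  )
  cf <- summary(fit)$coefficients
  row <- "subsistenceagriculturalist"
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    coef = cf[row, "Estimate"],
    se = cf[row, "Std. Error"],
    p = cf[row, "Pr(>|z|)"],
    ranef_var = stats::setNames(vc$vcov, vc$grp),
    n = nrow(table),
    fit = fit
  )
}
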