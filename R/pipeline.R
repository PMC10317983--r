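#' Build a run configuration
#'
#' Collects the input paths and every analysis threshold, with the
#' defaults used throughout: site QUAL > 30, GQ > 20, individual call rate
#' > 0.50, site call rate > 0.75, gene-depth percentile 0.20, 1 kb
#' Tajima's D windows with >= 3 segregating SNPs, neutral-set LD pruning
#' at r^2 0.5, outlier FDR 0.05, haploblock linking at r^2 > 0.65 within
#' 1 Mb.
#'
#' @param vcf,annotations,popmap input paths (required at run time).
#' @param depth optional gene x individual depth TSV.
#' @param curated_lof,curated_rescue optional variant-id list files.
#' @param roster optional scan roster data.frame with columns `focal`,
#'   `neighbor` (comma-separated for pooled), `outgroup`, `derived`;
#'   `NULL` builds the six-scans-per-region roster from the population
#'   map.
#' @param out_dir optional output directory for the report and tables.
#' @param seed RNG seed recorded in the report (the analysis itself is
#'   deterministic).
#' @param min_qual,min_gq,indiv_rate,site_rate,depth_percentile,window,min_snps,neutral_prune_r2,q_threshold,haploblock_r2,haploblock_gap,p_mode
#'   analysis thresholds; see module documentation.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, annotations = NULL, popmap = NULL,
                       depth = NULL, curated_lof = NULL,
                       curated_rescue = NULL, roster = NULL, out_dir = NULL,
                       seed = 1L, min_qual = 30, min_gq = 20,
                       indiv_rate = 0.5, site_rate = 0.75,
                       depth_percentile = 0.20, window = 1000L,
                       min_snps = 3L, neutral_prune_r2 = 0.5,
                       q_threshold = 0.05, haploblock_r2 = 0.65,
                       haploblock_gap = 1e6, p_mode = "ecdf") {
  structure(list(
    vcf = vcf, annotations = annotations, popmap = popmap, depth = depth,
    curated_lof = curated_lof, curated_rescue = curated_rescue,
    roster = roster, out_dir = out_dir, seed = as.integer(seed),
    min_qual = min_qual, min_gq = min_gq, indiv_rate = indiv_rate,
    site_rate = site_rate, depth_percentile = depth_percentile,
    window = as.integer(window), min_snps = as.integer(min_snps),
    neutral_prune_r2 = neutral_prune_r2, q_threshold = q_threshold,
    haploblock_r2 = haploblock_r2, haploblock_gap = haploblock_gap,
    p_mode = p_mode
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg a [run_config()].
#' @param pops optional population map against which the scan roster is
#'   checked.
#' @return character vector of problems (empty when valid). Never mutates
#'   `cfg`.
#' @export
validate_config <- function(cfg, pops = NULL) {
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  in01 <- function(x) is.numeric(x) && x >= 0 && x <= 1
  chk(in01(cfg$indiv_rate), "indiv_rate must be in [0, 1]")
  chk(in01(cfg$site_rate), "site_rate must be in [0, 1]")
  chk(in01(cfg$depth_percentile), "depth_percentile must be in [0, 1]")
  chk(in01(cfg$neutral_prune_r2), "neutral_prune_r2 must be in [0, 1]")
  chk(in01(cfg$q_threshold), "q_threshold must be in [0, 1]")
  chk(in01(cfg$haploblock_r2), "haploblock_r2 must be in [0, 1]")
  chk(is.numeric(cfg$min_qual) && cfg$min_qual >= 0, "min_qual must be >= 0")
  chk(is.numeric(cfg$min_gq) && cfg$min_gq >= 0, "min_gq must be >= 0")
  chk(cfg$window >= 1, "window must be >= 1 bp")
  chk(cfg$min_snps >= 1, "min_snps must be >= 1")
  chk(cfg$haploblock_gap >= 1, "haploblock_gap must be >= 1 bp")
  chk(cfg$p_mode %in% c("add_one", "ecdf"), "p_mode must be add_one or ecdf")
  if (!is.null(cfg$roster) && !is.null(pops)) {
    named <- unique(unlist(c(
      strsplit(cfg$roster$focal, ","), strsplit(cfg$roster$neighbor, ","),
      strsplit(cfg$roster$outgroup, ",")
    )))
    unknown <- setdiff(trimws(named), unique(pops$population))
    if (length(unknown) > 0L) {
      problems <- c(problems, paste0("roster names unknown population(s): ",
                                     paste(unknown, collapse = ", ")))
    }
  }
  problems
}

#' Default scan roster: six analyses per region
#'
#' For each continent, three scans with the agriculturalist branch as
#' focal (against each forager neighbor and against the two pooled) using
#' a forager from the other continent as outgroup, and three with the
#' forager branch(es) as focal against the agriculturalist neighbor using
#' the other continent's agriculturalist as outgroup.
#'
#' @param pops population map data.frame.
#' @return data.frame: `region`, `derived`, `focal`, `neighbor`,
#'   `outgroup` (pooled groups comma-separated).
#' @export
default_scan_roster <- function(pops) {
  info <- unique(pops[c("population", "continent", "subsistence")])
  rows <- list()
  for (cont in unique(info$continent)) {
    agr <- sort(info$population[info$continent == cont &
                                  info$subsistence == "agriculturalist"])
    hg <- sort(info$population[info$continent == cont &
                                 info$subsistence == "forager"])
    other_hg <- sort(info$population[info$continent != cont &
                                       info$subsistence == "forager"])[1]
    other_agr <- sort(info$population[info$continent != cont &
                                        info$subsistence == "agriculturalist"])[1]
    if (length(agr) == 0L || length(hg) == 0L) next
    a <- agr[1]
    neighbor_sets <- c(as.list(hg), list(hg))
    for (nb in neighbor_sets) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = cont, derived = "agriculturalist", focal = a,
        neighbor = paste(nb, collapse = ","), outgroup = other_hg,
        stringsAsFactors = FALSE
      )
    }
    focal_sets <- c(as.list(hg), list(hg))
    for (fc in focal_sets) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = cont, derived = "forager",
        focal = paste(fc, collapse = ","), neighbor = a,
        outgroup = other_agr, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read inputs; variant/sample quality filtering;
#' read-depth QC (when a depth table is supplied); annotation resolution
#' and LOF classification; chemosensory/neutral dataset partition;
#' per-individual homozygous LOF loads with Wilcoxon contrasts and the
#' Poisson mixed model; per-population nucleotide diversity; windowed
#' Tajima's D over chemosensory genes versus chromosome-level neutral
#' values, with one-tailed Wilcoxon contrasts per population; the PBS
#' outlier scan for every roster entry; haploblock clustering of each
#' scan's outliers. Any stage failure aborts with a stage-labeled error.
#' The run is deterministic given the config and inputs; the report
#' carries a config hash and can be hashed whole with [report_hash()].
#'
#' @param cfg a [run_config()] with at least `vcf`, `annotations` and
#'   `popmap` set.
#' @return list of class `run_report`.
#' @export
run_all <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  for (f in c("vcf", "annotations", "popmap")) {
    if (is.null(cfg[[f]])) stop("config is missing required input: ", f)
    if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  }
  report <- list(package_version = as.character(utils::packageVersion("neighborscan")),
                 config_hash = digest::digest(unclass(cfg)),
                 stages = list())

  inputs <- stage("read_inputs", {
    list(gm = read_vcf(cfg$vcf),
         ann = read_annotation_table(cfg$annotations),
         pops = read_population_map(cfg$popmap),
         depth = if (!is.null(cfg$depth)) read_depth_table(cfg$depth),
         curated_lof = if (!is.null(cfg$curated_lof))
           readLines(cfg$curated_lof) else character(0),
         curated_rescue = if (!is.null(cfg$curated_rescue))
           readLines(cfg$curated_rescue) else character(0))
  })
  report$stages$read_inputs <- list(
    n_sites = n_sites(inputs$gm), n_individuals = n_individuals(inputs$gm),
    n_annotation_rows = nrow(inputs$ann)
  )

  gm <- stage("quality_filters", {
    apply_quality_filters(inputs$gm, min_qual = cfg$min_qual,
                          min_gq = cfg$min_gq,
                          min_indiv_call_rate = cfg$indiv_rate,
                          min_site_call_rate = cfg$site_rate)
  })
  report$stages$quality_filters <- list(
    n_sites = n_sites(gm), n_individuals = n_individuals(gm)
  )

  ann <- stage("annotation", resolve_annotation(inputs$ann))
  gene_map <- stats::setNames(ann$gene, ann$variant_id)

  if (!is.null(inputs$depth)) {
    dq <- stage("depth_qc", depth_qc(inputs$depth, gm, gene_map,
                                     low_percentile = cfg$depth_percentile))
    gm <- dq$gm
    report$stages$depth_qc <- list(
      removed_genes = length(dq$report$removed_genes),
      removed_individuals = length(dq$report$removed_individuals),
      n_sites = n_sites(gm), n_individuals = n_individuals(gm)
    )
  }
  pops <- inputs$pops[inputs$pops$individual %in% gm$individuals, , drop = FALSE]

  catalog <- stage("lof_classification", {
    classify_lof(ann, inputs$curated_lof, inputs$curated_rescue)
  })
  partition <- stage("partition", {
    partition_datasets(ann, gm, r2_prune = cfg$neutral_prune_r2)
  })
  report$stages$partition <- list(
    n_chemosensory = length(partition$chemosensory),
    n_neutral = length(partition$neutral),
    n_lof = sum(catalog$is_lof), n_rescue = sum(catalog$is_rescue)
  )

  loads <- stage("lof_load", hom_lof_load(gm, catalog, pops = pops))
  contrasts <- stage("lof_contrasts", lof_contrasts(loads))
  model <- stage("lof_model", {
    if (length(unique(loads$population)) >= 4L) {
      m <- poisson_load_model(loads)
      m$fit <- NULL
      m
    }
  })
  report$stages$lof_load <- list(
    mean_load_by_continent = tapply(loads$n_hom_lof_genes, loads$continent, mean),
    contrasts = lapply(contrasts, unclass),
    poisson_model = model
  )

  pi_tab <- stage("nucleotide_diversity", {
    mean_pi_by_population(gm, pops, ids = partition$neutral)
  })
  report$stages$nucleotide_diversity <- pi_tab

  td <- stage("tajimas_d", {
    tajima_contrasts(gm, pops, partition, gene_map,
                     window = cfg$window, min_snps = cfg$min_snps)
  })
  report$stages$tajimas_d <- td

  roster <- if (is.null(cfg$roster)) default_scan_roster(pops) else cfg$roster
  problems <- validate_config(cfg, pops)
  if (length(problems) > 0L) {
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  }
  scans <- stage("pbs_scans", {
    lapply(seq_len(nrow(roster)), function(k) {
      ot <- run_scan(
        gm, partition, pops,
        focal = trimws(strsplit(roster$focal[k], ",")[[1]]),
        neighbor = trimws(strsplit(roster$neighbor[k], ",")[[1]]),
        outgroup = roster$outgroup[k],
        gene_map = gene_map, q_threshold = cfg$q_threshold,
        p_mode = cfg$p_mode
      )
      hb <- cluster_haploblocks(ot, gm, r2_min = cfg$haploblock_r2,
                                max_gap = cfg$haploblock_gap)
      list(roster = roster[k, , drop = FALSE], outliers = ot, haploblocks = hb)
    })
  })
  report$stages$pbs_scans <- lapply(scans, function(s) {
    list(
      focal = s$roster$focal, neighbor = s$roster$neighbor,
      outgroup = s$roster$outgroup, derived = s$roster$derived,
      n_exonic = attr(s$outliers, "scan")$n_exonic,
      n_neutral = attr(s$outliers, "scan")$n_neutral,
      n_outliers = sum(s$outliers$outlier),
      outlier_genes = sort(unique(s$outliers$gene[s$outliers$outlier])),
      n_haploblocks = nrow(s$haploblocks$blocks),
      n_singletons = length(s$haploblocks$singletons)
    )
  })
  report$seed <- cfg$seed
  class(report) <- "run_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_report(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (k in seq_along(scans)) {
      utils::write.table(
        as.data.frame(scans[[k]]$outliers),
        file.path(cfg$out_dir, sprintf("scan_%02d.tsv", k)),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  attr(report, "scans") <- scans
  attr(report, "loads") <- loads
  report
}

# wilcoxon contrasts the load analysis reports: per continent
# agriculturalist vs forager (predicted greater under relaxation), plus
# the between-continent contrast
lof_contrasts <- function(loads) {
  out <- list()
  for (cont in unique(loads$continent)) {
    sub <- loads[loads$continent == cont, , drop = FALSE]
    agr <- sub$n_hom_lof_genes[sub$subsistence == "agriculturalist"]
    hg <- sub$n_hom_lof_genes[sub$subsistence == "forager"]
    if (length(agr) > 0L && length(hg) > 0L) {
      out[[paste0(cont, "_agr_vs_forager")]] <-
        wilcoxon_one_tailed(agr, hg, "greater",
                            label = paste0(cont, ": agriculturalist > forager"))
    }
  }
  conts <- unique(loads$continent)
  if (length(conts) == 2L) {
    x <- loads$n_hom_lof_genes[loads$continent == conts[1]]
    y <- loads$n_hom_lof_genes[loads$continent == conts[2]]
    if (mean(x) < mean(y)) { tmp <- x; x <- y; y <- tmp
      conts <- rev(conts) }
    out[["between_continents"]] <-
      wilcoxon_one_tailed(x, y, "greater",
                          label = paste0(conts[1], " > ", conts[2]))
  }
  out
}

# per population: windowed D over chemosensory genes vs chromosome-level
# neutral D, one-tailed Wilcoxon (chemosensory < neutral under stronger
# purifying selection)
tajima_contrasts <- function(gm, pops, partition, gene_map, window = 1000L,
                             min_snps = 3L) {
  chem_gm <- gm_subset(gm, sites = intersect(partition$chemosensory,
                                             gm$sites$id))
  windows <- make_windows(chem_gm, gene_map, width = window)
  out <- list()
  for (p in unique(pops$population)) {
    inds <- pops$individual[pops$population == p]
    sub_c <- gm_subset(chem_gm, individuals = intersect(inds, gm$individuals))
    dc <- tajimas_d(sub_c, windows, min_snps = min_snps)
    sub_all <- gm_subset(gm, individuals = intersect(inds, gm$individuals))
    dn <- tajimas_d_neutral(sub_all, intersect(partition$neutral, gm$sites$id),
                            min_snps = min_snps)
    ct <- if (nrow(dc) > 0L && nrow(dn) > 0L) {
      unclass(wilcoxon_one_tailed(dc$D, dn$D, "less",
                                  label = paste0(p, ": chemosensory < neutral")))
    }
    out[[p]] <- list(
      n_windows = nrow(dc), mean_window_D = mean(dc$D),
      n_neutral_chroms = nrow(dn), mean_neutral_D = mean(dn$D),
      contrast = ct
    )
  }
  out
}

unclass_report <- function(report) {
  r <- unclass(report)
  rapply(r, function(x) x, how = "replace")
}

#' Hash a run report
#'
#' Two runs with identical config and inputs produce identical hashes.
#'
#' @param report a `run_report`.
#' @return character md5 digest.
#' @export
report_hash <- function(report) {
  attr(report, "scans") <- NULL
  attr(report, "loads") <- NULL
  digest::digest(unclass(report))
}
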