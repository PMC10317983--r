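test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 77, n_chemosensory_sites = 200L,
                    n_neutral_sites = 100L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gm$dosage, b$gm$dosage)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotations, b$annotations)
  c2 <- simulate_cohort(sim_config(seed = 78, n_chemosensory_sites = 200L,
                                   n_neutral_sites = 100L))
  expect_false(identical(a$gm$dosage, c2$gm$dosage))
})

test_that("zero drift collapses population structure", {
  pops <- data.frame(label = c("P1", "P2"), continent = c("C", "C"),
                     subsistence = c("forager", "agriculturalist"),
                     n = c(30L, 30L))
  cfg <- sim_config(seed = 80, populations = pops, F_cont = 0, F_pop = 0,
                    n_chemosensory_sites = 800L, n_neutral_sites = 10L,
                    n_selected = 0L, lof_fraction = 0, missing_rate = 0)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$freq_P1, sim$truth$freq_P2)
  theta <- wc_fst_global(sim$gm, sim$popmap, "P1", "P2")
  expect_lt(abs(theta), 0.01)
})

test_that("emitted artifacts are mutually consistent", {
  sim <- simulate_cohort(sim_config(seed = 81, n_chemosensory_sites = 150L,
                                    n_neutral_sites = 80L))
  sim <- sync_indel_flags(sim)
  expect_setequal(sim$gm$sites$id, sim$annotations$variant_id)
  expect_setequal(sim$gm$sites$id, sim$truth$id)
  expect_equal(sim$gm$individuals, sim$popmap$individual)
  expect_true(all(sim$curated_rescue %in% sim$truth$id[sim$truth$is_rescue]))
  # indel flags agree between annotation table and genotype matrix
  fs <- sim$annotations$variant_id[sim$annotations$consequence ==
                                     "frameshift_variant"]
  expect_true(all(sim$gm$sites$is_indel[match(fs, sim$gm$sites$id)]))

  dir <- tempfile("cohort")
  write_cohort(sim, dir)
  back <- read_vcf(file.path(dir, "cohort.vcf"))
  expect_equal(unname(back$dosage), unname(sim$gm$dosage))
  pm <- read_population_map(file.path(dir, "popmap.tsv"))
  expect_equal(pm, sim$popmap)
  ann <- read_annotation_table(file.path(dir, "annotations.tsv"))
  expect_equal(nrow(ann), nrow(sim$annotations))
})

test_that("expected homozygous load: analytic cases and cohort agreement", {
  # a fully rescued gene contributes nothing; q = 0.5 contributes 0.25
  truth <- data.frame(
    id = c("a", "b"), is_lof = c(FALSE, TRUE), is_rescue = c(TRUE, FALSE),
    lof_allele = c("ref", "alt"), freq_P = c(1.0, 0.5),
    stringsAsFactors = FALSE
  )
  expect_equal(unname(expected_hom_load(truth, "P")), 0.25)

  # full cohort: observed mean load within 3 SE of the truth expectation
  sim <- simulate_cohort(sim_config(seed = 83, missing_rate = 0))
  catalog <- classify_lof(resolve_annotation(sim$annotations),
                          curated_rescue = sim$curated_rescue)
  loads <- hom_lof_load(sim$gm, catalog, pops = sim$popmap)
  exp_load <- expected_hom_load(sim$truth, unique(sim$popmap$population))
  for (p in unique(sim$popmap$population)) {
    obs <- loads$n_hom_lof_genes[loads$population == p]
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - exp_load[[p]]), 3 * se)
  }
})

test_that("LOF injection respects the configured design", {
  cfg <- sim_config(seed = 85)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  n_lof_sites <- sum(tr$is_lof | tr$is_rescue)
  expect_equal(n_lof_sites, round(cfg$lof_fraction * cfg$n_chemosensory_sites))
  expect_equal(sum(tr$is_rescue), round(cfg$rescue_fraction * n_lof_sites))
  # one LOF site per gene, never on neutral sites
  expect_false(any(tr$dataset == "neutral" & (tr$is_lof | tr$is_rescue)))
  expect_false(anyDuplicated(tr$gene[tr$is_lof | tr$is_rescue]) > 0)
  # the continental load targets order the realized expectations
  exp_load <- expected_hom_load(tr, cfg$populations$label)
  ph <- mean(exp_load[cfg$populations$label[cfg$populations$continent ==
                                              "Philippines"]])
  ug <- mean(exp_load[cfg$populations$label[cfg$populations$continent ==
                                              "Uganda"]])
  expect_gt(ph, ug)
})

test_that("selected sites out-differentiate matched neutral sites", {
  sim <- simulate_cohort(sim_config(seed = 87, n_chemosensory_sites = 800L,
                                    n_neutral_sites = 400L, n_selected = 15L))
  ann <- resolve_annotation(sim$annotations)
  part <- partition_datasets(ann, sim$gm)
  ot <- run_scan(sim$gm, part, sim$popmap, "BaKiga", c("Sua", "Twa"), "Agta")
  sel <- sim$truth$id[sim$truth$selected]
  pbs_sel <- ot$pbs[ot$id %in% sel]
  null <- attr(ot, "null")
  expect_gt(mean(pbs_sel), mean(null) + 2 * stats::sd(null))
})

test_that("expansion-skewed cohorts push windowed D below neutral cohorts", {
  pops1 <- data.frame(label = "P1", continent = "C", subsistence = "forager",
                      n = 40L)
  d_of <- function(mode, seed) {
    cfg <- sim_config(seed = seed, populations = pops1, F_cont = 0, F_pop = 0,
                      n_chemosensory_sites = 2000L, n_neutral_sites = 10L,
                      n_selected = 0L, lof_fraction = 0, missing_rate = 0,
                      sfs_mode = mode)
    sim <- simulate_cohort(cfg)
    ann <- resolve_annotation(sim$annotations)
    w <- make_windows(sim$gm, stats::setNames(ann$gene, ann$variant_id))
    tajimas_d(sim$gm, w, min_snps = 3)$D
  }
  dn <- d_of("neutral", 91)
  dx <- d_of("expansion", 91)
  expect_gt(length(dn), 200)
  # sign test over windows: expansion skew makes negative D dominate
  expect_gt(mean(dx < 0), 0.5)
  expect_lt(mean(dx), mean(dn))
})

test_that("fixture suite is deterministic and paper-shaped", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  make_fixture_suite(d1)
  make_fixture_suite(d2)
  for (f in c("filter_fixture.vcf", "wc_fixture.vcf", "ld_fixture.vcf",
              file.path("scan_cohort", "cohort.vcf"),
              file.path("scan_cohort", "truth.tsv"))) {
    a <- readLines(file.path(d1, f)); b <- readLines(file.path(d2, f))
    a <- a[!startsWith(a, "##fileDate")]
    b <- b[!startsWith(b, "##fileDate")]
    expect_identical(a, b)
  }
  pm <- read_population_map(file.path(d1, "scan_cohort", "popmap.tsv"))
  sizes <- table(pm$population)
  expect_equal(unname(sizes[c("Agta", "BaKiga", "Mamanwa", "Manobo",
                              "Sua", "Twa")]),
               as.table(c(21L, 26L, 18L, 24L, 21L, 23L)),
               ignore_attr = TRUE)
  # filter fixture carries exactly the planned number of failing genotypes
  fx <- read_vcf(file.path(d1, "filter_fixture.vcf"))
  expect_equal(sum(fx$gq <= 20), 9L)
  expect_equal(sum(fx$sites$qual <= 30), 1L)
})
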