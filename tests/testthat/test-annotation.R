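test_that("annotation resolution follows the four priority rules", {
  # rule 1-2: exonic beats upstream
  cand <- rbind(
    h_ann(consequence = "upstream_gene_variant", gene = "geneA"),
    h_ann(consequence = "missense_variant", gene = "geneB")
  )
  expect_equal(resolve_annotation(cand)$gene, "geneB")

  # rule 2: exonic beats UTR/intron
  cand <- rbind(
    h_ann(consequence = "5_prime_UTR_variant", transcript_id = "T1"),
    h_ann(consequence = "synonymous_variant", transcript_id = "T2")
  )
  expect_equal(resolve_annotation(cand)$transcript_id, "T2")

  # rule 3: sensory gene beats RNA gene
  cand <- rbind(
    h_ann(gene = "LINC1", gene_family = "other", is_rna_gene = TRUE,
          consequence = "intron_variant"),
    h_ann(gene = "OR5A1", gene_family = "OR", consequence = "intron_variant")
  )
  expect_equal(resolve_annotation(cand)$gene, "OR5A1")

  # rule 4: longest transcript
  cand <- rbind(
    h_ann(transcript_id = "Tshort", transcript_length = 900),
    h_ann(transcript_id = "Tlong", transcript_length = 1400)
  )
  expect_equal(resolve_annotation(cand)$transcript_id, "Tlong")

  # single candidate: identity
  one <- h_ann()
  expect_equal(resolve_annotation(one), one)
  expect_error(resolve_annotation(one[0, ]), "no candidate")
})

test_that("annotation resolution is invariant to candidate order", {
  set.seed(1)
  cand <- rbind(
    h_ann(consequence = "upstream_gene_variant", transcript_id = "T1"),
    h_ann(consequence = "intron_variant", transcript_id = "T2",
          transcript_length = 500),
    h_ann(consequence = "missense_variant", transcript_id = "T3",
          transcript_length = 800),
    h_ann(consequence = "missense_variant", transcript_id = "T4",
          transcript_length = 1200),
    h_ann(consequence = "missense_variant", transcript_id = "T5",
          transcript_length = 1200)  # length tie -> lexicographic id
  )
  ref <- resolve_annotation(cand)
  for (k in 1:10) {
    perm <- cand[sample.int(nrow(cand)), , drop = FALSE]
    expect_equal(resolve_annotation(perm)$transcript_id, ref$transcript_id)
  }
  expect_equal(ref$transcript_id, "T4")
})

test_that("LOF classification handles consequences, curation, and polarity", {
  ann <- rbind(
    h_ann("v1", consequence = "missense_variant"),
    h_ann("v2", consequence = "stop_gained"),
    h_ann("v3", consequence = "frameshift_variant"),
    h_ann("v4", consequence = "synonymous_variant"),
    h_ann("v5", consequence = "missense_variant")
  )
  cat <- classify_lof(ann, curated_lof = "v4", curated_rescue = "v5")
  expect_false(cat$is_lof[cat$variant_id == "v1"])
  expect_true(cat$is_lof[cat$variant_id == "v2"])
  expect_equal(cat$lof_allele[cat$variant_id == "v2"], "alt")
  expect_true(cat$is_lof[cat$variant_id == "v3"])
  expect_equal(cat$source[cat$variant_id == "v4"], "curated")
  expect_true(cat$is_rescue[cat$variant_id == "v5"])
  expect_equal(cat$lof_allele[cat$variant_id == "v5"], "ref")
  # rescue and LOF are mutually exclusive; every LOF has one polarity
  expect_false(any(cat$is_lof & cat$is_rescue))
  expect_true(all(!is.na(cat$lof_allele[cat$is_lof | cat$is_rescue])))
  expect_error(classify_lof(ann, curated_lof = "v5", curated_rescue = "v5"),
               "both curated")
})

test_that("dataset partition separates chemosensory and neutral SNPs", {
  d <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L), 6), 6, 8, byrow = TRUE)
  d[5, ] <- d[4, ]  # two intergenic SNPs in perfect LD
  gm <- h_gm(d, ids = paste0("v", 1:6),
             is_indel = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  ann <- rbind(
    h_ann("v1", gene = "TAS2R5", gene_family = "TAS2R",
          consequence = "synonymous_variant"),
    h_ann("v2", gene = "OR9X1P", gene_family = "OR", gene_type = "pseudogene",
          consequence = "stop_gained", is_ancient_pseudogene = TRUE),
    h_ann("v3", gene = "ZNF1", gene_family = "other",
          consequence = "regulatory_region_variant"),
    h_ann("v4", gene = "NEU1", gene_family = "intergenic",
          gene_type = "pseudogene", consequence = "intergenic_variant"),
    h_ann("v5", gene = "NEU1", gene_family = "intergenic",
          gene_type = "pseudogene", consequence = "intergenic_variant"),
    h_ann("v6", gene = "OR2A5", gene_family = "OR",
          consequence = "frameshift_variant")
  )
  part <- partition_datasets(ann, gm)
  expect_equal(part$chemosensory, "v1")             # functional TAS2R exon
  expect_true("v2" %in% part$neutral)               # ancient OR pseudogene
  expect_false("v3" %in% c(part$chemosensory, part$neutral))  # regulatory
  # LD pruning keeps exactly one of the perfect-LD intergenic pair
  expect_equal(sum(c("v4", "v5") %in% part$neutral), 1L)
  expect_false("v6" %in% part$chemosensory)         # indel excluded
  expect_length(intersect(part$chemosensory, part$neutral), 0L)
})

test_that("partition reproduces the generator's designed labels exactly", {
  sim <- simulate_cohort(sim_config(seed = 31, n_chemosensory_sites = 300L,
                                    n_neutral_sites = 150L))
  sim <- sync_indel_flags(sim)
  ann <- resolve_annotation(sim$annotations)
  part <- partition_datasets(ann, sim$gm, ld_pruner = function(gm, ids, r2) ids)
  truth <- sim$truth
  want_chem <- truth$id[truth$dataset == "chemosensory" & !truth$is_indel]
  want_neu <- truth$id[truth$dataset == "neutral"]
  expect_setequal(part$chemosensory, want_chem)
  expect_setequal(part$neutral, want_neu)
})

test_that("greedy LD pruning drops linked sites at the threshold", {
  d <- rbind(c(0, 0, 1, 1, 2, 2, 1, 0),
             c(0, 0, 1, 1, 2, 2, 1, 0),
             c(2, 2, 1, 1, 0, 0, 1, 2))
  gm <- h_gm(d, ids = c("a", "b", "c"))
  kept <- ld_prune(gm, c("a", "b", "c"), r2_max = 0.5)
  expect_true("a" %in% kept)
  expect_false("b" %in% kept)   # r2 = 1 with a
  expect_false("c" %in% kept)   # perfect negative correlation, r2 = 1
})
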