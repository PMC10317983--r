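test_that("empirical p-values equal brute-force rank counting", {
  set.seed(12)
  null <- round(runif(20, 0, 2), 2)
  null[3] <- null[7]   # force a tie in the null
  obs <- c(-1, null[7], 0.5, 2.5, max(null))
  p_ecdf <- suppressWarnings(empirical_pvalues(obs, null, mode = "ecdf"))
  p_add <- suppressWarnings(empirical_pvalues(obs, null, mode = "add_one"))
  for (k in seq_along(obs)) {
    expect_equal(p_ecdf[k], sum(null > obs[k]) / 20)
    expect_equal(p_add[k], (1 + sum(null >= obs[k])) / 21)
  }
  # below the null minimum: ecdf p = 1; add-one bound above the maximum
  expect_equal(p_ecdf[1], 1)
  p99 <- suppressWarnings(empirical_pvalues(10, runif(99), mode = "add_one"))
  expect_equal(p99, 1 / 100)
  expect_error(empirical_pvalues(1, numeric(0)), "empty")
})

test_that("small nulls warn about unstable percentiles", {
  expect_warning(empirical_pvalues(0.5, runif(50)), "fewer than 100")
})

test_that("BH q-values match hand computation and are monotone", {
  expect_equal(bh_fdr(0.03), 0.03)                       # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))                # m*p(i)/i with step-up
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "must be in")
})

test_that("neutral p-values against their own null are super-uniform (add_one)", {
  set.seed(33)
  null <- rexp(400)
  p <- empirical_pvalues(null, null, mode = "add_one")
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(p <= alpha), alpha + 1 / 401 + 1e-12)
  }
})

test_that("unphased LD r2 equals the squared dosage correlation", {
  ld <- neighborscan:::ld_fixture_gm()
  expect_equal(ld_r2(ld, "s1", "s1"), 1)
  expect_equal(ld_r2(ld, "s1", "s2"), 1)   # engineered perfect LD
  d <- ld$dosage
  expect_equal(ld_r2(ld, "s1", "s3"),
               stats::cor(d["s1", ], d["s3", ])^2)
  mono <- h_gm(rbind(rep(1L, 8), rep(0L, 8)), ids = c("a", "b"))
  expect_warning(r <- ld_r2(mono, "a", "b"), "monomorphic")
  expect_true(is.na(r))
  expect_error(ld_r2(ld, "s1", "nope"), "unknown site")
})

test_that("dosage independence by construction gives r2 near zero", {
  set.seed(41)
  d <- rbind(rbinom(500, 2, 0.4), rbinom(500, 2, 0.4))
  gm <- h_gm(d, ids = c("u", "v"))
  expect_lt(ld_r2(gm, "u", "v"), 0.05)
})

test_that("phased r2 comes from gametic counts", {
  gt <- rbind(c("0|1", "1|1", "0|0", "1|0", "0|0", "1|1"),
              c("0|1", "1|1", "0|0", "1|0", "0|0", "1|1"),
              c("0|0", "1|0", "0|1", "1|1", "0|0", "0|1"))
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      id = c("h1", "h2", "h3"), ref = "A", alt = "G",
                      qual = 100, is_indel = FALSE, stringsAsFactors = FALSE)
  dos <- matrix(c(1L, 2L, 0L, 1L, 0L, 2L), 3, 6, byrow = TRUE)
  dos[2, ] <- dos[1, ]
  dos[3, ] <- c(0L, 1L, 1L, 2L, 0L, 1L)
  gm <- genotype_matrix(sites, paste0("P", 1:6), dos, gt = gt)
  expect_equal(ld_r2(gm, "h1", "h2", phased = TRUE, min_pairs = 3), 1)
  # oracle: gamete table of h1 vs h3
  h1 <- c(0, 1, 1, 1, 0, 0, 1, 0, 0, 0, 1, 1)
  h3 <- c(0, 0, 1, 0, 0, 1, 1, 1, 0, 0, 0, 1)
  D <- mean(h1 * h3) - mean(h1) * mean(h3)
  want <- D^2 / (mean(h1) * (1 - mean(h1)) * mean(h3) * (1 - mean(h3)))
  expect_equal(ld_r2(gm, "h1", "h3", phased = TRUE, min_pairs = 3), want)
})

test_that("haploblock clustering follows distance and LD rules", {
  # three engineered haplotype groups on one chromosome
  base <- c(0, 0, 1, 1, 2, 2, 1, 0, 2, 1)
  far <- c(2, 1, 0, 2, 0, 1, 0, 2, 0, 1)
  d <- rbind(base, base, far, c(0, 1, 0, 1, 2, 0, 1, 2, 0, 1))
  gm <- h_gm(d, ids = paste0("o", 1:4),
             pos = c(1000L, 11000L, 2500000L, 21000L))
  out <- data.frame(chrom = "chr1", pos = gm$sites$pos, id = gm$sites$id,
                    stringsAsFactors = FALSE)

  hb <- cluster_haploblocks(out, gm)
  # o1-o2 linked (r2 = 1, 10 kb); o3 is 2.5 Mb away despite r2 with nothing;
  # o4 nearby but unlinked
  expect_equal(nrow(hb$blocks), 1L)
  expect_setequal(hb$membership$id, c("o1", "o2"))
  expect_setequal(hb$singletons, c("o3", "o4"))

  # distance rule: two perfectly linked SNPs 2 Mb apart stay separate
  gm2 <- h_gm(rbind(base, base), ids = c("a", "b"),
              pos = c(1000L, 2001000L))
  hb2 <- cluster_haploblocks(
    data.frame(chrom = "chr1", pos = gm2$sites$pos, id = gm2$sites$id), gm2)
  expect_equal(nrow(hb2$blocks), 0L)
  expect_setequal(hb2$singletons, c("a", "b"))
})

test_that("single linkage chains A-B-C into one block (graph oracle)", {
  set.seed(51)
  hapA <- rbinom(40, 1, 0.5)
  flip <- function(h, k) { i <- sample.int(40, k); h[i] <- 1 - h[i]; h }
  hapB <- flip(hapA, 3)
  hapC <- flip(hapB, 3)
  tod <- function(h) h[c(TRUE, FALSE)] + h[c(FALSE, TRUE)]
  d <- rbind(tod(hapA), tod(hapB), tod(hapC))
  gm <- h_gm(d, ids = c("A", "B", "C"), pos = c(1000L, 2000L, 3000L))
  r_ab <- ld_r2(gm, "A", "B"); r_bc <- ld_r2(gm, "B", "C")
  r_ac <- ld_r2(gm, "A", "C")
  expect_gt(r_ab, 0.65); expect_gt(r_bc, 0.65)
  out <- data.frame(chrom = "chr1", pos = gm$sites$pos, id = gm$sites$id)
  hb <- cluster_haploblocks(out, gm)
  # oracle: connected components of the thresholded adjacency by hand
  adj <- matrix(c(r_ab > 0.65, r_bc > 0.65, r_ac > 0.65), 1)
  expected_one_block <- (r_ab > 0.65 && r_bc > 0.65)
  expect_true(expected_one_block)
  expect_equal(hb$blocks$n_snps, 3L)
  expect_equal(hb$blocks$start, 1000L)
  expect_equal(hb$blocks$end, 3000L)
})

test_that("run_scan output is invariant to input site order", {
  sim <- simulate_cohort(sim_config(seed = 61, n_chemosensory_sites = 300L,
                                    n_neutral_sites = 150L, n_selected = 5L))
  ann <- resolve_annotation(sim$annotations)
  part <- partition_datasets(ann, sim$gm)
  ot1 <- suppressWarnings(run_scan(sim$gm, part, sim$popmap, "BaKiga",
                                   c("Sua", "Twa"), "Agta"))
  perm <- sample(n_sites(sim$gm))
  gm2 <- gm_subset(sim$gm, sites = perm)
  ot2 <- suppressWarnings(run_scan(gm2, part, sim$popmap, "BaKiga",
                                   c("Sua", "Twa"), "Agta"))
  o1 <- ot1[order(ot1$id), c("id", "pbs", "p_emp", "q_bh", "outlier")]
  o2 <- ot2[order(ot2$id), c("id", "pbs", "p_emp", "q_bh", "outlier")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("run_scan validates its population arguments", {
  sim <- simulate_cohort(sim_config(seed = 62, n_chemosensory_sites = 120L,
                                    n_neutral_sites = 60L, n_selected = 0L))
  ann <- resolve_annotation(sim$annotations)
  part <- partition_datasets(ann, sim$gm)
  expect_error(run_scan(sim$gm, part, sim$popmap, "BaKiga", "Sua", "BaKiga"),
               "distinct")
  # fewer than 100 neutral null values still runs, with a warning
  expect_warning(run_scan(sim$gm, part, sim$popmap, "BaKiga", "Sua", "Agta"),
                 "fewer than 100|unstable")
})
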