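---
title: "Methods: subsistence-related selection scans on chemosensory genes"
author: "neighborscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subsistence-related selection scans on chemosensory genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Transitions from rainforest foraging to agriculture change what people
eat and how they find food, and have been hypothesized to relax natural
selection on the chemosensory gene repertoire — the olfactory receptor
(*OR*) and taste receptor (*TAS1R*, *TAS2R*) families. `neighborscan`
implements a geographic-neighbors analysis of that hypothesis: within
each of two regions, neighboring forager and agriculturalist populations
are compared so that subsistence contrasts are not confounded with
continental ancestry. Two complementary analyses are provided:

1. **Relaxation of constraint** — loss-of-function (LOF) repertoire
   profiling under a recessive model, with Wilcoxon contrasts and a
   Poisson mixed model; and windowed Tajima's D over chemosensory genes
   compared against chromosome-level neutral estimates.
2. **Local adaptation** — a per-SNP population branch statistic (PBS)
   scan ranked against an empirical neutral null, with FDR control and
   linkage-disequilibrium haploblock clustering of outliers.

Because the motivating human cohort is access-restricted, the package
ships a first-class synthetic-cohort generator with the same design
(six populations, two continents, two subsistence classes) so every
stage is testable end to end.

## Input filtering

Variants arrive as a multi-sample VCF with site QUAL and per-genotype
GQ. Filters are applied with **strict** inequalities, matching the
printed thresholds of the original protocol: site QUAL > 30, genotype
GQ > 20, per-individual call rate > 50%, per-site call rate > 75%. The
pass order is: mask low-GQ genotypes, then drop low-call-rate
individuals, then drop low-call-rate sites. The order is a design
choice — individual call rates should reflect genotype masking, and
site call rates should be evaluated on the final cohort — and the
filters are idempotent under it.

Read-depth QC mirrors capture-panel practice for segmental-duplication-
rich gene families: genes whose mean depth falls below the 20th
percentile (empirical type-7 quantile) of all gene mean depths are
removed wholesale, and individuals whose mean depth exceeds the Tukey
upper fence (Q3 + 1.5·IQR) are excluded as capture-biased samples. The
fence is a package choice: the source protocol excluded
"consistently high depth" individuals without stating a rule, and the
Tukey fence is the standard parameter-free outlier cut; it is
configurable.

## Annotation, LOF classification, and dataset partition

Multiple transcript isoforms yield multiple candidate annotations per
variant. One is chosen deterministically by four ordered rules: coding
region over upstream/downstream, exonic over intronic/UTR, sensory gene
families over RNA genes, then the longest transcript. Remaining ties
break lexicographically on transcript id so the result is order-
invariant.

A variant is classified LOF (broken allele = alternate) when its
consequence is stop gained, start lost, stop lost or frameshift, or
when it appears on a curated LOF list. *Rescue* variants are the
special case where the reference genome carries the pseudogenized
state: the reference allele is the broken one and the alternate allele
restores function. Curated rescue status overrides consequence-based
classification, since rescue variants frequently carry stop-related
consequence terms for exactly that reason. Under the recessive model an
individual loses a gene only when homozygous for the broken allele —
dosage 2 for alternate-broken sites, dosage 0 for rescue-polarity
sites. Compound heterozygotes are deliberately not counted: only
homozygous LOF genotypes enter the load, the conservative reading of
the recessive model.

SNPs are partitioned into a **chemosensory** dataset (exons and UTRs of
functional — protein-coding or segregating-pseudogene — OR/TAS1R/TAS2R
genes) and a **putatively neutral** dataset (targeted intergenic SNPs,
LD-pruned at r² ≥ 0.5, plus SNPs annotated intergenic,
upstream/downstream, pseudogene-intronic, or in ancient pseudogenes
shared with chimpanzee). Indels participate in LOF classification but
never enter the SNP datasets. Regulatory-region SNPs are excluded from
both sets: their neutrality is not defensible a priori, and the
original dataset definitions do not mention them.

## Load statistics

The per-individual load is the number of genes with at least one
homozygous-broken catalogued site; the companion denominator counts
genes with any called genotype at a catalogued site. One-tailed
Wilcoxon rank-sum tests contrast agriculturalists against foragers
within each continent (predicted greater under relaxation) and the two
continents against each other. The Poisson mixed model is

```
n_hom_lof_genes ~ subsistence + (1 | continent/population),
offset = log(n_called_lof_genes)
```

so the fixed effect is the log rate ratio of lost genes per called
gene. The offset is gene-level, matching the response's units. With
only a handful of population clusters the random-intercept variances
are weakly identified; the Wald test on the fixed effect is accurate
when between-population heterogeneity is small, and parameter-recovery
tests are run under that regime (a known limitation of few-cluster
mixed models, not of this implementation).

## Diversity and Tajima's D

Per-site nucleotide diversity is `2·c_ref·c_alt / (n·(n−1))` over
called chromosomes. Tajima's D is computed in 1 kb half-open windows
anchored at each gene's first site, with the 1989 normalizing constants
evaluated at the window's modal called-chromosome count; windows with
fewer than `min_snps` segregating sites are omitted. The source
protocol states both "more than 3 SNPs" and "3 or more SNPs"; the
default is `min_snps = 3` (the figure-caption reading), configurable.
The neutral reference is one pooled D per chromosome over the neutral
SNPs, and each population's chemosensory window values are compared to
its neutral chromosome values with a one-tailed Wilcoxon test
(chemosensory lower under stronger purifying selection).

## F_ST, PBS, and the empirical null

Per-site two-population F_ST uses the Weir & Cockerham (1984) variance
components a, b, c computed from per-site called sample sizes, allele
frequencies and observed heterozygote frequencies; θ = a/(a+b+c),
undefined when the denominator is zero (e.g. shared fixation). The
estimator is symmetric and handles missing data site by site. For
multi-site summaries (e.g. checking a simulated drift parameter) the
weighted ratio-of-sums Σa/Σ(a+b+c) is provided: the mean of per-site
ratios is substantially downward-biased when rare variants dominate the
SFS, so parameter recovery must use the weighted form.

PBS for focal f, neighbor n, outgroup o is

```
T = −log(1 − F_ST),   PBS = max(0, (T_fn + T_fo − T_no) / 2)
```

with these handling rules: undefined θ → 0; θ < 0 → 0 before the
transform; θ ≥ 1 clamped to 1 − 1e−9 so branches stay finite (outlier
ranking only needs order preservation); sites invariant across the
pooled focal pair are omitted (a flag switches to requiring
monomorphism in each focal population separately). Scans are run six
ways per region: the agriculturalist branch against each forager
neighbor and the pooled pair (outgroup: a forager from the other
continent), and the forager branch(es) against the agriculturalist
neighbor (outgroup: the other continent's agriculturalist).

Exonic SNPs are ranked against the neutral-SNP PBS distribution. The
default converts the rank to `p = #(null > obs)/N` (one minus the
empirical CDF), then applies Benjamini–Hochberg and flags outliers at
q < 0.05. An `add_one` mode, `p = (1 + #(null ≥ obs))/(N + 1)`, is also
exposed; it is the standard permutation-style correction and is
super-uniform by construction, but its p floor of 1/(N+1) means that
with a neutral null smaller than the number of exonic tests no SNP can
ever reach q < 0.05 — the scan would be blind by construction at
realistic dataset shapes (null ≈ 0.7–1.5k, tests ≈ 2–4k). The ECDF
convention, which assigns exact zeros beyond the null maximum, is
therefore the default; in effect an outlier is an exonic SNP whose PBS
exceeds everything observed at neutral sites. Both tie conventions
(strict > for ecdf, ≥ for add-one) are stated in the function
documentation because percentile conventions differ between tools.

Outlier SNPs on the same chromosome within 1 Mb and with dosage
r² > 0.65 are linked, and haploblocks are the connected components with
at least two members (single linkage — the published clustering demands
LD "to each other" along a chain, not a complete graph); singletons are
reported separately.

## The synthetic cohort generator

The generator emulates the study design, not human genomes: six
populations (Agta 21, Mamanwa 18, Manobo 24, BaKiga 26, Sua 21,
Twa 23), 4913 chemosensory exonic SNPs across 378 OR + 2 TAS1R +
24 TAS2R genes, and 1704 putatively neutral intergenic SNPs across 51
regions. Ancestral alternate-allele frequencies follow a standard
neutral SFS (count i out of 2N with probability ∝ 1/i), optionally with
extra singleton mass to mimic post-expansion skew. Differentiation is
hierarchical Balding–Nichols drift: continent frequencies are Beta
draws around the ancestral frequency with parameter F_cont (default
0.10, the scale of African/Asian differentiation), population
frequencies Beta draws around their continent with F_pop (default
0.03, the scale of neighboring forager/agriculturalist pairs).
Genotypes are Hardy–Weinberg binomial draws. Two numerical choices
matter:

- With **zero drift** the cohort *is* the population, so the configured
  sample SFS is realized exactly by placing i alternate alleles on the
  2N chromosomes. Binomial resampling around p = i/2N would silently
  drop about a third of singletons (P(1 → 0) ≈ 0.37 at 2N = 100) and
  bias neutral Tajima's D to ≈ +0.2.
- **Selected sites** (default 20, focal-branch shift Δ = +0.5 on
  BaKiga) are injected only at sites whose ancestral frequency admits
  the full shift without clipping at 1. Their stated role is to be
  strongly differentiated; a site already near fixation that clips to a
  +0.1 effective shift would not be.

LOF sites (5% of chemosensory sites, one per gene; 6% of them with
rescue polarity, ≈ 15 sites at full scale; 30% simulated as frameshift
indels) get broken-allele frequencies scaled per continent so the
expected homozygous load (Σ q² under one-site-per-gene Hardy–Weinberg)
matches continent-level targets of 11.78 (Philippines) and 8.22
(Uganda) lost genes per individual — the observed scale of
out-of-Africa LOF load differences. At reduced site counts the 0.98
frequency cap makes the realized expectation undershoot the target;
cohort tests therefore compare observed loads to the truth-table
expectation, which is exact by construction.

What the generator does **not** emulate: linkage disequilibrium between
sites (sites are drawn independently, so haploblock tests build their
own LD by copying haplotypes with flips), realistic gene coordinates,
sequence-level indels, archaic introgression, and coalescent noise
(Balding–Nichols drift has closed-form F_ST expectations, which is what
makes parameter recovery assertable). A green pipeline test therefore
establishes correctness of the statistics and plumbing under the
assumed frequency model, not demographic realism.

## Determinism and reproducibility

All simulation is seed-deterministic; the analysis itself contains no
randomness. `run_all()` records per-stage record counts, test
statistics, per-scan outlier counts and a config hash, and two runs on
identical inputs hash identically (`report_hash()`).

## Known limitations

- The empirical-null scan detects only focal-branch shifts that beat
  the most extreme of N neutral PBS values; with N in the hundreds a
  single large neutral drift draw can mask genuine signals. This is a
  property of the published procedure, faithfully reproduced.
- Mixed-model inference with two continents and six populations leans
  on Wald approximations; random-effect variances are reported but
  should not be over-interpreted.
- Phased haplotype r² is available only when the input VCF carries
  phased genotypes; the default composite (dosage) r² is what the
  haploblock clustering uses.
- The population-level printed results of the motivating study (mean
  loads, per-scan outlier counts) depend on its restricted-access
  cohort and are not reproduced here; the package reproduces the
  *procedures* and validates them on synthetic cohorts with known
  truth.
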