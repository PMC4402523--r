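# basecomp

Individual-strand DNA base composition as a genome phenotype: parity
metrics for assembled sequences, per-individual base composition across
polymorphic and mutation sites, genome scans of that composition as a
quantitative trait, and gene-set enrichment around the association signals
— with a bundled strand-symmetric, AT-biased mutation/bottleneck simulator
so the whole pipeline runs end to end with recorded ground truth.

## Who this is for

Population geneticists and genome scientists interested in Chargaff's
second parity rule (PR2: within one strand, [A] ≈ [T] and [G] ≈ [C]) and in
compositional divergence between populations separated by a bottleneck
(out-of-Africa migration, domestication), where derived groups show an
A&T-increase / G&C-decrease across polymorphic sites.

## The statistic at the core

For a diploid individual genotyped at biallelic SNPs, each non-missing site
contributes its two alleles; the **base-composition phenotype** is

    [X] = (number of alleles equal to base X) / (2 × number of sites),   X ∈ {A, C, G, T}

(equivalently: reference homozygotes weight the reference base 1,
heterozygotes 0.5, alternative homozygotes 0). Aggregated over tens of
thousands to millions of sites, [A] is a precise per-individual trait: PR2
makes [A] + [C] ≈ 0.5, population structure splits it, and it can be
scanned genome-wide like any quantitative phenotype — here with a linear
model (thresholded by an allele-switching simulation) and an EMMAX-style
mixed model with PC2–PC6 covariates and a VanRaden kinship random effect
(thresholded by Bonferroni α/m). Genes near trait-associated SNPs (TASs)
are then tested for annotation-term and DNA-repair-gene enrichment with
one-sided Fisher tests on gene-level 2×2 tables.

## Worked example

```r
library(basecomp)
library(dplyr)

# simulate 50 + 50 diploids at ~6600 SNPs, bottleneck-diverged,
# AT-biased mutation, with a planted bias-modifier locus
sim <- simulate_populations(pop_sim_config(
  n_basal = 50, n_derived = 50, n_snps = 6000,
  modifier = list(delta = 0.6, frac_sites = 0.1, freq = 0.3), seed = 1))

ph <- base_phenotype(sim$variants, sim$genotypes)
head(ph, 3)
#>   sample    frac_a frac_c frac_g frac_t n_sites_used
#> 1 basal_001  0.250  0.248  0.248  0.254         6601
#> 2 basal_002  0.251  0.247  0.248  0.254         6601
#> 3 basal_003  0.261  0.240  0.247  0.252         6601
```

Per individual, `frac_a ≈ frac_t` and `frac_c ≈ frac_g` — PR2 across
polymorphic sites. The derived group sits higher in [A]:

```r
glance(group_separation(ph, sim$groups))
#>   basal derived estimate statistic    df     p_value
#> 1 basal derived  0.00391      5.66  84.9 0.000000197
```

`estimate` is the derived-minus-basal difference in mean [A]: positive, the
A&T-increase. The mixed-model scan recovers the planted modifier locus as
the top association:

```r
pca  <- genotype_pca(sim$genotypes, k = 6)
kin  <- compute_kinship(sim$genotypes)
scan <- mixed_scan(ph, sim$genotypes, kin,
                   covariates = pc_covariates(pca, 2:6),
                   variants = sim$variants)
head(arrange(tidy(scan), p_value), 1)
#>   id        chrom   pos        F   p_value model
#> 1 snp_04710 chr4  12106072  17.8  0.0000559 mixed
sim$truth$modifier$id
#> [1] "snp_04710"
```

Downstream, `flag_tas()` + `build_windows()` + `term_enrichment()` /
`repair_gene_enrichment()` carry TASs into window-based gene-set tests, and
`run_pipeline(demo_config())` chains every stage (simulate → filter →
phenotype → structure → scan → threshold → regions → enrichment) into TSV
outputs with an MD5 manifest.

## Layout

- `R/` — implementation (sequence composition, VCF filtering + HWE,
  phenotype, kinship/PCA, scans + thresholds, enrichment, simulator,
  pipeline).
- `tests/testthat/` — unit, property and end-to-end acceptance tests; all
  fixtures are generated in code.
- `vignettes/base-composition-methods.Rmd` — models, assumptions, defaults
  and their rationale, numerical choices, limitations.
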