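---
title: "Individual-strand base composition as a genome phenotype: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-strand base composition as a genome phenotype: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basecomp)
library(dplyr)
```

## The science in brief

Chargaff's second parity rule (PR2) says that within a *single* strand of
double-stranded DNA, the fraction of A approximately equals that of T, and G
approximately equals C. `basecomp` studies this parity — and departures from
compositional equilibrium — at four levels:

1. **Assembled sequences** (`count_bases()`, `aggregate_composition()`,
   `parity_metrics()`): base counts, AT/GC skews and a PR2-deviation summary
   at the sequence, chromosome and genome level.
2. **Polymorphic sites** (`load_variants()`, `base_phenotype()`): for each
   diploid individual, the fraction of its SNP alleles that are A, C, G and
   T. A reference homozygote contributes the reference base with weight 1, a
   heterozygote with weight 0.5, an alternative homozygote with weight 0.
   This per-individual vector ([A], [C], [G], [T]) is the *genome
   phenotype*: an aggregate over very many sites, hence a precise trait that
   separates populations that diverged through a bottleneck (the derived
   group shows an A&T increase under AT-biased mutation).
3. **Mutation sites** (`mutation_site_composition()`): in
   mutation-accumulation lines, the composition of the mutant (alt) bases
   contrasted with the ancestral (ref) bases at the same sites.
4. **Genome scans and annotation** (`linear_scan()`, `mixed_scan()`,
   `term_enrichment()`, ...): treating [A] as a quantitative trait, scanning
   SNPs for association with it, and asking which gene classes cluster near
   the trait-associated SNPs (TASs).

## The PR2-deviation statistic

No standard scalar exists for "how far a strand is from PR2"; the package
reports

$$\mathrm{pr2} = |[A] - [T]| + |[G] - [C]|,$$

which is zero exactly at parity, together with the conventional skews
$(A-T)/(A+T)$ and $(C-G)/(C+G)$. This statistic is a package choice, made
because it is interpretable (total absolute fraction misallocated between
complementary pairs) and because both skews are recoverable alongside it.
Bases other than A/C/G/T (N and all IUPAC ambiguity codes) are excluded from
both numerator and denominator; lowercase (soft-masked) bases are counted as
their uppercase base because masking is annotation, not composition.

## Site filtering

`load_variants()` applies filters in a fixed order: biallelic SNPs only
(multiallelic records are dropped, not decomposed, because the phenotype's
allele-pair bookkeeping assumes exactly two bases per site); sex and
mitochondrial chromosomes out (the analyses are autosomal); call rate
$\ge$ 0.8; then minor allele frequency $\ge$ 0.05 computed on the overall
retained sample, not per group. Hardy–Weinberg equilibrium is tested per
group (1-df chi-square by default, an exact conditional test for small
counts) and *reported*, not used for removal unless `hwe_alpha` is set —
deviation rates are a data-quality readout here, not a default filter.
Missing genotypes are excluded from that sample's phenotype denominator, so
the four fractions always sum to 1 regardless of missingness patterns.

## The mixed-model scan

Population structure makes naive association tests on [A] uninterpretable:
the trait is itself a linear readout of the genotype matrix, so its first
principal component is nearly collinear with it. The package follows the
established two-stage ("P3D"/EMMAX-style) approach:

* `compute_kinship()` builds a VanRaden genomic relationship matrix
  (centred cross-product scaled by $2\sum p_j(1-p_j)$; missing dosages
  mean-imputed per variant for this computation only). An allele-sharing
  similarity is available as a cross-check.
* `mixed_scan()` estimates the polygenic variance ratio once, on the null
  model trait ~ covariates + kinship random effect, by restricted maximum
  likelihood over the kinship eigenbasis, then tests every SNP by
  generalised least squares under that fitted covariance. With an identity
  kinship the scan reduces *exactly* to the covariate-adjusted linear scan,
  which the tests assert. Exact per-SNP variance re-estimation is not
  implemented; at the sample sizes involved the two-stage approximation is
  the field's standard and the package's oracle tests bound its error.
* Covariates default to PCs 2–6. PC1 is excluded deliberately: it *is* the
  trait, to within correlation ~1, so conditioning on it would remove the
  signal under study.

Significance comes from two routes, mirroring the two scans' needs:
`bonferroni_threshold()` ($\alpha/m$) for the mixed model, and
`allele_switch_threshold()` for the linear model, where p-values are not
trustworthy at scale. The switching simulation starts from the pseudo-SNP
perfectly fixed between the two groups — by construction the strongest
association pattern the structure can produce — and randomly flips the
genotype in an increasing proportion of samples (1000 randomisations per
proportion by default), tracing how the F statistic decays. The mapping
from these distributions to a single threshold is not canonical, so the
package exposes it as configuration (default: the 97.5th percentile at the
largest requested proportion) and always returns the full distribution
table; any other rule can be applied downstream.

## Enrichment around trait-associated SNPs

Windows of a configurable size series (0.5–2 Mb; 1.5 Mb is the
representative size) are centred on each TAS, merged where they overlap (so
clustered TASs do not multiply-count genes), and genes are tested for
membership by any-overlap — full containment would silently exclude long
genes, though it is available. Over-representation of an annotation term
among in-window genes is tested one-sided by Fisher's exact test on the
gene-level 2×2 table; the reported odds ratio is the sample cross-product
$ad/bc$ (0 or infinity at degenerate margins, flagged). Raw p-values are
reported, with a Benjamini–Hochberg column alongside; no ontology-graph
propagation is performed — terms are used as annotated. Tagging rules are
deliberately per-SNP and unmerged: a gene counts as tagged when hit by at
least 2 TASs, a DNA-repair gene when hit by at least 3. Fixed 1-Mb tiles
with at least 5 TASs give the coarse region view. Coordinates are 0-based
half-open internally; VCF's 1-based positions are converted at the
boundary.

## The simulator: what it emulates, and what it does not

`simulate_populations()` generates the study design all of the above is
exercised on: a basal group and a derived group separated by a bottleneck,
genotyped at biallelic SNPs whose ref/alt bases arise from a
**strand-symmetric mutation spectrum** — twelve substitution rates
constrained by $r(X \to Y) = r(\bar{X} \to \bar{Y})$, six free parameters,
built by `mutation_spectrum()`. Mutations are drawn by the explicit
two-strand mechanism (`draw_mutation()`): a template strand is chosen
uniformly, the substitution is drawn on it, and the equivalent
reference-strand change is reported. Strand symmetry makes this
distributionally equal to drawing on the reference strand directly, which
is precisely the no-strand-bias explanation of PR2; simulating the
mechanism rather than its consequence keeps that explanation testable.

Key modelling choices, each with its rationale:

* **Frequency-level Wright–Fisher.** Drift is simulated on allele
  frequencies (binomial resampling for `bottleneck_gen` generations at size
  `bottleneck_n`), not on individuals; no recombination, linkage or
  selection. This is sufficient for phenotype-level patterns and runs in
  seconds at the default scale.
* **Default scale: 100 + 100 diploids, 50,000 SNPs.** The per-individual
  [A] shift between groups is a mean-level effect of order $10^{-3}$, while
  site-ensemble noise shrinks as $1/\sqrt{m}$; at this scale the direction
  of the shift is stable across seeds, and the scale matches what the
  phenotype's precision argument requires anyway.
* **Default bottleneck `bottleneck_n = 30`, `bottleneck_gen = 45`**
  ($F_{ST} \approx 0.5$): a strong founder event of the magnitude
  domestication comparisons show, chosen so the basal/derived separation is
  visually and statistically unambiguous at desk scale.
* **Uniform ancestral composition.** Because variant sites are conditioned
  on a mutation having occurred, per-base mutability cancels out of the
  draw; a composition away from the spectrum's equilibrium would then
  create a compositional flux even for a symmetric spectrum (a symmetric
  spectrum pushes an AT-rich genome GC-ward). The uniform composition is
  the equilibrium of every base-symmetric spectrum, making `at_bias = 1`
  exactly flux-free — the correct null — and `at_bias > 1` a genuinely
  AT-ward flux. Skewed compositions remain available as a parameter.
* **Ancestral frequencies** follow a discretised neutral SFS (density
  $\propto 1/x$), on [0.05, 0.95] for shared variants and [0.02, 0.5] for
  private ones; every emitted variant is conditioned (by redrawing) on
  empirically passing the default call-rate/MAF filters, so simulated
  VCFs survive `load_variants()` intact. It is this conditioning, applied
  after bottleneck drift, that lifts surviving derived-private allele
  frequencies and — combined with the AT excess of alt alleles under a
  biased spectrum — produces the derived-group A&T increase without any
  group-specific spectrum.
* **The bias-modifier locus** is a generative invention: the hypothesis
  that DNA-repair polymorphism drives base-composition variation needs a
  causal locus to recover. Modifier-sensitive sites carry the AT-gaining
  flux (G/C reference, A/T alternative drawn from the spectrum with its AT
  bias amplified by $1+\delta$), and each individual's alt-allele frequency
  at them scales with $1 + \delta \cdot \mathrm{dosage}/2$. Carriers
  therefore accumulate extra A/T alleles in proportion to their modifier
  dosage, making the locus recoverable by the mixed scan (rank-1 in the
  package's parameter-recovery tests at the default $\delta = 0.6$). The
  modifier frequency is equal in both groups so that recovery tests the
  within-population machinery, not the group split.
* **`at_bias = 2` default.** The real magnitude of AT-biased mutation is
  not pinned down per dataset; 2 is a test-scale placeholder that makes the
  directional patterns unambiguous, not an empirical estimate.

`simulate_mut_accum()` generates the experimental-line analogue: one
ancestor sequence, independent mutation sets per line (uniform positions,
substitutions via the same two-strand draw), feeding
`mutation_site_composition()`.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and recombination,
selection, genotyping error and imputation artefacts, realistic human
demography, per-base mutability and context effects (CpG), and any real
annotation geometry (the bundled `simulate_gene_annotation()` places genes
independently of variants, so enrichment results on simulated data
demonstrate machinery and type-I behaviour only).

## Numerical choices

* Monomorphic genotype columns get F = 0 in scans (no information), and a
  constant trait yields F = 0 everywhere; an exactly perfectly-fitting SNP
  would report infinite F rather than overflow.
* REML for the variance ratio optimises over $\log \lambda \in [-12, 12]$
  with `optimize()`; a boundary optimum at the lower end is reported as
  $\lambda = 0$ (no polygenic component). Kinship matrices are symmetrised
  and eigenvalues clipped at zero; badly indefinite inputs error.
* HWE monomorphic sites return p = 1 by convention (no test possible).
* The one-way random-effects variance fraction in `subsample_variance()`
  uses the method-of-moments estimator with the unbalanced-design
  correction and clamps negative between-group components at zero.
* All simulation entry points take one integer seed; derived stream seeds
  are deterministic functions of it, kept below $2^{31}$, and recorded in
  the truth object. Reruns are byte-identical.

## Problem sizes

The package's own test battery runs, per property, at: 10^6 bases for
sequence-level parity; 50,000 SNPs × 200 individuals for phenotype-level
parity, the [A]+[C] = 0.5 relation and the 100-seed direction/null battery;
6,000 SNPs × 100 individuals × 20 replicates for modifier recovery;
universes ≤ 100 genes for exact enrichment enumeration. These sizes were
chosen so every Monte-Carlo tolerance in the tests is a small multiple of
the corresponding standard error.

## Limitations

Real-data headline quantities (SNP counts in the millions, specific F
thresholds, specific GO odds ratios) depend on external data releases and
are out of the package's scope; the pipeline reproduces the *patterns* and
the *machinery* end to end on synthetic data with recorded ground truth.
The mixed model assumes a single polygenic variance component; the
enrichment test treats genes as exchangeable units (no length or SNP-density
correction, as in the emulated design); and the allele-switching threshold
is a descriptive baseline for structure-driven signals, not a familywise
error guarantee.
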