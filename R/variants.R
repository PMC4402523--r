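#' Site-filter configuration
#'
#' Thresholds applied, in order, when loading variants: biallelic SNPs only,
#' autosome restriction, genotype call rate, then minor allele frequency
#' computed on the overall retained sample (not per group). Hardy-Weinberg
#' testing is reported per group but is not a removal filter by default.
#'
#' @param min_call_rate Minimum fraction of genotyped samples per site
#'   (default 0.8, i.e. "more than 80% genotyped").
#' @param min_maf Minimum minor allele frequency in the overall sample
#'   (default 0.05).
#' @param hwe_alpha Significance level for an optional Hardy-Weinberg
#'   removal filter, or `NULL` (default) to only report.
#' @param biallelic_only Drop multiallelic records (default `TRUE`; they are
#'   dropped, not decomposed, because the phenotype's allele-pair bookkeeping
#'   assumes two bases per site).
#' @param autosomes_only Drop X/Y/MT records (default `TRUE`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_call_rate = 0.8, min_maf = 0.05,
                          hwe_alpha = NULL, biallelic_only = TRUE,
                          autosomes_only = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  if (!is.null(hwe_alpha)) stopifnot(hwe_alpha > 0, hwe_alpha < 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, biallelic_only = biallelic_only,
                 autosomes_only = autosomes_only),
            class = "filter_config")
}

SEX_CHROMS <- c("X", "Y", "MT", "M", "chrX", "chrY", "chrM", "chrMT")

#' Load and filter biallelic SNPs from a VCF
#'
#' Reads GT fields from a VCF (plain or gzipped), converts genotypes to
#' alt-allele dosage, and applies the site filters of a [filter_config()] in
#' a fixed order: non-SNP/multiallelic records, sex/mitochondrial
#' chromosomes, call rate, then MAF on the retained overall sample. A filter
#' report itemises how many records each rule removed.
#'
#' @param vcf Path to a VCF file, or a `vcfR` object.
#' @param filters A [filter_config()].
#' @param groups Optional sample-group tibble (`sample`, `group`); when
#'   given, per-group Hardy-Weinberg test summaries are included in the
#'   report (and used for removal when `hwe_alpha` is set).
#' @return A list of class `variant_set`: `variants` (tibble: `id`, `chrom`,
#'   `pos`, `ref`, `alt`), `genotypes` (samples x variants dosage matrix),
#'   `report` (tibble: `rule`, `n_removed`, `n_remaining`).
#' @export
load_variants <- function(vcf, filters = filter_config(), groups = NULL) {
  if (is.character(vcf)) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  if (!methods::is(vcf, "vcfR")) abort("`vcf` must be a path or a vcfR object.")
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records.")
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw) || ncol(gt_raw) == 0) {
    abort("VCF contains no sample genotypes (GT field required).")
  }

  # GT string -> dosage; anything not a diploid 0/1 call is missing
  to_dosage <- function(g) {
    g <- sub("\\|", "/", g)
    d <- rep(NA_integer_, length(g))
    d[g %in% c("0/0")] <- 0L
    d[g %in% c("0/1", "1/0")] <- 1L
    d[g %in% c("1/1")] <- 2L
    d
  }
  dosage <- apply(gt_raw, 2, to_dosage)
  dosage <- matrix(dosage, nrow = nrow(gt_raw),
                   dimnames = dimnames(gt_raw))

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble(id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT)

  report <- tibble(rule = character(), n_removed = integer(),
                   n_remaining = integer())
  note <- function(rule, keep) {
    report <<- bind_rows(report, tibble(
      rule = rule, n_removed = sum(!keep), n_remaining = sum(keep)))
    keep
  }
  drop <- function(keep) {
    variants <<- variants[keep, , drop = FALSE]
    dosage <<- dosage[keep, , drop = FALSE]
  }

  if (filters$biallelic_only) {
    keep <- !grepl(",", variants$alt) &
      variants$ref %in% BASES & variants$alt %in% BASES
    drop(note("biallelic_snp", keep))
  }
  if (filters$autosomes_only) {
    drop(note("autosome", !(variants$chrom %in% SEX_CHROMS)))
  }
  if (nrow(variants) > 0 && anyDuplicated(paste(variants$chrom, variants$pos))) {
    drop(note("duplicate_position",
              !duplicated(paste(variants$chrom, variants$pos))))
  }
  call_rate <- rowMeans(!is.na(dosage))
  drop(note("call_rate", call_rate >= filters$min_call_rate))

  af <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  drop(note("maf", maf >= filters$min_maf & maf > 0))

  hwe <- NULL
  if (!is.null(groups) && nrow(variants) > 0) {
    hwe <- hwe_by_group(dosage, groups)
    if (!is.null(filters$hwe_alpha)) {
      worst <- apply(hwe, 1, min, na.rm = TRUE)
      drop(note("hwe", worst >= filters$hwe_alpha))
      hwe <- hwe[worst >= filters$hwe_alpha, , drop = FALSE]
    }
  }
  if (nrow(variants) == 0) {
    abort("no variants survive the configured filters.")
  }

  out <- list(variants = select(variants, -dplyr::any_of("origin")),
              genotypes = t(dosage), report = report, hwe = hwe)
  rownames(out$genotypes) <- colnames(gt_raw)
  colnames(out$genotypes) <- variants$id
  structure(out, class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d samples x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  print(x$report)
  invisible(x)
}

# matrix of per-group HWE p-values (variants x groups)
hwe_by_group <- function(dosage, groups) {
  assert_cols(groups, c("sample", "group"))
  gs <- split(groups$sample, groups$group)
  out <- sapply(gs, function(smp) {
    smp <- intersect(smp, colnames(dosage))
    d <- dosage[, smp, drop = FALSE]
    n_rr <- rowSums(d == 0, na.rm = TRUE)
    n_ra <- rowSums(d == 1, na.rm = TRUE)
    n_aa <- rowSums(d == 2, na.rm = TRUE)
    hwe_test(n_rr, n_ra, n_aa)
  })
  matrix(out, nrow = nrow(dosage),
         dimnames = list(rownames(dosage), names(gs)))
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Chi-square goodness-of-fit with 1 degree of freedom of the observed
#' genotype counts against Hardy-Weinberg expectations at the observed
#' allele frequency (default), or the exact conditional test for small
#' samples. Monomorphic sites return p = 1 by convention. All three count
#' arguments are vectorised.
#'
#' @param n_aa,n_ab,n_bb Counts of the two homozygote classes and the
#'   heterozygote class (`n_ab`).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return Vector of p-values.
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: p = 1
#' hwe_test(0, 100, 0)   # all heterozygous: chi-square = n
hwe_test <- function(n_aa, n_ab, n_bb, method = c("chisq", "exact")) {
  method <- match.arg(method)
  k <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(n_aa, k); n_ab <- rep_len(n_ab, k); n_bb <- rep_len(n_bb, k)
  n <- n_aa + n_ab + n_bb
  if (any(n == 0)) abort("total genotype count must be positive.")
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (method == "chisq") {
    e_aa <- n * p^2; e_ab <- 2 * n * p * (1 - p); e_bb <- n * (1 - p)^2
    chi <- rep(0, k)
    poly <- p > 0 & p < 1
    chi[poly] <- (n_aa - e_aa)[poly]^2 / e_aa[poly] +
      (n_ab - e_ab)[poly]^2 / e_ab[poly] +
      (n_bb - e_bb)[poly]^2 / e_bb[poly]
    pv <- pchisq(chi, df = 1, lower.tail = FALSE)
    pv[!poly] <- 1
    pv
  } else {
    vapply(seq_len(k), function(i) hwe_exact_one(n_aa[i], n_ab[i], n_bb[i]),
           numeric(1))
  }
}

# exact HWE test: probability of heterozygote counts at least as unusual as
# observed, conditional on allele counts (two-sided by probability ordering)
hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2; bb <- (n_b - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs + 1e-12])
}
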