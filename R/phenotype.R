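#' Per-individual base composition across polymorphic sites
#'
#' The genome phenotype: for every sample, the fraction of its SNP alleles
#' that are A, C, G and T. At each non-missing site a diploid sample
#' contributes its two alleles — a reference homozygote contributes the ref
#' base twice (weight 1 on the ref base), a heterozygote once each (weight
#' 0.5), an alternative homozygote the alt base twice. Sites with a missing
#' genotype are excluded from that sample's denominator, so the four
#' fractions always sum to 1.
#'
#' @param variants Tibble with `id`, `ref`, `alt` (single A/C/G/T bases), or
#'   a `variant_set` from [load_variants()] (in which case `genotypes` is
#'   taken from it).
#' @param genotypes Samples x variants alt-dosage matrix (0/1/2, `NA`
#'   missing), columns aligned with `variants`.
#' @return A tibble of class `base_phenotype` with columns `sample`,
#'   `frac_a`, `frac_c`, `frac_g`, `frac_t`, `n_sites_used`. Samples with no
#'   non-missing site get `NA` fractions and a warning.
#' @export
#' @examples
#' v <- tibble::tibble(id = c("s1", "s2", "s3"),
#'                     ref = c("A", "C", "A"), alt = c("G", "T", "C"))
#' g <- matrix(c(0L, 1L, 1L), 1, dimnames = list("ind1", v$id))
#' base_phenotype(v, g)  # alleles {A,A,C,T,A,C}
base_phenotype <- function(variants, genotypes = NULL) {
  if (inherits(variants, "variant_set")) {
    genotypes <- genotypes %||% variants$genotypes
    variants <- variants$variants
  }
  assert_cols(variants, c("ref", "alt"))
  if (is.null(genotypes)) abort("`genotypes` is required.")
  if (ncol(genotypes) != nrow(variants)) {
    abort("`genotypes` columns must align with `variants` rows.")
  }
  if (!all(is_base(variants$ref)) || !all(is_base(variants$alt))) {
    abort("`ref` and `alt` must be single A/C/G/T bases.")
  }
  if (any(toupper(variants$ref) == toupper(variants$alt))) {
    abort("`ref` must differ from `alt` at every site.")
  }
  d <- genotypes
  miss <- is.na(d)
  d0 <- d; d0[miss] <- 0L
  obs <- !miss
  # allele counts per sample: alt base gets dosage, ref base gets 2 - dosage
  counts <- sapply(BASES, function(b) {
    is_alt <- toupper(variants$alt) == b
    is_ref <- toupper(variants$ref) == b
    as.vector(d0 %*% is_alt + (2 * obs - d0) %*% is_ref)
  })
  counts <- matrix(counts, nrow = nrow(d), dimnames = list(rownames(d), BASES))
  n_sites <- rowSums(obs)
  denom <- 2 * n_sites
  none <- denom == 0
  if (any(none)) {
    warn(sprintf("%d sample(s) have no non-missing genotype; fractions set to NA.",
                 sum(none)))
    denom[none] <- NA_real_
  }
  out <- tibble(
    sample = rownames(d) %||% paste0("sample_", seq_len(nrow(d))),
    frac_a = unname(counts[, "A"] / denom),
    frac_c = unname(counts[, "C"] / denom),
    frac_g = unname(counts[, "G"] / denom),
    frac_t = unname(counts[, "T"] / denom),
    n_sites_used = as.integer(unname(n_sites)))
  class(out) <- c("base_phenotype", class(out))
  out
}

#' Base composition across mutation sites
#'
#' For mutation tables from mutation-accumulation (or mutagenesis) lines:
#' the derived line's composition counts the alternative (mutant) base at
#' each of its mutation sites, and the ancestor's composition counts the
#' reference base at the same sites. Under AT-biased mutation the derived
#' lines show higher `[A] + [T]` than the ancestor — the experimental-line
#' analogue of the population-level A&T increase.
#'
#' @param mutations Tibble with columns `line`, `chrom`, `pos`, `ref`, `alt`.
#' @return Tibble with one row per line and role (`derived` / `ancestor`):
#'   `line`, `role`, `frac_a` .. `frac_t`, `n_sites_used`.
#' @export
mutation_site_composition <- function(mutations) {
  if (!is.data.frame(mutations) || nrow(mutations) == 0) {
    abort("`mutations` must be a non-empty mutation table.")
  }
  assert_cols(mutations, c("line", "pos", "ref", "alt"))
  if (!all(is_base(mutations$ref)) || !all(is_base(mutations$alt))) {
    abort("`ref` and `alt` must be single A/C/G/T bases.")
  }
  if (any(toupper(mutations$ref) == toupper(mutations$alt))) {
    abort("`ref` must differ from `alt` at every mutation.")
  }
  frac_of <- function(bases) {
    tab <- table(factor(toupper(bases), levels = BASES))
    as.list(as.numeric(tab) / length(bases))
  }
  per_line <- mutations |>
    group_by(line) |>
    summarise(
      derived = list(frac_of(alt)),
      ancestor = list(frac_of(ref)),
      n_sites_used = dplyr::n(), .groups = "drop")
  out <- tidyr::pivot_longer(per_line, c("derived", "ancestor"),
                             names_to = "role", values_to = "f")
  fr <- purrr::map_dfr(out$f, ~ setNames(.x, c("frac_a", "frac_c",
                                               "frac_g", "frac_t")))
  bind_cols(select(out, line, role, n_sites_used), fr) |>
    arrange(line, dplyr::desc(role))
}

#' Per-variant allele-frequency divergence between two groups
#'
#' Absolute difference in alt-allele frequency between two groups, the
#' quantity whose genome-wide peaks coincide with the strongest
#' base-composition association signals in structured samples.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param groups Tibble (`sample`, `group`).
#' @param which_groups Character vector of the two group labels to compare;
#'   default: the two labels present.
#' @return Tibble: `id`, `freq_1`, `freq_2`, `abs_diff` (NA + flag when a
#'   group has no called genotype at a site).
#' @export
allele_freq_divergence <- function(genotypes, groups, which_groups = NULL) {
  assert_cols(groups, c("sample", "group"))
  labels <- which_groups %||% unique(groups$group)
  if (length(labels) != 2) abort("exactly two groups must be selected.")
  freq_in <- function(lab) {
    smp <- intersect(groups$sample[groups$group == lab], rownames(genotypes))
    if (length(smp) == 0) abort(sprintf("no samples for group '%s'.", lab))
    colMeans(genotypes[smp, , drop = FALSE], na.rm = TRUE) / 2
  }
  f1 <- freq_in(labels[1]); f2 <- freq_in(labels[2])
  tibble(id = colnames(genotypes) %||% paste0("v", seq_along(f1)),
         freq_1 = unname(f1), freq_2 = unname(f2),
         abs_diff = unname(abs(f1 - f2)),
         undefined = unname(is.nan(f1) | is.nan(f2)))
}

#' Group separation of the base-composition phenotype
#'
#' Per-group mean and standard deviation of each base fraction, plus a Welch
#' two-sample t-test on `frac_a`, with the difference reported as derived
#' minus basal (positive = A&T increase in the derived group).
#'
#' @param phenotype A [base_phenotype()] tibble.
#' @param groups Tibble (`sample`, `group`) and optionally `role` marking
#'   which group is `basal` and which `derived`; without roles the first
#'   group label is treated as basal.
#' @return List of class `group_separation`: `summary` (per-group stats),
#'   `test` (tibble: estimate = derived - basal mean `frac_a`, statistic,
#'   p_value, df).
#' @export
group_separation <- function(phenotype, groups) {
  assert_cols(phenotype, c("sample", "frac_a"))
  assert_cols(groups, c("sample", "group"))
  df <- left_join(phenotype, groups, by = "sample")
  if (any(is.na(df$group))) abort("every phenotyped sample needs a group label.")
  if (dplyr::n_distinct(df$group) < 2) {
    abort("at least two groups are required.")
  }
  if (any(table(df$group) < 2)) abort("each group needs at least two samples.")
  summary <- df |>
    group_by(group) |>
    summarise(across(c(frac_a, frac_c, frac_g, frac_t),
                     list(mean = mean, sd = sd)),
              n = dplyr::n(), .groups = "drop")
  if ("role" %in% names(groups)) {
    role <- distinct(groups, group, role)
    basal <- role$group[role$role == "basal"][1]
    derived <- role$group[role$role == "derived"][1]
  } else {
    labs <- unique(df$group)
    basal <- labs[1]; derived <- labs[2]
  }
  a_b <- df$frac_a[df$group == basal]
  a_d <- df$frac_a[df$group == derived]
  tt <- t.test(a_d, a_b)
  structure(list(
    summary = summary,
    test = tibble(basal = basal, derived = derived,
                  estimate = mean(a_d) - mean(a_b),
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter),
                  p_value = tt$p.value)
  ), class = "group_separation")
}

#' @export
print.group_separation <- function(x, ...) {
  cat("Base-composition group separation (Welch test on [A], derived - basal)\n")
  print(x$test)
  print(x$summary)
  invisible(x)
}
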