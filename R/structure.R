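#' Genomic relationship (kinship) matrix
#'
#' VanRaden-type genomic relationship matrix: dosages are centred at twice
#' the allele frequency and the cross-product is scaled by `2 * sum(p(1-p))`,
#' so unrelated individuals in an unstructured population have values near 0
#' and the diagonal is near 1. Missing dosages are mean-imputed per variant
#' for this computation only. In samples split by a bottleneck the matrix is
#' block-diagonal when sorted by group, which is exactly the structure the
#' mixed-model scan absorbs. A simple allele-sharing similarity is available
#' as a cross-check.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param method `"vanraden"` (default) or `"allele_sharing"`.
#' @return A symmetric n x n matrix with sample dimnames, class `kinship`.
#' @export
compute_kinship <- function(genotypes, method = c("vanraden", "allele_sharing")) {
  method <- match.arg(method)
  d <- impute_mean(genotypes)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all variants are monomorphic; kinship is undefined.")
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  if (method == "vanraden") {
    z <- sweep(d, 2, 2 * p)
    k <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  } else {
    m <- ncol(d)
    ind <- lapply(0:2, function(v) (abs(d - v) < 0.5) * 1)
    absdiff <- matrix(0, nrow(d), nrow(d))
    for (a in 0:2) for (b in 0:2) {
      if (a == b) next
      absdiff <- absdiff + abs(a - b) * tcrossprod(ind[[a + 1]], ind[[b + 1]])
    }
    k <- 1 - absdiff / (2 * m)
  }
  dimnames(k) <- list(rownames(genotypes), rownames(genotypes))
  structure(k, class = c("kinship", "matrix"))
}

impute_mean <- function(genotypes) {
  d <- as.matrix(genotypes)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' Principal component analysis of the genotype matrix
#'
#' PCA of the column-standardised dosage matrix (each variant centred and
#' scaled to unit variance; missing dosages mean-imputed). With strongly
#' diverged groups PC1 separates them — and, because the base-composition
#' phenotype is itself a linear readout of the same dosages, PC1 correlates
#' almost perfectly with it; that is why the scans use PCs 2..k as
#' covariates rather than PC1.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param k Number of components to return.
#' @return List of class `genotype_pca`: `scores` (tibble: `sample`, `PC1`,
#'   ...), `eigenvalues` (length-k vector, non-increasing).
#' @export
genotype_pca <- function(genotypes, k = 10) {
  d <- impute_mean(genotypes)
  if (k > min(dim(d))) {
    abort("`k` cannot exceed min(n_samples, n_variants).")
  }
  sds <- apply(d, 2, sd)
  keep <- sds > 0
  z <- scale(d[, keep, drop = FALSE])
  sv <- svd(z, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = bind_cols(
      tibble(sample = rownames(d) %||% paste0("sample_", seq_len(nrow(d)))),
      as_tibble(scores)),
    eigenvalues = sv$d[seq_len(k)]^2 / (nrow(d) - 1)
  ), class = "genotype_pca")
}

#' Correlation between the base-composition phenotype and a principal component
#'
#' @param phenotype A [base_phenotype()] tibble.
#' @param pca A [genotype_pca()] result.
#' @param which_pc Component number (default 1).
#' @param trait Phenotype column (default `"frac_a"`).
#' @return Pearson correlation coefficient.
#' @export
corr_phenotype_pc <- function(phenotype, pca, which_pc = 1, trait = "frac_a") {
  assert_cols(phenotype, c("sample", trait))
  pc_col <- paste0("PC", which_pc)
  assert_cols(pca$scores, c("sample", pc_col), "pca$scores")
  df <- left_join(phenotype, pca$scores, by = "sample")
  x <- df[[trait]]; y <- df[[pc_col]]
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance input; correlation undefined.")
  cor(x, y)
}
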