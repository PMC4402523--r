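#' Linear-model genome scan of the base-composition phenotype
#'
#' Per-SNP F statistic (1 numerator degree of freedom) for the genotype term
#' in a linear regression of the trait on dosage, optionally adjusting for
#' fixed covariates such as principal-component scores. The F statistic is
#' invariant to affine recoding of both dosage and trait. P-values are
#' reported by default but the F statistics are the primary output: in very
#' large structured samples the null distribution is not trustworthy, which
#' is why thresholds come from [bonferroni_threshold()] or
#' [allele_switch_threshold()] instead.
#'
#' @param phenotype A [base_phenotype()] tibble, or a named numeric vector.
#' @param genotypes Samples x variants dosage matrix (missing dosages
#'   mean-imputed per variant).
#' @param covariates Optional numeric matrix / data frame of covariates
#'   (rows aligned with samples), e.g. `pc_covariates()` output.
#' @param variants Optional variant tibble (`id`, `chrom`, `pos`) merged
#'   into the result for plotting.
#' @param trait Phenotype column to scan (default `"frac_a"`).
#' @param p_values Compute p-values from the F distribution (default TRUE).
#' @return A tibble of class `scan_result`: `id`, (`chrom`, `pos`,) `F`,
#'   `p_value`, `model`.
#' @export
linear_scan <- function(phenotype, genotypes, covariates = NULL,
                        variants = NULL, trait = "frac_a", p_values = TRUE) {
  y <- trait_vector(phenotype, genotypes, trait)
  scan_core(y, genotypes, covariates, variants,
            model = if (is.null(covariates)) "linear" else "linear+PC",
            p_values = p_values)
}

trait_vector <- function(phenotype, genotypes, trait) {
  if (is.numeric(phenotype)) {
    y <- phenotype
    if (!is.null(names(y)) && !is.null(rownames(genotypes))) {
      y <- y[rownames(genotypes)]
    }
  } else {
    assert_cols(phenotype, c("sample", trait), "phenotype")
    y <- setNames(phenotype[[trait]], phenotype$sample)
    if (!is.null(rownames(genotypes))) y <- y[rownames(genotypes)]
  }
  if (length(y) != nrow(genotypes) || anyNA(y)) {
    abort("phenotype does not align with the genotype rows (or has NAs).")
  }
  unname(y)
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "genotype_pca")) {
    covariates <- pc_covariates(covariates)
  }
  x <- as.matrix(as.data.frame(covariates)[
    , setdiff(colnames(as.data.frame(covariates)), "sample"), drop = FALSE])
  storage.mode(x) <- "double"
  if (nrow(x) != n) abort("covariates do not align with the samples.")
  x
}

#' Extract PC covariates (default PCs 2-6) from a PCA result
#'
#' PC1 is excluded by default because it is nearly collinear with the
#' base-composition trait itself.
#'
#' @param pca A [genotype_pca()] result.
#' @param pcs Integer vector of component numbers (default `2:6`).
#' @return Numeric matrix of scores.
#' @export
pc_covariates <- function(pca, pcs = 2:6) {
  cols <- paste0("PC", pcs)
  assert_cols(pca$scores, cols, "pca$scores")
  as.matrix(pca$scores[, cols, drop = FALSE])
}

# shared OLS scan machinery: F for each genotype column given covariates
scan_core <- function(y, genotypes, covariates, variants, model, p_values,
                      weights_transform = NULL) {
  n <- length(y)
  g <- impute_mean(genotypes)
  x0 <- cbind(`(Intercept)` = rep(1, n), as_covariate_matrix(covariates, n))
  if (!is.null(weights_transform)) {
    y <- weights_transform(y)
    g <- weights_transform(g)
    x0 <- weights_transform(x0)
  }
  qx <- qr(x0)
  if (qx$rank < ncol(x0)) {
    bad <- colnames(x0)[qx$pivot[(qx$rank + 1):ncol(x0)]]
    abort(paste0("collinear covariate(s): ", paste(bad, collapse = ", ")))
  }
  p0 <- ncol(x0)
  if (n <= p0 + 1) abort("too few samples for the requested model.")
  ry <- qr.resid(qx, y)
  rg <- qr.resid(qx, g)
  gg <- unname(colSums(rg^2))
  gy <- as.vector(crossprod(rg, ry))
  yy <- sum(ry^2)
  df2 <- n - p0 - 1
  eps <- 1e-12 * max(yy, 1)
  ss_model <- ifelse(gg > 1e-12, gy^2 / gg, 0)
  rss <- pmax(yy - ss_model, 0)
  f <- ifelse(ss_model <= eps, 0,
              ifelse(rss > eps, ss_model / (rss / df2), Inf))
  out <- tibble(
    id = colnames(genotypes) %||% paste0("v", seq_along(f)),
    F = f,
    p_value = if (p_values) pf(f, 1, df2, lower.tail = FALSE) else NA_real_,
    model = model)
  if (!is.null(variants)) {
    out <- left_join(select(variants, dplyr::any_of(c("id", "chrom", "pos"))),
                     out, by = "id") |>
      select(id, dplyr::any_of(c("chrom", "pos")), F, p_value, model)
  }
  attr(out, "df") <- c(1, df2)
  class(out) <- c("scan_result", class(out))
  out
}

#' Mixed-model genome scan with a kinship random effect
#'
#' Two-stage (EMMAX/P3D-style) association scan: the polygenic variance
#' ratio is estimated once by restricted maximum likelihood on the null
#' model (trait ~ covariates + kinship random effect), then every SNP is
#' tested by generalised least squares under that fitted covariance. With
#' `kinship = diag(n)` the scan reduces exactly to [linear_scan()] with the
#' same covariates.
#'
#' @inheritParams linear_scan
#' @param kinship A [compute_kinship()] matrix (positive semidefinite after
#'   the standard diagonal shift).
#' @return A `scan_result` tibble (`model = "mixed"`); variance-component
#'   estimates are in `attr(, "vc")`: `lambda` (sigma_g^2/sigma_e^2),
#'   `sigma_g2`, `sigma_e2`, `h2`.
#' @export
mixed_scan <- function(phenotype, genotypes, kinship, covariates = NULL,
                       variants = NULL, trait = "frac_a", p_values = TRUE) {
  y <- trait_vector(phenotype, genotypes, trait)
  n <- length(y)
  k <- as.matrix(kinship)
  if (nrow(k) != n || ncol(k) != n) abort("kinship does not match sample count.")
  ek <- eigen((k + t(k)) / 2, symmetric = TRUE)
  evals <- ek$values
  if (min(evals) < -1e-6 * max(abs(evals))) {
    # shift to PSD; refuse if badly indefinite
    if (min(evals) < -0.05 * max(abs(evals))) {
      abort("kinship matrix is not positive semidefinite after shifting.")
    }
  }
  evals <- pmax(evals, 0)
  u <- ek$vectors
  x0 <- cbind(rep(1, n), as_covariate_matrix(covariates, n))
  fit <- reml_lambda(y, x0, u, evals)

  w <- fit$lambda * evals + 1
  transform <- function(m) {
    r <- crossprod(u, m) / sqrt(w)
    if (is.matrix(m)) r else as.vector(r)
  }
  out <- scan_core(y, genotypes, covariates, variants, model = "mixed",
                   p_values = p_values, weights_transform = transform)
  attr(out, "vc") <- fit
  out
}

# REML estimation of lambda = sigma_g^2 / sigma_e^2 on the null model,
# via the eigendecomposition of the kinship matrix
reml_lambda <- function(y, x0, u, evals) {
  n <- length(y)
  p <- ncol(x0)
  ystar <- as.vector(crossprod(u, y))
  xstar <- crossprod(u, x0)
  crit <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * evals + 1
    xtwx <- crossprod(xstar / w, xstar)
    beta <- solve(xtwx, crossprod(xstar / w, ystar))
    r <- ystar - xstar %*% beta
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    # negative restricted log-likelihood (constants dropped)
    0.5 * ((n - p) * log(s2) + sum(log(w)) +
             determinant(xtwx, logarithm = TRUE)$modulus)
  }
  opt <- optimize(crit, c(-12, 12))
  lam <- exp(opt$minimum)
  w <- lam * evals + 1
  xtwx <- crossprod(xstar / w, xstar)
  beta <- solve(xtwx, crossprod(xstar / w, ystar))
  rss <- sum((ystar - xstar %*% beta)^2 / w)
  s2e <- rss / (n - p)
  # boundary optima: lambda ~ 0 means no polygenic component; the upper
  # bound arises when the trait is almost entirely kinship-aligned (common
  # with strong structure) and the GLS then approaches a projection
  boundary <- opt$minimum <= -12 + 1e-6 || opt$minimum >= 12 - 1e-6
  if (opt$minimum <= -12 + 1e-6) lam <- 0
  list(lambda = lam, sigma_e2 = s2e, sigma_g2 = lam * s2e,
       h2 = lam / (lam + 1), reml = -opt$objective,
       converged = TRUE, boundary = boundary)
}

#' Flag trait-associated SNPs (TASs) in a scan result
#'
#' @param scan A `scan_result` tibble.
#' @param f_threshold,p_threshold Declare a SNP a TAS when its F statistic
#'   is at least `f_threshold`, or its p-value at most `p_threshold`
#'   (exactly one must be given).
#' @return The scan tibble with an `is_tas` column; the rule is recorded in
#'   `attr(, "tas_rule")`.
#' @export
flag_tas <- function(scan, f_threshold = NULL, p_threshold = NULL) {
  if (is.null(f_threshold) == is.null(p_threshold)) {
    abort("give exactly one of `f_threshold` or `p_threshold`.")
  }
  if (!is.null(f_threshold)) {
    scan$is_tas <- scan$F >= f_threshold
    attr(scan, "tas_rule") <- list(type = "F", value = f_threshold)
  } else {
    scan$is_tas <- !is.na(scan$p_value) & scan$p_value <= p_threshold
    attr(scan, "tas_rule") <- list(type = "p", value = p_threshold)
  }
  scan
}

#' Bonferroni genome-wide significance threshold
#'
#' @param m Number of tests.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble: `m`, `alpha`, `p_threshold` (= alpha/m), `neg_log10`.
#' @export
#' @examples
#' bonferroni_threshold(7003981)  # ~7e-9, -log10 ~ 8.1
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  tibble(m = m, alpha = alpha, p_threshold = alpha / m,
         neg_log10 = -log10(alpha / m))
}

#' Allele-switching simulation threshold for the linear scan
#'
#' Builds the pseudo-SNP with perfectly fixed opposite alleles in the two
#' groups (the strongest association pattern the sample structure can
#' produce), then randomly switches the genotype in an increasing proportion
#' of samples and records the F statistic of the switched pseudo-SNP against
#' the real phenotype. The resulting F distributions show how the maximal
#' structure-driven signal decays under perturbation; the reported baseline
#' threshold is a configurable percentile of the distribution at a
#' configurable proportion, and the full table is returned so any other rule
#' can be applied.
#'
#' @param phenotype A [base_phenotype()] tibble or named numeric vector.
#' @param groups Tibble (`sample`, `group`), two groups.
#' @param proportions Switching proportions in [0, 0.5].
#' @param reps Randomisations per proportion (default 1000).
#' @param percentile Percentile of the F distribution used for the baseline
#'   (default 0.975).
#' @param at_proportion Proportion whose distribution supplies the baseline
#'   (default: the largest in `proportions`).
#' @param trait Phenotype column (default `"frac_a"`).
#' @param seed Optional seed for the switching randomisations.
#' @return List of class `switch_threshold`: `threshold`, `baseline_f` (the
#'   unswitched pseudo-SNP F), `distributions` (tibble: `proportion`, `rep`,
#'   `F`), `summary` (per-proportion mean and percentile).
#' @export
allele_switch_threshold <- function(phenotype, groups,
                                    proportions = seq(0, 0.5, by = 0.1),
                                    reps = 1000, percentile = 0.975,
                                    at_proportion = NULL, trait = "frac_a",
                                    seed = NULL) {
  if (any(proportions < 0 | proportions > 0.5)) {
    abort("`proportions` must lie in [0, 0.5] (switching is symmetric).")
  }
  if (!is.null(seed)) set.seed(seed)
  assert_cols(groups, c("sample", "group"))
  labs <- unique(groups$group)
  if (length(labs) != 2) abort("exactly two groups are required.")
  if (is.numeric(phenotype)) {
    y <- phenotype[groups$sample]
  } else {
    assert_cols(phenotype, c("sample", trait), "phenotype")
    y <- setNames(phenotype[[trait]], phenotype$sample)[groups$sample]
  }
  if (anyNA(y)) abort("phenotype does not cover every grouped sample.")
  n <- length(y)
  d0 <- ifelse(groups$group == labs[1], 0, 2)  # perfectly fixed pseudo-SNP

  f_of <- function(d) {
    if (var(d) == 0) return(0)
    r <- cor(d, y)
    (n - 2) * r^2 / (1 - r^2)
  }
  baseline_f <- f_of(d0)
  dist <- purrr::map_dfr(proportions, function(pr) {
    n_flip <- round(pr * n)
    f <- vapply(seq_len(reps), function(i) {
      d <- d0
      if (n_flip > 0) {
        idx <- sample.int(n, n_flip)
        d[idx] <- 2 - d[idx]
      }
      f_of(d)
    }, numeric(1))
    tibble(proportion = pr, rep = seq_len(reps), F = f)
  })
  summary <- dist |>
    group_by(proportion) |>
    summarise(mean_f = mean(F),
              q_upper = stats::quantile(F, percentile), .groups = "drop")
  at <- at_proportion %||% max(proportions)
  thr <- stats::quantile(dist$F[dist$proportion == at], percentile)
  structure(list(threshold = unname(thr), baseline_f = baseline_f,
                 percentile = percentile, at_proportion = at,
                 distributions = dist, summary = summary),
            class = "switch_threshold")
}

#' @export
print.switch_threshold <- function(x, ...) {
  cat(sprintf(
    "Allele-switching threshold: F = %.1f (%.1f%% percentile at proportion %.2f)\n",
    x$threshold, 100 * x$percentile, x$at_proportion))
  cat(sprintf("unswitched (fully fixed) pseudo-SNP F = %.1f\n", x$baseline_f))
  print(x$summary)
  invisible(x)
}

#' Between-group variance fraction of [A] under site subsampling
#'
#' How precise is the base-composition phenotype as a function of the number
#' of sites it is computed from? For each site count `k`, variants are
#' resampled without replacement, the `[A]` phenotype recomputed, and the
#' between-group share of its variance estimated by a one-way
#' random-effects (method-of-moments) decomposition. With structured data
#' the fraction rises towards its full-data value as `k` grows, showing that
#' the arithmetic `[A]` value is an increasingly precise estimate of an
#' underlying individual trait.
#'
#' @param variants,genotypes As in [base_phenotype()].
#' @param groups Tibble (`sample`, `group`).
#' @param k_grid Integer vector of site counts (each >= 2, <= total sites).
#' @param reps Resamples per site count (default 20).
#' @param seed Optional seed.
#' @return List of class `subsample_variance`: `summary` (tibble: `k`,
#'   `mean_fraction`, `sd_fraction`), `draws` (per-rep fractions).
#' @export
subsample_variance <- function(variants, genotypes, groups, k_grid,
                               reps = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(variants)
  if (any(k_grid < 2)) abort("every `k` must be at least 2.")
  if (any(k_grid > m)) abort("`k` cannot exceed the number of variants.")
  draws <- purrr::map_dfr(k_grid, function(k) {
    fr <- vapply(seq_len(reps), function(i) {
      idx <- if (k == m) seq_len(m) else sort(sample.int(m, k))
      ph <- suppressWarnings(
        base_phenotype(variants[idx, , drop = FALSE],
                       genotypes[, idx, drop = FALSE]))
      variance_fraction(ph$frac_a, groups$group[
        match(ph$sample, groups$sample)])
    }, numeric(1))
    tibble(k = k, rep = seq_len(reps), fraction = fr)
  })
  summary <- draws |>
    group_by(k) |>
    summarise(mean_fraction = mean(fraction),
              sd_fraction = sd(fraction), .groups = "drop")
  structure(list(summary = summary, draws = draws),
            class = "subsample_variance")
}

# one-way random-effects between/(between+within) variance fraction
variance_fraction <- function(y, group) {
  ok <- !is.na(y) & !is.na(group)
  y <- y[ok]; group <- factor(group[ok])
  a <- nlevels(group)
  ni <- tabulate(group)
  n <- sum(ni)
  gm <- mean(y)
  mi <- tapply(y, group, mean)
  msb <- sum(ni * (mi - gm)^2) / (a - 1)
  msw <- sum((y - mi[group])^2) / (n - a)
  n0 <- (n - sum(ni^2) / n) / (a - 1)
  sb2 <- max((msb - msw) / n0, 0)
  sb2 / (sb2 + msw)
}
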