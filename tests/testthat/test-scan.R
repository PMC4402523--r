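test_that("linear scan F equals the closed-form one-way ANOVA F on a fixed SNP", {
  set.seed(41)
  n <- 40
  grp <- rep(c(0, 2), each = n / 2)                 # perfectly fixed SNP
  y <- 0.3 + 0.002 * grp + rnorm(n, sd = 0.002)
  g <- cbind(fixed = grp, noise = rbinom(n, 2, 0.5))
  rownames(g) <- paste0("i", 1:n)
  scan <- linear_scan(setNames(y, rownames(g)), g)
  # one-way ANOVA oracle computed from group means
  m1 <- mean(y[grp == 0]); m2 <- mean(y[grp == 2]); gm <- mean(y)
  ssb <- (n / 2) * ((m1 - gm)^2 + (m2 - gm)^2)
  ssw <- sum((y[grp == 0] - m1)^2) + sum((y[grp == 2] - m2)^2)
  f_anova <- (ssb / 1) / (ssw / (n - 2))
  expect_equal(scan$F[scan$id == "fixed"], f_anova)
})

test_that("linear scan F is invariant to affine recodings", {
  set.seed(42)
  n <- 30
  g <- matrix(rbinom(n * 50, 2, 0.3), nrow = n,
              dimnames = list(paste0("i", 1:n), paste0("v", 1:50)))
  y <- setNames(rnorm(n), rownames(g))
  f0 <- linear_scan(y, g)$F
  expect_equal(linear_scan(y, g / 2)$F, f0)          # dosage {0,.5,1}
  expect_equal(linear_scan(y * 3 + 1, g)$F, f0)      # affine trait
  expect_equal(linear_scan(y, 2 - g)$F, f0)          # allele relabel
  # constant phenotype: F = 0 everywhere
  expect_equal(linear_scan(setNames(rep(1, n), rownames(g)), g)$F,
               rep(0, 50))
})

test_that("collinear covariates are rejected by name", {
  set.seed(43)
  n <- 20
  g <- matrix(rbinom(n * 10, 2, 0.5), nrow = n,
              dimnames = list(paste0("i", 1:n), paste0("v", 1:10)))
  y <- setNames(rnorm(n), rownames(g))
  cov <- cbind(a = rnorm(n), b = 0)
  cov <- cbind(cov, c = cov[, "a"] * 2)
  expect_error(linear_scan(y, g, covariates = cov), "collinear")
})

test_that("mixed scan with identity kinship reproduces the covariate OLS scan", {
  set.seed(44)
  n <- 30
  g <- matrix(rbinom(n * 80, 2, runif(80, 0.1, 0.9)), nrow = n,
              dimnames = list(paste0("i", 1:n), paste0("v", 1:80)))
  y <- setNames(rnorm(n), rownames(g))
  cov <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("c1", "c2")))
  ols <- linear_scan(y, g, covariates = cov)
  mm <- mixed_scan(y, g, kinship = diag(n), covariates = cov)
  expect_equal(mm$F, ols$F, tolerance = 1e-8)
  expect_equal(mm$p_value, ols$p_value, tolerance = 1e-8)
})

test_that("REML variance components match a grid-search likelihood oracle", {
  # n = 12 toy data with a polygenic signal drawn from a known kinship
  set.seed(45)
  n <- 12
  g <- matrix(rbinom(n * 60, 2, runif(60, 0.2, 0.8)), nrow = n,
              dimnames = list(paste0("i", 1:n), paste0("v", 1:60)))
  k <- compute_kinship(g)
  ek <- eigen(as.matrix(k), symmetric = TRUE)
  u_g <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n))
  y <- setNames(as.vector(2 + 1.5 * u_g + rnorm(n, sd = 1)), rownames(g))
  fit <- attr(mixed_scan(y, g, k), "vc")
  # independent oracle: profile the restricted likelihood over h2 on a grid,
  # evaluating it directly from the covariance matrix with solve()
  x <- matrix(1, n, 1)
  reml_direct <- function(h2) {
    lam <- h2 / (1 - h2)
    v <- lam * as.matrix(k) + diag(n)
    vi <- solve(v)
    xvx <- t(x) %*% vi %*% x
    beta <- solve(xvx, t(x) %*% vi %*% y)
    r <- y - x %*% beta
    rss <- as.numeric(t(r) %*% vi %*% r)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2) + determinant(v)$modulus +
              determinant(xvx)$modulus)
  }
  grid <- seq(0.001, 0.999, by = 0.0005)
  h2_grid <- grid[which.max(vapply(grid, reml_direct, numeric(1)))]
  expect_equal(fit$h2, h2_grid, tolerance = 1e-3)
})

test_that("the planted bias-modifier locus tops the mixed scan", {
  sim <- simulate_populations(pop_sim_config(
    n_basal = 50, n_derived = 50, n_snps = 6000,
    modifier = list(delta = 0.6, frac_sites = 0.1, freq = 0.3), seed = 46))
  ph <- base_phenotype(sim$variants, sim$genotypes)
  pca <- genotype_pca(sim$genotypes, k = 6)
  kin <- compute_kinship(sim$genotypes)
  scan <- mixed_scan(ph, sim$genotypes, kin,
                     covariates = pc_covariates(pca, 2:6))
  top5 <- scan$id[order(-scan$F)][1:5]
  expect_true(sim$truth$modifier$id %in% top5)
})

test_that("Bonferroni thresholds follow alpha / m", {
  expect_equal(bonferroni_threshold(1)$p_threshold, 0.05)
  expect_equal(bonferroni_threshold(100)$p_threshold, 5e-4)
  thr <- bonferroni_threshold(7003981)
  expect_equal(thr$neg_log10, -log10(0.05 / 7003981))
})

test_that("allele switching starts at the maximal F and decays with proportion", {
  sim <- small_sim(seed = 47)
  ph <- base_phenotype(sim$variants, sim$genotypes)
  thr <- allele_switch_threshold(ph, sim$groups,
                                 proportions = c(0, 0.1, 0.25, 0.5),
                                 reps = 200, seed = 48)
  d <- thr$distributions
  # proportion 0: every rep is exactly the unswitched pseudo-SNP F
  expect_equal(unique(d$F[d$proportion == 0]), thr$baseline_f)
  # the unswitched pseudo-SNP F beats every same-pattern variant by
  # construction and the mean decays in the switching proportion
  means <- tapply(d$F, d$proportion, mean)
  expect_true(all(diff(means) < 0))
  # at proportion 0.5 the switched SNP is indistinguishable from a random
  # SNP null on the same phenotype
  y <- ph$frac_a
  set.seed(49)
  null_f <- replicate(600, {
    dnull <- ifelse(runif(length(y)) < 0.5, 0, 2)
    if (var(dnull) == 0) return(0)
    r <- cor(dnull, y)
    (length(y) - 2) * r^2 / (1 - r^2)
  })
  expect_lt(abs(mean(d$F[d$proportion == 0.5]) - mean(null_f)), 0.75)
  expect_error(allele_switch_threshold(ph, sim$groups, proportions = 0.7),
               "0.5")
})

test_that("the unswitched pseudo-SNP attains the maximal F among group-fixed patterns", {
  sim <- small_sim(seed = 50)
  ph <- base_phenotype(sim$variants, sim$genotypes)
  thr <- allele_switch_threshold(ph, sim$groups, proportions = 0,
                                 reps = 1, seed = 1)
  scan <- linear_scan(ph, sim$genotypes)
  # any real variant with the same group-fixed pattern would equal it;
  # all other variants cannot exceed the perfectly separated pattern's F
  # unless they are better correlated with frac_a than group membership is
  grp <- ifelse(sim$groups$role == "derived", 2, 0)
  f_grp <- {
    r <- cor(grp, ph$frac_a)
    (length(grp) - 2) * r^2 / (1 - r^2)
  }
  expect_equal(thr$baseline_f, f_grp)
})

test_that("subsampled variance fractions reach the full-data value and rise with k", {
  sim <- small_sim(seed = 51)
  ph <- base_phenotype(sim$variants, sim$genotypes)
  full <- basecomp:::variance_fraction(
    ph$frac_a, sim$groups$group[match(ph$sample, sim$groups$sample)])
  m <- nrow(sim$variants)
  sv <- subsample_variance(sim$variants, sim$genotypes, sim$groups,
                           k_grid = c(10, 100, 1000, m), reps = 40, seed = 52)
  expect_equal(sv$summary$mean_fraction[sv$summary$k == m], full)
  expect_true(all(diff(sv$summary$mean_fraction) > -0.05))
  expect_gt(sv$summary$mean_fraction[4], sv$summary$mean_fraction[1])
  expect_error(subsample_variance(sim$variants, sim$genotypes, sim$groups,
                                  k_grid = 1), "at least 2")
  # unstructured data: fraction stays near its null level at every k
  sim0 <- small_sim(seed = 53, shared_frac = 1, bottleneck_gen = 0,
                    spectrum = mutation_spectrum(at_bias = 1))
  ph0 <- base_phenotype(sim0$variants, sim0$genotypes)
  sv0 <- subsample_variance(sim0$variants, sim0$genotypes, sim0$groups,
                            k_grid = c(100, 1000), reps = 10, seed = 54)
  expect_true(all(sv0$summary$mean_fraction < 0.3))
})

test_that("scan tidiers and TAS flagging are consistent", {
  sim <- small_sim(seed = 55)
  ph <- base_phenotype(sim$variants, sim$genotypes)
  scan <- linear_scan(ph, sim$genotypes, variants = sim$variants)
  scan <- flag_tas(scan, f_threshold = 10)
  expect_identical(scan$is_tas, scan$F >= 10)
  g <- glance(scan)
  expect_equal(g$n_tas, sum(scan$is_tas))
  expect_equal(g$n_variants, nrow(sim$variants))
  expect_error(flag_tas(scan), "exactly one")
})
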