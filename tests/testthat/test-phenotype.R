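test_that("the worked 3-SNP example enumerates to the exact fractions", {
  # genotypes AA, CT, AC contribute alleles {A,A, C,T, A,C}
  ph <- base_phenotype(worked_variants(), worked_genotypes())
  expect_equal(ph$frac_a, 0.5)
  expect_equal(ph$frac_c, 1 / 3)
  expect_equal(ph$frac_t, 1 / 6)
  expect_equal(ph$frac_g, 0)
  expect_equal(ph$n_sites_used, 3L)
})

test_that("a missing genotype drops that site from the sample's denominator", {
  g <- worked_genotypes()
  g[1, 2] <- NA_integer_
  ph <- base_phenotype(worked_variants(), g)
  # alleles {A,A, A,C}: denominator 4
  expect_equal(ph$frac_a, 0.75)
  expect_equal(ph$frac_c, 0.25)
  expect_equal(ph$n_sites_used, 2L)
  # a single heterozygous A/T site splits evenly
  ph2 <- base_phenotype(
    tibble::tibble(id = "x", ref = "A", alt = "T"),
    matrix(1L, 1, 1, dimnames = list("i", "x")))
  expect_equal(ph2$frac_a, 0.5)
  expect_equal(ph2$frac_t, 0.5)
  # all-missing sample is flagged
  expect_warning(
    ph3 <- base_phenotype(worked_variants(),
                          matrix(NA_integer_, 1, 3,
                                 dimnames = list("i", c("s1", "s2", "s3")))),
    "no non-missing")
  expect_true(is.na(ph3$frac_a))
})

test_that("phenotype fractions sum to one and respect invariances", {
  sim <- small_sim(seed = 4, missing_rate = 0.1)
  ph <- base_phenotype(sim$variants, sim$genotypes)
  expect_lt(max(abs(ph$frac_a + ph$frac_c + ph$frac_g + ph$frac_t - 1)),
            1e-12 * ncol(sim$genotypes))
  # invariant to variant order
  ord <- sample(nrow(sim$variants))
  ph_perm <- base_phenotype(sim$variants[ord, ], sim$genotypes[, ord])
  expect_equal(ph_perm, ph)
  # invariant to ref/alt swap with complementary dosage recoding
  v2 <- sim$variants
  swap <- seq(1, nrow(v2), by = 3)
  tmp <- v2$ref[swap]; v2$ref[swap] <- v2$alt[swap]; v2$alt[swap] <- tmp
  g2 <- sim$genotypes
  g2[, swap] <- 2L - g2[, swap]
  expect_equal(base_phenotype(v2, g2), ph)
})

test_that("the union phenotype is the site-weighted average of subsets", {
  sim <- small_sim(seed = 5)
  m <- nrow(sim$variants)
  a <- seq_len(floor(m / 3)); b <- setdiff(seq_len(m), a)
  ph_a <- base_phenotype(sim$variants[a, ], sim$genotypes[, a])
  ph_b <- base_phenotype(sim$variants[b, ], sim$genotypes[, b])
  ph <- base_phenotype(sim$variants, sim$genotypes)
  w <- ph_a$n_sites_used / (ph_a$n_sites_used + ph_b$n_sites_used)
  expect_equal(ph$frac_a, w * ph_a$frac_a + (1 - w) * ph_b$frac_a)
})

test_that("mutation-site composition contrasts derived alt vs ancestral ref", {
  mut <- tibble::tibble(line = "l1", chrom = "c", pos = 1:2,
                        ref = c("G", "C"), alt = c("A", "T"))
  mc <- mutation_site_composition(mut)
  der <- mc[mc$role == "derived", ]
  anc <- mc[mc$role == "ancestor", ]
  expect_equal(der$frac_a, 0.5); expect_equal(der$frac_t, 0.5)
  expect_equal(anc$frac_g, 0.5); expect_equal(anc$frac_c, 0.5)
  expect_error(mutation_site_composition(mut[0, ]), "non-empty")
  mut_bad <- mut; mut_bad$alt[1] <- "G"
  expect_error(mutation_site_composition(mut_bad), "differ")
})

test_that("allele frequency divergence matches brute-force counting", {
  set.seed(12)
  g <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
              nrow = 6, dimnames = list(paste0("i", 1:6), paste0("v", 1:10)))
  groups <- tibble::tibble(sample = paste0("i", 1:6),
                           group = rep(c("g1", "g2"), each = 3))
  div <- allele_freq_divergence(g, groups)
  for (j in 1:10) {
    f1 <- mean(g[1:3, j], na.rm = TRUE) / 2
    f2 <- mean(g[4:6, j], na.rm = TRUE) / 2
    if (is.nan(f1) || is.nan(f2)) {
      expect_true(div$undefined[j])
    } else {
      expect_equal(div$abs_diff[j], abs(f1 - f2))
    }
  }
  # fixed opposite alleles diverge by 1; identical frequencies by 0
  g2 <- cbind(fix = c(0, 0, 0, 2, 2, 2), same = c(1, 1, 1, 1, 1, 1))
  rownames(g2) <- paste0("i", 1:6)
  div2 <- allele_freq_divergence(g2, groups)
  expect_equal(div2$abs_diff, c(1, 0))
})

test_that("group separation reports Welch statistics, derived minus basal", {
  ph <- tibble::tibble(sample = paste0("i", 1:4),
                       frac_a = c(0.30, 0.32, 0.28, 0.29),
                       frac_c = 0.2, frac_g = 0.2,
                       frac_t = 1 - 0.4 - c(0.30, 0.32, 0.28, 0.29),
                       n_sites_used = 100L)
  groups <- tibble::tibble(sample = paste0("i", 1:4),
                           group = rep(c("pop_b", "pop_d"), each = 2),
                           role = rep(c("basal", "derived"), each = 2))
  gs <- group_separation(ph, groups)
  # textbook Welch computation on the two pairs
  m1 <- mean(c(0.30, 0.32)); m2 <- mean(c(0.28, 0.29))
  v1 <- var(c(0.30, 0.32)); v2 <- var(c(0.28, 0.29))
  se <- sqrt(v1 / 2 + v2 / 2)
  t_manual <- (m2 - m1) / se
  df_manual <- se^4 / ((v1 / 2)^2 / 1 + (v2 / 2)^2 / 1)
  expect_equal(gs$test$estimate, m2 - m1)
  expect_equal(gs$test$statistic, t_manual)
  expect_equal(gs$test$df, df_manual)
  # identical groups: difference 0, p = 1
  ph_same <- ph; ph_same$frac_a <- c(0.3, 0.31, 0.3, 0.31)
  gs0 <- group_separation(ph_same, groups)
  expect_equal(gs0$test$estimate, 0)
  expect_gt(gs0$test$p_value, 0.95)
  expect_error(group_separation(ph, dplyr::mutate(groups, group = "one")),
               "two groups")
})
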