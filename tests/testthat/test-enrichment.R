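toy_genes <- function() {
  tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    chrom = rep(c("chr1", "chr2"), each = 10),
    start = rep(seq(0, 9e6, by = 1e6), 2),
    end = rep(seq(0, 9e6, by = 1e6), 2) + 5e5)
}

test_that("TAS windows follow the centred half-open arithmetic and merge", {
  tas <- tibble::tibble(chrom = "chr1", pos = 2000000)
  w <- build_windows(tas, 1.5e6)
  expect_equal(w$start, 2000000 - 1 - 750000)
  expect_equal(w$end, 2000000 - 1 + 750000)
  # two TASs 100 kb apart with 1.5 Mb windows merge into one interval
  tas2 <- tibble::tibble(chrom = "chr1", pos = c(2e6, 2.1e6))
  w2 <- build_windows(tas2, 1.5e6)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$end - w2$start, 1.5e6 + 1e5)
  # oracle: merging equals the union computed by hand
  expect_equal(w2$start, 2e6 - 1 - 7.5e5)
  expect_equal(w2$end, 2.1e6 - 1 + 7.5e5)
  # without merging both windows remain
  expect_equal(nrow(build_windows(tas2, 1.5e6, merge = FALSE)), 2)
  # clipping at chromosome bounds
  w3 <- build_windows(tibble::tibble(chrom = "chr1", pos = 100), 1e6,
                      chrom_lengths = c(chr1 = 5000))
  expect_equal(w3$start, 0)
  expect_equal(w3$end, 5000)
})

test_that("window series are monotone nested in size", {
  set.seed(61)
  tas <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
                        pos = sample.int(2e7, 15))
  sizes <- c(0.5e6, 1e6, 1.5e6, 2e6)
  genes <- toy_genes()
  hits <- sapply(sizes, function(s) {
    sum(basecomp:::genes_in_windows(genes, build_windows(tas, s)))
  })
  expect_true(all(diff(hits) >= 0))
})

test_that("1 Mb tiles report only >= 5 TASs and conserve counts", {
  tas5 <- tibble::tibble(chrom = "chr1",
                         pos = c(3100000, 3200000, 3300000, 3400000, 3500000))
  r5 <- tabulate_tas_regions(tas5)
  expect_equal(nrow(r5), 1)
  expect_equal(r5$n_tas, 5L)
  expect_equal(r5$start, 3e6)
  r4 <- tabulate_tas_regions(tas5[1:4, ])
  expect_equal(nrow(r4), 0)
  # boundary straddling: each TAS in exactly one tile
  tas_b <- tibble::tibble(chrom = "chr1", pos = c(999999, 1000000, 1000001))
  all_tiles <- tabulate_tas_regions(tas_b, min_count = 1)
  expect_equal(sum(all_tiles$n_tas), 3L)
  expect_equal(all_tiles$n_tas, c(2L, 1L))  # pos 1e6 is the last bp of tile 1
  # empty input is an empty result, not an error
  expect_equal(nrow(tabulate_tas_regions(tas5[0, ])), 0)
})

test_that("term enrichment produces the hand-computed odds ratio", {
  # construct a universe realising the 2x2 table (10, 90, 100, 9900)
  genes <- tibble::tibble(
    gene_id = sprintf("g%05d", 1:10100),
    chrom = "chr1",
    start = seq(0, by = 1000, length.out = 10100),
    end = seq(0, by = 1000, length.out = 10100) + 500)
  # windows covering exactly the first 100 genes (window = [0, 99400))
  windows <- build_windows(tibble::tibble(chrom = "chr1", pos = 1), 198800)
  inw <- basecomp:::genes_in_windows(genes, windows)
  expect_equal(sum(inw), 100)
  terms <- tibble::tibble(
    gene_id = c(genes$gene_id[inw][1:10], genes$gene_id[!inw][1:100]),
    term = "t1")
  enr <- term_enrichment(windows, genes, terms)
  expect_equal(enr$odds_ratio, (10 * 9900) / (90 * 100))  # 11.0
  expect_equal(enr$n_in_with, 10L)
  # no in-window gene with the term: odds ratio 0, p = 1
  terms0 <- tibble::tibble(gene_id = genes$gene_id[!inw][1:50], term = "t2")
  enr0 <- term_enrichment(windows, genes, terms0)
  expect_equal(enr0$odds_ratio, 0)
  expect_equal(enr0$p_value, 1)
})

test_that("term enrichment equals brute-force enumeration on small universes", {
  set.seed(62)
  n_g <- 80
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n_g),
    chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
    start = sample.int(5e6, n_g))
  genes$end <- genes$start + sample.int(2e4, n_g)
  terms <- tibble::tibble(
    gene_id = sample(genes$gene_id, 150, replace = TRUE),
    term = sample(paste0("t", 1:6), 150, replace = TRUE))
  tas <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                        pos = sample.int(5e6, 8))
  windows <- build_windows(tas, 8e5)
  got <- term_enrichment(windows, genes, terms)
  # brute force: per-gene window membership by scanning every interval pair
  in_win <- sapply(seq_len(n_g), function(i) {
    any(windows$chrom == genes$chrom[i] &
          windows$start < genes$end[i] &
          windows$end > genes$start[i])
  })
  for (tm in unique(terms$term)) {
    with_t <- genes$gene_id %in% terms$gene_id[terms$term == tm]
    a <- sum(in_win & with_t); b <- sum(in_win & !with_t)
    cc <- sum(!in_win & with_t); d <- sum(!in_win & !with_t)
    row <- got[got$term == tm, ]
    expect_equal(c(row$n_in_with, row$n_in_without,
                   row$n_out_with, row$n_out_without), c(a, b, cc, d))
    expect_equal(row$odds_ratio,
                 if (b * cc > 0) a * d / (b * cc) else if (a * d > 0) Inf else 0)
    # hypergeometric tail identity for the one-sided Fisher p
    expect_equal(row$p_value,
                 phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE))
    expect_equal(a + b + cc + d, n_g)
  }
})

test_that("gene tagging applies the >=2 / >=3 rules and matches brute force", {
  genes <- toy_genes()
  # place 2 TASs within 750 kb of gene g01 ([0, 5e5)), 3 near g02
  tas <- tibble::tibble(
    chrom = "chr1",
    pos = c(6e5, 7e5,                      # tag g01 (2x)
            1e6 + c(6e5, 7e5, 7.5e5)))     # tag g02 ([1e6, 1.5e6)) (3x)
  tg <- gene_tagging(genes, tas, size = 1.5e6)
  expect_true(tg$tagged[tg$gene_id == "g01"])
  expect_false(tg$tagged_repair[tg$gene_id == "g01"])
  expect_true(tg$tagged[tg$gene_id == "g02"])
  expect_true(tg$tagged_repair[tg$gene_id == "g02"])
  # brute-force all-pairs oracle on a random map
  set.seed(63)
  rg <- tibble::tibble(gene_id = paste0("r", 1:30),
                       chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                       start = sample.int(1e7, 30))
  rg$end <- rg$start + sample.int(5e4, 30)
  rt <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 25, replace = TRUE),
                       pos = sample.int(1e7, 25))
  size <- 1e6
  tg2 <- gene_tagging(rg, rt, size)
  for (i in 1:30) {
    cnt <- sum(rt$chrom == rg$chrom[i] &
                 rt$pos > rg$start[i] - size / 2 &
                 rt$pos <= rg$end[i] + size / 2)
    expect_equal(tg2$n_tas[i], cnt)
  }
})

test_that("repair-gene enrichment handles the toy and degenerate tables", {
  # toy universe: 20 genes, 4 repair, 5 in windows of which 3 repair
  genes <- toy_genes()
  # windows covering genes g01..g05 exactly (chr1 0..4.5e6)
  tas <- tibble::tibble(chrom = "chr1", pos = 2.25e6)
  win_size <- 4.8e6
  inw <- basecomp:::genes_in_windows(genes, build_windows(tas, win_size))
  expect_equal(sum(inw), 5)
  repair <- c(genes$gene_id[inw][1:3], genes$gene_id[!inw][1])
  enr <- repair_gene_enrichment(genes, tas, repair, sizes = win_size)
  expect_equal(enr$odds_ratio, (3 / 2) / (1 / 14))  # 21.0
  expect_equal(enr$p_value,
               phyper(2, 4, 16, 5, lower.tail = FALSE))
  # all repair genes inside, none outside: infinite odds ratio
  enr_inf <- repair_gene_enrichment(genes, tas, genes$gene_id[inw][1:3],
                                    sizes = win_size)
  expect_true(is.infinite(enr_inf$odds_ratio))
  expect_lt(enr_inf$p_value, 1)
  expect_error(repair_gene_enrichment(genes, tas, character(0)), "non-empty")
  expect_error(repair_gene_enrichment(genes, tas, "nope"), "universe")
})

test_that("enrichment p-values control type I error under random TAS placement", {
  set.seed(64)
  ann <- simulate_gene_annotation(n_genes = 400, n_terms = 100,
                                  terms_per_gene = 4, seed = 65)
  tas <- tibble::tibble(chrom = paste0("chr", sample.int(5, 25, replace = TRUE)),
                        pos = sample.int(2e7, 25))
  enr <- term_enrichment(build_windows(tas, 1e6), ann$genes, ann$terms)
  alpha <- 0.05
  frac_sig <- mean(enr$p_value < alpha)
  tol <- 3 * sqrt(alpha * (1 - alpha) / nrow(enr))
  expect_lte(frac_sig, alpha + tol)
})

test_that("repair enrichment is near-null when repair genes are placed at random", {
  set.seed(66)
  ors <- replicate(20, {
    ann <- simulate_gene_annotation(n_genes = 300, seed = sample.int(1e6, 1))
    tas <- tibble::tibble(chrom = paste0("chr", sample.int(5, 20, TRUE)),
                          pos = sample.int(2e7, 20))
    repair <- sample(ann$genes$gene_id, 30)
    repair_gene_enrichment(ann$genes, tas, repair, sizes = 1.5e6)$odds_ratio
  })
  ors <- ors[is.finite(ors) & ors > 0]
  expect_lt(abs(mean(log(ors[ors > 0]))), 0.75)
})
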