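#' Simulate a gene annotation to accompany a simulated population
#'
#' Random non-overlapping gene intervals on the simulated chromosomes, a
#' random many-to-many term assignment, and a designated repair-gene subset,
#' so the enrichment stage can run end to end on synthetic data. The
#' annotation is synthetic: gene placement is independent of the variants,
#' so enrichment results on it demonstrate the machinery and its type-I
#' behaviour, not biology.
#'
#' @param n_genes Number of genes.
#' @param n_chrom,chrom_length Chromosome layout (match the population
#'   simulation's).
#' @param gene_length Mean gene length in bp (exponential).
#' @param n_terms Number of annotation terms.
#' @param terms_per_gene Mean number of terms per gene (Poisson, >= 1).
#' @param repair_frac Fraction of genes designated DNA-repair genes.
#' @param seed Integer seed.
#' @return List: `genes` (tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `is_repair_gene`), `terms` (tibble: `gene_id`, `term`), `repair_genes`
#'   (character vector).
#' @export
simulate_gene_annotation <- function(n_genes = 500, n_chrom = 5,
                                     chrom_length = 2e7, gene_length = 3e4,
                                     n_terms = 40, terms_per_gene = 3,
                                     repair_frac = 0.08, seed = 1L) {
  set.seed(seed)
  chrom <- sort(sample(seq_len(n_chrom), n_genes, replace = TRUE))
  start <- floor(runif(n_genes, 0, chrom_length - 10 * gene_length))
  len <- pmax(200, stats::rexp(n_genes, 1 / gene_length))
  genes <- tibble(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    chrom = paste0("chr", chrom),
    start = start, end = pmin(start + round(len), chrom_length)) |>
    arrange(chrom, start)
  repair_genes <- sort(sample(genes$gene_id, max(2, round(repair_frac * n_genes))))
  genes$is_repair_gene <- genes$gene_id %in% repair_genes
  term_ids <- sprintf("term_%03d", seq_len(n_terms))
  terms <- purrr::map_dfr(genes$gene_id, function(g) {
    k <- max(1, stats::rpois(1, terms_per_gene))
    tibble(gene_id = g, term = sample(term_ids, min(k, n_terms)))
  })
  list(genes = genes, terms = terms, repair_genes = repair_genes)
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for all stage files.
#' @param sim A [pop_sim_config()] for the simulation stage, or `NULL` when
#'   `vcf`/`groups_file` point at existing inputs.
#' @param vcf,groups_file Paths to an existing VCF and sample-group TSV
#'   (used instead of simulation when given).
#' @param filters A [filter_config()].
#' @param scan_model `"mixed"`, `"linear"` or `"linear+PC"`.
#' @param pcs PC numbers used as scan covariates (default `2:6`).
#' @param threshold `"bonferroni"` or `"switch_sim"`.
#' @param alpha Family-wise error rate for the Bonferroni rule.
#' @param tas_percentile,switch_proportions,switch_reps Allele-switching
#'   threshold settings (used when `threshold = "switch_sim"`).
#' @param window_sizes Enrichment window-size series in bp.
#' @param region_size,region_min_count TAS-region tabulation settings.
#' @param annotation `NULL` (simulate one) or a list with `genes`, `terms`,
#'   `repair_genes` as produced by [simulate_gene_annotation()].
#' @param seed Integer seed governing every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("basecomp_run_"),
                       sim = pop_sim_config(), vcf = NULL, groups_file = NULL,
                       filters = filter_config(),
                       scan_model = "mixed", pcs = 2:6,
                       threshold = "bonferroni", alpha = 0.05,
                       tas_percentile = 0.975,
                       switch_proportions = seq(0, 0.5, by = 0.1),
                       switch_reps = 200,
                       window_sizes = c(0.5e6, 1e6, 1.5e6, 2e6),
                       region_size = 1e6, region_min_count = 5,
                       annotation = NULL, seed = 1L) {
  scan_model <- match.arg(scan_model, c("mixed", "linear", "linear+PC"))
  threshold <- match.arg(threshold, c("bonferroni", "switch_sim"))
  structure(list(out_dir = out_dir, sim = sim, vcf = vcf,
                 groups_file = groups_file, filters = filters,
                 scan_model = scan_model, pcs = pcs, threshold = threshold,
                 alpha = alpha, tas_percentile = tas_percentile,
                 switch_proportions = switch_proportions,
                 switch_reps = switch_reps, window_sizes = window_sizes,
                 region_size = region_size,
                 region_min_count = region_min_count,
                 annotation = annotation, seed = as.integer(seed)),
            class = "run_config")
}

#' A ready-made demonstration configuration
#'
#' Small enough to run in seconds: the default simulated bottleneck
#' population with a planted bias-modifier locus, the mixed-model scan, and
#' enrichment against a simulated annotation.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return A [run_config()].
#' @export
demo_config <- function(out_dir = tempfile("basecomp_demo_"), seed = 1L) {
  run_config(
    out_dir = out_dir,
    sim = pop_sim_config(n_snps = 6000, n_basal = 50, n_derived = 50,
                         modifier = list(delta = 0.6, frac_sites = 0.1,
                                         freq = 0.3),
                         seed = child_seed(seed, 1)),
    switch_reps = 200,
    seed = seed)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or load) genotypes; filter sites;
#' compute the base-composition phenotype; PCA and kinship; genome scan;
#' significance threshold and TAS flagging; TAS-region tabulation; term and
#' repair-gene enrichment. Every output file is TSV/JSON, listed with its
#' MD5 checksum in the returned manifest; rerunning with the same
#' configuration and seed reproduces the checksums.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return List of class `pipeline_run`: stage results (`sim`, `vset`,
#'   `phenotype`, `pca`, `kinship`, `scan`, `threshold`, `tas_regions`,
#'   `term_enrichment`, `repair_enrichment`) plus `manifest` (tibble:
#'   `file`, `md5`).
#' @export
run_pipeline <- function(config = demo_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config().")
  say <- function(...) if (!quiet) message(sprintf(...))
  t_all <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  keep <- function(x) { files <<- c(files, x); x }

  # --- inputs: simulate or load ------------------------------------------
  if (is.null(config$vcf)) {
    say("stage simulate: %d + %d samples, %d SNPs",
        config$sim$n_basal, config$sim$n_derived, config$sim$n_snps)
    sim <- simulate_populations(config$sim)
    paths <- write_sim(sim, config$out_dir)
    keep(paths)
    vcf_path <- paths[["vcf"]]
    groups <- sim$groups
  } else {
    if (!file.exists(config$vcf)) {
      abort(sprintf("stage load: VCF not found: %s", config$vcf))
    }
    if (is.null(config$groups_file) || !file.exists(config$groups_file)) {
      abort("stage load: `groups_file` is required and must exist.")
    }
    sim <- NULL
    vcf_path <- config$vcf
    groups <- readr::read_tsv(config$groups_file, show_col_types = FALSE)
  }

  say("stage filter: loading %s", basename(vcf_path))
  vset <- load_variants(vcf_path, config$filters, groups = groups)
  readr::write_tsv(vset$report,
                   keep(file.path(config$out_dir, "filter_report.tsv")))

  say("stage phenotype: %d samples x %d sites",
      nrow(vset$genotypes), ncol(vset$genotypes))
  pheno <- base_phenotype(vset)
  readr::write_tsv(left_join(pheno, groups, by = "sample"),
                   keep(file.path(config$out_dir, "phenotype.tsv")))

  say("stage structure: PCA + kinship")
  k_pcs <- max(config$pcs, 2)
  pca <- genotype_pca(vset$genotypes, k = min(k_pcs, nrow(pheno) - 1))
  kin <- compute_kinship(vset$genotypes)

  say("stage scan: %s model", config$scan_model)
  covar <- pc_covariates(pca, config$pcs)
  scan <- switch(config$scan_model,
    mixed = mixed_scan(pheno, vset$genotypes, kin, covariates = covar,
                       variants = vset$variants),
    linear = linear_scan(pheno, vset$genotypes, variants = vset$variants),
    `linear+PC` = linear_scan(pheno, vset$genotypes, covariates = covar,
                              variants = vset$variants))

  say("stage threshold: %s", config$threshold)
  if (config$threshold == "bonferroni") {
    thr <- bonferroni_threshold(nrow(scan), config$alpha)
    scan <- flag_tas(scan, p_threshold = thr$p_threshold)
  } else {
    thr <- allele_switch_threshold(
      pheno, groups, proportions = config$switch_proportions,
      reps = config$switch_reps, percentile = config$tas_percentile,
      seed = child_seed(config$seed, 2))
    scan <- flag_tas(scan, f_threshold = thr$threshold)
  }
  readr::write_tsv(scan, keep(file.path(config$out_dir, "scan.tsv")))

  tas <- filter(scan, is_tas)
  say("stage regions: %d TASs", nrow(tas))
  regions <- tabulate_tas_regions(tas, config$region_size,
                                  config$region_min_count)
  readr::write_tsv(regions, keep(file.path(config$out_dir, "tas_regions.tsv")))

  say("stage enrichment: %d window size(s)", length(config$window_sizes))
  ann <- config$annotation %||% simulate_gene_annotation(
    n_chrom = if (!is.null(sim)) config$sim$n_chrom else 5,
    chrom_length = if (!is.null(sim)) config$sim$chrom_length else 2e7,
    seed = child_seed(config$seed, 3))
  enr <- purrr::map_dfr(config$window_sizes, function(s) {
    win <- build_windows(tas, s)
    bind_cols(tibble(size = s), term_enrichment(win, ann$genes, ann$terms))
  })
  rep_enr <- repair_gene_enrichment(ann$genes, tas, ann$repair_genes,
                                    sizes = config$window_sizes)
  readr::write_tsv(enr, keep(file.path(config$out_dir, "term_enrichment.tsv")))
  readr::write_tsv(rep_enr,
                   keep(file.path(config$out_dir, "repair_enrichment.tsv")))

  manifest <- tibble(file = unname(files),
                     md5 = unname(tools::md5sum(unname(files))))
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  say("done in %.1f s", as.numeric(Sys.time() - t_all, units = "secs"))
  structure(list(sim = sim, vset = vset, phenotype = pheno, pca = pca,
                 kinship = kin, scan = scan, threshold = thr,
                 tas_regions = regions, term_enrichment = enr,
                 repair_enrichment = rep_enr, manifest = manifest,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("basecomp pipeline run\n")
  cat(sprintf("  %d samples x %d SNPs after filtering\n",
              nrow(x$vset$genotypes), ncol(x$vset$genotypes)))
  cat(sprintf("  scan model: %s; TASs: %d\n",
              x$scan$model[1], sum(x$scan$is_tas, na.rm = TRUE)))
  cat(sprintf("  outputs: %s\n", x$config$out_dir))
  invisible(x)
}
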