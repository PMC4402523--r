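#' Configuration for the population simulator
#'
#' Describes two populations (a large "basal" group and a "derived" group
#' separated from it by a bottleneck) genotyped at biallelic SNPs whose
#' ref/alt bases arise from a strand-symmetric mutation spectrum. The
#' simulator is a frequency-level Wright-Fisher model: shared variants start
#' from a neutral ancestral frequency and the derived group's frequency
#' drifts for `bottleneck_gen` generations at size `bottleneck_n`; each group
#' additionally carries private variants. All variants are conditioned on
#' passing the default call-rate/MAF filters in the combined sample, which is
#' what makes surviving derived-private alleles drift upwards in frequency
#' and — under an AT-biased spectrum — produces the derived-group A&T
#' increase.
#'
#' @param n_basal,n_derived Diploid sample counts per group.
#' @param n_snps Target number of SNPs (before any modifier-linked extras).
#' @param shared_frac Fraction of SNPs polymorphic in both groups; the rest
#'   are split equally into basal-private and derived-private.
#' @param spectrum A [mutation_spectrum()]; default AT-biased with
#'   `at_bias = 2`.
#' @param ancestral_comp Genome base composition the ancestral (ref) alleles
#'   are drawn from. The default is uniform — the equilibrium of every
#'   base-symmetric spectrum — so that `at_bias = 1` gives exactly zero net
#'   AT flux and `at_bias > 1` a positive one; set a skewed composition to
#'   emulate genomes away from that equilibrium.
#' @param sfs_range,private_sfs_range Frequency support of the discretised
#'   neutral site-frequency spectrum (density proportional to 1/x) used for
#'   shared and private variants respectively.
#' @param bottleneck_n,bottleneck_gen Bottleneck effective size (diploids)
#'   and its duration in generations of binomial drift.
#' @param min_maf Minor-allele-frequency floor (in the combined genotyped
#'   sample) every emitted variant is conditioned to pass.
#' @param missing_rate Per-genotype missingness probability.
#' @param n_chrom Number of chromosomes variants are spread over.
#' @param chrom_length Length (bp) of each simulated chromosome.
#' @param modifier `NULL`, or a list with elements `delta` (relative
#'   amplification of the AT mutation bias per carried modifier allele,
#'   applied as `1 + delta * dosage/2`), `frac_sites` (number of
#'   modifier-sensitive extra sites as a fraction of `n_snps`) and `freq`
#'   (modifier allele frequency, equal in both groups). See
#'   [simulate_populations()].
#' @param seed Integer seed; the entire output is reproducible from it.
#' @return A list of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_basal = 100, n_derived = 100, n_snps = 50000,
                           shared_frac = 0.6,
                           spectrum = mutation_spectrum(at_bias = 2),
                           ancestral_comp = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                           sfs_range = c(0.05, 0.95),
                           private_sfs_range = c(0.02, 0.5),
                           bottleneck_n = 30, bottleneck_gen = 45,
                           min_maf = 0.05, missing_rate = 0,
                           n_chrom = 5, chrom_length = 2e7,
                           modifier = NULL, seed = 1L) {
  stopifnot(n_basal > 1, n_derived > 1, n_snps > 0,
            shared_frac >= 0, shared_frac <= 1,
            bottleneck_n >= 1, bottleneck_gen >= 0,
            min_maf >= 0, min_maf < 0.5, missing_rate >= 0, missing_rate < 1)
  if (!is_strand_symmetric(spectrum)) {
    abort("`spectrum` must be strand-symmetric.")
  }
  if (!is.null(modifier)) {
    modifier <- utils::modifyList(
      list(delta = 0.6, frac_sites = 0.1, freq = 0.3), modifier)
    stopifnot(modifier$delta >= 0, modifier$frac_sites > 0,
              modifier$freq > 0, modifier$freq < 1)
  }
  structure(
    list(n_basal = n_basal, n_derived = n_derived, n_snps = n_snps,
         shared_frac = shared_frac, spectrum = spectrum,
         ancestral_comp = ancestral_comp[BASES], sfs_range = sfs_range,
         private_sfs_range = private_sfs_range,
         bottleneck_n = bottleneck_n, bottleneck_gen = bottleneck_gen,
         min_maf = min_maf, missing_rate = missing_rate,
         n_chrom = n_chrom, chrom_length = chrom_length,
         modifier = modifier, seed = as.integer(seed)),
    class = "pop_sim_config")
}

# draw from a discretised neutral SFS: density ~ 1/x on [lo, hi]
rsfs <- function(n, range) {
  lo <- range[1]; hi <- range[2]
  u <- runif(n)
  lo * (hi / lo)^u   # inverse CDF of the 1/x density
}

# g generations of Wright-Fisher binomial drift at diploid size n_e
drift_freq <- function(p, n_e, g) {
  two_n <- 2 * n_e
  for (i in seq_len(g)) {
    p <- rbinom(length(p), two_n, p) / two_n
  }
  p
}

#' Simulate bottleneck-diverged populations genotyped at biallelic SNPs
#'
#' See [pop_sim_config()] for the model. When a bias-modifier locus is
#' configured, one extra biallelic SNP (the modifier, equal-frequency in both
#' groups) plus a block of modifier-sensitive sites are appended: at those
#' sites the alt allele is drawn from the spectrum with its AT bias amplified
#' by `1 + delta`, and each individual's alt-allele frequency is scaled by
#' `1 + delta * dosage/2` where `dosage` is the individual's modifier count.
#' Carriers therefore accumulate extra AT alleles, making the modifier a
#' causal locus for the base-composition phenotype that a genome scan should
#' recover.
#'
#' @param config A [pop_sim_config()].
#' @return A list of class `pop_sim` with elements `variants` (tibble: `id`,
#'   `chrom`, `pos`, `ref`, `alt`, `origin`), `genotypes` (integer matrix,
#'   samples x variants, alt-allele dosage 0/1/2, `NA` missing), `groups`
#'   (tibble: `sample`, `group`, `role`), and `truth` (ground-truth list:
#'   config, seed, modifier id/effect, per-variant origin).
#' @export
simulate_populations <- function(config = pop_sim_config()) {
  if (!inherits(config, "pop_sim_config")) {
    abort("`config` must come from pop_sim_config().")
  }
  set.seed(config$seed)
  n_b <- config$n_basal; n_d <- config$n_derived; n <- n_b + n_d

  n_shared <- round(config$n_snps * config$shared_frac)
  n_priv <- config$n_snps - n_shared
  n_pb <- floor(n_priv / 2)
  n_pd <- n_priv - n_pb
  origin <- c(rep("shared", n_shared),
              rep("private_basal", n_pb),
              rep("private_derived", n_pd))
  m <- length(origin)

  draw_freqs <- function(idx) {
    p_b <- numeric(length(idx)); p_d <- numeric(length(idx))
    o <- origin[idx]
    sh <- o == "shared"
    if (any(sh)) {
      p0 <- rsfs(sum(sh), config$sfs_range)
      p_b[sh] <- p0
      p_d[sh] <- drift_freq(p0, config$bottleneck_n, config$bottleneck_gen)
    }
    pb <- o == "private_basal"
    if (any(pb)) {
      p_b[pb] <- rsfs(sum(pb), config$private_sfs_range)
      p_d[pb] <- 0
    }
    pd <- o == "private_derived"
    if (any(pd)) {
      p0 <- rsfs(sum(pd), config$private_sfs_range)
      p_b[pd] <- 0
      p_d[pd] <- drift_freq(p0, config$bottleneck_n, config$bottleneck_gen)
    }
    list(p_b = p_b, p_d = p_d)
  }

  draw_geno <- function(p_b, p_d) {
    k <- length(p_b)
    g_b <- matrix(rbinom(n_b * k, 2, rep(p_b, each = n_b)), nrow = n_b)
    g_d <- matrix(rbinom(n_d * k, 2, rep(p_d, each = n_d)), nrow = n_d)
    rbind(g_b, g_d)
  }

  # draw, then redraw any site failing the empirical polymorphism/MAF
  # condition so the emitted table passes the default filters
  geno <- matrix(NA_integer_, n, m)
  todo <- seq_len(m)
  for (round in 1:200) {
    fr <- draw_freqs(todo)
    geno[, todo] <- draw_geno(fr$p_b, fr$p_d)
    af <- colMeans(geno[, todo, drop = FALSE]) / 2
    maf <- pmin(af, 1 - af)
    ok <- maf >= config$min_maf & maf > 0
    todo <- todo[!ok]
    if (length(todo) == 0) break
  }
  if (length(todo) > 0) {
    abort(paste0("could not realise ", length(todo), " site(s) passing the ",
                 "MAF condition; lower `min_maf`, raise sample sizes, or ",
                 "widen the SFS range."))
  }

  # ref = ancestral allele drawn from the genome composition,
  # alt via the two-strand mutation mechanism
  ref <- sample(BASES, m, replace = TRUE, prob = config$ancestral_comp)
  alt <- draw_mutation(ref, config$spectrum)$alt

  truth_modifier <- NULL
  if (!is.null(config$modifier)) {
    mod <- config$modifier
    n_mod <- max(1, round(config$n_snps * mod$frac_sites))
    d_mod <- rbinom(n, 2, mod$freq)                 # modifier dosage
    while (var(d_mod) == 0) d_mod <- rbinom(n, 2, mod$freq)
    # amplified spectrum: multiply the configured spectrum's AT bias by 1+delta
    amp_m <- unclass(config$spectrum)
    amp_m[, c("A", "T")] <- amp_m[, c("A", "T")] * (1 + mod$delta)
    amp_spec <- structure(amp_m, class = c("mutation_spectrum", "matrix"),
                          at_bias = sum(amp_m[, c("A", "T")]) /
                                    sum(amp_m[, c("C", "G")]))
    # modifier-sensitive sites carry the AT-gaining mutation flux the
    # modifier amplifies: GC reference base, AT alternative allele drawn
    # from the amplified spectrum conditional on that flow; carriers'
    # alt-allele frequency is scaled by 1 + delta * dosage/2
    p_mod <- runif(n_mod, 0.1, 0.4)
    w <- 1 + mod$delta * d_mod / 2                  # per-individual scaling
    pm <- outer(w, p_mod)                           # n x n_mod allele prob
    pm[pm > 0.95] <- 0.95
    g_extra <- matrix(rbinom(n * n_mod, 2, pm), n, n_mod)
    gc_comp <- config$ancestral_comp[c("C", "G")]
    ref_extra <- sample(c("C", "G"), n_mod, replace = TRUE,
                        prob = gc_comp / sum(gc_comp))
    alt_extra <- draw_mutation(ref_extra, amp_spec)$alt
    for (i in 1:50) {                               # condition on AT-gain
      redo <- !(alt_extra %in% c("A", "T"))
      if (!any(redo)) break
      alt_extra[redo] <- draw_mutation(ref_extra[redo], amp_spec)$alt
    }
    keep_at <- alt_extra %in% c("A", "T")
    g_extra <- g_extra[, keep_at, drop = FALSE]
    ref_extra <- ref_extra[keep_at]; alt_extra <- alt_extra[keep_at]
    n_mod <- sum(keep_at)

    geno <- cbind(geno, d_mod, g_extra)
    mref <- sample(BASES, 1, prob = config$ancestral_comp)
    ref <- c(ref, mref, ref_extra)
    alt <- c(alt, sample(setdiff(BASES, mref), 1), alt_extra)
    origin <- c(origin, "modifier", rep("modifier_sensitive", n_mod))
    m <- length(origin)
  }

  # lay variants on chromosomes: coordinates in genome order, variants
  # assigned to them at random so variant origin is independent of position
  chrom <- sort(sample(seq_len(config$n_chrom), m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
    sort(sample.int(config$chrom_length, length(ix)))
  }), use.names = FALSE)
  vidx <- sample.int(m)
  id <- sprintf("snp_%05d", seq_len(m))

  variants <- tibble(id = id,
                     chrom = paste0("chr", chrom),
                     pos = pos, ref = ref[vidx], alt = alt[vidx],
                     origin = origin[vidx])
  geno <- geno[, vidx, drop = FALSE]

  if (config$missing_rate > 0) {
    geno[runif(length(geno)) < config$missing_rate] <- NA_integer_
  }
  samples <- c(sprintf("basal_%03d", seq_len(n_b)),
               sprintf("derived_%03d", seq_len(n_d)))
  dimnames(geno) <- list(samples, variants$id)

  groups <- tibble(sample = samples,
                   group = c(rep("basal", n_b), rep("derived", n_d)),
                   role = c(rep("basal", n_b), rep("derived", n_d)))

  if (!is.null(config$modifier)) {
    truth_modifier <- list(id = variants$id[variants$origin == "modifier"],
                           delta = config$modifier$delta,
                           dosage = setNames(geno[, variants$id[
                             variants$origin == "modifier"]], samples))
  }
  structure(list(
    variants = variants,
    genotypes = geno,
    groups = groups,
    truth = list(config = config, seed = config$seed,
                 spectrum = config$spectrum,
                 origin = setNames(variants$origin, variants$id),
                 modifier = truth_modifier)
  ), class = "pop_sim")
}

#' @export
print.pop_sim <- function(x, ...) {
  cat(sprintf("Simulated population: %d samples x %d SNPs (%d basal, %d derived)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$groups$role == "basal"), sum(x$groups$role == "derived")))
  if (!is.null(x$truth$modifier)) {
    cat(sprintf("bias-modifier locus: %s (delta = %.2f)\n",
                x$truth$modifier$id, x$truth$modifier$delta))
  }
  invisible(x)
}

#' Write a simulated population to VCF, groups TSV and truth JSON
#'
#' The VCF is plain-text VCFv4.2 with GT-only genotype columns, readable by
#' any standard VCF reader (including [load_variants()]).
#'
#' @param sim A `pop_sim` from [simulate_populations()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  groups_path <- file.path(dir, paste0(prefix, "_groups.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))

  gt <- t(sim$genotypes)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
  gt_str[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=basecomp-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(sim$genotypes)), collapse = "\t"))
  body <- paste(sim$variants$chrom, sim$variants$pos, sim$variants$id,
                sim$variants$ref, sim$variants$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  readr::write_tsv(sim$groups, groups_path)
  jsonlite::write_json(
    list(seed = sim$truth$seed,
         n_basal = sum(sim$groups$role == "basal"),
         n_derived = sum(sim$groups$role == "derived"),
         at_bias = attr(sim$truth$spectrum, "at_bias"),
         origin = as.list(table(sim$variants$origin)),
         modifier = if (is.null(sim$truth$modifier)) NULL else
           sim$truth$modifier[c("id", "delta")]),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(vcf = vcf_path, groups = groups_path, truth = truth_path))
}

#' Configuration for the mutation-accumulation simulator
#'
#' @param genome_length Ancestor genome length in bp (>= 1e4).
#' @param n_lines Number of independently propagated lines.
#' @param muts_per_line New mutations per line.
#' @param composition Ancestor base composition.
#' @param spectrum [mutation_spectrum()] generating the mutations.
#' @param seed Integer seed.
#' @return A list of class `mut_accum_config`.
#' @export
mut_accum_config <- function(genome_length = 5e4, n_lines = 10,
                             muts_per_line = 200,
                             composition = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                             spectrum = mutation_spectrum(at_bias = 2),
                             seed = 1L) {
  stopifnot(genome_length >= 1e4, n_lines >= 1, muts_per_line >= 1)
  if (muts_per_line > genome_length) {
    abort("`muts_per_line` cannot exceed `genome_length`.")
  }
  structure(list(genome_length = genome_length, n_lines = n_lines,
                 muts_per_line = muts_per_line,
                 composition = composition[BASES], spectrum = spectrum,
                 seed = as.integer(seed)),
            class = "mut_accum_config")
}

#' Simulate mutation-accumulation lines from a common ancestor
#'
#' Draws one ancestor sequence, then gives each line an independent set of
#' point mutations (uniform positions without replacement, substitution via
#' [draw_mutation()]). The mutation table feeds
#' [mutation_site_composition()] to reproduce the derived-vs-ancestor
#' composition contrast seen in mutation-accumulation experiments.
#'
#' @param config A [mut_accum_config()].
#' @return List of class `mut_accum_sim`: `ancestor` (character string),
#'   `mutations` (tibble: `line`, `chrom`, `pos`, `ref`, `alt`), `truth`.
#' @export
simulate_mut_accum <- function(config = mut_accum_config()) {
  if (!inherits(config, "mut_accum_config")) {
    abort("`config` must come from mut_accum_config().")
  }
  set.seed(config$seed)
  anc <- paste(sample(BASES, config$genome_length, replace = TRUE,
                      prob = config$composition), collapse = "")
  anc_vec <- strsplit(anc, "")[[1]]
  mutations <- purrr::map_dfr(seq_len(config$n_lines), function(l) {
    pos <- sort(sample.int(config$genome_length, config$muts_per_line))
    ref <- anc_vec[pos]
    alt <- draw_mutation(ref, config$spectrum)$alt
    tibble(line = sprintf("line_%02d", l), chrom = "ancestor",
           pos = pos, ref = ref, alt = alt)
  })
  structure(list(ancestor = anc, mutations = mutations,
                 truth = list(config = config, seed = config$seed)),
            class = "mut_accum_sim")
}

#' Write a mutation-accumulation simulation to FASTA + TSV
#'
#' @param sim A `mut_accum_sim`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_mut_accum <- function(sim, dir, prefix = "mutaccum") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, "_ancestor.fasta"))
  tsv <- file.path(dir, paste0(prefix, "_mutations.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(ancestor = sim$ancestor)), fa)
  readr::write_tsv(sim$mutations, tsv)
  invisible(c(fasta = fa, mutations = tsv))
}
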