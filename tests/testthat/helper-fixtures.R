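# Shared fixtures, all built in code at test time.

# a small hand-written VCF covering every filter rule:
# 10 records: 1 indel, 1 triallelic, 2 low call rate, 2 MAF < 5%, 4 clean
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  samples <- sprintf("s%02d", 1:20)
  gt <- function(...) paste(c(...), collapse = "\t")
  het_one <- function() c("0/1", rep("0/0", 19))       # MAF 1/40 < 5%
  common <- function() c(rep("0/1", 8), rep("0/0", 12)) # MAF 0.2
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste("chr1", 100, "v_indel", "A", "AT", ".", ".", ".", "GT",
          gt(common()), sep = "\t"),
    paste("chr1", 200, "v_tri", "A", "C,G", ".", ".", ".", "GT",
          gt(common()), sep = "\t"),
    paste("chr1", 300, "v_lowcall1", "A", "G", ".", ".", ".", "GT",
          gt(c(rep("./.", 10), common()[1:10])), sep = "\t"),
    paste("chr1", 400, "v_lowcall2", "C", "T", ".", ".", ".", "GT",
          gt(rep("./.", 20)), sep = "\t"),
    paste("chr1", 500, "v_rare1", "A", "G", ".", ".", ".", "GT",
          gt(het_one()), sep = "\t"),
    paste("chr1", 600, "v_rare2", "C", "T", ".", ".", ".", "GT",
          gt(het_one()), sep = "\t"),
    paste("chr1", 700, "v_ok1", "A", "G", ".", ".", ".", "GT",
          gt(common()), sep = "\t"),
    paste("chr1", 800, "v_ok2", "C", "T", ".", ".", ".", "GT",
          gt(common()), sep = "\t"),
    paste("chr2", 100, "v_ok3", "G", "T", ".", ".", ".", "GT",
          gt(common()), sep = "\t"),
    paste("chr2", 200, "v_ok4", "T", "A", ".", ".", ".", "GT",
          gt(common()), sep = "\t"))
  writeLines(lines, path)
  path
}

# the worked 3-SNP phenotype example: SNPs A/G, C/T, A/C with genotypes
# AA, CT, AC for one individual
worked_variants <- function() {
  tibble::tibble(id = c("s1", "s2", "s3"),
                 chrom = "chr1", pos = c(10L, 20L, 30L),
                 ref = c("A", "C", "A"), alt = c("G", "T", "C"))
}
worked_genotypes <- function() {
  matrix(c(0L, 1L, 1L), nrow = 1,
         dimnames = list("ind1", c("s1", "s2", "s3")))
}

# independent per-character tally (oracle for count_bases)
tally_oracle <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"),
    excluded = sum(!ch %in% c("A", "C", "G", "T")))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T", "N"),
                       prob = c(0.24, 0.24, 0.24, 0.24, 0.04)) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# small simulated dataset reused by several structure/scan tests
small_sim <- function(seed = 11, n_snps = 2000, ...) {
  simulate_populations(pop_sim_config(
    n_basal = 30, n_derived = 30, n_snps = n_snps, seed = seed, ...))
}
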