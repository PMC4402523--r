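#' Tabulate fixed genomic tiles by trait-associated SNP count
#'
#' Divides each chromosome into non-overlapping fixed-size tiles (1 Mb by
#' default) and reports the tiles containing at least `min_count` TASs — the
#' "regions with five or more TASs" view of a genome scan. Tiles are
#' half-open `[start, end)` in 0-based coordinates; a TAS at 1-based
#' position p falls in tile `floor((p - 1)/size)`.
#'
#' @param tas Tibble with `chrom` and `pos` (1-based) of trait-associated
#'   SNPs, e.g. `dplyr::filter(flag_tas(scan, ...), is_tas)`.
#' @param region_size Tile width in bp (default 1e6).
#' @param min_count Minimum TAS count for a tile to be reported (default 5).
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open), `n_tas`.
#'   Empty input yields an empty tibble.
#' @export
tabulate_tas_regions <- function(tas, region_size = 1e6, min_count = 5) {
  if (nrow(tas) == 0) {
    return(tibble(chrom = character(), start = numeric(),
                  end = numeric(), n_tas = integer()))
  }
  assert_cols(tas, c("chrom", "pos"))
  tas |>
    mutate(tile = floor((pos - 1) / region_size)) |>
    count(chrom, tile, name = "n_tas") |>
    filter(n_tas >= min_count) |>
    mutate(start = tile * region_size, end = start + region_size) |>
    select(chrom, start, end, n_tas) |>
    arrange(chrom, start)
}

#' Build (and merge) windows centred on trait-associated SNPs
#'
#' Each TAS gets a window of `size` bp centred on it, `[pos - size/2,
#' pos + size/2)` in 0-based half-open coordinates, clipped at chromosome
#' bounds when supplied. Overlapping windows on a chromosome are merged so
#' clustered TASs do not multiply-count the genes they cover.
#'
#' @param tas Tibble with `chrom`, `pos` (1-based TAS positions).
#' @param size Window size in bp (e.g. `1.5e6`).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping.
#' @param merge Merge overlapping windows (default `TRUE`).
#' @return Tibble of class `tas_windows`: `chrom`, `start`, `end` (0-based
#'   half-open); attribute `size`.
#' @export
build_windows <- function(tas, size, chrom_lengths = NULL, merge = TRUE) {
  stopifnot(size > 0)
  assert_cols(tas, c("chrom", "pos"))
  win <- tas |>
    mutate(start = pmax(pos - 1 - size / 2, 0),
           end = pos - 1 + size / 2) |>
    select(chrom, start, end)
  if (!is.null(chrom_lengths)) {
    win <- mutate(win, end = pmin(end, chrom_lengths[chrom]))
  }
  if (merge && nrow(win) > 0) {
    win <- purrr::map_dfr(split(win, win$chrom), function(w) {
      ir <- IRanges::reduce(IRanges::IRanges(w$start + 1, w$end))
      tibble(chrom = w$chrom[1],
             start = IRanges::start(ir) - 1,
             end = as.numeric(IRanges::end(ir)))
    })
  }
  out <- arrange(win, chrom, start)
  attr(out, "size") <- size
  class(out) <- c("tas_windows", class(out))
  out
}

# logical: does each gene interval (0-based half-open) overlap any window?
genes_in_windows <- function(genes, windows, mode = c("any", "within")) {
  mode <- match.arg(mode)
  hit <- rep(FALSE, nrow(genes))
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) next
    wr <- IRanges::IRanges(w$start + 1, w$end)
    gr <- IRanges::IRanges(genes$start[gi] + 1, genes$end[gi])
    type <- if (mode == "any") "any" else "within"
    hit[gi] <- IRanges::overlapsAny(gr, wr, type = type)
  }
  hit
}

enrichment_2x2 <- function(in_window, has_term) {
  a <- sum(in_window & has_term)
  b <- sum(in_window & !has_term)
  c_ <- sum(!in_window & has_term)
  d <- sum(!in_window & !has_term)
  or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else 0
  p <- fisher.test(matrix(c(a, b, c_, d), 2), alternative = "greater")$p.value
  tibble(n_in_with = a, n_in_without = b,
         n_out_with = c_, n_out_without = d,
         odds_ratio = or, p_value = p)
}

#' Annotation-term over-representation in TAS windows
#'
#' For every annotation term (e.g. a GO id), compares the share of genes
#' carrying the term among genes inside the merged TAS windows against the
#' genome-wide share, via a one-sided Fisher's exact test on the gene-level
#' 2x2 table. The odds ratio is the sample cross-product `ad/bc` (infinite
#' when no out-of-window gene carries the term, 0 when no in-window gene
#' does). Raw p-values are reported, with a Benjamini-Hochberg column
#' alongside for convenience.
#'
#' @param windows A [build_windows()] result.
#' @param genes Gene tibble: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param terms Two-column tibble `gene_id`, `term` (a gene may carry many
#'   terms). Terms whose genes are absent from `genes` are skipped.
#' @param overlap `"any"` (default: a gene is in-window when its interval
#'   overlaps any merged window) or `"within"` (full containment).
#' @return Tibble: `term`, 2x2 counts, `odds_ratio`, `p_value`, `p_bh`,
#'   sorted by p-value.
#' @export
term_enrichment <- function(windows, genes, terms, overlap = "any") {
  assert_cols(genes, c("gene_id", "chrom", "start", "end"))
  assert_cols(terms, c("gene_id", "term"))
  if (nrow(genes) == 0) abort("the gene universe is empty.")
  orphan <- setdiff(terms$gene_id, genes$gene_id)
  if (length(orphan) > 0) {
    warn(sprintf("%d term assignment(s) reference genes outside the universe; skipped.",
                 length(orphan)))
    terms <- filter(terms, gene_id %in% genes$gene_id)
  }
  inw <- genes_in_windows(genes, windows, mode = overlap)
  names(inw) <- genes$gene_id
  out <- terms |>
    distinct(gene_id, term) |>
    group_by(term) |>
    summarise(res = list(enrichment_2x2(inw, names(inw) %in% gene_id)),
              .groups = "drop") |>
    tidyr::unnest(res) |>
    arrange(p_value)
  mutate(out, p_bh = p.adjust(p_value, "BH"))
}

#' Count tagging TASs per gene
#'
#' A TAS "tags" a gene when the gene's interval overlaps the window of
#' half-width `size/2` centred on the TAS (equivalently, when the TAS lies
#' within `size/2` of the gene). Counting is per TAS, without window
#' merging, because the tagging rules are per-SNP: a gene counts as tagged
#' when hit by at least 2 TASs, and a DNA-repair gene when hit by at least 3.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`; optional
#'   logical `is_repair_gene`).
#' @param tas TAS tibble (`chrom`, `pos`).
#' @param size Window size in bp.
#' @param min_tags,min_tags_repair Tagging thresholds (defaults 2 and 3).
#' @return Tibble: `gene_id`, `n_tas`, `tagged`, `tagged_repair`.
#' @export
gene_tagging <- function(genes, tas, size, min_tags = 2, min_tags_repair = 3) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end"))
  assert_cols(tas, c("chrom", "pos"))
  half <- size / 2
  n_tas <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    tp <- tas$pos[tas$chrom == ch]
    if (length(tp) == 0) next
    gr <- IRanges::IRanges(pmax(genes$start[gi] + 1 - half, 1),
                           genes$end[gi] + half)
    tr <- IRanges::IRanges(tp, tp)
    n_tas[gi] <- IRanges::countOverlaps(gr, tr)
  }
  tibble(gene_id = genes$gene_id, n_tas = n_tas,
         tagged = n_tas >= min_tags,
         tagged_repair = n_tas >= min_tags_repair)
}

#' DNA-repair gene over-representation in TAS windows
#'
#' One-sided Fisher's exact test of the repair-gene share among in-window
#' genes against the genome-wide share, computed for one window size or a
#' series of sizes.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param tas TAS tibble (`chrom`, `pos`).
#' @param repair_genes Character vector of repair-gene ids (must be a subset
#'   of the universe).
#' @param sizes Numeric vector of window sizes in bp (default
#'   `c(0.5, 1, 1.5, 2) * 1e6`).
#' @param chrom_lengths Optional chromosome lengths for window clipping.
#' @param overlap Gene-in-window rule, as in [term_enrichment()].
#' @return Tibble with one row per window size: `size`, 2x2 counts,
#'   `odds_ratio`, `p_value`.
#' @export
repair_gene_enrichment <- function(genes, tas, repair_genes,
                                   sizes = c(0.5e6, 1e6, 1.5e6, 2e6),
                                   chrom_lengths = NULL, overlap = "any") {
  assert_cols(genes, c("gene_id", "chrom", "start", "end"))
  if (length(repair_genes) == 0) abort("`repair_genes` must be non-empty.")
  missing <- setdiff(repair_genes, genes$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("%d repair gene(s) are not in the gene universe.",
                  length(missing)))
  }
  is_rep <- genes$gene_id %in% repair_genes
  purrr::map_dfr(sizes, function(s) {
    win <- build_windows(tas, s, chrom_lengths = chrom_lengths)
    inw <- genes_in_windows(genes, win, mode = overlap)
    bind_cols(tibble(size = s), enrichment_2x2(inw, is_rep))
  })
}
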