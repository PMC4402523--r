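#' Count bases along one strand of a DNA sequence
#'
#' Tallies A, C, G and T along the strand as given, case-insensitively.
#' Every other symbol (N and all ambiguity codes) is excluded from both the
#' counts and the denominator used for composition fractions, so the fractions
#' always refer to unambiguously called bases only. Soft-masked (lowercase)
#' bases count as their uppercase base: masking is annotation, not
#' composition.
#'
#' @param sequence Character vector of DNA sequences (one element per record),
#'   or a [Biostrings::DNAStringSet].
#' @param seq_id Optional character vector of sequence identifiers; defaults
#'   to names of `sequence` or `seq_1`, `seq_2`, ...
#'
#' @return A tibble with one row per sequence and columns `seq_id`, `length`,
#'   `n_a`, `n_c`, `n_g`, `n_t`, `n_excluded`, and composition fractions
#'   `frac_a` .. `frac_t` (NA when no countable base is present).
#' @export
#' @examples
#' count_bases("ACGT")
#' count_bases("AAANNTT")   # N excluded: [A] = 0.6, [T] = 0.4
count_bases <- function(sequence, seq_id = NULL) {
  if (methods::is(sequence, "XStringSet")) {
    seq_id <- seq_id %||% names(sequence) %||% paste0("seq_", seq_along(sequence))
    sequence <- as.character(sequence)
  }
  if (!is.character(sequence)) {
    abort("`sequence` must be a character vector or DNAStringSet.")
  }
  seq_id <- seq_id %||% names(sequence) %||% paste0("seq_", seq_along(sequence))
  if (length(seq_id) != length(sequence)) {
    abort("`seq_id` must have one entry per sequence.")
  }
  up <- stringr::str_to_upper(sequence)
  len <- stringr::str_length(up)
  counts <- vapply(
    BASES,
    function(b) stringr::str_count(up, stringr::fixed(b)),
    numeric(length(up))
  )
  counts <- matrix(counts, nrow = length(up), ncol = 4,
                   dimnames = list(NULL, BASES))
  acgt <- rowSums(counts)
  out <- tibble(
    seq_id = as.character(seq_id),
    length = as.integer(len),
    n_a = as.integer(counts[, "A"]),
    n_c = as.integer(counts[, "C"]),
    n_g = as.integer(counts[, "G"]),
    n_t = as.integer(counts[, "T"]),
    n_excluded = as.integer(len - acgt)
  )
  add_fractions(out)
}

add_fractions <- function(comp) {
  denom <- with(comp, length - n_excluded)
  denom[denom == 0] <- NA_integer_
  mutate(comp,
         frac_a = n_a / denom, frac_c = n_c / denom,
         frac_g = n_g / denom, frac_t = n_t / denom)
}

#' Base composition of a FASTA file, per record
#'
#' Reads a (possibly gzipped) multi-record FASTA and returns the per-record
#' base composition together with parity metrics, i.e. the table needed to
#' examine PR2 at the chromosome level.
#'
#' @param fasta Path to a FASTA file.
#' @param aggregate If `TRUE`, append a final row aggregating all records
#'   (the genome-level composition), with `seq_id = "genome"`.
#' @return A tibble as [count_bases()] plus `at_skew`, `gc_skew`,
#'   `pr2_deviation` columns.
#' @export
genome_composition <- function(fasta, aggregate = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  comp <- count_bases(seqs)
  if (aggregate) {
    comp <- bind_rows(comp, aggregate_composition(comp, seq_id = "genome"))
  }
  parity_metrics(comp)
}

#' Aggregate per-sequence compositions into one
#'
#' Field-wise sums over a set of [count_bases()] rows, e.g. chromosomes into
#' a genome. Duplicate `seq_id`s are rejected to prevent double counting.
#'
#' @param parts Tibble of compositions (rows of [count_bases()]).
#' @param seq_id Identifier for the aggregate row.
#' @return A one-row composition tibble.
#' @export
aggregate_composition <- function(parts, seq_id = "aggregate") {
  if (!is.data.frame(parts) || nrow(parts) == 0) {
    abort("`parts` must be a non-empty composition table.")
  }
  assert_cols(parts, c("seq_id", "length", "n_a", "n_c", "n_g", "n_t", "n_excluded"))
  if (anyDuplicated(parts$seq_id)) {
    abort("duplicate `seq_id` in `parts`: aggregation would double-count.")
  }
  out <- tibble(
    seq_id = seq_id,
    length = as.integer(sum(parts$length)),
    n_a = as.integer(sum(parts$n_a)), n_c = as.integer(sum(parts$n_c)),
    n_g = as.integer(sum(parts$n_g)), n_t = as.integer(sum(parts$n_t)),
    n_excluded = as.integer(sum(parts$n_excluded))
  )
  add_fractions(out)
}

#' Strand parity metrics
#'
#' AT skew `(A - T)/(A + T)`, GC skew `(C - G)/(C + G)` and the PR2 deviation
#' `|[A] - [T]| + |[G] - [C]|`. The deviation is zero exactly when the strand
#' satisfies the second parity rule; it is a summary statistic of this
#' package, not a universal convention.
#'
#' @param comp Composition tibble from [count_bases()].
#' @return `comp` with `at_skew`, `gc_skew` and `pr2_deviation` columns added.
#' @export
parity_metrics <- function(comp) {
  assert_cols(comp, c("n_a", "n_c", "n_g", "n_t", "length", "n_excluded"))
  if (any(comp$length - comp$n_excluded == 0)) {
    abort("parity metrics are undefined for sequences with no countable bases.")
  }
  mutate(comp,
    at_skew = (n_a - n_t) / (n_a + n_t),
    gc_skew = (n_c - n_g) / (n_c + n_g),
    pr2_deviation = abs(frac_a - frac_t) + abs(frac_g - frac_c)
  )
}
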