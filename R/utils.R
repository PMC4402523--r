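#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n across all_of rename count distinct pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pf pchisq optimize prcomp t.test var sd setNames
#'   complete.cases fisher.test p.adjust qf rbinom runif rnorm cor
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# complement of a vector of single bases
complement_base <- function(x) {
  unname(COMPLEMENT[match(toupper(x), BASES)])
}

is_base <- function(x) toupper(x) %in% BASES

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Derive a child RNG seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483629
}
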