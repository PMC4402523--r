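#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.scan_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "scan_result")
  out
}

#' @export
glance.scan_result <- function(x, ...) {
  vc <- attr(x, "vc")
  tibble(
    n_variants = nrow(x),
    model = x$model[1],
    df1 = attr(x, "df")[1], df2 = attr(x, "df")[2],
    max_f = max(x$F, na.rm = TRUE),
    n_tas = if ("is_tas" %in% names(x)) sum(x$is_tas, na.rm = TRUE) else NA_integer_,
    h2 = if (!is.null(vc)) vc$h2 else NA_real_,
    lambda = if (!is.null(vc)) vc$lambda else NA_real_)
}

#' @export
tidy.group_separation <- function(x, ...) x$summary

#' @export
glance.group_separation <- function(x, ...) x$test

#' @export
tidy.switch_threshold <- function(x, ...) x$summary

#' @export
glance.switch_threshold <- function(x, ...) {
  tibble(threshold = x$threshold, baseline_f = x$baseline_f,
         percentile = x$percentile, at_proportion = x$at_proportion)
}

#' @export
tidy.genotype_pca <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         prop_variance = x$eigenvalues / sum(x$eigenvalues))
}

#' @export
tidy.subsample_variance <- function(x, ...) x$summary
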