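#' Quantile normalization of an expression matrix
#'
#' Forces every sample's intensity distribution onto the common distribution
#' of row means over column-sorted values, the standard quantile algorithm
#' for one-color microarray data. The actual transform is delegated to
#' [limma::normalizeQuantiles()]; feature and sample order are preserved.
#'
#' A single-column matrix is returned unchanged (its distribution already
#' equals the reference distribution).
#'
#' @param x An [expression_matrix()].
#' @return An `expr_matrix` whose columns all share the same multiset of
#'   values.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!all(is.finite(x$values))) {
    stop_config("quantile_normalize: values must be finite")
  }
  if (ncol(x$values) == 1L) {
    return(x)
  }
  norm <- limma::normalizeQuantiles(x$values, ties = TRUE)
  expression_matrix(norm, x$feature_ids, x$feature_kinds,
                    x$sample_ids, x$sample_groups)
}
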