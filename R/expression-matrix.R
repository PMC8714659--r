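#' Expression matrix with feature kinds and sample groups
#'
#' Container for log2-scale expression intensities together with the two
#' annotations every downstream stage needs: the molecular kind of each
#' feature (`mRNA`, `lncRNA`, `circRNA` or `miRNA`) and the group of each
#' sample (`case` or `control`).
#'
#' @param values Numeric matrix of log2 intensities, features x samples.
#'   Row and column names, if present, are overridden by `feature_ids` /
#'   `sample_ids`.
#' @param feature_ids Character vector of unique feature identifiers.
#' @param feature_kinds Character vector, one of `"mRNA"`, `"lncRNA"`,
#'   `"circRNA"`, `"miRNA"` per feature.
#' @param sample_ids Character vector of sample identifiers.
#' @param sample_groups Character vector, `"case"` or `"control"` per sample.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to `values` (for raw
#'   intensities); the default assumes input is already log2 scale, the usual
#'   convention for microarray matrices.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `feature_ids`, `feature_kinds`, `sample_ids`, `sample_groups`.
#' @export
expression_matrix <- function(values, feature_ids, feature_kinds,
                              sample_ids, sample_groups,
                              log2_transform = FALSE) {
  values <- as.matrix(values)
  if (isTRUE(log2_transform)) values <- log2(values + 1)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop_config("expression values must all be finite")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids) ||
      nrow(values) != length(feature_kinds)) {
    stop_config("feature annotation length does not match row count")
  }
  if (ncol(values) != length(sample_ids) ||
      ncol(values) != length(sample_groups)) {
    stop_config("sample annotation length does not match column count")
  }
  if (anyDuplicated(feature_ids)) {
    stop_config("feature_ids must be unique")
  }
  feature_kinds <- as.character(feature_kinds)
  if (!all(feature_kinds %in% FEATURE_KINDS)) {
    stop_config("feature_kinds must be one of: %s",
                paste(FEATURE_KINDS, collapse = ", "))
  }
  sample_groups <- as.character(sample_groups)
  if (!all(sample_groups %in% c("case", "control"))) {
    stop_config("sample_groups must be 'case' or 'control'")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values,
                 feature_ids = feature_ids,
                 feature_kinds = feature_kinds,
                 sample_ids = sample_ids,
                 sample_groups = sample_groups),
            class = "expr_matrix")
}

FEATURE_KINDS <- c("mRNA", "lncRNA", "circRNA", "miRNA")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_groups == "case"),
              sum(x$sample_groups == "control")))
  kt <- table(factor(x$feature_kinds, levels = FEATURE_KINDS))
  cat("  kinds:", paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix by feature id
#' @param x An `expr_matrix`.
#' @param features Character vector of feature ids to keep (order preserved).
#' @return An `expr_matrix` restricted to `features`.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "expr_matrix"))
  idx <- match(features, x$feature_ids)
  if (anyNA(idx)) {
    stop_config("features not present in matrix: %s",
                paste(features[is.na(idx)], collapse = ", "))
  }
  expression_matrix(x$values[idx, , drop = FALSE],
                    x$feature_ids[idx], x$feature_kinds[idx],
                    x$sample_ids, x$sample_groups)
}

#' Write an expression matrix as TSV
#'
#' The dialect is `feature_id`, `kind`, then one column per sample; sample
#' groups are encoded in a `#groups:` comment line so the file round-trips.
#'
#' @param x An `expr_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#groups: %s",
                     paste(x$sample_groups, collapse = "\t")), con)
  df <- data.frame(feature_id = x$feature_ids, kind = x$feature_kinds,
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", "kind", x$sample_ids)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an expression matrix from TSV
#' @param path File written by [write_expression_tsv()], or any TSV in the
#'   same dialect.
#' @param sample_groups Optional character vector overriding the `#groups:`
#'   header line.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, sample_groups = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#groups:")) {
    if (is.null(sample_groups)) {
      sample_groups <- strsplit(trimws(sub("^#groups:", "", first)),
                                "\t")[[1]]
    }
    skip <- 1L
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, skip = skip,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(sample_groups)) {
    stop_config("no sample groups: file lacks a '#groups:' line and none given")
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  expression_matrix(vals, df$feature_id, df$kind, colnames(vals),
                    sample_groups)
}
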