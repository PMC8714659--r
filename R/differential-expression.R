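#' Fold-change / t-test differential expression screen
#'
#' Per-feature two-group comparison on log2-scale data: the log2 fold change
#' is `mean(case) - mean(control)` and significance comes from a two-tailed
#' Student's t-test (pooled variance by default). A feature is flagged
#' differentially expressed when `|log2FC| > fc_log2_threshold` AND
#' `p < p_threshold` (both strict), matching the usual microarray screen of
#' fold change > 2 with p < 0.05 on log2 data. Raw p-values gate the flag;
#' Benjamini-Hochberg q-values are reported alongside for transparency but
#' do not affect it.
#'
#' Degenerate features with zero variance in both groups get `t = 0, p = 1`
#' when the group means are equal; when the means differ the limiting
#' `p = 0` is recorded (with `t = +/-Inf`) and a count of such features is
#' logged, so constant-but-shifted features are never silently dropped and
#' NaN never propagates.
#'
#' @param x An [expression_matrix()]; both groups must have >= 2 samples.
#' @param fc_log2_threshold Log2 fold-change cutoff (default 1, i.e. FC > 2).
#' @param p_threshold P-value cutoff (default 0.05).
#' @param var_equal Use the pooled-variance Student's t-test (default);
#'   `FALSE` gives Welch's correction.
#' @return A data.frame with one row per feature: `feature_id`, `kind`,
#'   `mean_case`, `mean_control`, `log2fc`, `t_stat`, `p_value`, `q_value`,
#'   `is_de`.
#' @export
differential_expression <- function(x, fc_log2_threshold = 1,
                                    p_threshold = 0.05, var_equal = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  case_idx <- which(x$sample_groups == "case")
  ctrl_idx <- which(x$sample_groups == "control")
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L) {
    stop_config("differential_expression: each group needs >= 2 samples (case=%d, control=%d)",
                length(case_idx), length(ctrl_idx))
  }
  n <- nrow(x$values)
  mean_case <- rowMeans(x$values[, case_idx, drop = FALSE])
  mean_ctrl <- rowMeans(x$values[, ctrl_idx, drop = FALSE])
  log2fc <- mean_case - mean_ctrl
  t_stat <- numeric(n)
  p_value <- numeric(n)
  n_degenerate <- 0L
  eps <- 1e-12
  for (i in seq_len(n)) {
    a <- x$values[i, case_idx]
    b <- x$values[i, ctrl_idx]
    if (stats::var(a) < eps && stats::var(b) < eps) {
      if (abs(log2fc[i]) < eps) {
        t_stat[i] <- 0; p_value[i] <- 1
      } else {
        t_stat[i] <- sign(log2fc[i]) * Inf
        p_value[i] <- 0
        n_degenerate <- n_degenerate + 1L
      }
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
      t_stat[i] <- unname(tt$statistic)
      p_value[i] <- tt$p.value
    }
  }
  if (n_degenerate > 0L) {
    log_msg("de", "%d zero-variance feature(s) with differing means: p recorded as the 0 limit",
            n_degenerate)
  }
  data.frame(feature_id = x$feature_ids,
             kind = x$feature_kinds,
             mean_case = mean_case,
             mean_control = mean_ctrl,
             log2fc = log2fc,
             t_stat = t_stat,
             p_value = p_value,
             q_value = stats::p.adjust(p_value, method = "BH"),
             is_de = abs(log2fc) > fc_log2_threshold & p_value < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export volcano-plot coordinates
#' @param de Data.frame from [differential_expression()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_volcano_tsv <- function(de, path) {
  write_tsv_file(data.frame(feature_id = de$feature_id,
                            log2fc = de$log2fc,
                            neg_log10_p = -log10(pmax(de$p_value, 1e-300)),
                            stringsAsFactors = FALSE),
                 path)
}
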