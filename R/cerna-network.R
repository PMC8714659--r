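# ceRNA triple construction: intersect target-pair predictions through
# shared miRNAs, keep triples whose miRNA is on a curated, literature-backed
# list, gate on Pearson correlation of ceRNA vs mRNA expression, and
# assemble the surviving triples into an undirected network.

#' Default curated miRNA list
#'
#' Five miRNAs with experimentally established direction of dysregulation
#' in Graves' ophthalmopathy orbital fibroblasts: miR-21, miR-146a and
#' miR-155 up in cases; miR-27a and miR-27b down.
#'
#' @return data.frame with columns `name` and `direction` (`up`/`down`).
#' @export
default_curated_mirnas <- function() {
  data.frame(name = c("miR-21", "miR-27a", "miR-27b", "miR-146a", "miR-155"),
             direction = c("up", "down", "down", "up", "up"),
             stringsAsFactors = FALSE)
}

#' Validate a curated miRNA table
#' @noRd
check_curated <- function(curated) {
  if (is.null(curated) || nrow(curated) == 0L) {
    stop_config("curated miRNA list is empty: cross-validation would discard everything")
  }
  if (!all(c("name", "direction") %in% colnames(curated))) {
    stop_config("curated miRNA table needs columns 'name' and 'direction'")
  }
  if (anyDuplicated(normalize_mirna_name(curated$name))) {
    stop_config("curated miRNA names must be unique")
  }
  if (!all(curated$direction %in% c("up", "down"))) {
    stop_config("curated miRNA direction must be 'up' or 'down'")
  }
  curated
}

#' Intersect ceRNA-side and mRNA-side target pairs through shared miRNAs
#'
#' Every (ceRNA, miRNA) pair from the lncRNA/circRNA predictions is joined
#' with every (mRNA, miRNA) pair sharing the miRNA, so the candidate count
#' is the sum over shared miRNAs of |ceRNAs| x |mRNAs|.
#'
#' @param ce_pairs [predict_targets()] output for lncRNA/circRNA targets.
#' @param m_pairs [predict_targets()] output for mRNA targets.
#' @return data.frame of candidate triples: `cerna_id`, `cerna_kind`,
#'   `mirna_id`, `mrna_id`, sorted.
#' @export
intersect_pairs <- function(ce_pairs, m_pairs) {
  empty <- data.frame(cerna_id = character(0), cerna_kind = character(0),
                      mirna_id = character(0), mrna_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(ce_pairs) == 0L || nrow(m_pairs) == 0L) return(empty)
  ce <- data.frame(cerna_id = ce_pairs$target_id,
                   cerna_kind = ce_pairs$target_kind,
                   mirna_id = ce_pairs$mirna_id, stringsAsFactors = FALSE)
  mm <- data.frame(mirna_id = m_pairs$mirna_id,
                   mrna_id = m_pairs$target_id, stringsAsFactors = FALSE)
  out <- merge(ce, mm, by = "mirna_id")
  if (nrow(out) == 0L) return(empty)
  out <- out[, c("cerna_id", "cerna_kind", "mirna_id", "mrna_id")]
  out <- out[order(out$cerna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-validate candidate triples against a curated miRNA list
#'
#' Keeps candidates whose miRNA matches a curated entry. Matching is
#' case-insensitive; an optional species prefix (`hsa-`) and mature-arm
#' suffix (`-3p`/`-5p`) on the candidate match a bare stem in the curated
#' list, so `hsa-miR-27b-3p` matches curated `miR-27b`.
#'
#' @param candidates data.frame from [intersect_pairs()].
#' @param curated data.frame with `name`, `direction`
#'   ([default_curated_mirnas()] by default).
#' @return The surviving candidates with an added `mirna_direction` column.
#' @export
cross_validate <- function(candidates, curated = default_curated_mirnas()) {
  curated <- check_curated(curated)
  stems <- normalize_mirna_name(curated$name)
  idx <- match(normalize_mirna_name(candidates$mirna_id), stems)
  out <- candidates[!is.na(idx), , drop = FALSE]
  out$mirna_direction <- curated$direction[idx[!is.na(idx)]]
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: requires equal lengths
#' >= 3 and nonzero variance in both vectors (a correlation is undefined
#' for a constant profile, and callers are expected to discard such pairs).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation, in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_config("pearson_r: vectors must have equal length >= 3")
  }
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    stop_config("pearson_r: undefined for zero-variance input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Correlation and direction filter for candidate triples
#'
#' Keeps candidates whose ceRNA and mRNA expression profiles (Pearson,
#' across all samples, case and control pooled) correlate strictly above
#' `r_threshold`. With direction consistency on (the default), the ceRNA
#' and mRNA must additionally share their differential-expression sign and
#' that sign must oppose the curated miRNA direction -- the expression
#' pattern the RISC-competition mechanism predicts (abundant ceRNA
#' sequesters the miRNA and de-represses the mRNA). Candidates with a
#' zero-variance member are discarded with a logged count.
#'
#' @param candidates data.frame from [cross_validate()] (needs
#'   `mirna_direction` when direction consistency is on).
#' @param expr An [expression_matrix()] holding every candidate member.
#' @param de [differential_expression()] table (needed for the direction
#'   rule).
#' @param r_threshold Strict correlation cutoff (default 0.95).
#' @param require_direction_consistency Apply the direction rule?
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame of ceRNA triples: candidate columns plus `r`,
#'   `cerna_log2fc`, `mrna_log2fc` and `passed_filters`, sorted by
#'   (cerna_id, mirna_id, mrna_id).
#' @export
filter_correlation <- function(candidates, expr, de = NULL,
                               r_threshold = 0.95,
                               require_direction_consistency = TRUE,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expr_matrix"))
  empty <- cbind(candidates[0, , drop = FALSE],
                 data.frame(r = numeric(0), cerna_log2fc = numeric(0),
                            mrna_log2fc = numeric(0),
                            passed_filters = character(0),
                            stringsAsFactors = FALSE))
  if (nrow(candidates) == 0L) return(empty)
  if (require_direction_consistency) {
    if (is.null(de)) {
      stop_config("filter_correlation: direction consistency needs the DE table")
    }
    if (!"mirna_direction" %in% colnames(candidates)) {
      stop_config("filter_correlation: candidates lack mirna_direction (run cross_validate first)")
    }
  }
  members <- unique(c(candidates$cerna_id, candidates$mrna_id))
  missing <- setdiff(members, expr$feature_ids)
  if (length(missing) > 0L) {
    stop_config("filter_correlation: feature(s) absent from matrix: %s",
                paste(missing, collapse = ", "))
  }
  vals <- expr$values
  n_dropped <- 0L
  keep <- logical(nrow(candidates))
  r <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    x <- vals[candidates$cerna_id[i], ]
    y <- vals[candidates$mrna_id[i], ]
    if (stats::var(x) <= 0 || stats::var(y) <= 0) {
      n_dropped <- n_dropped + 1L
      next
    }
    r[i] <- if (method == "pearson") pearson_r(x, y) else
      stats::cor(x, y, method = "spearman")
    keep[i] <- r[i] > r_threshold
  }
  if (n_dropped > 0L) {
    log_msg("cerna", "%d candidate(s) dropped: zero-variance expression profile",
            n_dropped)
  }
  out <- candidates[keep, , drop = FALSE]
  out$r <- r[keep]
  filters <- "correlation"
  if (require_direction_consistency && nrow(out) > 0L) {
    ce_fc <- de$log2fc[match(out$cerna_id, de$feature_id)]
    m_fc <- de$log2fc[match(out$mrna_id, de$feature_id)]
    mir_sign <- ifelse(out$mirna_direction == "up", 1, -1)
    ok <- !is.na(ce_fc) & !is.na(m_fc) &
      sign(ce_fc) == sign(m_fc) & sign(ce_fc) == -mir_sign
    out <- out[ok, , drop = FALSE]
    ce_fc <- ce_fc[ok]; m_fc <- m_fc[ok]
    out$cerna_log2fc <- ce_fc
    out$mrna_log2fc <- m_fc
    filters <- c(filters, "direction")
  } else if (nrow(out) > 0L) {
    if (!is.null(de)) {
      out$cerna_log2fc <- de$log2fc[match(out$cerna_id, de$feature_id)]
      out$mrna_log2fc <- de$log2fc[match(out$mrna_id, de$feature_id)]
    } else {
      out$cerna_log2fc <- NA_real_
      out$mrna_log2fc <- NA_real_
    }
  }
  if (nrow(out) == 0L) return(empty)
  out$passed_filters <- paste(c("seed", "cross-validation", filters),
                              collapse = "+")
  out <- out[order(out$cerna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a ceRNA network from filtered triples
#'
#' Nodes are deduplicated across triples and carry `kind` (lncRNA, circRNA,
#' miRNA or mRNA) and `regulation` (`up`/`down` from the DE sign; the
#' miRNA's regulation comes from its curated direction; `n/a` when
#' unknown). Undirected edges (ceRNA-miRNA and miRNA-mRNA) are collapsed
#' across triples, retaining the source triples as provenance.
#'
#' @param triples data.frame from [filter_correlation()].
#' @return An object of class `cerna_network`: list with `nodes`, `edges`
#'   data.frames, the `igraph` graph, and the `triples` table.
#' @export
assemble_network <- function(triples) {
  reg_of_fc <- function(fc) {
    ifelse(is.na(fc), "n/a", ifelse(fc > 0, "up", "down"))
  }
  if (nrow(triples) == 0L) {
    nodes <- data.frame(id = character(0), kind = character(0),
                        regulation = character(0), stringsAsFactors = FALSE)
    edges <- data.frame(from = character(0), to = character(0),
                        edge_type = character(0), triples = character(0),
                        stringsAsFactors = FALSE)
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(structure(list(nodes = nodes, edges = edges, graph = g,
                          triples = triples), class = "cerna_network"))
  }
  triple_id <- sprintf("%s|%s|%s", triples$cerna_id, triples$mirna_id,
                       triples$mrna_id)
  has_fc <- all(c("cerna_log2fc", "mrna_log2fc") %in% colnames(triples))
  has_dir <- "mirna_direction" %in% colnames(triples)
  nodes <- rbind(
    data.frame(id = triples$cerna_id, kind = triples$cerna_kind,
               regulation = if (has_fc) reg_of_fc(triples$cerna_log2fc)
                            else "n/a", stringsAsFactors = FALSE),
    data.frame(id = triples$mirna_id, kind = "miRNA",
               regulation = if (has_dir) triples$mirna_direction else "n/a",
               stringsAsFactors = FALSE),
    data.frame(id = triples$mrna_id, kind = "mRNA",
               regulation = if (has_fc) reg_of_fc(triples$mrna_log2fc)
                            else "n/a", stringsAsFactors = FALSE))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  raw_edges <- rbind(
    data.frame(from = triples$cerna_id, to = triples$mirna_id,
               edge_type = "cerna-mirna", triple = triple_id,
               stringsAsFactors = FALSE),
    data.frame(from = triples$mirna_id, to = triples$mrna_id,
               edge_type = "mirna-mrna", triple = triple_id,
               stringsAsFactors = FALSE))
  key <- paste(raw_edges$from, raw_edges$to)
  edges <- do.call(rbind, lapply(split(seq_len(nrow(raw_edges)), key),
    function(idx) {
      data.frame(from = raw_edges$from[idx[1]], to = raw_edges$to[idx[1]],
                 edge_type = raw_edges$edge_type[idx[1]],
                 triples = paste(sort(unique(raw_edges$triple[idx])),
                                 collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g, triples = triples),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d nodes, %d edges, %d triples\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$triples)))
  invisible(x)
}

#' Network summary counts
#'
#' The three natural "pair" counts of a ceRNA network, which disambiguate
#' what a headline pair figure may refer to: triples, distinct ceRNA-mRNA
#' pairs, and edges.
#'
#' @param net A `cerna_network`.
#' @return Named list: `n_triples`, `n_cerna_mrna_pairs`, `n_edges`,
#'   `n_nodes`.
#' @export
network_counts <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  list(n_triples = nrow(net$triples),
       n_cerna_mrna_pairs = if (nrow(net$triples) == 0L) 0L else
         nrow(unique(net$triples[, c("cerna_id", "mrna_id")])),
       n_edges = nrow(net$edges),
       n_nodes = nrow(net$nodes))
}

#' Write a network in SIF format
#' @param net A `cerna_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "cerna_network"))
  lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$edge_type,
                   net$edges$to)
  writeLines(lines, path)
  invisible(path)
}

#' Write a network in GraphML format (Cytoscape-loadable)
#' @param net A `cerna_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Write node and edge attribute tables
#' @param net A `cerna_network`.
#' @param nodes_path,edges_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_network_tables <- function(net, nodes_path, edges_path) {
  stopifnot(inherits(net, "cerna_network"))
  write_tsv_file(net$nodes, nodes_path)
  write_tsv_file(net$edges, edges_path)
  invisible(c(nodes_path, edges_path))
}
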