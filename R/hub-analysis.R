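# Degree-based hub-gene ranking on a STRING-style PPI edge list.

#' Load a protein-protein interaction edge list
#'
#' Reads the STRING export dialect (tab-separated columns `protein1`,
#' `protein2`, `combined_score`), drops self-loops (logged), collapses
#' duplicate undirected edges keeping the maximum score, and discards edges
#' below `min_score`. Scores given on STRING's 0-999 integer scale are
#' rescaled by 1/1000 with a warning.
#'
#' @param path TSV path.
#' @param min_score Minimum combined confidence score, inclusive
#'   (default 0.4).
#' @return An object of class `ppi_graph`: list with `edges` (data.frame
#'   `gene_a`, `gene_b`, `combined_score`), `graph` (igraph), `min_score`.
#' @export
load_ppi_edges <- function(path, min_score = 0.4) {
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_config("failed to parse PPI file '%s': %s",
                                    path, conditionMessage(e)))
  if (nrow(df) == 0L) {
    warning("empty PPI edge list: ", path, call. = FALSE)
    return(ppi_from_edges(data.frame(gene_a = character(0),
                                     gene_b = character(0),
                                     combined_score = numeric(0),
                                     stringsAsFactors = FALSE), min_score))
  }
  needed <- c("protein1", "protein2", "combined_score")
  if (!all(needed %in% colnames(df))) {
    stop_config("PPI file '%s' lacks columns: %s", path,
                paste(setdiff(needed, colnames(df)), collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    stop_config("PPI file '%s': non-numeric combined_score at line %d",
                path, which(is.na(score))[1] + 1L)
  }
  if (any(score > 1)) {
    if (all(score >= 0 & score <= 999)) {
      warning("combined_score appears to be on the 0-999 scale; rescaling by 1/1000",
              call. = FALSE)
      score <- score / 1000
    } else {
      stop_config("PPI file '%s': combined_score outside [0, 1] (and not 0-999)",
                  path)
    }
  }
  if (any(score < 0)) {
    stop_config("PPI file '%s': negative combined_score", path)
  }
  edges <- data.frame(gene_a = as.character(df$protein1),
                      gene_b = as.character(df$protein2),
                      combined_score = score, stringsAsFactors = FALSE)
  self <- edges$gene_a == edges$gene_b
  if (any(self)) {
    log_msg("ppi", "dropped %d self-loop(s)", sum(self))
    edges <- edges[!self, , drop = FALSE]
  }
  # undirected dedup: canonical order, keep max score
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  best <- tapply(edges$combined_score, key, max)
  uniq <- !duplicated(key)
  edges <- data.frame(gene_a = a[uniq], gene_b = b[uniq],
                      combined_score = unname(best[key[uniq]]),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$combined_score >= min_score, , drop = FALSE]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  ppi_from_edges(edges, min_score)
}

#' @noRd
ppi_from_edges <- function(edges, min_score) {
  g <- if (nrow(edges) == 0L) {
    igraph::make_empty_graph(0, directed = FALSE)
  } else {
    igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  structure(list(edges = edges, graph = g, min_score = min_score),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges (combined_score >= %.2f)\n",
              igraph::vcount(x$graph), nrow(x$edges), x$min_score))
  invisible(x)
}

#' Rank hub genes by node degree
#'
#' Sorts nodes by degree, descending, ties broken lexicographically by gene
#' id (so the ranking is invariant to input row order), and returns the top
#' `k` -- the Degree method of CytoHubba-style hub identification.
#'
#' @param ppi A `ppi_graph` from [load_ppi_edges()].
#' @param k Number of hubs to keep (default 30); truncated to the node
#'   count.
#' @return data.frame `gene`, `degree`, `rank`.
#' @export
rank_hubs <- function(ppi, k = 30) {
  stopifnot(inherits(ppi, "ppi_graph"))
  if (!is.numeric(k) || k <= 0) stop_config("rank_hubs: k must be > 0")
  deg <- igraph::degree(ppi$graph)
  ord <- order(-deg, names(deg))
  n <- min(as.integer(k), length(deg))
  sel <- ord[seq_len(n)]
  data.frame(gene = names(deg)[sel], degree = unname(deg[sel]),
             rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Select validation candidates: hub genes present in the ceRNA network
#'
#' The intersection of the ranked hub genes with the mRNA nodes of the
#' ceRNA network, in hub-rank order -- the genes that are both
#' high-connectivity in the PPI graph and ceRNA-regulated, the natural
#' candidates for wet-lab validation.
#'
#' @param hubs data.frame from [rank_hubs()].
#' @param network A `cerna_network`.
#' @return Character vector of gene ids in hub order.
#' @export
select_validation_candidates <- function(hubs, network) {
  stopifnot(inherits(network, "cerna_network"))
  mrnas <- network$nodes$id[network$nodes$kind == "mRNA"]
  hubs$gene[hubs$gene %in% mrnas]
}
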