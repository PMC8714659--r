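# Fisher's-exact (hypergeometric) over-representation analysis against
# GMT gene-set collections, with Benjamini-Hochberg q-values.

#' Gene-set collection
#'
#' @param terms Named list: term id -> character vector of member genes.
#' @param category Named character vector: term id -> category label (e.g.
#'   BP/CC/MF); defaults to `"NA"` for terms without one.
#' @param universe Background gene set; defaults to the union of all term
#'   members. Term members are restricted to the universe.
#' @param names Optional named character vector of human-readable term
#'   names; defaults to the term ids.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, category = NULL, universe = NULL,
                                names = NULL) {
  if (length(terms) == 0L) stop_config("gene-set collection is empty")
  if (is.null(universe)) universe <- unique(unlist(terms))
  universe <- unique(as.character(universe))
  terms <- lapply(terms, function(g) intersect(unique(as.character(g)),
                                               universe))
  if (is.null(category)) {
    category <- stats::setNames(rep("NA", length(terms)),
                                base::names(terms))
  }
  if (is.null(names)) {
    names <- stats::setNames(base::names(terms), base::names(terms))
  }
  structure(list(terms = terms, category = category, names = names,
                 universe = universe), class = "gene_set_collection")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member genes. The description field is used as the category label
#' (this package's dialect writes BP/CC/MF-style labels there).
#'
#' @param path GMT file path.
#' @param universe Optional background gene set.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  terms <- fgsea::gmtPathways(path)
  # recover the description (2nd) field for category labels
  lines <- strsplit(readLines(path), "\t")
  category <- stats::setNames(vapply(lines, function(x) x[2], character(1)),
                              vapply(lines, function(x) x[1], character(1)))
  gene_set_collection(terms, category = category[names(terms)],
                      universe = universe)
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$terms), function(id) {
    paste(c(id, collection$category[[id]], collection$terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); `q >= p` element-wise and `q <= 1`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop_config("bh_adjust: p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fisher's-exact over-representation analysis
#'
#' For each term with `K` members in a universe of `N` genes and a query of
#' `n` genes with `k` in the term, computes the one-sided Fisher's exact
#' p-value, i.e. the hypergeometric upper tail `P(X >= k)`, then BH-adjusts
#' across all tested terms. Terms with no member in the universe are
#' skipped with a warning.
#'
#' @param query Character vector of genes (restricted to the universe; an
#'   empty intersection is an error).
#' @param collection A [gene_set_collection()].
#' @param q_threshold Significance cutoff on the q-value (default 0.05,
#'   inclusive).
#' @return data.frame sorted by (q, p): `term_id`, `term_name`, `category`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, `significant`, `genes`
#'   (comma-joined overlap).
#' @export
fisher_enrichment <- function(query, collection, q_threshold = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- intersect(unique(as.character(query)), collection$universe)
  if (length(query) == 0L) {
    stop_config("fisher_enrichment: query has no genes in the universe")
  }
  N <- length(collection$universe)
  n <- length(query)
  ids <- names(collection$terms)
  K <- vapply(collection$terms, length, integer(1))
  if (any(K == 0L)) {
    warning(sprintf("%d term(s) with no genes in the universe skipped",
                    sum(K == 0L)), call. = FALSE)
    ids <- ids[K > 0L]
  }
  rows <- lapply(ids, function(id) {
    members <- collection$terms[[id]]
    hit <- intersect(query, members)
    k <- length(hit)
    Ki <- length(members)
    p <- stats::phyper(k - 1L, Ki, N - Ki, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = collection$names[[id]],
               category = collection$category[[id]],
               k = k, K = Ki, n = n, N = N, p_value = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value <= q_threshold
  out <- out[order(out$q_value, out$p_value, out$term_id),
             c("term_id", "term_name", "category", "k", "K", "n", "N",
               "p_value", "q_value", "significant", "genes")]
  rownames(out) <- NULL
  out
}

#' Per-category query-gene counts
#'
#' Counts the distinct query genes falling in each category's terms
#' (deduplicated across terms), the data behind the classic BP/CC/MF
#' classification bar chart.
#'
#' @param records data.frame from [fisher_enrichment()].
#' @param collection The [gene_set_collection()] used.
#' @param query The query gene set used.
#' @return data.frame `category`, `n_genes`, sorted by category.
#' @export
category_counts <- function(records, collection, query) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (nrow(records) == 0L) {
    return(data.frame(category = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE))
  }
  query <- intersect(unique(as.character(query)), collection$universe)
  cats <- sort(unique(records$category))
  counts <- vapply(cats, function(cat) {
    terms_in <- records$term_id[records$category == cat]
    length(intersect(query,
                     unique(unlist(collection$terms[terms_in]))))
  }, integer(1))
  data.frame(category = cats, n_genes = unname(counts),
             stringsAsFactors = FALSE)
}
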