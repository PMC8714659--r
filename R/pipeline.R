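# End-to-end orchestration: simulate (or load) -> quantile normalize ->
# differential expression -> seed-site target prediction -> pair
# intersection -> curated cross-validation -> correlation filter ->
# network assembly -> hub ranking (optional) -> enrichment (optional).

#' Pipeline configuration
#'
#' Either a simulation block (`simulation`) or input paths must be given.
#' Thresholds default to the standard screen: |log2FC| > 1 with t-test
#' p < 0.05 for differential expression, Pearson r > 0.95 for ceRNA pairs,
#' PPI combined score >= 0.4, top 30 hubs, enrichment q <= 0.05.
#'
#' @param simulation A [simulation_config()], or `NULL` when reading files.
#' @param expression_tsv,transcripts_fasta Input paths (ignored when
#'   `simulation` is given).
#' @param curated Curated miRNA table (default [default_curated_mirnas()]).
#' @param ppi_tsv Optional STRING-style PPI edge list path.
#' @param gmt Optional gene-set GMT path.
#' @param fc_log2 Log2 fold-change threshold (strict).
#' @param p P-value threshold (strict).
#' @param r Correlation threshold (strict).
#' @param ppi_min_score PPI combined-score cutoff (inclusive).
#' @param hub_k Number of hub genes.
#' @param q Enrichment q-value cutoff (inclusive).
#' @param direction_consistency Enforce the RISC direction rule?
#' @param seed_types Allowed seed-site classes.
#' @param out_dir Output directory for all artifacts.
#' @param rng_seed Seed for any randomness in the run.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            expression_tsv = NULL, transcripts_fasta = NULL,
                            curated = default_curated_mirnas(),
                            ppi_tsv = NULL, gmt = NULL,
                            fc_log2 = 1, p = 0.05, r = 0.95,
                            ppi_min_score = 0.4, hub_k = 30, q = 0.05,
                            direction_consistency = TRUE,
                            seed_types = SITE_TYPES,
                            out_dir = tempfile("cernet_run_"),
                            rng_seed = 1) {
  if (is.null(simulation) &&
      (is.null(expression_tsv) || is.null(transcripts_fasta))) {
    stop_config("pipeline_config: give either a simulation block or expression_tsv + transcripts_fasta")
  }
  if (p <= 0 || p > 1) stop_config("pipeline_config: p must be in (0, 1]")
  if (q <= 0 || q > 1) stop_config("pipeline_config: q must be in (0, 1]")
  if (r < -1 || r >= 1) stop_config("pipeline_config: r must be in [-1, 1)")
  if (fc_log2 < 0) stop_config("pipeline_config: fc_log2 must be >= 0")
  if (ppi_min_score < 0 || ppi_min_score > 1) {
    stop_config("pipeline_config: ppi_min_score must be in [0, 1]")
  }
  if (hub_k < 1) stop_config("pipeline_config: hub_k must be >= 1")
  structure(list(simulation = simulation, expression_tsv = expression_tsv,
                 transcripts_fasta = transcripts_fasta, curated = curated,
                 ppi_tsv = ppi_tsv, gmt = gmt, fc_log2 = fc_log2, p = p,
                 r = r, ppi_min_score = ppi_min_score, hub_k = hub_k,
                 q = q, direction_consistency = direction_consistency,
                 seed_types = seed_types, out_dir = out_dir,
                 rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Run the ceRNA network inference pipeline end-to-end
#'
#' Executes every stage, writes all artifacts (TSV tables, FASTA, SIF,
#' GraphML) under `config$out_dir`, and returns a run manifest with the
#' effective configuration, per-stage record counts and per-artifact MD5
#' checksums. Identical config and seed reproduce identical artifact
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_manifest`: `config` (echo), `counts`,
#'   `checksums`, `results` (in-memory stage outputs: `expression`,
#'   `normalized`, `de`, `pairs_cerna`, `pairs_mrna`, `candidates`,
#'   `validated`, `triples`, `network`, `truth`, `hubs`,
#'   `validation_candidates`, `enrichment`), `version`, `timestamp`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)

  # --- inputs --------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    log_msg("simulate", "generating synthetic dataset")
    sim <- generate_dataset(config$simulation)
    expr <- sim$expression
    transcripts <- sim$transcripts
    truth <- sim$truth
    write_expression_tsv(expr, file.path(out_dir, "expression.tsv"))
    write_transcripts_fasta(transcripts, file.path(out_dir,
                                                   "transcripts.fasta"))
    write_truth_tsv(truth, file.path(out_dir, "truth"))
  } else {
    log_msg("load", "reading %s", config$expression_tsv)
    expr <- read_expression_tsv(config$expression_tsv)
    transcripts <- read_transcripts_fasta(config$transcripts_fasta)
  }

  # --- normalize + differential expression ---------------------------------
  log_msg("normalize", "quantile normalization of %d x %d matrix",
          nrow(expr$values), ncol(expr$values))
  norm <- quantile_normalize(expr)
  write_expression_tsv(norm, file.path(out_dir, "normalized.tsv"))
  de <- differential_expression(norm, fc_log2_threshold = config$fc_log2,
                                p_threshold = config$p)
  write_tsv_file(de, file.path(out_dir, "de.tsv"))
  write_volcano_tsv(de, file.path(out_dir, "volcano.tsv"))
  de_counts <- table(factor(de$kind[de$is_de], levels = FEATURE_KINDS))
  log_msg("de", "flagged: %s",
          paste(sprintf("%s=%d", names(de_counts), de_counts),
                collapse = ", "))

  # --- target prediction on differentially expressed transcripts ----------
  de_ids <- de$feature_id[de$is_de]
  mirnas <- transcripts[transcripts$kind == "miRNA", , drop = FALSE]
  ce_targets <- transcripts[transcripts$kind %in% c("lncRNA", "circRNA") &
                              transcripts$id %in% de_ids, , drop = FALSE]
  m_targets <- transcripts[transcripts$kind == "mRNA" &
                             transcripts$id %in% de_ids, , drop = FALSE]
  class(mirnas) <- class(ce_targets) <- class(m_targets) <-
    c("transcript_set", "data.frame")
  sites <- scan_seed_sites(mirnas,
                           rbind(ce_targets, m_targets),
                           allowed_types = config$seed_types)
  write_sites_tsv(sites, file.path(out_dir, "sites.tsv"))
  pairs_all <- pairs_to_table(sites)
  pairs_cerna <- pairs_all[pairs_all$target_kind %in% c("lncRNA", "circRNA"),
                           , drop = FALSE]
  pairs_mrna <- pairs_all[pairs_all$target_kind == "mRNA", , drop = FALSE]
  write_tsv_file(pairs_cerna, file.path(out_dir, "pairs_cerna.tsv"))
  write_tsv_file(pairs_mrna, file.path(out_dir, "pairs_mrna.tsv"))
  log_msg("targets", "%d ceRNA-miRNA pairs, %d mRNA-miRNA pairs",
          nrow(pairs_cerna), nrow(pairs_mrna))

  # --- intersect, cross-validate, correlation filter -----------------------
  candidates <- intersect_pairs(pairs_cerna, pairs_mrna)
  write_tsv_file(candidates, file.path(out_dir, "candidates.tsv"))
  validated <- cross_validate(candidates, config$curated)
  triples <- filter_correlation(validated, norm, de = de,
                                r_threshold = config$r,
                                require_direction_consistency =
                                  config$direction_consistency)
  write_tsv_file(triples, file.path(out_dir, "triples.tsv"))
  log_msg("cerna", "%d candidates -> %d cross-validated -> %d triples",
          nrow(candidates), nrow(validated), nrow(triples))

  # --- network -------------------------------------------------------------
  network <- assemble_network(triples)
  write_network_sif(network, file.path(out_dir, "network.sif"))
  if (nrow(network$nodes) > 0L) {
    write_network_graphml(network, file.path(out_dir, "network.graphml"))
  }
  write_network_tables(network, file.path(out_dir, "nodes.tsv"),
                       file.path(out_dir, "edges.tsv"))

  # --- optional: hubs ------------------------------------------------------
  hubs <- NULL
  validation_candidates <- NULL
  if (!is.null(config$ppi_tsv)) {
    ppi <- load_ppi_edges(config$ppi_tsv, min_score = config$ppi_min_score)
    hubs <- rank_hubs(ppi, k = config$hub_k)
    write_tsv_file(hubs, file.path(out_dir, "hubs.tsv"))
    validation_candidates <- select_validation_candidates(hubs, network)
    write_tsv_file(data.frame(gene = validation_candidates,
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "validation_candidates.tsv"))
    log_msg("hubs", "%d hubs, %d validation candidate(s)",
            nrow(hubs), length(validation_candidates))
  }

  # --- optional: enrichment ------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$gmt) && nrow(network$nodes) > 0L) {
    collection <- read_gmt(config$gmt)
    query <- network$nodes$id[network$nodes$kind == "mRNA"]
    if (length(intersect(query, collection$universe)) > 0L) {
      enrichment <- fisher_enrichment(query, collection,
                                      q_threshold = config$q)
      write_tsv_file(enrichment, file.path(out_dir, "enrichment.tsv"))
      write_tsv_file(category_counts(enrichment, collection, query),
                     file.path(out_dir, "category_counts.tsv"))
      log_msg("enrich", "%d terms tested, %d significant at q <= %g",
              nrow(enrichment), sum(enrichment$significant), config$q)
    } else {
      log_msg("enrich", "no network mRNA in the gene-set universe; skipped")
    }
  }

  counts <- c(list(de = as.list(de_counts),
                   pairs_cerna = nrow(pairs_cerna),
                   pairs_mrna = nrow(pairs_mrna),
                   candidates = nrow(candidates),
                   cross_validated = nrow(validated)),
              network_counts(network),
              list(hubs = if (is.null(hubs)) NA_integer_ else nrow(hubs),
                   validation_candidates =
                     if (is.null(validation_candidates)) NA_integer_
                     else length(validation_candidates)))
  artifacts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  checksums <- tools::md5sum(artifacts)
  names(checksums) <- list.files(out_dir, recursive = TRUE)

  manifest <- structure(
    list(config = config, counts = counts, checksums = as.list(checksums),
         results = list(expression = expr, normalized = norm, de = de,
                        sites = sites, pairs_cerna = pairs_cerna,
                        pairs_mrna = pairs_mrna, candidates = candidates,
                        validated = validated, triples = triples,
                        network = network, truth = truth, hubs = hubs,
                        validation_candidates = validation_candidates,
                        enrichment = enrichment),
         version = as.character(utils::packageVersion("cernet")),
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
  manifest
}

#' Write a run manifest as JSON
#'
#' Serializes the config echo (file paths and thresholds), stage counts,
#' artifact checksums, version and timestamp; in-memory results are not
#' serialized.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  cfg$curated <- NULL
  cfg$simulation <- if (!is.null(cfg$simulation)) {
    s <- unclass(cfg$simulation); s$curated <- NULL; s
  }
  jsonlite::write_json(list(config = unclass(cfg),
                            counts = manifest$counts,
                            checksums = manifest$checksums,
                            version = manifest$version,
                            timestamp = manifest$timestamp),
                       path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("cernet run manifest\n")
  cat(sprintf("  triples: %d  nodes: %d  edges: %d\n",
              x$counts$n_triples, x$counts$n_nodes, x$counts$n_edges))
  cat(sprintf("  candidates: %d  cross-validated: %d\n",
              x$counts$candidates, x$counts$cross_validated))
  invisible(x)
}
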