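# Synthetic-data generator: emulates the shape of a small paired case/control
# ceRNA microarray study (3 vs 3 samples; mRNA + lncRNA + circRNA + miRNA
# features; a minority of features differentially expressed) and plants known
# ceRNA triples with seed sites so the whole pipeline has a recoverable
# ground truth.

#' Simulation configuration
#'
#' @param n_case,n_control Samples per group (default 3 vs 3).
#' @param n_mrna,n_lncrna,n_circrna,n_mirna Feature counts per kind.
#' @param frac_de Fraction of all features carrying a planted effect
#'   (planted-triple members always do, and count toward it).
#' @param planted_log2fc Planted effect size, log2 units (default 2: a
#'   fourfold change, comfortably past an FC > 2 screen).
#' @param noise_sd Within-group standard deviation in log2 units.
#' @param n_triples Number of planted ceRNA triples.
#' @param transcript_len Target transcript length, nucleotides.
#' @param mirna_len miRNA length, nucleotides (default 22).
#' @param rng_seed Integer seed; identical seeds reproduce the dataset
#'   bit-for-bit.
#' @param curated Curated miRNA table ([default_curated_mirnas()] by
#'   default); planted miRNAs are named as mature arms (-5p, then -3p) of
#'   these stems so the cross-validation gate can be exercised, and their
#'   planted direction follows the curated label.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 3, n_control = 3,
                              n_mrna = 50, n_lncrna = 20, n_circrna = 20,
                              n_mirna = 10, frac_de = 0.1,
                              planted_log2fc = 2.0, noise_sd = 0.1,
                              n_triples = 5, transcript_len = 300,
                              mirna_len = 22, rng_seed = 1,
                              curated = default_curated_mirnas()) {
  cfg <- list(n_case = n_case, n_control = n_control, n_mrna = n_mrna,
              n_lncrna = n_lncrna, n_circrna = n_circrna, n_mirna = n_mirna,
              frac_de = frac_de, planted_log2fc = planted_log2fc,
              noise_sd = noise_sd, n_triples = n_triples,
              transcript_len = transcript_len, mirna_len = mirna_len,
              rng_seed = rng_seed, curated = curated)
  for (f in c("n_case", "n_control", "n_mrna", "n_lncrna", "n_circrna",
              "n_mirna")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) {
      stop_config("invalid simulation config: %s must be >= 1", f)
    }
  }
  if (!is.numeric(frac_de) || frac_de < 0 || frac_de > 1) {
    stop_config("invalid simulation config: frac_de must be in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_config("invalid simulation config: noise_sd must be >= 0")
  }
  if (!is.numeric(n_triples) || n_triples < 0) {
    stop_config("invalid simulation config: n_triples must be >= 0")
  }
  if (n_triples > min(n_lncrna + n_circrna, n_mirna, n_mrna)) {
    stop_config("invalid simulation config: n_triples exceeds min(n_lncrna + n_circrna, n_mirna, n_mrna)")
  }
  if (n_triples > 2L * nrow(curated)) {
    stop_config("invalid simulation config: n_triples exceeds 2 x nrow(curated) distinct mature arms")
  }
  if (mirna_len < 8) {
    stop_config("invalid simulation config: mirna_len must be >= 8")
  }
  if (transcript_len < 8) {
    stop_config("invalid simulation config: transcript_len must be >= 8")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Plant a seed site into a transcript sequence
#'
#' Overwrites the bases at `position` with the site string of the requested
#' class for the given miRNA: read 5'->3' on the target,
#' `[m8 complement][reverse complement of seed 2-7][A]` trimmed to the
#' class. Sequence length is unchanged. On circular sequences the site may
#' wrap the back-splice junction.
#'
#' @param sequence Target sequence (A/C/G/U; T accepted).
#' @param mirna_seq miRNA sequence, 5'->3', >= 8 nt.
#' @param position 0-based offset of the site's first base.
#' @param site_type One of [SITE_TYPES].
#' @param circular Does the sequence wrap (circRNA)?
#' @return The modified sequence.
#' @export
plant_seed_site <- function(sequence, mirna_seq, position,
                            site_type = "6mer", circular = FALSE) {
  sequence <- rna_sanitize(sequence, "target sequence")
  mirna_seq <- rna_sanitize(mirna_seq, "miRNA sequence")
  site_type <- match.arg(site_type, SITE_TYPES)
  site <- seed_site_string(mirna_seq, site_type)
  L <- nchar(sequence)
  len <- nchar(site)
  if (len > L) stop_config("site longer than target sequence")
  if (position < 0 ||
      (!circular && position + len > L) ||
      (circular && position >= L)) {
    stop_config("site position %d out of range for length-%d %s sequence",
                position, L, if (circular) "circular" else "linear")
  }
  chars <- strsplit(sequence, "")[[1]]
  idx <- ((position + seq_len(len) - 1L) %% L) + 1L
  chars[idx] <- strsplit(site, "")[[1]]
  paste(chars, collapse = "")
}

# The target-side site string for a miRNA and class, 5'->3'.
#' @noRd
seed_site_string <- function(mirna_seq, site_type) {
  core <- rna_revcomp(substr(mirna_seq, 2L, 7L))
  m8c <- unname(rna_complement_base(substr(mirna_seq, 8L, 8L)))
  switch(site_type,
         "6mer" = core,
         "7mer-A1" = paste0(core, "A"),
         "7mer-m8" = paste0(m8c, core),
         "8mer" = paste0(m8c, core, "A"))
}

#' @noRd
random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(RNA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic ceRNA study dataset
#'
#' Produces an expression matrix, transcript sequences and a ground-truth
#' table. Baseline log2 intensities are drawn N(8, 2) per feature
#' (microarray log-intensity scale); planted differential-expression
#' effects shift the case-group mean by a signed `planted_log2fc`. Each
#' planted triple (ceRNA, miRNA, mRNA) gets a shared per-sample latent term
#' (amplitude `2 * noise_sd`, negated for the miRNA) on top of the group
#' effect, so its ceRNA-mRNA correlation approaches 1 as `noise_sd -> 0`
#' and stays above chance same-sign pairs at any noise level. Triple
#' ceRNA/mRNA members share the planted sign, opposite the miRNA's curated
#' direction. Non-planted features are mutually independent.
#'
#' Transcript sequences are uniform over A/C/G/U, then scrubbed of any
#' accidental seed-complement anchor for every simulated miRNA before the
#' declared sites are planted, so seed sites gate candidacy exactly: the
#' only (miRNA, target) seed matches in the output are the planted ones.
#' Flanking bases of each planted site are pinned so the realized site
#' class equals the declared one.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `expression` ([expression_matrix()]),
#'   `transcripts` ([transcript_set()]) and `truth` (list with
#'   `de_features`, a named signed-log2FC vector; `planted_triples`, a
#'   data.frame `cerna_id`/`mirna_id`/`mrna_id`; `planted_sites`, a
#'   data.frame `mirna_id`/`target_id`/`position`/`site_type`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  cfg <- config
  set.seed(cfg$rng_seed)

  mrna_ids <- sprintf("mRNA_%03d", seq_len(cfg$n_mrna))
  lnc_ids <- sprintf("lncRNA_%03d", seq_len(cfg$n_lncrna))
  circ_ids <- sprintf("circRNA_%03d", seq_len(cfg$n_circrna))
  arm_names <- c(sprintf("hsa-%s-5p", cfg$curated$name),
                 sprintf("hsa-%s-3p", cfg$curated$name))
  arm_dirs <- rep(cfg$curated$direction, 2L)
  n_arm <- min(cfg$n_mirna, length(arm_names))
  mirna_ids <- c(arm_names[seq_len(n_arm)],
                 if (cfg$n_mirna > n_arm)
                   sprintf("sim-miR-%02d", seq_len(cfg$n_mirna - n_arm)))
  mirna_dirs <- c(arm_dirs[seq_len(n_arm)],
                  rep(NA_character_, cfg$n_mirna - n_arm))

  feature_ids <- c(mrna_ids, lnc_ids, circ_ids, mirna_ids)
  feature_kinds <- rep(c("mRNA", "lncRNA", "circRNA", "miRNA"),
                       c(cfg$n_mrna, cfg$n_lncrna, cfg$n_circrna,
                         cfg$n_mirna))
  n_feat <- length(feature_ids)

  # --- planted triples -----------------------------------------------------
  triples <- NULL
  if (cfg$n_triples > 0L) {
    tri_mirna <- sample(mirna_ids[seq_len(n_arm)], cfg$n_triples)
    tri_cerna <- sample(c(lnc_ids, circ_ids), cfg$n_triples)
    tri_mrna <- sample(mrna_ids, cfg$n_triples)
    triples <- data.frame(cerna_id = tri_cerna, mirna_id = tri_mirna,
                          mrna_id = tri_mrna, stringsAsFactors = FALSE)
  } else {
    triples <- data.frame(cerna_id = character(0), mirna_id = character(0),
                          mrna_id = character(0), stringsAsFactors = FALSE)
  }

  # --- planted DE effects --------------------------------------------------
  dir_sign <- function(d) ifelse(d == "up", 1, -1)
  de_features <- numeric(0)
  if (nrow(triples) > 0L) {
    for (t in seq_len(nrow(triples))) {
      s_mir <- dir_sign(mirna_dirs[match(triples$mirna_id[t], mirna_ids)])
      de_features[triples$mirna_id[t]] <- s_mir * cfg$planted_log2fc
      de_features[triples$cerna_id[t]] <- -s_mir * cfg$planted_log2fc
      de_features[triples$mrna_id[t]] <- -s_mir * cfg$planted_log2fc
    }
  }
  n_de_target <- round(cfg$frac_de * n_feat)
  n_extra <- max(0L, n_de_target - length(de_features))
  pool <- setdiff(feature_ids, names(de_features))
  if (n_extra > 0L && length(pool) > 0L) {
    extra <- sample(pool, min(n_extra, length(pool)))
    de_features[extra] <- sample(c(-1, 1), length(extra), replace = TRUE) *
      cfg$planted_log2fc
  }

  # --- sequences -----------------------------------------------------------
  mirna_seqs <- random_rna(cfg$n_mirna, cfg$mirna_len)
  repeat {
    # seeds must be distinct, and no miRNA's seed complement may occur
    # inside another miRNA's full 8mer site string: otherwise planting a
    # site for one miRNA deterministically creates a site for the other and
    # the planted truth could never be exact
    seeds <- substr(mirna_seqs, 2L, 7L)
    cores <- vapply(seeds, rna_revcomp, character(1))
    full_sites <- vapply(mirna_seqs, seed_site_string, character(1),
                         site_type = "8mer")
    bad <- duplicated(seeds)
    for (j in seq_along(mirna_seqs)) {
      if (bad[j]) next
      others <- full_sites[-j]
      if (any(vapply(others, function(s) grepl(cores[j], s, fixed = TRUE),
                     logical(1)))) {
        bad[j] <- TRUE
      }
    }
    if (!any(bad)) break
    mirna_seqs[bad] <- random_rna(sum(bad), cfg$mirna_len)
  }
  target_ids <- c(mrna_ids, lnc_ids, circ_ids)
  target_kinds <- rep(c("mRNA", "lncRNA", "circRNA"),
                      c(cfg$n_mrna, cfg$n_lncrna, cfg$n_circrna))
  target_seqs <- random_rna(length(target_ids), cfg$transcript_len)
  names(target_seqs) <- target_ids

  planted_sites <- plan_planted_sites(triples, mirna_ids, mirna_seqs,
                                      target_kinds, target_ids, cfg)
  sp <- scrub_and_plant(target_seqs, target_kinds, mirna_ids,
                        mirna_seqs, planted_sites)
  target_seqs <- sp$seqs
  planted_sites <- sp$planted_sites

  transcripts <- transcript_set(c(target_ids, mirna_ids),
                                c(target_kinds, rep("miRNA", cfg$n_mirna)),
                                c(unname(target_seqs), mirna_seqs))

  # --- expression values ---------------------------------------------------
  n_samp <- cfg$n_case + cfg$n_control
  sample_ids <- c(sprintf("case_%d", seq_len(cfg$n_case)),
                  sprintf("control_%d", seq_len(cfg$n_control)))
  sample_groups <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  is_case <- as.numeric(sample_groups == "case")

  baseline <- stats::rnorm(n_feat, mean = 8, sd = 2)
  # A planted effect is only a recoverable condition when both states sit in
  # the array's dynamic range: features carrying an effect get baselines from
  # the central band of the same N(8, 2) (rejection sampling), so a +/-2
  # shift never lands at the sparse tail of the intensity distribution.
  for (i in match(names(de_features), feature_ids)) {
    while (baseline[i] < 6.5 || baseline[i] > 9.5) {
      baseline[i] <- stats::rnorm(1, mean = 8, sd = 2)
    }
  }
  delta <- numeric(n_feat)
  delta[match(names(de_features), feature_ids)] <- de_features

  latent_sign <- numeric(n_feat)           # +1 ceRNA/mRNA, -1 miRNA, 0 else
  latent_of <- integer(n_feat)             # triple index owning the feature
  if (nrow(triples) > 0L) {
    for (t in seq_len(nrow(triples))) {
      i_ce <- match(triples$cerna_id[t], feature_ids)
      i_m <- match(triples$mrna_id[t], feature_ids)
      i_mi <- match(triples$mirna_id[t], feature_ids)
      latent_sign[c(i_ce, i_m)] <- 1
      latent_sign[i_mi] <- -1
      latent_of[c(i_ce, i_m, i_mi)] <- t
    }
  }
  z <- matrix(stats::rnorm(max(1L, nrow(triples)) * n_samp), ncol = n_samp)
  noise <- matrix(stats::rnorm(n_feat * n_samp, sd = cfg$noise_sd),
                  nrow = n_feat)

  values <- matrix(baseline, nrow = n_feat, ncol = n_samp) +
    outer(delta, is_case) + noise
  shared <- which(latent_sign != 0)
  for (i in shared) {
    values[i, ] <- values[i, ] +
      latent_sign[i] * 2 * cfg$noise_sd * z[latent_of[i], ]
  }

  expr <- expression_matrix(values, feature_ids, feature_kinds,
                            sample_ids, sample_groups)
  truth <- list(de_features = de_features,
                planted_triples = triples,
                planted_sites = planted_sites[, c("mirna_id", "target_id",
                                                  "position", "site_type")])
  list(expression = expr, transcripts = transcripts, truth = truth)
}

# Choose one seed site per planted-triple member (ceRNA and mRNA).
#' @noRd
plan_planted_sites <- function(triples, mirna_ids, mirna_seqs,
                               target_kinds, target_ids, cfg) {
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      position = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(triples) == 0L) return(empty)
  rows <- list()
  for (t in seq_len(nrow(triples))) {
    for (tid in c(triples$cerna_id[t], triples$mrna_id[t])) {
      type <- sample(SITE_TYPES, 1L)
      len <- SITE_TYPE_LEN[[type]]
      circular <- target_kinds[match(tid, target_ids)] == "circRNA"
      max_pos <- if (circular) cfg$transcript_len - 1L else
        cfg$transcript_len - len
      pos <- sample.int(max_pos + 1L, 1L) - 1L
      rows[[length(rows) + 1L]] <-
        data.frame(mirna_id = triples$mirna_id[t], target_id = tid,
                   position = pos, site_type = type,
                   circular = circular, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Remove accidental seed-complement anchors and plant declared sites so the
# realized seed matches equal the planted ones exactly. When a chance anchor
# falls wholly inside a planted (protected) region, the planted site is
# re-drawn at a new position rather than mutated.
#' @noRd
scrub_and_plant <- function(target_seqs, target_kinds, mirna_ids,
                            mirna_seqs, planted_sites) {
  L <- nchar(target_seqs[[1]])
  cores <- vapply(mirna_seqs, function(s) rna_revcomp(substr(s, 2, 7)),
                  character(1))
  names(cores) <- mirna_ids

  protected <- NULL  # per-target positions covered by sites + pinned flanks
  plant_all <- function(seqs) {
    protected <<- lapply(target_seqs, function(s) integer(0))
    for (r in seq_len(nrow(planted_sites))) {
      tid <- planted_sites$target_id[r]
      mseq <- mirna_seqs[match(planted_sites$mirna_id[r], mirna_ids)]
      type <- planted_sites$site_type[r]
      pos <- planted_sites$position[r]
      circ <- planted_sites$circular[r]
      seqs[[tid]] <- plant_seed_site(seqs[[tid]], mseq, pos, type, circ)
      len <- SITE_TYPE_LEN[[type]]
      site_pos <- (pos + seq_len(len) - 1L) %% L
      # pin flanks so a 6mer/7mer cannot be upgraded by a chance A or m8 base
      anchor <- if (type %in% c("8mer", "7mer-m8")) (pos + 1L) %% L else pos
      chars <- strsplit(seqs[[tid]], "")[[1]]
      pin <- integer(0)
      if (!type %in% c("8mer", "7mer-m8")) {
        p <- if (circ) (anchor - 1L) %% L else anchor - 1L
        if (p >= 0L) {
          m8c <- unname(rna_complement_base(substr(mseq, 8, 8)))
          if (chars[p + 1L] == m8c) {
            chars[p + 1L] <- sample(setdiff(RNA_ALPHABET, m8c), 1L)
          }
          pin <- c(pin, p)
        }
      }
      if (!type %in% c("8mer", "7mer-A1")) {
        p <- if (circ) (anchor + 6L) %% L else anchor + 6L
        if (p < L) {
          if (chars[p + 1L] == "A") {
            chars[p + 1L] <- sample(c("C", "G", "U"), 1L)
          }
          pin <- c(pin, p)
        }
      }
      seqs[[tid]] <- paste(chars, collapse = "")
      protected[[tid]] <<- union(protected[[tid]], c(site_pos, pin))
    }
    seqs
  }

  anchor_keys <- function() {
    if (nrow(planted_sites) == 0L) return(character(0))
    anchors <- ifelse(planted_sites$site_type %in% c("8mer", "7mer-m8"),
                      (planted_sites$position + 1L) %% L,
                      planted_sites$position %% L)
    paste(planted_sites$mirna_id, planted_sites$target_id, anchors)
  }

  redraw_site <- function(r) {
    type <- planted_sites$site_type[r]
    max_pos <- if (planted_sites$circular[r]) L - 1L else
      L - SITE_TYPE_LEN[[type]]
    planted_sites$position[r] <<- sample.int(max_pos + 1L, 1L) - 1L
  }

  base_seqs <- target_seqs
  for (iter in seq_len(500L)) {
    seqs <- plant_all(base_seqs)
    planted_anchor_key <- anchor_keys()
    extra <- list()
    for (j in seq_along(seqs)) {
      circ <- target_kinds[j] == "circRNA"
      subject <- if (circ) paste0(seqs[[j]], seqs[[j]]) else seqs[[j]]
      for (m in seq_along(cores)) {
        hits <- find_all_occurrences(cores[m], subject)
        if (circ) hits <- unique(hits[hits < L] %% L)
        for (a in hits) {
          key <- paste(mirna_ids[m], names(seqs)[j], a)
          if (!key %in% planted_anchor_key) {
            extra[[length(extra) + 1L]] <- list(target = j, anchor = a)
          }
        }
      }
    }
    if (length(extra) == 0L) {
      return(list(seqs = seqs, planted_sites = planted_sites))
    }
    for (e in extra) {
      tid <- names(base_seqs)[e$target]
      span <- (e$anchor + 0:5) %% L
      open <- setdiff(span, protected[[tid]])
      if (length(open) == 0L) {
        # chance anchor wholly inside a planted region: move that site
        for (r in which(planted_sites$target_id == tid)) redraw_site(r)
        next
      }
      chars <- strsplit(base_seqs[[tid]], "")[[1]]
      chars[open + 1L] <- sample(RNA_ALPHABET, length(open), replace = TRUE)
      base_seqs[[tid]] <- paste(chars, collapse = "")
    }
  }
  stop("seed-site scrubbing did not converge; try a different rng_seed")
}

#' Write the ground-truth tables as TSV
#' @param truth `truth` element of [generate_dataset()] output.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_truth_tsv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(data.frame(feature_id = names(truth$de_features),
                            planted_log2fc = unname(truth$de_features),
                            stringsAsFactors = FALSE),
                 file.path(dir, "de_features.tsv"))
  write_tsv_file(truth$planted_triples, file.path(dir, "planted_triples.tsv"))
  write_tsv_file(truth$planted_sites, file.path(dir, "planted_sites.tsv"))
  invisible(dir)
}

#' Simulate a STRING-style PPI edge list
#'
#' Builds an undirected protein-protein interaction table in the STRING
#' export dialect (`protein1`, `protein2`, `combined_score`). Genes in
#' `hubs` are wired to every other gene with confident scores so they rank
#' first by degree; remaining genes get sparse random edges, a fraction of
#' them below the conventional 0.4 confidence cutoff.
#'
#' @param genes Character vector of gene ids.
#' @param hubs Subset of `genes` to make high-degree.
#' @param background_edges Number of random non-hub edges.
#' @return data.frame `protein1`, `protein2`, `combined_score`.
#' @export
simulate_ppi_edges <- function(genes, hubs = character(0),
                               background_edges = 2L * length(genes)) {
  stopifnot(all(hubs %in% genes))
  rows <- list()
  for (h in hubs) {
    others <- setdiff(genes, h)
    rows[[length(rows) + 1L]] <-
      data.frame(protein1 = h, protein2 = others,
                 combined_score = round(stats::runif(length(others),
                                                     0.5, 0.99), 3),
                 stringsAsFactors = FALSE)
  }
  nonhub <- setdiff(genes, hubs)
  if (background_edges > 0L && length(nonhub) >= 2L) {
    p1 <- sample(nonhub, background_edges, replace = TRUE)
    p2 <- sample(nonhub, background_edges, replace = TRUE)
    keep <- p1 != p2
    rows[[length(rows) + 1L]] <-
      data.frame(protein1 = p1[keep], protein2 = p2[keep],
                 combined_score = round(stats::runif(sum(keep), 0.1, 0.99), 3),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a gene-set collection
#'
#' Random gene sets over a universe, plus optional "planted" terms that
#' contain a given query so over-representation is recoverable. Categories
#' cycle over the classic BP/CC/MF labels.
#'
#' @param universe Character vector of background genes.
#' @param n_terms Number of random terms.
#' @param term_size Genes per random term.
#' @param planted_query Genes to concentrate into the planted term
#'   (optional).
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(universe, n_terms = 10, term_size = 15,
                               planted_query = NULL) {
  cats <- c("BP", "CC", "MF")
  terms <- list()
  category <- character(0)
  for (i in seq_len(n_terms)) {
    id <- sprintf("TERM_%03d", i)
    terms[[id]] <- sample(universe, min(term_size, length(universe)))
    category[id] <- cats[(i - 1L) %% 3L + 1L]
  }
  if (!is.null(planted_query)) {
    terms[["TERM_PLANTED"]] <- unique(c(planted_query,
                                        sample(universe,
                                               min(3, length(universe)))))
    category["TERM_PLANTED"] <- "BP"
  }
  gene_set_collection(terms, category = category, universe = universe)
}
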