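# Canonical miRNA seed-site prediction. The seed is miRNA nucleotides 2-7
# (5'->3'); a target site is the Watson-Crick reverse complement of the seed,
# optionally extended by pairing to miRNA position 8 (m8) and/or an adenine
# on the target opposite miRNA position 1 (A1). Read 5'->3' on the target a
# full site is: [m8 complement][seed complement][A], giving the four
# canonical classes. G:U wobble pairs are not accepted in the seed.

#' Site classes from strongest to weakest
#' @export
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

SITE_TYPE_LEN <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)

# All (possibly overlapping) 0-based occurrences of `pattern` in `subject`.
#' @noRd
find_all_occurrences <- function(pattern, subject) {
  m <- gregexpr(sprintf("(?=%s)", pattern), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# Base at 0-based position i, wrapping modulo length when circular.
#' @noRd
base_at <- function(seq, i, circular) {
  L <- nchar(seq)
  if (circular) i <- i %% L
  if (i < 0L || i >= L) return(NA_character_)
  substr(seq, i + 1L, i + 1L)
}

# Substring [start, start+len) with circular wrap.
#' @noRd
substr_wrap <- function(seq, start, len, circular) {
  L <- nchar(seq)
  if (circular) {
    start <- start %% L
    doubled <- paste0(seq, seq)
    substr(doubled, start + 1L, start + len)
  } else {
    substr(seq, start + 1L, start + len)
  }
}

#' Find canonical seed sites of a miRNA on a target sequence
#'
#' Scans the target (sense strand, 5'->3') for perfect Watson-Crick
#' complements of the miRNA seed (positions 2-7) and classifies each hit
#' into the canonical classes `6mer`, `7mer-A1`, `7mer-m8`, `8mer`.
#' Each seed-complementary position is reported once, with the most
#' specific (longest) class applicable among `allowed_types`.
#'
#' Circular targets are scanned across the back-splice junction by doubling
#' the sequence; reported starts are taken modulo the length, so
#' `start < nchar(target_seq)` always, and a site may wrap (its `end`,
#' `start + site length`, then exceeds the length). Sites longer than the
#' whole circle are rejected.
#'
#' @param mirna_seq miRNA sequence, 5'->3', length >= 8 (T accepted for U).
#' @param target_seq Target sequence, 5'->3'.
#' @param circular Is the target a circular transcript (circRNA)?
#' @param allowed_types Subset of [SITE_TYPES] to report.
#' @return data.frame with columns `start` (0-based), `end` (= start + site
#'   length, half-open), `site_type`, `site_seq` (matched target substring).
#' @export
find_seed_sites <- function(mirna_seq, target_seq, circular = FALSE,
                            allowed_types = SITE_TYPES) {
  mirna_seq <- rna_sanitize(mirna_seq, "miRNA sequence")
  target_seq <- rna_sanitize(target_seq, "target sequence")
  if (nchar(mirna_seq) < 8L) {
    stop_config("miRNA sequence must be >= 8 nt (got %d)", nchar(mirna_seq))
  }
  allowed_types <- match.arg(allowed_types, SITE_TYPES, several.ok = TRUE)
  L <- nchar(target_seq)
  core <- rna_revcomp(substr(mirna_seq, 2L, 7L))        # complement of seed 2-7
  m8c <- unname(rna_complement_base(substr(mirna_seq, 8L, 8L)))
  empty <- data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), site_seq = character(0),
                      stringsAsFactors = FALSE)
  if (L < 6L) return(empty)

  if (circular) {
    anchors <- find_all_occurrences(core, paste0(target_seq, target_seq))
    anchors <- anchors[anchors < L]
  } else {
    anchors <- find_all_occurrences(core, target_seq)
  }
  if (length(anchors) == 0L) return(empty)

  rows <- lapply(anchors, function(a) {
    has_m8 <- identical(base_at(target_seq, a - 1L, circular), m8c)
    has_a1 <- identical(base_at(target_seq, a + 6L, circular), "A")
    applicable <- c("6mer",
                    if (has_a1) "7mer-A1",
                    if (has_m8) "7mer-m8",
                    if (has_m8 && has_a1) "8mer")
    applicable <- intersect(SITE_TYPES, intersect(applicable, allowed_types))
    applicable <- applicable[SITE_TYPE_LEN[applicable] <= L]  # window <= circle
    if (length(applicable) == 0L) return(NULL)
    type <- applicable[1L]                              # most specific
    len <- SITE_TYPE_LEN[[type]]
    start <- if (type %in% c("8mer", "7mer-m8")) a - 1L else a
    if (circular) start <- start %% L
    data.frame(start = start, end = start + len, site_type = type,
               site_seq = substr_wrap(target_seq, start, len, circular),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a miRNA set against a transcript set for seed sites
#'
#' @param mirnas A [transcript_set()] of miRNAs (kind `miRNA`).
#' @param targets A [transcript_set()] of candidate targets; circRNA entries
#'   are scanned circularly.
#' @param allowed_types Subset of [SITE_TYPES].
#' @return data.frame with `mirna_id`, `target_id`, `target_kind`, `start`,
#'   `end`, `site_type`, `site_seq`, sorted by (mirna_id, target_id, start).
#' @export
scan_seed_sites <- function(mirnas, targets, allowed_types = SITE_TYPES) {
  stopifnot(inherits(mirnas, "transcript_set"),
            inherits(targets, "transcript_set"))
  res <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(targets))) {
      s <- find_seed_sites(mirnas$sequence[i], targets$sequence[j],
                           circular = targets$topology[j] == "circular",
                           allowed_types = allowed_types)
      if (nrow(s) > 0L) {
        res[[length(res) + 1L]] <-
          cbind(data.frame(mirna_id = mirnas$id[i],
                           target_id = targets$id[j],
                           target_kind = targets$kind[j],
                           stringsAsFactors = FALSE), s)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), start = integer(0),
                      end = integer(0), site_type = character(0),
                      site_seq = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$mirna_id, out$target_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict miRNA-target pairs by seed matching
#'
#' One pair is emitted per (miRNA, target) with at least one seed site;
#' `n_sites` counts the sites and `best_site_type` is the strongest class
#' found (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#'
#' @inheritParams scan_seed_sites
#' @return data.frame with `mirna_id`, `target_id`, `target_kind`,
#'   `n_sites`, `best_site_type`, sorted by (mirna_id, target_id).
#' @export
predict_targets <- function(mirnas, targets, allowed_types = SITE_TYPES) {
  if (nrow(mirnas) == 0L || nrow(targets) == 0L) {
    log_msg("targets", "empty miRNA or target set: no pairs predicted")
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), n_sites = integer(0),
                      best_site_type = character(0), stringsAsFactors = FALSE))
  }
  sites <- scan_seed_sites(mirnas, targets, allowed_types)
  pairs_to_table(sites)
}

#' @noRd
pairs_to_table <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), n_sites = integer(0),
                      best_site_type = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(sites$mirna_id, sites$target_id, sep = "\r")
  split_idx <- split(seq_len(nrow(sites)), key)
  rows <- lapply(split_idx, function(idx) {
    data.frame(mirna_id = sites$mirna_id[idx[1]],
               target_id = sites$target_id[idx[1]],
               target_kind = sites$target_kind[idx[1]],
               n_sites = length(idx),
               best_site_type = SITE_TYPES[min(match(sites$site_type[idx],
                                                     SITE_TYPES))],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write seed sites as a BED-like TSV
#' @param sites data.frame from [scan_seed_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  write_tsv_file(sites[, c("target_id", "start", "end", "mirna_id",
                           "site_type")], path)
}
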