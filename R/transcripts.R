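#' Transcript set
#'
#' A table of RNA sequences with their molecular kind and topology. circRNA
#' entries are circular (the sequence is the back-spliced circle read once
#' from the junction); all other kinds are linear. DNA input (T) is accepted
#' and mapped to U.
#'
#' @param id Character vector of transcript ids.
#' @param kind Character vector: `mRNA`, `lncRNA`, `circRNA` or `miRNA`.
#' @param sequence Character vector of sequences over A/C/G/U (T accepted).
#' @return A data.frame of class `transcript_set` with columns `id`, `kind`,
#'   `topology`, `sequence`.
#' @export
transcript_set <- function(id, kind, sequence) {
  id <- as.character(id)
  kind <- as.character(kind)
  if (anyDuplicated(id)) stop_config("transcript ids must be unique")
  if (!all(kind %in% FEATURE_KINDS)) {
    stop_config("transcript kind must be one of: %s",
                paste(FEATURE_KINDS, collapse = ", "))
  }
  sequence <- rna_sanitize(as.character(sequence), "transcript sequence")
  if (any(nchar(sequence) == 0L)) stop_config("empty transcript sequence")
  out <- data.frame(id = id, kind = kind,
                    topology = ifelse(kind == "circRNA", "circular", "linear"),
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Write transcripts to FASTA
#'
#' Kind and topology are carried in the header as `id kind=<kind>
#' topology=<linear|circular>` so the file is self-describing.
#'
#' @param ts A [transcript_set()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(ts, path) {
  stopifnot(inherits(ts, "transcript_set"))
  seqs <- Biostrings::RNAStringSet(ts$sequence)
  names(seqs) <- sprintf("%s kind=%s topology=%s", ts$id, ts$kind, ts$topology)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read transcripts from FASTA
#'
#' Accepts the header-tag dialect written by [write_transcripts_fasta()], or
#' a plain FASTA plus a sidecar TSV (`id`, `kind`) from which topology is
#' derived (circRNA => circular).
#'
#' @param path FASTA path (RNA or DNA alphabet; T mapped to U).
#' @param kinds_tsv Optional sidecar TSV with columns `id` and `kind`.
#' @return A [transcript_set()].
#' @export
read_transcripts_fasta <- function(path, kinds_tsv = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (!is.null(kinds_tsv)) {
    ann <- read_tsv_file(kinds_tsv)
    kind <- ann$kind[match(ids, ann$id)]
    if (anyNA(kind)) {
      stop_config("transcripts missing from sidecar TSV: %s",
                  paste(ids[is.na(kind)], collapse = ", "))
    }
  } else {
    kind <- ifelse(grepl("kind=\\S+", headers),
                   sub(".*kind=(\\S+).*", "\\1", headers), NA_character_)
    if (anyNA(kind)) {
      stop_config("FASTA headers lack kind= tags and no sidecar TSV given")
    }
  }
  transcript_set(ids, kind, as.character(seqs))
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d sequences (", nrow(x)))
  kt <- table(factor(x$kind, levels = FEATURE_KINDS))
  cat(paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), ")\n")
  invisible(x)
}
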