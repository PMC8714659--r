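# Internal helpers shared across modules.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' @noRd
rna_sanitize <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("invalid characters in %s: %s", what,
                 paste(unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), ""))),
                       collapse = ", ")), call. = FALSE)
  }
  x
}

#' @noRd
rna_complement_base <- function(b) {
  c(A = "U", C = "G", G = "C", U = "A")[b]
}

#' Reverse complement of an RNA string
#' @noRd
rna_revcomp <- function(x) {
  chars <- strsplit(x, "")[[1]]
  paste(rev(unname(rna_complement_base(chars))), collapse = "")
}

# Stage-tagged logging to stderr; record-level drops are counted, never silent.
#' @noRd
log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' @noRd
stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Canonical miRNA name: lower case, optional species prefix ("hsa-") and
# mature-arm suffix ("-3p"/"-5p") stripped so curated stems match mature arms.
#' @noRd
normalize_mirna_name <- function(x) {
  x <- tolower(x)
  x <- sub("^[a-z]{3}-(?=(mir|let)-)", "", x, perl = TRUE)
  sub("-(3p|5p)$", "", x)
}

#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @noRd
read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
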