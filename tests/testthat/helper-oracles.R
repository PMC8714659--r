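# Independent oracles, written from first principles and kept free of the
# package's own scanning/statistics code paths.

# -- brute-force seed-site scan ---------------------------------------------
# Position-by-position modular base comparison against the miRNA itself
# (no reverse-complement precomputation shared with the implementation).
WC_PAIR <- c(A = "U", U = "A", C = "G", G = "C")

oracle_base <- function(seq, i, circular) {
  L <- nchar(seq)
  if (circular) i <- i %% L
  if (i < 0 || i >= L) return(NA_character_)
  substr(seq, i + 1, i + 1)
}

# does target position (anchor + offset) pair Watson-Crick with miRNA
# position mir_pos?  miRNA pairs antiparallel: target 5'->3' runs opposite
# the miRNA, so the base across from miRNA position p sits at
# anchor + (7 - p) for the seed-aligned anchor.
oracle_pairs_with <- function(target, anchor, mir, mir_pos, circular) {
  tb <- oracle_base(target, anchor + (7 - mir_pos), circular)
  mb <- substr(mir, mir_pos, mir_pos)
  !is.na(tb) && identical(unname(WC_PAIR[mb]), tb)
}

oracle_seed_sites <- function(mir, target, circular = FALSE,
                              allowed = c("8mer", "7mer-m8", "7mer-A1",
                                          "6mer")) {
  L <- nchar(target)
  hierarchy <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  len_of <- c("8mer" = 8, "7mer-m8" = 7, "7mer-A1" = 7, "6mer" = 6)
  out <- NULL
  anchors <- if (circular) 0:(L - 1) else 0:(L - 6)
  if (L < 6) anchors <- integer(0)
  for (a in anchors) {
    seed_ok <- all(vapply(2:7, function(p) {
      oracle_pairs_with(target, a, mir, p, circular)
    }, logical(1)))
    if (!seed_ok) next
    has_m8 <- oracle_pairs_with(target, a, mir, 8, circular)
    a1 <- oracle_base(target, a + 6, circular)
    has_a1 <- !is.na(a1) && a1 == "A"
    applicable <- c("6mer", if (has_a1) "7mer-A1", if (has_m8) "7mer-m8",
                    if (has_m8 && has_a1) "8mer")
    applicable <- hierarchy[hierarchy %in% intersect(applicable, allowed)]
    applicable <- applicable[len_of[applicable] <= L]
    if (length(applicable) == 0) next
    type <- applicable[1]
    start <- if (type %in% c("8mer", "7mer-m8")) a - 1 else a
    if (circular) start <- start %% L
    out <- rbind(out, data.frame(start = start, type = type,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  out[order(out$start), , drop = FALSE]
}

# -- pooled-variance t oracle ------------------------------------------------
# t from the closed form; two-tailed p by numeric integration of the t
# density (never via pt()).
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p <- 2 * integrate(dens, lower = abs(t), upper = Inf,
                     rel.tol = 1e-12)$value
  list(t = t, p = p)
}

# -- quantile normalization oracle -------------------------------------------
# sort each column, take row means, substitute by rank.
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) ref[rank(col)])
}

# -- hypergeometric upper tail by enumeration --------------------------------
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# -- Benjamini-Hochberg step-up, by hand -------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# -- misc --------------------------------------------------------------------
random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

triple_key <- function(d) paste(d$cerna_id, d$mirna_id, d$mrna_id)

small_sim <- function(...) {
  args <- utils::modifyList(list(n_mrna = 20, n_lncrna = 8, n_circrna = 8,
                                 n_mirna = 6, n_triples = 3,
                                 transcript_len = 150), list(...))
  do.call(simulation_config, args)
}

run_sim_pipeline <- function(sim_cfg, ...) {
  suppressMessages(run_pipeline(pipeline_config(simulation = sim_cfg,
                                                out_dir = tempfile("run_"),
                                                ...)))
}
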