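test_that("plant_seed_site writes the expected site string and respects bounds", {
  mir <- "AAGGCAAUGUCAGUCAGUCAGU"          # seed AGGCAA -> complement UUGCCU
  out <- plant_seed_site(strrep("G", 30), mir, 10, "6mer")
  expect_equal(substr(out, 11, 16), "UUGCCU")
  expect_equal(nchar(out), 30L)

  # planting then scanning returns the planted site
  hits <- find_seed_sites(mir, out)
  expect_equal(hits$start, 10L)

  # wrap on a circular sequence at position L - 3
  circ <- plant_seed_site(strrep("G", 25), mir, 22, "6mer", circular = TRUE)
  expect_equal(nchar(circ), 25L)
  hits_c <- find_seed_sites(mir, circ, circular = TRUE)
  expect_equal(hits_c$start, 22L)

  expect_error(plant_seed_site(strrep("G", 20), mir, 15, "8mer"),
               "out of range")
  expect_error(plant_seed_site(strrep("G", 20), mir, 20, "6mer",
                               circular = TRUE), "out of range")
  expect_error(plant_seed_site(strrep("G", 20), mir, -1, "6mer"),
               "out of range")
})

test_that("invalid simulation configs are rejected naming the offending field", {
  expect_error(simulation_config(n_case = 0), "n_case")
  expect_error(simulation_config(frac_de = 1.2), "frac_de")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
  expect_error(simulation_config(n_mirna = 3, n_triples = 4), "n_triples")
  expect_error(simulation_config(n_triples = 11, n_mirna = 11, n_mrna = 11),
               "curated")
})

test_that("equal seeds reproduce the dataset bit-for-bit; different seeds differ", {
  a <- generate_dataset(small_sim(rng_seed = 5))
  b <- generate_dataset(small_sim(rng_seed = 5))
  c <- generate_dataset(small_sim(rng_seed = 6))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$transcripts$sequence, b$transcripts$sequence)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("zero-noise planted effects appear exactly and the null config is empty", {
  sim <- generate_dataset(small_sim(noise_sd = 0, rng_seed = 3))
  de <- suppressMessages(differential_expression(sim$expression))
  planted <- sim$truth$de_features
  fc <- de$log2fc[match(names(planted), de$feature_id)]
  expect_equal(fc, unname(planted), tolerance = 1e-12)
  expect_setequal(de$feature_id[de$is_de], names(planted))

  null_sim <- generate_dataset(small_sim(frac_de = 0, n_triples = 0,
                                         noise_sd = 0, rng_seed = 3))
  expect_length(null_sim$truth$de_features, 0L)
  de0 <- differential_expression(null_sim$expression)
  expect_equal(sum(de0$is_de), 0L)
})

test_that("planted triples have consistent DE signs and seed sites on both members", {
  sim <- generate_dataset(small_sim(rng_seed = 9))
  tt <- sim$truth
  de <- tt$de_features
  for (t in seq_len(nrow(tt$planted_triples))) {
    tri <- tt$planted_triples[t, ]
    expect_equal(sign(de[[tri$cerna_id]]), sign(de[[tri$mrna_id]]))
    expect_equal(sign(de[[tri$cerna_id]]), -sign(de[[tri$mirna_id]]))
    expect_true(any(tt$planted_sites$mirna_id == tri$mirna_id &
                      tt$planted_sites$target_id == tri$cerna_id))
    expect_true(any(tt$planted_sites$mirna_id == tri$mirna_id &
                      tt$planted_sites$target_id == tri$mrna_id))
  }
})

test_that("seed sites gate candidacy: realized sites equal the planted ones exactly", {
  sim <- generate_dataset(small_sim(rng_seed = 13))
  tr <- sim$transcripts
  mirnas <- tr[tr$kind == "miRNA", ]; class(mirnas) <- class(tr)
  targets <- tr[tr$kind != "miRNA", ]; class(targets) <- class(tr)
  sites <- scan_seed_sites(mirnas, targets)
  got <- sites[, c("mirna_id", "target_id", "start", "site_type")]
  exp <- sim$truth$planted_sites[, c("mirna_id", "target_id", "position",
                                     "site_type")]
  got <- got[order(got$mirna_id, got$target_id), ]
  exp <- exp[order(exp$mirna_id, exp$target_id), ]
  expect_equal(got$mirna_id, exp$mirna_id)
  expect_equal(got$target_id, exp$target_id)
  expect_equal(got$start, exp$position)
  expect_equal(got$site_type, exp$site_type)
})

test_that("planted-triple members are tightly correlated at low noise", {
  sim <- generate_dataset(small_sim(noise_sd = 0.05, rng_seed = 17))
  v <- sim$expression$values
  for (t in seq_len(nrow(sim$truth$planted_triples))) {
    tri <- sim$truth$planted_triples[t, ]
    expect_gt(cor(v[tri$cerna_id, ], v[tri$mrna_id, ]), 0.95)
  }
})

test_that("triple recall degrades monotonically with noise", {
  recall_at <- function(noise_sd) {
    mean(vapply(1:20, function(s) {
      m <- run_sim_pipeline(small_sim(noise_sd = noise_sd, rng_seed = s))
      tt <- m$results$truth$planted_triples
      mean(triple_key(tt) %in% triple_key(m$results$triples))
    }, numeric(1)))
  }
  recalls <- vapply(c(0.05, 0.8, 2.0), recall_at, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_gte(recalls[1], 0.95)
})

test_that("generated artifacts round-trip through their file formats", {
  sim <- generate_dataset(small_sim(rng_seed = 23))
  dir <- tempfile(); dir.create(dir)
  fasta <- file.path(dir, "t.fasta")
  write_transcripts_fasta(sim$transcripts, fasta)
  back <- read_transcripts_fasta(fasta)
  expect_identical(back$sequence, sim$transcripts$sequence)
  expect_identical(back$kind, sim$transcripts$kind)
  expect_identical(back$topology, sim$transcripts$topology)
  write_truth_tsv(sim$truth, dir)
  expect_true(all(file.exists(file.path(dir, c("de_features.tsv",
                                               "planted_triples.tsv",
                                               "planted_sites.tsv")))))
})
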