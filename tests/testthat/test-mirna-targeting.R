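# The worked example miRNA: 5'-AAGGCAAU...-3', seed (2-7) = AGGCAA, whose
# target-side complement read 5'->3' is UUGCCU; the m8 base on the target
# is A (complement of U at miRNA position 8).
MIR <- "AAGGCAAUGUCAGUCAGUCAGU"

test_that("a 6mer seed complement is found where planted, with A1/m8 upgrades", {
  target <- paste0("GGGGGGGGGG", "UUGCCU", "GGGGGGGG")   # offset 10, flank G
  hits <- find_seed_sites(MIR, target)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10L)
  expect_equal(hits$site_type, "6mer")
  expect_equal(hits$site_seq, "UUGCCU")

  # A immediately 3' of the seed match upgrades to 7mer-A1
  target_a1 <- paste0("GGGGGGGGGG", "UUGCCU", "A", "GGGGGGG")
  hits_a1 <- find_seed_sites(MIR, target_a1)
  expect_equal(hits_a1$site_type, "7mer-A1")
  expect_equal(hits_a1$start, 10L)
  expect_equal(hits_a1$site_seq, "UUGCCUA")

  # m8 complement immediately 5' upgrades to 7mer-m8; both give 8mer
  target_m8 <- paste0("GGGGGGGGG", "A", "UUGCCU", "GGGGGGG")
  hits_m8 <- find_seed_sites(MIR, target_m8)
  expect_equal(hits_m8$site_type, "7mer-m8")
  expect_equal(hits_m8$start, 9L)
  target_8 <- paste0("GGGGGGGGG", "AUUGCCUA", "GGGGGG")
  hits_8 <- find_seed_sites(MIR, target_8)
  expect_equal(hits_8$site_type, "8mer")
  expect_equal(hits_8$site_seq, "AUUGCCUA")
})

test_that("targets without a seed complement yield no sites", {
  expect_equal(nrow(find_seed_sites(MIR, strrep("G", 50))), 0L)
  expect_equal(nrow(find_seed_sites(MIR, "UUGCC")), 0L)  # shorter than a site
})

test_that("each position is reported once with its most specific allowed type", {
  target_8 <- paste0("GGGGGGGGG", "AUUGCCUA", "GGGGGG")
  # full hierarchy: one site, the 8mer
  expect_equal(nrow(find_seed_sites(MIR, target_8)), 1L)
  # restricting the allowed classes falls back down the hierarchy
  expect_equal(find_seed_sites(MIR, target_8,
                               allowed_types = c("7mer-A1", "6mer"))$site_type,
               "7mer-A1")
  expect_equal(find_seed_sites(MIR, target_8,
                               allowed_types = "6mer")$site_type, "6mer")
})

test_that("sites wrapping the back-splice junction of a circular target are found", {
  # complement split across the junction: last 3 nt ... first 3 nt
  L <- 40
  base <- strrep("G", L)
  target <- plant_seed_site(base, MIR, L - 3, "6mer", circular = TRUE)
  hits <- find_seed_sites(MIR, target, circular = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, L - 3)
  expect_equal(hits$site_seq, "UUGCCU")
  # the same sequence scanned linearly has no site
  expect_equal(nrow(find_seed_sites(MIR, target, circular = FALSE)), 0L)
})

test_that("sites are reported on the sense strand only", {
  # a G-padded target with one planted site: its reverse complement holds
  # the seed itself, not the seed complement, so the scan finds nothing
  target <- plant_seed_site(strrep("G", 60), MIR, 20, "8mer")
  rc <- paste(rev(strsplit(chartr("ACGU", "UGCA", target), "")[[1]]),
              collapse = "")
  expect_gte(nrow(find_seed_sites(MIR, target)), 1L)
  expect_equal(nrow(find_seed_sites(MIR, rc)), 0L)
})

test_that("invalid miRNA input is rejected", {
  expect_error(find_seed_sites("AAGGCAA", "GGGGGGGG"), ">= 8")
  expect_error(find_seed_sites("AAGGCAAX", "GGGGGGGG"), "invalid characters")
  expect_error(find_seed_sites(MIR, "GGGXGGGG"), "invalid characters")
})

test_that("random linear and circular scans equal the brute-force oracle", {
  set.seed(99)
  for (i in 1:150) {
    mir <- random_rna_str(22)
    L <- sample(20:200, 1)
    circular <- i %% 3 == 0
    target <- random_rna_str(L)
    if (i %% 2 == 0) {  # plant a site, sometimes wrapping
      type <- sample(c("6mer", "7mer-A1", "7mer-m8", "8mer"), 1)
      pos <- if (circular) sample(0:(L - 1), 1) else
        sample(0:(L - 8), 1)
      target <- plant_seed_site(target, mir, pos, type, circular = circular)
    }
    got <- find_seed_sites(mir, target, circular = circular)
    exp <- oracle_seed_sites(mir, target, circular = circular)
    expect_equal(got$start, exp$start, info = sprintf("iter %d", i))
    expect_equal(got$site_type, exp$type, info = sprintf("iter %d", i))
  }
})

test_that("predict_targets aggregates sites per pair and sorts deterministically", {
  target <- strrep("G", 80)
  target <- plant_seed_site(target, MIR, 10, "6mer")
  target <- plant_seed_site(target, MIR, 40, "8mer")
  mirnas <- transcript_set("mir1", "miRNA", MIR)
  targets <- transcript_set("t1", "mRNA", target)
  pairs <- predict_targets(mirnas, targets)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$n_sites, 2L)
  expect_equal(pairs$best_site_type, "8mer")

  # seed absent by construction -> zero pairs
  no_site <- transcript_set("t2", "mRNA", strrep("G", 50))
  expect_equal(nrow(predict_targets(mirnas, no_site)), 0L)

  # empty input -> empty output with a logged message
  empty <- transcript_set("x", "miRNA", MIR)[0, ]
  class(empty) <- c("transcript_set", "data.frame")
  expect_message(out <- predict_targets(empty, targets), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("pairs from a generated dataset match an exhaustive per-combination oracle", {
  sim <- generate_dataset(small_sim(rng_seed = 21))
  tr <- sim$transcripts
  mirnas <- tr[tr$kind == "miRNA", ]; class(mirnas) <- class(tr)
  targets <- tr[tr$kind != "miRNA", ]; class(targets) <- class(tr)
  pairs <- predict_targets(mirnas, targets)
  # oracle: brute-force every combination
  expected <- NULL
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(targets))) {
      o <- oracle_seed_sites(mirnas$sequence[i], targets$sequence[j],
                             circular = targets$topology[j] == "circular")
      if (nrow(o) > 0) {
        expected <- rbind(expected,
                          data.frame(mirna_id = mirnas$id[i],
                                     target_id = targets$id[j],
                                     n_sites = nrow(o),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  expected <- expected[order(expected$mirna_id, expected$target_id), ]
  expect_equal(pairs$mirna_id, expected$mirna_id)
  expect_equal(pairs$target_id, expected$target_id)
  expect_equal(pairs$n_sites, expected$n_sites)
})
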