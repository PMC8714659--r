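fake_pairs <- function(mirna, target, kind) {
  data.frame(mirna_id = mirna, target_id = target, target_kind = kind,
             n_sites = 1L, best_site_type = "6mer", stringsAsFactors = FALSE)
}

test_that("pair intersection is the join on shared miRNAs", {
  ce <- fake_pairs(c("m1", "m1"), c("lnc1", "lnc2"), "lncRNA")
  mm <- fake_pairs(c("m1", "m1", "m1"), c("g1", "g2", "g3"), "mRNA")
  out <- intersect_pairs(ce, mm)
  expect_equal(nrow(out), 6L)   # 2 ceRNAs x 3 mRNAs through one miRNA

  disjoint <- intersect_pairs(fake_pairs("m1", "lnc1", "lncRNA"),
                              fake_pairs("m2", "g1", "mRNA"))
  expect_equal(nrow(disjoint), 0L)
  expect_equal(nrow(intersect_pairs(ce[0, ], mm)), 0L)

  # nested-loop join oracle on a random pair set
  set.seed(31)
  ce2 <- fake_pairs(sample(paste0("m", 1:4), 12, TRUE),
                    sample(paste0("lnc", 1:6), 12, TRUE), "lncRNA")
  ce2 <- ce2[!duplicated(ce2[, 1:2]), ]
  mm2 <- fake_pairs(sample(paste0("m", 1:4), 12, TRUE),
                    sample(paste0("g", 1:6), 12, TRUE), "mRNA")
  mm2 <- mm2[!duplicated(mm2[, 1:2]), ]
  got <- intersect_pairs(ce2, mm2)
  expected <- 0L
  for (i in seq_len(nrow(ce2))) for (j in seq_len(nrow(mm2))) {
    if (ce2$mirna_id[i] == mm2$mirna_id[j]) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
})

test_that("cross-validation keeps curated miRNAs, matching arms to stems", {
  cands <- data.frame(cerna_id = c("l1", "l2", "l3"),
                      cerna_kind = "lncRNA",
                      mirna_id = c("hsa-miR-27b-3p", "miR-999", "MIR-146A"),
                      mrna_id = c("g1", "g2", "g3"),
                      stringsAsFactors = FALSE)
  out <- cross_validate(cands)
  expect_setequal(out$mirna_id, c("hsa-miR-27b-3p", "MIR-146A"))
  expect_equal(out$mirna_direction[out$mirna_id == "hsa-miR-27b-3p"], "down")
  expect_equal(out$mirna_direction[out$mirna_id == "MIR-146A"], "up")

  expect_error(cross_validate(cands, data.frame(name = character(0),
                                                direction = character(0))),
               "empty")
})

test_that("pearson_r matches the first-principles formula and validates input", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 1, 4, 3, 6, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_r(1:2, 1:2), "length")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero-variance")
})

make_cand_expr <- function(profiles) {
  ids <- names(profiles)
  expression_matrix(do.call(rbind, profiles), ids,
                    rep("mRNA", length(ids)),
                    sprintf("s%d", seq_len(6)),
                    rep(c("case", "control"), each = 3))
}

test_that("the correlation filter applies the strict r threshold and direction rule", {
  prof <- list(lnc1 = c(10, 10.1, 9.9, 8, 8.1, 7.9),
               g1 = c(12, 12.1, 11.9, 10, 10.1, 9.9),      # r = 1 with lnc1
               g2 = c(12, 11.9, 12.1, 10.1, 9.5, 10.6))     # decorrelated
  expr <- make_cand_expr(prof)
  r_g2 <- cor(prof$lnc1, prof$g2)
  expect_lt(r_g2, 0.95)      # the fixture sits below the strict threshold
  cands <- data.frame(cerna_id = "lnc1", cerna_kind = "lncRNA",
                      mirna_id = "hsa-miR-27b-3p", mrna_id = c("g1", "g2"),
                      mirna_direction = "down", stringsAsFactors = FALSE)
  de <- differential_expression(expr)
  out <- filter_correlation(cands, expr, de = de)
  expect_equal(out$mrna_id, "g1")
  expect_gt(out$r, 0.95)

  # the g2 candidate survives only when the threshold is lowered below its r
  out_low <- filter_correlation(cands, expr, de = de, r_threshold = r_g2 - 0.01)
  expect_setequal(out_low$mrna_id, c("g1", "g2"))

  # direction rule: an up-regulated curated miRNA kills a same-sign-up pair
  cands_up <- transform(cands, mirna_direction = "up")
  out_up <- filter_correlation(cands_up, expr, de = de)
  expect_equal(nrow(out_up), 0L)
  out_up_off <- filter_correlation(cands_up, expr, de = de,
                                   require_direction_consistency = FALSE)
  expect_equal(out_up_off$mrna_id, "g1")

  # missing member is an error naming the id
  bad <- transform(cands, mrna_id = c("gX", "g2"))
  expect_error(filter_correlation(bad, expr, de = de), "gX")
})

test_that("triple count is monotone in r_threshold and in the direction flag", {
  m <- run_sim_pipeline(small_sim(noise_sd = 0.3, rng_seed = 41))
  validated <- m$results$validated
  expr <- m$results$normalized
  de <- m$results$de
  counts <- vapply(c(0.5, 0.8, 0.95, 0.99), function(thr) {
    nrow(filter_correlation(validated, expr, de = de, r_threshold = thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  n_dir_on <- nrow(filter_correlation(validated, expr, de = de))
  n_dir_off <- nrow(filter_correlation(validated, expr, de = de,
                                       require_direction_consistency = FALSE))
  expect_gte(n_dir_off, n_dir_on)
})

demo_triples <- function() {
  data.frame(cerna_id = c("lnc1", "circ1"), cerna_kind = c("lncRNA", "circRNA"),
             mirna_id = "mirA", mrna_id = c("g1", "g2"),
             mirna_direction = "down", r = c(0.99, 0.98),
             cerna_log2fc = 2, mrna_log2fc = 2,
             passed_filters = "seed+cross-validation+correlation+direction",
             stringsAsFactors = FALSE)
}

test_that("network assembly deduplicates nodes and annotates regulation", {
  one <- assemble_network(demo_triples()[1, ])
  expect_equal(nrow(one$nodes), 3L)
  expect_equal(nrow(one$edges), 2L)

  two <- assemble_network(demo_triples())   # two triples sharing the miRNA
  expect_equal(nrow(two$nodes), 5L)
  expect_equal(nrow(two$edges), 4L)
  expect_equal(two$nodes$regulation[two$nodes$id == "mirA"], "down")
  expect_equal(two$nodes$regulation[two$nodes$id == "g1"], "up")
  expect_setequal(two$nodes$kind[two$nodes$id %in% c("lnc1", "circ1")],
                  c("lncRNA", "circRNA"))
  # every edge endpoint is a node and every edge traces to a triple
  expect_true(all(c(two$edges$from, two$edges$to) %in% two$nodes$id))
  expect_true(all(nchar(two$edges$triples) > 0))

  counts <- network_counts(two)
  expect_equal(counts$n_triples, 2L)
  expect_equal(counts$n_cerna_mrna_pairs, 2L)
  expect_equal(counts$n_edges, 4L)
})

test_that("network export formats are readable", {
  net <- assemble_network(demo_triples())
  sif <- tempfile(fileext = ".sif")
  graphml <- tempfile(fileext = ".graphml")
  write_network_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, 4L)
  expect_true(all(grepl("\t(cerna-mirna|mirna-mrna)\t", lines)))
  write_network_graphml(net, graphml)
  g <- igraph::read_graph(graphml, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
})

test_that("emitted triples always carry curated miRNAs and planted recovery holds across seeds", {
  curated_stems <- tolower(sub("^hsa-", "",
                               default_curated_mirnas()$name))
  recalls <- vapply(1:20, function(s) {
    m <- run_sim_pipeline(small_sim(noise_sd = 0.05, rng_seed = 100 + s))
    tr <- m$results$triples
    tt <- m$results$truth$planted_triples
    if (nrow(tr) > 0) {
      stems <- tolower(sub("^hsa-", "", sub("-(3p|5p)$", "", tr$mirna_id)))
      expect_true(all(stems %in% curated_stems))
      # precision: nothing outside the planted truth survives
      expect_true(all(triple_key(tr) %in% triple_key(tt)))
    }
    mean(triple_key(tt) %in% triple_key(tr))
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})
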