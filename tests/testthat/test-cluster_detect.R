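# Anchor finding and the neighborhood calling rule.

make_genome <- function(families, contig = "c1", genome = "g1") {
  n <- length(families)
  data.frame(genome_id = genome, contig_id = contig, ordinal = 0:(n - 1),
             gene_id = sprintf("%s_%s_g%02d", genome, contig, 1:n),
             length_nt = 1000L, families = families,
             stringsAsFactors = FALSE)
}

## a full 7-gene cluster padded with unannotated genes on both sides
full_cluster <- function(pad = 10) {
  make_genome(c(rep(NA, pad),
                "PF01497", "PF01032", "PF00005", "PF00593",
                "PF03544", "PF01618", "PF02472",
                rep(NA, pad)))
}

test_that("anchors are found by family match and returned in stable order", {
  g <- make_genome(c(NA, "PF01497", NA))
  expect_equal(nrow(find_anchors(g)), 0)

  g2 <- full_cluster()
  a <- find_anchors(g2)
  expect_equal(nrow(a), 1)
  expect_equal(a$ordinal, 13)

  ## two receptors on different contigs, sorted (contig_id, ordinal)
  g3 <- rbind(make_genome(c(NA, "COG4771", NA), contig = "c2"),
              make_genome(c("PF00593", NA, NA), contig = "c1"))
  a3 <- find_anchors(g3)
  expect_equal(nrow(a3), 2)
  expect_equal(a3$contig_id, c("c1", "c2"))
  expect_equal(a3$ordinal, c(0, 1))
})

test_that("duplicate gene ids are rejected", {
  g <- full_cluster()
  g$gene_id[2] <- g$gene_id[1]
  expect_error(find_anchors(g), "duplicate")
})

test_that("neighborhood honors the window and excludes the anchor", {
  g <- make_genome(c("PF00593", NA, NA))
  expect_equal(nrow(neighborhood(g, g$gene_id[1], window = 8)), 2)

  g5 <- make_genome(c(NA, NA, "PF00593", NA, NA))
  nb <- neighborhood(g5, g5$gene_id[3], window = 1)
  expect_equal(nb$ordinal, c(1, 3))

  big <- full_cluster(pad = 20)
  anchor <- big$gene_id[big$ordinal == 23]
  expect_lte(nrow(neighborhood(big, anchor, window = 8)), 16)
})

test_that("consumer calls follow the quorum-or-interrupted rule", {
  g <- full_cluster()
  anchor <- find_anchors(g)$gene_id
  call <- call_consumer(g, anchor)
  expect_true(call$is_consumer)
  expect_false(call$interrupted)
  expect_equal(call$n_found, 6)

  ## 4 accessory groups, anchor mid-contig on a long contig: not a consumer
  g4 <- make_genome(c(rep(NA, 10), "PF01497", "PF01032", "PF00005",
                      "PF00593", "PF03544", rep(NA, 10)))
  call4 <- call_consumer(g4, find_anchors(g4)$gene_id)
  expect_equal(call4$n_found, 4)
  expect_false(call4$interrupted)
  expect_false(call4$is_consumer)

  ## bare anchor 2 genes from the contig end: interrupted, hence consumer
  ge <- make_genome(c(rep(NA, 12), "PF00593", NA, NA))
  calle <- call_consumer(ge, find_anchors(ge)$gene_id)
  expect_equal(calle$n_found, 0)
  expect_true(calle$interrupted)
  expect_true(calle$is_consumer)
})

test_that("genome verdicts aggregate anchors and default to non-consumer", {
  empty <- data.frame(genome_id = character(), is_consumer = logical())
  v <- genome_verdict(empty, genome_ids = c("gA", "gB"))
  expect_false(any(v$is_consumer))

  calls <- data.frame(genome_id = "gA",
                      is_consumer = c(FALSE, TRUE, FALSE))
  expect_true(genome_verdict(calls)$is_consumer)

  calls_all_false <- data.frame(genome_id = "gA", is_consumer = rep(FALSE, 3))
  expect_false(genome_verdict(calls_all_false)$is_consumer)
})

test_that("calls match a brute-force scan on random genomes", {
  ann <- random_genomes(100, seed = 7)
  res <- detect_clusters(ann)
  for (g in split(ann, ann$genome_id)) {
    oracle <- brute_force_calls(g)
    mine <- res$calls[res$calls$genome_id == g$genome_id[1], , drop = FALSE]
    mine <- mine[order(mine$anchor_gene_id), , drop = FALSE]
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(mine$anchor_gene_id, oracle$anchor_gene_id)
      expect_equal(mine$n_found, oracle$n_found)
      expect_equal(mine$interrupted, oracle$interrupted)
      expect_equal(mine$is_consumer, oracle$is_consumer)
    }
  }
})

test_that("adding accessory genes or widening the window is monotone", {
  g4 <- make_genome(c(rep(NA, 10), "PF01497", "PF01032", "PF00005",
                      "PF00593", "PF03544", NA, rep(NA, 9)))
  anchor <- find_anchors(g4)$gene_id
  before <- call_consumer(g4, anchor)
  g5 <- g4
  g5$families[g5$ordinal == 15] <- "PF01618"  # add a fifth group in-window
  after <- call_consumer(g5, anchor)
  expect_gte(after$n_found, before$n_found)
  expect_true(after$is_consumer)

  narrow <- call_consumer(g5, anchor, trait_profile(window = 2, edge_margin = 8))
  wide <- call_consumer(g5, anchor, trait_profile(window = 8))
  expect_gte(wide$n_found, narrow$n_found)
})

test_that("an external biosynthesis screen demotes producers", {
  sim <- simulate_genomes(genome_sim_spec(10, trait_freq = 1,
                                          completeness = 1, seed = 6))
  ids <- sort(unique(sim$annotations$genome_id))
  syn <- setNames(rep(c(TRUE, FALSE), length.out = length(ids)), ids)
  res <- detect_clusters(sim$annotations, biosynthesis = syn)
  expect_true(all(res$verdicts$has_cluster))
  expect_equal(res$verdicts$is_consumer, !unname(syn[res$verdicts$genome_id]))
})

test_that("calling is invariant to gene relabeling and contig order", {
  ann <- random_genomes(20, seed = 9)
  base <- detect_clusters(ann)$verdicts

  relabeled <- ann
  relabeled$gene_id <- paste0("x_", relabeled$gene_id)
  shuffled <- relabeled[sample.int(nrow(relabeled)), ]
  v2 <- detect_clusters(shuffled)$verdicts
  expect_equal(base$is_consumer, v2$is_consumer)
})
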