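test_that("mapping-graph edges weight length times identity and accumulate", {
  m <- mk_hits(query = "ctgA", qs = 0, qe = 1e5, target = "ctgB",
               identity = 0.95, qlen = 2e6, tlen = 2e6)
  g <- build_mapping_graph(m, min_contig_len = 1e6)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 95000)

  # parallel mappings accumulate; direction does not matter
  m2 <- rbind(m, mk_hits(query = "ctgB", qs = 2e5, qe = 3e5, target = "ctgA",
                         identity = 0.9, qlen = 2e6, tlen = 2e6))
  g <- build_mapping_graph(m2, min_contig_len = 1e6)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 95000 + 90000)

  # short contigs are excluded entirely
  m3 <- mk_hits(query = "ctgC", qs = 0, qe = 1e5, target = "ctgA",
                identity = 0.95, qlen = 9e5, tlen = 2e6)
  g <- build_mapping_graph(rbind(m, m3), min_contig_len = 1e6)
  expect_false("ctgC" %in% igraph::V(g)$name)

  # no mappings -> isolated nodes only
  empty <- m[0, ]
  g <- build_mapping_graph(empty, min_contig_len = 1e6,
                           contig_lens = c(a = 2e6, b = 3e6))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 0)
})

test_that("chromosome/arm labelling follows the pq rule", {
  arms <- reference_arms("chr13", 4e6, 5e6, 12e6)
  # 5 kb on each arm, 2 Mb from the centromere -> pq
  h <- rbind(mk_hits(query = "c1", qs = 0, qe = 5e3, target = "chr13",
                     identity = 0.95, ts = 2e6, te = 2.005e6,
                     qlen = 2e6, tlen = 12e6),
             mk_hits(query = "c1", qs = 1e6, qe = 1.005e6, target = "chr13",
                     identity = 0.95, ts = 7e6, te = 7.005e6,
                     qlen = 2e6, tlen = 12e6))
  lab <- assign_chromosome_labels(h, arms)
  expect_equal(lab$arm, "pq")
  expect_equal(lab$chromosome, "chr13")

  # q-arm-only contig
  h <- mk_hits(query = "c2", qs = 0, qe = 1e5, target = "chr13",
               identity = 0.95, ts = 7e6, te = 7.1e6, qlen = 2e6, tlen = 12e6)
  expect_equal(assign_chromosome_labels(h, arms)$arm, "q")

  # 500-bp p-arm mapping falls below arm_min -> q
  h <- rbind(mk_hits(query = "c3", qs = 0, qe = 500, target = "chr13",
                     identity = 0.95, ts = 2e6, te = 2.0005e6,
                     qlen = 2e6, tlen = 12e6),
             mk_hits(query = "c3", qs = 1e6, qe = 1.5e6, target = "chr13",
                     identity = 0.95, ts = 7e6, te = 7.5e6,
                     qlen = 2e6, tlen = 12e6))
  expect_equal(assign_chromosome_labels(h, arms)$arm, "q")

  # unknown chromosome in the mapping -> error
  h <- mk_hits(query = "c4", qs = 0, qe = 1e5, target = "chrZ",
               identity = 0.95, ts = 0, te = 1e5, qlen = 2e6, tlen = 12e6)
  expect_error(assign_chromosome_labels(h, arms), "chrZ")

  # unmapped contigs listed explicitly come back unassigned
  lab <- assign_chromosome_labels(
    mk_hits(query = "c2", qs = 0, qe = 1e5, target = "chr13",
            identity = 0.95, ts = 7e6, te = 7.1e6, qlen = 2e6, tlen = 12e6),
    arms, contigs = c("c2", "c9"))
  expect_equal(lab$arm[lab$contig == "c9"], "unassigned")
})

test_that("detect_communities splits weakly joined cliques and not uniform graphs", {
  clique_edges <- function(nodes) {
    t(utils::combn(nodes, 2))
  }
  e1 <- clique_edges(paste0("a", 1:6))
  e2 <- clique_edges(paste0("b", 1:6))
  g <- igraph::graph_from_data_frame(
    data.frame(from = c(e1[, 1], e2[, 1], "a1"),
               to = c(e1[, 2], e2[, 2], "b1"),
               weight = c(rep(1, nrow(e1) + nrow(e2)), 0.01)),
    directed = FALSE)
  part <- detect_communities(g, seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[paste0("a", 1:6)])), 1)
  expect_equal(length(unique(part[paste0("b", 1:6)])), 1)
  # deterministic under a fixed seed
  expect_identical(part, detect_communities(g, seed = 1))

  full <- igraph::make_full_graph(8)
  igraph::V(full)$name <- paste0("n", 1:8)
  igraph::E(full)$weight <- 1
  expect_equal(length(unique(detect_communities(full, seed = 1))), 1)
})

test_that("planted 5-block graphs are recovered with high ARI", {
  skip_if_not_installed("mclust")
  for (sd in 1:3) {
    set.seed(sd)
    blocks <- rep(1:5, each = 30)
    n <- length(blocks)
    pairs <- t(utils::combn(n, 2))
    p <- ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]], 0.6, 0.01)
    keep <- runif(nrow(pairs)) < p
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("v", pairs[keep, 1]),
                 to = paste0("v", pairs[keep, 2]), weight = 1),
      directed = FALSE,
      vertices = data.frame(name = paste0("v", 1:n)))
    part <- detect_communities(g, seed = sd)
    ari <- mclust::adjustedRandIndex(part[paste0("v", 1:n)], blocks)
    expect_gte(ari, 0.9)
  }
})

test_that("community_contingency counts contigs and sequence fractions", {
  part <- c(c1 = 1L, c2 = 1L, c3 = 2L)
  labels <- data.frame(contig = c("c1", "c2", "c3"),
                       chromosome = c("chr13", "chr13", "chr21"),
                       arm = c("p", "q", "p"), stringsAsFactors = FALSE)
  lens <- c(c1 = 1e6, c2 = 2e6, c3 = 1e6)
  tab <- community_contingency(part, labels, lens)
  expect_equal(sum(tab$n_contigs), 3)
  expect_equal(sum(tab$seq_fraction), 1)
  expect_equal(tab$n_contigs[tab$community == 1 & tab$chromosome == "chr13"], 2)

  expect_equal(nrow(community_contingency(integer(), labels, lens)), 0)
})

test_that("exchange fixtures merge the sharing set's p-arm contigs", {
  rs <- std_refset(seed = 3, sharing = list(c(1, 2, 4), c(1, 2, 4)))
  sim <- simulate_mosaic_contigs(rs, contigs_per_chrom = 6,
                                 exchange_rate = 1.0, seed = 3)
  cg <- simulate_contig_graph_mappings(rs, sim$truth)
  g <- build_mapping_graph(cg$records, min_contig_len = 1e5,
                           contig_lens = cg$part_lens)
  part <- detect_communities(g, seed = 1)
  share_p <- cg$part_labels$part[cg$part_labels$arm == "p" &
                                   cg$part_labels$chromosome %in%
                                   c("chr01", "chr02", "chr04")]
  expect_equal(length(unique(part[share_p])), 1)

  # without exchange every chromosome keeps its own communities
  sim0 <- simulate_mosaic_contigs(rs, contigs_per_chrom = 6,
                                  exchange_rate = 0, seed = 3)
  cg0 <- simulate_contig_graph_mappings(rs, sim0$truth)
  g0 <- build_mapping_graph(cg0$records, min_contig_len = 1e5,
                            contig_lens = cg0$part_lens)
  part0 <- detect_communities(g0, seed = 1)
  lab0 <- stats::setNames(cg0$part_labels$chromosome, cg0$part_labels$part)
  # each community contains contigs of exactly one chromosome
  for (cm in unique(part0))
    expect_equal(length(unique(lab0[names(part0)[part0 == cm]])), 1)
})
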