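test_that("identity_from_jaccard applies the Dice transform", {
  expect_equal(identity_from_jaccard(1), 1)
  expect_equal(identity_from_jaccard(0), 0)
  expect_equal(identity_from_jaccard(0.9), 2 * 0.9 / 1.9)
  expect_error(identity_from_jaccard(1.1), "out of")
  expect_error(identity_from_jaccard(-0.1), "out of")
  # monotone, and the inverse round-trips
  j <- seq(0, 1, by = 0.01)
  expect_true(all(diff(identity_from_jaccard(j)) > 0))
  expect_equal(jaccard_from_identity(identity_from_jaccard(j)), j,
               tolerance = 1e-12)
})

test_that("filter_hits enforces the strict identity floor and masks", {
  h <- mk_hits(qs = c(0, 5e4, 1e5), qe = c(5e4, 1e5, 1.5e5),
               target = "chrA", identity = c(0.89, 0.90, 0.95))
  out <- filter_hits(h, min_identity = 0.90)
  # 0.89 and exactly 0.90 both fail the strict "greater than" rule
  expect_equal(out$identity, 0.95)
  expect_equal(attr(out, "removed_identity_bases"), 1e5)

  # one-base mask overlap removes the segment
  h <- mk_hits(qs = c(0, 5e4), qe = c(5e4, 1e5), target = "chrA",
               identity = 0.95)
  mask <- genomic_intervals("ctg1", 49999, 50010)
  out <- filter_hits(h, masks = mask)
  expect_equal(nrow(out), 0)  # mask straddles both segments
  mask <- genomic_intervals("ctg1", 99999, 100000)
  out <- filter_hits(h, masks = mask)
  expect_equal(out$query_start, 0)
  expect_equal(attr(out, "removed_masked_bases"), 5e4)

  # empty masks, all identities pass -> all retained
  out <- filter_hits(h, masks = genomic_intervals())
  expect_equal(nrow(out), 2)

  # unknown-contig mask warns and is ignored
  expect_warning(filter_hits(h, masks = genomic_intervals("ghost", 0, 10)),
                 "unknown contigs")
})

test_that("anchor_contig picks the q-arm argmax with documented tie rule", {
  arms <- reference_arms(c("chr13", "chr21"), c(1e6, 1e6), c(1.2e6, 1.2e6),
                         c(5e6, 5e6))
  # q-arm hits only to chr13
  h <- mk_hits(qs = 0, qe = 1e5, target = "chr13", identity = 0.95,
               ts = 2e6, te = 2.1e6, qlen = 5e6, tlen = 5e6)
  expect_equal(anchor_contig(h, arms), "chr13")

  # argmax of identity-weighted q-arm aligned length
  h <- rbind(mk_hits(qs = 0, qe = 2e6, target = "chr13", identity = 0.95,
                     ts = 2e6, te = 4e6, qlen = 5e6, tlen = 5e6),
             mk_hits(qs = 0, qe = 3e4, target = "chr21", identity = 0.99,
                     ts = 2e6, te = 2.03e6, qlen = 5e6, tlen = 5e6))
  expect_equal(anchor_contig(h, arms), "chr13")

  # exact tie -> lexicographically smallest with a warning
  h <- rbind(mk_hits(qs = 0, qe = 1e5, target = "chr21", identity = 0.95,
                     ts = 2e6, te = 2.1e6, qlen = 5e6, tlen = 5e6),
             mk_hits(qs = 1e5, qe = 2e5, target = "chr13", identity = 0.95,
                     ts = 2e6, te = 2.1e6, qlen = 5e6, tlen = 5e6))
  expect_warning(a <- anchor_contig(h, arms), "tie")
  expect_equal(a, "chr13")

  # p-arm-only contig cannot be anchored
  h <- mk_hits(qs = 0, qe = 1e5, target = "chr13", identity = 0.95,
               ts = 0, te = 1e5, qlen = 5e6, tlen = 5e6)
  expect_message(a <- anchor_contig(h, arms), "no q-arm hit")
  expect_true(is.na(a))
})

test_that("rank_hits puts the anchor first among max-identity ties", {
  h <- mk_hits(qs = 0, qe = 5e4, target = c("chr13", "chr21", "chr14"),
               identity = c(0.98, 0.98, 0.95))
  r <- rank_hits(h, anchor_chromosome = "chr21")
  expect_equal(r$target_name, c("chr21", "chr13", "chr14"))
  expect_equal(r$rank, 1:3)

  one <- mk_hits(qs = 0, qe = 5e4, target = "chr13", identity = 0.95)
  expect_equal(rank_hits(one, "chr13")$rank, 1)

  six <- mk_hits(qs = 0, qe = 5e4,
                 target = sprintf("chr%02d", 1:6),
                 identity = c(0.99, 0.98, 0.97, 0.96, 0.95, 0.94))
  r <- rank_hits(six, "chr01", top_n = 5)
  expect_equal(nrow(r), 5)
  expect_false("chr06" %in% r$target_name)

  # permutation property: nothing invented or lost before truncation
  set.seed(5)
  for (rep in 1:20) {
    n <- sample.int(6, 1)
    h <- mk_hits(qs = 0, qe = 5e4, target = sprintf("t%d", sample.int(9, n)),
                 identity = round(runif(n, 0.5, 1), 3))
    r <- rank_hits(h, "t1", top_n = 10)
    expect_setequal(paste(r$target_name, r$identity),
                    paste(h$target_name, h$identity))
    expect_true(all(diff(r$identity) <= 0))
  }
})

test_that("rank_hits tie-breaking is bit-identical across repeated runs", {
  h <- mk_hits(qs = 0, qe = 5e4,
               target = c("chrC", "chrA", "chrB", "chrD"),
               identity = c(0.97, 0.97, 0.97, 0.91))
  runs <- lapply(1:5, function(i) rank_hits(h, "chrB"))
  for (r in runs[-1]) expect_identical(r, runs[[1]])
  expect_equal(runs[[1]]$target_name, c("chrB", "chrA", "chrC", "chrD"))
})

test_that("collapse_consecutive_duplicates is a run-length collapse", {
  expect_equal(collapse_consecutive_duplicates(c("13", "13", "21", "21", "13")),
               c("13", "21", "13"))
  expect_equal(collapse_consecutive_duplicates("13"), "13")
  expect_equal(collapse_consecutive_duplicates(character()), character())
})

test_that("ground_to_target keeps the best grounding per reference segment", {
  # single covering contribution
  h <- mk_hits(qs = 0, qe = 1e5, target = "chr13", identity = 0.95)
  g <- ground_to_target(h, "chr13", "chr13")
  expect_equal(nrow(g), 1)
  expect_equal(g$target_start, 0)
  expect_equal(g$grounding_identity, 0.95)

  # two query segments grounding to one reference segment: 0.97 wins
  h <- rbind(mk_hits(qs = 0, qe = 5e4, target = "chr13", identity = 0.97,
                     ts = 2e5, te = 2.5e5),
             mk_hits(qs = 5e4, qe = 1e5, target = "chr13", identity = 0.93,
                     ts = 2e5, te = 2.5e5))
  g <- ground_to_target(h, "chr13", "chr13")
  expect_equal(nrow(g), 1)
  expect_equal(g$grounding_identity, 0.97)
  expect_equal(g$query_start, 0)

  # contig with no hits to the target -> empty
  expect_equal(nrow(ground_to_target(h, "chr21", "chr13")), 0)

  # tuple reflects rank order with consecutive duplicates collapsed
  h <- rbind(mk_hits(qs = 0, qe = 5e4, target = "chr13", identity = 0.98),
             mk_hits(qs = 0, qe = 5e4, target = "chr21", identity = 0.95))
  g <- ground_to_target(h, "chr13", "chr13")
  expect_equal(g$tuple, "chr13+chr21")
  expect_equal(g$best_hit, "chr13")
})
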