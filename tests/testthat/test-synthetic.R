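test_that("reference sets are deterministic and structurally sound", {
  r1 <- simulate_reference_set(n_chrom = 5, chrom_len = 3e6,
                               n_shared_blocks = 2, seed = 7)
  r2 <- simulate_reference_set(n_chrom = 5, chrom_len = 3e6,
                               n_shared_blocks = 2, seed = 7)
  expect_identical(r1$blocks, r2$blocks)
  expect_identical(r1$chroms, r2$chroms)

  # arms partition [0, length)
  for (ch in r1$chroms$name) {
    a <- r1$arms[r1$arms$seq_name == ch, ]
    a <- a[order(a$start), ]
    expect_equal(a$start[1], 0)
    expect_equal(a$end[3], 3e6)
    expect_equal(a$start[-1], a$end[-3])
  }

  # blocks sit inside p-arms, sharing sets have >= 2 members,
  # and the mixed configuration plants at least one set of size >= 3
  expect_true(all(r1$blocks$end <= r1$chroms$p_end[1]))
  sizes <- lengths(strsplit(r1$blocks$sharing, "+", fixed = TRUE))
  expect_true(all(sizes >= 2))
  expect_true(any(sizes >= 3))

  r0 <- simulate_reference_set(n_shared_blocks = 0, seed = 1)
  expect_equal(nrow(r0$blocks), 0)
  expect_equal(nrow(truth_phr_intervals(r0)), 0)

  expect_error(simulate_reference_set(chrom_len = 1e6, n_shared_blocks = 4,
                                      block_len = 3e5, seed = 1),
               "infeasible")
})

test_that("mosaic contigs obey the no-exchange null and determinism", {
  rs <- std_refset(seed = 2)
  s1 <- simulate_mosaic_contigs(rs, contigs_per_chrom = 3,
                                exchange_rate = 0, seed = 5)
  s2 <- simulate_mosaic_contigs(rs, contigs_per_chrom = 3,
                                exchange_rate = 0, seed = 5)
  expect_identical(s1$records, s2$records)
  validate_mappings(s1$records)

  # with no exchange, every donor equals the anchor and truth is empty
  expect_true(all(s1$truth$donor_path$donor == s1$truth$donor_path$anchor))
  expect_equal(nrow(s1$truth$phr), 0)
  expect_equal(nrow(s1$truth$switches), 0)

  # every segment's best hit is the anchor chromosome
  f <- filter_hits(s1$records)
  best <- tapply(seq_len(nrow(f)), paste(f$query_name, f$query_start),
                 function(i) f$target_name[i][which.max(f$identity[i])])
  anchor_of <- sub("_ctg.*", "", sub("sim#", "", names(best)))
  expect_true(all(best == sub(" .*", "", anchor_of)))
})

test_that("donor switches land only inside true PHR blocks at the planted rate", {
  rs <- std_refset(seed = 2)
  sim <- simulate_mosaic_contigs(rs, contigs_per_chrom = 40,
                                 exchange_rate = 1.0, seed = 9)
  sw <- sim$truth$switches
  expect_gt(nrow(sw), 0)
  truth <- sim$truth$phr
  # every switch position falls inside some true block
  inside <- vapply(sw$pos, function(p)
    any(truth$start <= p & p < truth$end), TRUE)
  expect_true(all(inside))

  # expected ~1 switch per contig per 300-kb block at rate 1.0:
  # 6 segments, each switching with probability 1/6
  b1 <- rs$blocks[1, ]
  sharing <- strsplit(b1$sharing, "+", fixed = TRUE)[[1]]
  share_ctgs <- unique(sim$truth$donor_path$contig[
    sim$truth$donor_path$anchor %in% sharing])
  n_in_b1 <- vapply(share_ctgs, function(ctg)
    sum(sw$contig == ctg & sw$pos >= b1$start & sw$pos < b1$end), 0)
  n <- length(share_ctgs)
  expect_equal(n, 120)
  mu <- 1; sd_one <- sqrt(6 * (1 / 6) * (5 / 6))
  expect_lt(abs(mean(n_in_b1) - mu), 3 * sd_one / sqrt(n))
})

test_that("similarity separation isolates homologous from decoy hits", {
  rs <- std_refset(seed = 2)
  sim <- simulate_mosaic_contigs(rs, contigs_per_chrom = 2,
                                 exchange_rate = 1.0, sep_margin = 0.05,
                                 seed = 1)
  id <- identity_from_jaccard(sim$records$jaccard)
  expect_true(all(id >= 0.95 | id <= 0.85))
})

test_that("unreliable masks hit the requested fraction deterministically", {
  expect_equal(nrow(simulate_unreliable_mask("c1", 1e6, 0, seed = 1)), 0)

  m <- simulate_unreliable_mask("c1", 1e6, 0.1, seed = 3)
  tot <- sum(m$end - m$start)
  expect_gte(tot, 8e4)
  expect_lte(tot, 1.2e5)
  # disjoint
  m <- m[order(m$start), ]
  if (nrow(m) > 1) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))

  expect_identical(simulate_unreliable_mask(c("a", "b"), 5e5, 0.2, seed = 9),
                   simulate_unreliable_mask(c("a", "b"), 5e5, 0.2, seed = 9))
})

test_that("founder panels show near-independent adjacent sites at generation 0", {
  panel <- simulate_haplotype_panel(1e6, n_hap = 60, mut_density = 5e-4,
                                    n_generations = 0, seed = 11)
  # minor-allele count >= 2 everywhere
  mac <- pmin(colSums(panel$mat), 60 - colSums(panel$mat))
  expect_true(all(mac >= 2))
  expect_true(all(diff(panel$positions) > 0))

  # independent founders: mean adjacent-pair r2 near the 1/n expectation
  r <- pairwise_r2(panel, max_dist = 5e3, keep_zero = TRUE)
  expect_gt(nrow(r), 100)
  expect_lt(mean(r$r2), 3 / 60)
})

test_that("PHR-elevated recombination accelerates LD decay", {
  rs <- std_refset(seed = 1)
  phr <- truth_phr_intervals(rs)
  phr1 <- phr[phr$seq_name == "chr01", ]
  regions <- rbind(
    genomic_intervals("chr01", 0, rs$chroms$p_end[1], "p_arm"),
    genomic_intervals("chr01", rs$chroms$q_start[1], 3e6, "q_arm"),
    genomic_intervals(phr1$seq_name, phr1$start, phr1$end, "PHR"))
  contrast <- function(mult, sd) {
    panel <- simulate_haplotype_panel(3e6, phr1, n_hap = 60,
                                      crossover_multiplier_phr = mult,
                                      n_generations = 50, seed = sd)
    st <- stratify_by_region(pairwise_r2(panel, max_dist = 4000), regions)
    sel <- st$distance >= 2000 & st$distance <= 4000
    c(phr = mean(st$r2[sel & st$region_class %in% "PHR"]),
      q = mean(st$r2[sel & st$region_class %in% "q_arm"]))
  }
  res <- vapply(1:3, function(sd) contrast(10, sd), numeric(2))
  expect_gte(sum(res["phr", ] < res["q", ]), 2)
})

test_that("motif hits are enriched inside the requested blocks", {
  blocks <- genomic_intervals("chr01", c(1e5, 5e5), c(4e5, 8e5))
  hits <- simulate_motif_hits("chr01", 3e6, blocks, enrichment = 5, seed = 2)
  expect_true(all(hits$confidence > 0 & hits$confidence <= 1))
  in_block <- vapply(hits$start, function(p)
    any(blocks$start <= p & p < blocks$end), TRUE)
  dens_in <- sum(in_block) / 6e5
  dens_out <- sum(!in_block) / (3e6 - 6e5)
  expect_gt(dens_in, 2 * dens_out)
})
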