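# Shared fixture builders and independent brute-force oracles.

# quick mapping-record builder with sensible defaults
mk_hits <- function(query = "ctg1", qs, qe, target, identity,
                    qlen = 1e6, tlen = 1e6, ts = qs, te = qe) {
  n <- max(length(qs), length(target), length(identity))
  mapping_records(
    query_name = rep_len(query, n), query_len = rep_len(qlen, n),
    query_start = rep_len(qs, n), query_end = rep_len(qe, n),
    strand = "+", target_name = rep_len(target, n),
    target_len = rep_len(tlen, n), target_start = rep_len(ts, n),
    target_end = rep_len(te, n),
    jaccard = jaccard_from_identity(rep_len(identity, n)),
    identity = rep_len(identity, n))
}

# brute-force paint-then-scan oracle for merge_intervals on an integer axis
oracle_merge <- function(intervals, max_gap, min_len, axis_len = 1.2e6) {
  paint <- rep(FALSE, axis_len)
  for (i in seq_len(nrow(intervals)))
    paint[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  # close gaps strictly shorter than max_gap between painted runs
  r <- rle(paint)
  ends <- cumsum(r$lengths)
  starts <- c(0, head(ends, -1))
  gap_runs <- which(!r$values & starts > 0 & ends < axis_len)
  for (g in gap_runs) {
    if (r$lengths[g] < max_gap) paint[(starts[g] + 1):ends[g]] <- TRUE
  }
  r <- rle(paint)
  ends <- cumsum(r$lengths)
  starts <- c(0, head(ends, -1))
  keep <- which(r$values & r$lengths >= min_len)
  if (length(keep) == 0) return(genomic_intervals())
  genomic_intervals(intervals$seq_name[1], starts[keep], ends[keep])
}

# per-base painting oracle for base-level overlap statistics
oracle_recovery <- function(called, truth, axis_len = 1.2e6) {
  paint <- function(x) {
    v <- rep(FALSE, axis_len)
    for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
    v
  }
  a <- if (nrow(called) > 0) paint(called) else rep(FALSE, axis_len)
  b <- if (nrow(truth) > 0) paint(truth) else rep(FALSE, axis_len)
  inter <- sum(a & b); uni <- sum(a | b)
  list(jaccard = if (uni > 0) inter / uni else NaN,
       precision = if (sum(a) > 0) inter / sum(a) else NaN,
       recall = if (sum(b) > 0) inter / sum(b) else NaN)
}

# closed-form 2x2 haplotype-table r2 oracle (no missing data)
oracle_r2 <- function(a, b) {
  pA <- mean(a); pB <- mean(b); pAB <- mean(a == 1 & b == 1)
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den == 0) return(NA_real_)
  (pAB - pA * pB)^2 / den
}

# small standard fixture: 5 chromosomes, two blocks shared by chr01-03
std_refset <- function(seed = 1, sharing = list(1:3, 1:3)) {
  simulate_reference_set(n_chrom = 5, chrom_len = 3e6, n_shared_blocks = 2,
                         block_len = 3e5, sharing = sharing, seed = seed)
}
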