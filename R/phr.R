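# Pseudo-homologous region calling from positional entropy tracks, plus
# the descriptive context tracks (PRDM9-motif window counts, SNP density).

#' Call pseudo-homologous regions from an entropy track
#'
#' Seed intervals are maximal runs of the track with entropy strictly
#' greater than `entropy_gt` (to floating tolerance 1e-12; the -1 sentinel
#' never qualifies) and support of at least `min_support` contigs. Seeds
#' closer than `merge_gap` are merged and merged regions shorter than
#' `min_len` removed, giving the called PHRs. Each call carries the
#' length-weighted mean entropy and mean support of the qualifying track
#' runs it contains.
#'
#' @param track an entropy track (one chromosome).
#' @param entropy_gt strict entropy threshold in nats (default 0).
#' @param min_support minimum per-position contig support (default 1).
#' @param merge_gap merge seeds with gap `< merge_gap` bases (default 30000).
#' @param min_len drop merged regions shorter than this (default 30000).
#' @return A data frame of PHR intervals: `chrom`, `start`, `end`,
#'   `mean_entropy`, `mean_support`.
#' @export
call_phrs <- function(track, entropy_gt = 0, min_support = 1,
                      merge_gap = 30000, min_len = 30000) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_entropy = numeric(),
                      mean_support = numeric(), stringsAsFactors = FALSE)
  if (nrow(track) == 0) return(empty)
  stopifnot(length(unique(track$chrom)) == 1)
  qual <- track$value > entropy_gt + 1e-12 & track$value >= 0 &
    track$support >= min_support
  if (!any(qual)) return(empty)
  seeds <- genomic_intervals(track$chrom[qual], track$start[qual],
                             track$end[qual])
  merged <- merge_intervals(seeds, max_gap = merge_gap, min_len = min_len)
  if (nrow(merged) == 0) return(empty)
  qt <- track[qual, , drop = FALSE]
  stats <- vapply(seq_len(nrow(merged)), function(i) {
    ol <- pmax(0, pmin(merged$end[i], qt$end) - pmax(merged$start[i], qt$start))
    c(sum(ol * qt$value) / sum(ol), sum(ol * qt$support) / sum(ol))
  }, numeric(2))
  data.frame(chrom = merged$seq_name, start = merged$start, end = merged$end,
             mean_entropy = stats[1, ], mean_support = stats[2, ],
             stringsAsFactors = FALSE)
}

# sorted non-overlapping canonical form of an interval set (per chromosome)
.canonicalize <- function(ivs) {
  if (nrow(ivs) == 0) return(ivs)
  do.call(rbind, lapply(split(ivs, ivs$seq_name), function(x)
    merge_intervals(x, max_gap = 0, min_len = 0)))
}

# total intersection length between two canonical interval sets
.intersect_len <- function(a, b) {
  total <- 0
  for (chrom in intersect(unique(a$seq_name), unique(b$seq_name))) {
    ac <- a[a$seq_name == chrom, ]; bc <- b[b$seq_name == chrom, ]
    for (i in seq_len(nrow(ac)))
      total <- total + interval_overlap_len(ac$start[i], ac$end[i], bc)
  }
  total
}

#' Base-level recovery of called PHRs against planted truth
#'
#' Compares two interval sets at base resolution: `jaccard` is
#' intersection over union, `precision` the fraction of called bases that
#' are true, `recall` the fraction of true bases that are called.
#'
#' @param called data frame with `chrom`/`seq_name`, `start`, `end`.
#' @param truth same layout.
#' @return A list with `jaccard`, `precision`, `recall` (each in `[0,1]`;
#'   `NaN` where the denominator is empty).
#' @export
evaluate_recovery <- function(called, truth) {
  std <- function(x) {
    if (nrow(x) == 0)
      return(genomic_intervals())
    nm <- if ("seq_name" %in% names(x)) "seq_name" else "chrom"
    .canonicalize(genomic_intervals(x[[nm]], x$start, x$end))
  }
  a <- std(called); b <- std(truth)
  la <- sum(a$end - a$start); lb <- sum(b$end - b$start)
  inter <- .intersect_len(a, b)
  union_len <- la + lb - inter
  list(jaccard = if (union_len > 0) inter / union_len else NaN,
       precision = if (la > 0) inter / la else NaN,
       recall = if (lb > 0) inter / lb else NaN)
}

#' Count motif occurrences per fixed-width window
#'
#' Motifs whose confidence (how likely the motif is a true binding
#' target) falls below `min_confidence` are excluded; each surviving hit
#' interval is counted in every window it intersects (BEDtools-intersect
#' semantics, so a hit straddling a boundary is counted in both windows).
#'
#' @param motif_hits data frame with `seq_name`, `start`, `end`, `motif`,
#'   `confidence`.
#' @param chrom chromosome to scan.
#' @param chrom_len chromosome length in bases.
#' @param min_confidence motif-level confidence floor (default 0.70).
#' @param window window width in bases (default 20000).
#' @return A data frame of windows with a `count` column.
#' @export
motif_window_counts <- function(motif_hits, chrom, chrom_len,
                                min_confidence = 0.70, window = 20000) {
  wins <- window_partition(chrom_len, window, chrom)
  wins$count <- 0
  h <- motif_hits[motif_hits$seq_name == chrom &
                    motif_hits$confidence >= min_confidence, , drop = FALSE]
  if (nrow(h) > 0) {
    for (w in seq_len(nrow(wins))) {
      wins$count[w] <- sum(h$start < wins$end[w] & h$end > wins$start[w])
    }
  }
  wins
}

#' Biallelic SNP density in fixed-width bins
#'
#' Counts variant positions per half-open bin (`[0, bin)`, `[bin, 2*bin)`,
#' ...); a position exactly on a boundary falls in the right-hand bin.
#' Positions are 0-based (convert VCF POS with `POS - 1`).
#'
#' @param positions 0-based variant positions on one chromosome.
#' @param chrom_len chromosome length in bases.
#' @param bin bin width in bases (default 100000).
#' @param chrom chromosome name for the output.
#' @return A data frame of bins with a `count` column summing to
#'   `length(positions)`.
#' @export
snp_density <- function(positions, chrom_len, bin = 100000, chrom = "chr") {
  stopifnot(all(positions >= 0 & positions < chrom_len))
  bins <- window_partition(chrom_len, bin, chrom)
  idx <- floor(positions / bin) + 1
  tab <- tabulate(idx, nbins = nrow(bins))
  bins$count <- tab
  bins
}
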