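# Homology-entropy metrics over grounded untangle hits. Both metrics are
# Shannon diversity indices (natural log); -1 is the sentinel for "no
# data", never a computed value.

#' Shannon diversity index of a count vector
#'
#' `SDI = -sum(p_i * log(p_i))` with `p_i = count_i / total`, natural
#' logarithm. Zero counts contribute nothing; a single category gives 0;
#' the maximum over `k` categories is `log(k)`.
#'
#' @param category_counts non-negative counts (named or not).
#' @return SDI in nats.
#' @export
shannon_diversity <- function(category_counts) {
  counts <- as.numeric(category_counts)
  if (any(counts < 0)) stop("negative count")
  total <- sum(counts)
  if (total == 0) stop("total count is zero; caller must use the sentinel")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Construct an entropy track
#'
#' A run-length encoded per-position track on one chromosome: `value` is
#' an SDI in nats or the sentinel `-1` for positions with no data;
#' `support` counts the contigs contributing at each position.
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open run bounds.
#' @param value SDI (>= 0) or -1.
#' @param support contributing-contig count (>= 0).
#' @return A `data.frame` with class `phr_entropy_track`.
#' @export
entropy_track <- function(chrom, start, end, value, support) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   support = as.numeric(support), stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    stopifnot(all(df$start < df$end),
              all(df$value >= 0 | df$value == -1),
              all(df$support >= 0),
              all(df$support >= 1 | df$value <= 0))
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phr_entropy_track", "data.frame")
  df
}

#' Write an entropy track as a bedGraph-style file
#'
#' Four tab-separated columns (chrom, start, end, value); the `-1`
#' sentinel is written literally. A companion `.support` file carries the
#' support channel in the same layout.
#'
#' @param track an entropy track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_entropy_track <- function(track, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(track$chrom, fmt(track$start), fmt(track$end),
                   format(track$value, trim = TRUE), sep = "\t"), path)
  writeLines(paste(track$chrom, fmt(track$start), fmt(track$end),
                   fmt(track$support), sep = "\t"),
             paste0(path, ".support"))
  invisible(path)
}

#' Regional homology entropy of best-hit mosaics
#'
#' For each contig anchored to a chromosome, the best-hit target label is
#' laid along the chromosome via the contig's grounding; the SDI of the
#' label distribution is computed per reference-aligned window (default
#' 50 kb), giving one window-wise SDI profile per contig (windows where
#' the contig has no data are missing). Profiles are then averaged across
#' contigs at each position, ignoring missing values; positions with no
#' contig data at all get the sentinel -1. Because windows are
#' reference-aligned, the average is constant within each window.
#'
#' @param groundings list of per-contig grounding frames (from
#'   [ground_to_target()]) of contigs anchored to `chrom`, grounded to
#'   `chrom`.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length in bases.
#' @param window window width in bases (default 50000).
#' @param min_identity only best hits above this identity contribute;
#'   grounded rows already passed the global filter, so this is normally
#'   a no-op guard.
#' @return An entropy track; `support` is the number of contigs with data
#'   in the window.
#' @export
regional_homology_entropy <- function(groundings, chrom, chrom_len,
                                      window = 50000, min_identity = 0.90) {
  wins <- window_partition(chrom_len, window, chrom)
  nw <- nrow(wins)
  sdi_sum <- numeric(nw)
  n_contig <- numeric(nw)
  for (g in groundings) {
    g <- g[g$grounding_identity > min_identity, , drop = FALSE]
    if (nrow(g) == 0) next
    for (w in seq_len(nw)) {
      ws <- wins$start[w]; we <- wins$end[w]
      ol <- pmax(0, pmin(we, g$target_end) - pmax(ws, g$target_start))
      if (all(ol == 0)) next
      counts <- tapply(ol[ol > 0], g$best_hit[ol > 0], sum)
      sdi_sum[w] <- sdi_sum[w] + shannon_diversity(counts)
      n_contig[w] <- n_contig[w] + 1
    }
  }
  value <- ifelse(n_contig > 0, sdi_sum / n_contig, -1)
  entropy_track(chrom, wins$start, wins$end, value, n_contig)
}

#' Positional homology entropy of multi-hit orderings
#'
#' For each reference segment (segments are shared across contigs because
#' untangling uses common cut points), each contributing contig supplies
#' its collapsed ordered tuple of unique targets (top hits ranked by
#' identity, anchor-first among ties, consecutive duplicates removed).
#' The SDI is computed over the multiset of tuples — each distinct tuple
#' is one category — and `support` is the number of contributing contigs.
#' Reference runs with no contig data get the sentinel -1.
#'
#' @param groundings list of per-contig grounding frames on one target
#'   chromosome (from [ground_to_target()]); one row per reference
#'   segment per contig, already de-duplicated to the best grounding.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length in bases.
#' @return An entropy track with one run per reference segment and -1
#'   runs filling uncovered gaps.
#' @export
positional_homology_entropy <- function(groundings, chrom, chrom_len) {
  all_rows <- do.call(rbind, c(list(data.frame(target_start = numeric(),
                                               target_end = numeric(),
                                               tuple = character(),
                                               stringsAsFactors = FALSE)),
                               lapply(groundings, function(g)
                                 g[, c("target_start", "target_end", "tuple")])))
  if (nrow(all_rows) == 0)
    return(entropy_track(chrom, 0, chrom_len, -1, 0))
  key <- paste(all_rows$target_start, all_rows$target_end, sep = ":")
  segs <- lapply(split(seq_len(nrow(all_rows)), key), function(idx) {
    tup_counts <- table(all_rows$tuple[idx])
    data.frame(start = all_rows$target_start[idx[1]],
               end = all_rows$target_end[idx[1]],
               value = shannon_diversity(tup_counts),
               support = length(idx))
  })
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  # fill uncovered runs with the sentinel
  out <- list()
  pos <- 0
  for (i in seq_len(nrow(segs))) {
    if (segs$start[i] > pos)
      out[[length(out) + 1]] <- data.frame(start = pos, end = segs$start[i],
                                           value = -1, support = 0)
    out[[length(out) + 1]] <- segs[i, , drop = FALSE]
    pos <- max(pos, segs$end[i])
  }
  if (pos < chrom_len)
    out[[length(out) + 1]] <- data.frame(start = pos, end = chrom_len,
                                         value = -1, support = 0)
  out <- do.call(rbind, out)
  entropy_track(chrom, out$start, out$end, out$value, out$support)
}
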