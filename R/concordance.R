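# Cross-assembly validation: per-base best-hit tracks and their
# base-level concordance.

#' Per-base best-hit track of one assembly on one chromosome
#'
#' For every base of the chromosome, records the rank-1 target of the
#' covering grounded contribution; where contributions overlap, the one
#' with the best grounding (highest placement identity) wins. Uncovered
#' bases carry `NA`.
#'
#' @param groundings list of per-contig grounding frames on the
#'   chromosome (from [ground_to_target()]).
#' @param chrom chromosome name.
#' @param chrom_len chromosome length in bases.
#' @param min_identity only contributions with grounding identity above
#'   this enter the track (default 0.90).
#' @return A run-length data frame: `chrom`, `start`, `end`, `target`
#'   (`NA` for uncovered runs), class `phr_besthit_track`.
#' @export
best_hit_track <- function(groundings, chrom, chrom_len,
                           min_identity = 0.90) {
  rows <- do.call(rbind, c(
    list(data.frame(target_start = numeric(), target_end = numeric(),
                    grounding_identity = numeric(), best_hit = character(),
                    stringsAsFactors = FALSE)),
    lapply(groundings, function(g)
      g[, c("target_start", "target_end", "grounding_identity", "best_hit")])))
  rows <- rows[rows$grounding_identity > min_identity, , drop = FALSE]
  targets <- sort(unique(rows$best_hit))
  code <- rep(NA_integer_, chrom_len)
  if (nrow(rows) > 0) {
    o <- order(rows$grounding_identity)  # best grounding painted last
    for (i in o) {
      s <- max(0, rows$target_start[i]); e <- min(chrom_len, rows$target_end[i])
      if (e > s)
        code[(s + 1):e] <- match(rows$best_hit[i], targets)
    }
  }
  r <- rle(ifelse(is.na(code), 0L, code))
  ends <- cumsum(r$lengths)
  out <- data.frame(chrom = chrom, start = c(0, utils::head(ends, -1)),
                    end = ends,
                    target = ifelse(r$values == 0L, NA_character_,
                                    targets[pmax(r$values, 1L)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("phr_besthit_track", "data.frame")
  out
}

# expand a best-hit track to a per-base integer code vector
.track_codes <- function(track, chrom_len, targets) {
  code <- rep(NA_integer_, chrom_len)
  for (i in seq_len(nrow(track))) {
    if (is.na(track$target[i])) next
    s <- max(0, track$start[i]); e <- min(chrom_len, track$end[i])
    if (e > s) code[(s + 1):e] <- match(track$target[i], targets)
  }
  code
}

#' Base-level concordance between two best-hit tracks
#'
#' Over the given regions (the whole chromosome if none), counts the
#' bases where both tracks have a best-hit; the concordance rate is
#' 100 x (bases where both agree) / (doubly covered bases). Singly
#' covered bases are reported separately; with no doubly covered base
#' the rate is undefined (`NA`).
#'
#' @param track_a,track_b best-hit tracks on the same chromosome.
#' @param regions optional genomic intervals restricting the comparison
#'   (e.g. p-arms or q-arms).
#' @return A list: `rate` (percentage or `NA`), `doubly_covered`,
#'   `concordant`, `singly_covered` (bases).
#' @export
concordance_rate <- function(track_a, track_b, regions = NULL) {
  stopifnot(track_a$chrom[1] == track_b$chrom[1])
  chrom_len <- max(track_a$end, track_b$end)
  targets <- sort(unique(stats::na.omit(c(track_a$target, track_b$target))))
  a <- .track_codes(track_a, chrom_len, targets)
  b <- .track_codes(track_b, chrom_len, targets)
  in_region <- if (is.null(regions) || nrow(regions) == 0)
    rep(TRUE, chrom_len)
  else {
    m <- rep(FALSE, chrom_len)
    for (i in seq_len(nrow(regions))) {
      s <- max(0, regions$start[i]); e <- min(chrom_len, regions$end[i])
      if (e > s) m[(s + 1):e] <- TRUE
    }
    m
  }
  both <- !is.na(a) & !is.na(b) & in_region
  one <- xor(!is.na(a), !is.na(b)) & in_region
  n_both <- sum(both)
  n_agree <- sum(a[both] == b[both])
  list(rate = if (n_both > 0) 100 * n_agree / n_both else NA_real_,
       doubly_covered = n_both, concordant = n_agree,
       singly_covered = sum(one))
}
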