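# Best-hit grounding of multi-target untangle hits. Pipeline order is
# fixed: filter -> anchor -> rank -> ground (masking happens before any
# ranking or aggregation).

#' Estimate sequence identity from a Jaccard similarity
#'
#' Untangle hits carry a Jaccard similarity between the query and target
#' segment node sets; downstream filtering works on estimated nucleotide
#' identity. The default transform is the Dice coefficient `2J / (1 + J)`,
#' which is monotone in `J` and maps `[0, 1]` onto `[0, 1]`. Alternative
#' monotone transforms can be plugged in; every result records which
#' transform produced it only through the caller's configuration, since
#' downstream logic depends only on monotonicity and the identity cutoff.
#'
#' @param j Jaccard similarity, in `[0, 1]` (vectorised).
#' @param transform `"dice"` (default) or `"identity"` (use `j` as-is).
#' @return Estimated identity in `[0, 1]`.
#' @export
identity_from_jaccard <- function(j, transform = c("dice", "identity")) {
  transform <- match.arg(transform)
  if (any(j < 0 | j > 1, na.rm = TRUE))
    stop("jaccard out of [0, 1]")
  switch(transform,
         dice = 2 * j / (1 + j),
         identity = j)
}

#' Invert the Dice identity transform
#'
#' Maps an identity back to the Jaccard value that would produce it under
#' the Dice transform: `j = i / (2 - i)`. Used by the synthetic generator
#' so that planted identities round-trip exactly.
#'
#' @param i identity in `[0, 1]`.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
jaccard_from_identity <- function(i) {
  stopifnot(all(i >= 0 & i <= 1))
  i / (2 - i)
}

#' Filter untangle hits by identity and unreliable-region masks
#'
#' Drops hits whose estimated identity is not strictly greater than
#' `min_identity`, and hits whose query segment overlaps (by at least one
#' base) an unreliable interval of its contig. Hits with missing identity
#' have it computed from `jaccard` first.
#'
#' @param hits a mapping-record data frame.
#' @param min_identity identity floor; survivors have
#'   `identity > min_identity` (strict). Default 0.90.
#' @param masks a genomic-interval data frame of unreliable regions in
#'   contig (query) coordinates, or `NULL`. Masks naming contigs absent
#'   from `hits` are ignored with a warning.
#' @param transform passed to [identity_from_jaccard()] for missing
#'   identities.
#' @return The surviving hits, with attributes `removed_identity_bases`
#'   and `removed_masked_bases` reporting the query bases removed by each
#'   rule.
#' @export
filter_hits <- function(hits, min_identity = 0.90, masks = NULL,
                        transform = "dice") {
  validate_mappings(hits)
  if (nrow(hits) > 0 && anyNA(hits$identity)) {
    miss <- is.na(hits$identity)
    hits$identity[miss] <- identity_from_jaccard(hits$jaccard[miss], transform)
  }
  keep_id <- hits$identity > min_identity
  removed_id <- sum((hits$query_end - hits$query_start)[!keep_id])
  hits <- hits[keep_id, , drop = FALSE]

  removed_mask <- 0
  if (!is.null(masks) && nrow(masks) > 0 && nrow(hits) > 0) {
    unknown <- setdiff(unique(masks$seq_name), unique(hits$query_name))
    if (length(unknown) > 0)
      warning("masks reference unknown contigs, ignored: ",
              paste(unknown, collapse = ", "))
    mask_by_contig <- split(masks, masks$seq_name)
    ol <- vapply(seq_len(nrow(hits)), function(i) {
      m <- mask_by_contig[[hits$query_name[i]]]
      if (is.null(m)) 0 else
        interval_overlap_len(hits$query_start[i], hits$query_end[i], m)
    }, 0)
    keep_m <- ol == 0
    removed_mask <- sum((hits$query_end - hits$query_start)[!keep_m])
    hits <- hits[keep_m, , drop = FALSE]
  }
  rownames(hits) <- NULL
  attr(hits, "removed_identity_bases") <- removed_id
  attr(hits, "removed_masked_bases") <- removed_mask
  hits
}

#' Anchor a contig to the reference chromosome its q-arm maps to
#'
#' Each contig is assigned the single reference chromosome carrying the
#' largest identity-weighted aligned length within that chromosome's
#' q-arm. Ties break to the lexicographically smallest chromosome with a
#' warning. A contig with no q-arm hit cannot be anchored.
#'
#' @param contig_hits filtered hits of one contig.
#' @param arms a genomic-interval data frame with `label` in
#'   `{"p", "cen", "q"}` giving each reference chromosome's arm structure
#'   (see [reference_arms()]).
#' @return The anchor chromosome name (character scalar), or `NA_character_`
#'   with a message if the contig has no q-arm hit.
#' @export
anchor_contig <- function(contig_hits, arms) {
  if (nrow(contig_hits) == 0) return(NA_character_)
  q_arms <- arms[arms$label == "q", , drop = FALSE]
  w <- numeric(0)
  for (chrom in unique(contig_hits$target_name)) {
    qa <- q_arms[q_arms$seq_name == chrom, , drop = FALSE]
    if (nrow(qa) == 0) next
    h <- contig_hits[contig_hits$target_name == chrom, , drop = FALSE]
    ol <- vapply(seq_len(nrow(h)), function(i)
      interval_overlap_len(h$target_start[i], h$target_end[i], qa), 0)
    w[chrom] <- sum(ol * h$identity)
  }
  w <- w[w > 0]
  if (length(w) == 0) {
    message("contig ", contig_hits$query_name[1],
            " has no q-arm hit; excluded from anchoring")
    return(NA_character_)
  }
  best <- names(w)[w == max(w)]
  if (length(best) > 1) {
    warning("anchor tie for contig ", contig_hits$query_name[1],
            "; taking lexicographically smallest of ",
            paste(sort(best), collapse = ", "))
  }
  sort(best)[1]
}

#' Rank the hits of one query segment
#'
#' Sorts hits by estimated identity, descending. Among hits tied at the
#' maximum identity, the hit targeting the contig's anchor chromosome (its
#' chromosome of origin) is placed first. Remaining ties break by target
#' name for determinism. The list is truncated to the `top_n` best hits.
#'
#' @param segment_hits hits sharing one query segment.
#' @param anchor_chromosome the parent contig's anchor chromosome.
#' @param top_n keep at most this many hits (default 5).
#' @return The ranked, truncated hits with a `rank` column (1 = best).
#' @export
rank_hits <- function(segment_hits, anchor_chromosome, top_n = 5) {
  if (nrow(segment_hits) == 0) {
    segment_hits$rank <- integer(0)
    return(segment_hits)
  }
  id <- segment_hits$identity
  is_max <- abs(id - max(id)) < 1e-12
  anchor_first <- is_max & segment_hits$target_name == anchor_chromosome
  o <- order(-id, -anchor_first, segment_hits$target_name)
  out <- segment_hits[o, , drop = FALSE][seq_len(min(top_n, nrow(segment_hits))), ,
                                         drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Collapse consecutive duplicate targets into an ordered unique set
#'
#' Run-length collapse: removes each element equal to its predecessor, so
#' no two consecutive elements are equal while first occurrences keep
#' their order. Applied to ranked target lists to avoid counting
#' intra-chromosomal segmental-duplication echoes as distinct homology
#' orders.
#'
#' @param targets character vector of target names in order.
#' @return The collapsed character vector.
#' @export
collapse_consecutive_duplicates <- function(targets) {
  if (length(targets) <= 1) return(targets)
  targets[c(TRUE, targets[-1] != targets[-length(targets)])]
}

#' Ground a contig's hits onto one target chromosome
#'
#' For every reference segment of `target_chromosome` covered by the
#' contig, emits the contig's placement there together with the identity
#' of that placement (the "grounding identity") and the contig's ranked
#' hit tuple for the corresponding query segment. When several query
#' segments of the contig ground to the same reference segment, the one
#' with the highest grounding identity is kept.
#'
#' @param contig_hits filtered hits of one contig (all targets).
#' @param target_chromosome chromosome to ground against.
#' @param anchor_chromosome the contig's anchor (for ranking).
#' @param top_n tuple length cap (default 5).
#' @return A data frame with one row per grounded reference segment:
#'   `query_name`, `query_start`, `query_end`, `target_start`,
#'   `target_end`, `grounding_identity`, `best_hit` (rank-1 target) and
#'   `tuple` (collapsed ordered targets, "+"-joined).
#' @export
ground_to_target <- function(contig_hits, target_chromosome,
                             anchor_chromosome, top_n = 5) {
  .ground_contig(contig_hits, target_chromosome, anchor_chromosome, top_n)
}

.ground_empty <- function() {
  data.frame(query_name = character(), query_start = numeric(),
             query_end = numeric(), target_start = numeric(),
             target_end = numeric(), grounding_identity = numeric(),
             best_hit = character(), tuple = character(),
             stringsAsFactors = FALSE)
}

# vectorised single-contig grounding; sorts hits once per contig into
# rank order (identity desc, anchor-first among max-identity ties, then
# target name) and derives tuples and placements per query segment.
.ground_contig <- function(h, target_chromosome, anchor_chromosome,
                           top_n = 5) {
  if (nrow(h) == 0) return(.ground_empty())
  seg_key <- paste(h$query_name, h$query_start, h$query_end, sep = ":")
  max_id <- stats::ave(h$identity, seg_key, FUN = max)
  is_max <- abs(h$identity - max_id) < 1e-12
  anchor_first <- is_max & h$target_name == anchor_chromosome
  o <- order(seg_key, -h$identity, -anchor_first, h$target_name)
  h2 <- h[o, , drop = FALSE]
  grp <- factor(seg_key[o], levels = unique(seg_key[o]))
  idx_by_seg <- split(seq_len(nrow(h2)), grp)
  rows <- lapply(idx_by_seg, function(idx) {
    tgt <- h2$target_name[idx]
    w <- idx[tgt == target_chromosome]
    if (length(w) == 0) return(NULL)
    place <- w[which.max(h2$identity[w])]
    top <- tgt[seq_len(min(top_n, length(tgt)))]
    c(place,
      paste(collapse_consecutive_duplicates(top), collapse = "+"),
      tgt[1])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(.ground_empty())
  place <- as.integer(vapply(rows, `[[`, "", 1))
  out <- data.frame(query_name = h2$query_name[place],
                    query_start = h2$query_start[place],
                    query_end = h2$query_end[place],
                    target_start = h2$target_start[place],
                    target_end = h2$target_end[place],
                    grounding_identity = h2$identity[place],
                    best_hit = vapply(rows, `[[`, "", 3),
                    tuple = vapply(rows, `[[`, "", 2),
                    stringsAsFactors = FALSE)
  # best grounding wins when several query segments hit one reference segment
  ref_key <- paste(out$target_start, out$target_end, sep = ":")
  o2 <- order(ref_key, -out$grounding_identity)
  out <- out[o2[!duplicated(ref_key[o2])], , drop = FALSE]
  out <- out[order(out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ground all contigs of an assembly against every target chromosome
#'
#' Runs the fixed pipeline filter -> anchor -> rank -> ground over a full
#' set of untangle hits: hits are identity- and mask-filtered, each contig
#' is anchored via its q-arm, and each contig is grounded against each
#' requested target chromosome. Contigs that cannot be anchored are
#' dropped (with a message).
#'
#' @param hits a mapping-record data frame (all contigs, all targets).
#' @param arms reference arm annotation (see [reference_arms()]).
#' @param targets chromosomes to ground against; defaults to all
#'   chromosomes in `arms`.
#' @param min_identity identity floor for [filter_hits()].
#' @param masks optional unreliable-region intervals for [filter_hits()].
#' @param top_n tuple length cap.
#' @return A named list, one element per target chromosome, each a list
#'   with `groundings` (per-contig list of [ground_to_target()] frames)
#'   and `anchors` (named character vector contig -> anchor).
#' @export
ground_assembly <- function(hits, arms, targets = unique(arms$seq_name),
                            min_identity = 0.90, masks = NULL, top_n = 5) {
  hits <- filter_hits(hits, min_identity = min_identity, masks = masks)
  by_contig <- split(hits, hits$query_name)
  anchors <- vapply(by_contig, anchor_contig, "", arms = arms)
  anchors <- anchors[!is.na(anchors)]
  by_contig <- by_contig[names(anchors)]
  out <- lapply(targets, function(chrom) {
    g <- lapply(names(by_contig), function(ctg)
      ground_to_target(by_contig[[ctg]], chrom, anchors[[ctg]], top_n = top_n))
    names(g) <- names(by_contig)
    list(groundings = g[vapply(g, nrow, 0L) > 0], anchors = anchors)
  })
  names(out) <- targets
  out
}
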