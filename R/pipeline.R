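# End-to-end PHR detection: grounding -> entropy tracks -> PHR calls.

#' Run the PHR detection pipeline over untangle records
#'
#' Executes the fixed stage order on a full set of multi-target untangle
#' hits: identity/mask filtering, q-arm anchoring, top-5 ranking with
#' anchor-first tie-breaks, grounding against every reference
#' chromosome, regional and positional homology entropy, and PHR calling
#' from the positional track.
#'
#' @param records a mapping-record data frame (all contigs, all targets).
#' @param arms reference arm annotation (see [reference_arms()]), or a
#'   `phr_refset` whose `arms` are used.
#' @param masks optional unreliable-region intervals in contig
#'   coordinates.
#' @param min_identity identity floor (default 0.90, strict).
#' @param window regional-entropy window in bases (default 5e4).
#' @param top_n multi-hit tuple cap (default 5).
#' @param merge_gap,min_len PHR merge-and-filter parameters (defaults
#'   30 kb each).
#' @return A list: `grounded` (per-target groundings and anchors),
#'   `regional` and `positional` (named lists of entropy tracks per
#'   chromosome), `phrs` (one data frame of calls over all chromosomes).
#' @export
phr_pipeline <- function(records, arms, masks = NULL, min_identity = 0.90,
                         window = 5e4, top_n = 5,
                         merge_gap = 30000, min_len = 30000) {
  if (inherits(arms, "phr_refset")) arms <- arms$arms
  chroms <- unique(arms$seq_name)
  chrom_len <- vapply(chroms, function(c)
    max(arms$end[arms$seq_name == c]), 0)
  grounded <- ground_assembly(records, arms, targets = chroms,
                              min_identity = min_identity, masks = masks,
                              top_n = top_n)
  regional <- list(); positional <- list(); phr_list <- list()
  for (chrom in chroms) {
    g <- grounded[[chrom]]
    anchors <- g$anchors
    own <- names(anchors)[anchors == chrom]
    regional[[chrom]] <- regional_homology_entropy(
      g$groundings[intersect(names(g$groundings), own)],
      chrom, chrom_len[[chrom]], window = window,
      min_identity = min_identity)
    positional[[chrom]] <- positional_homology_entropy(
      g$groundings, chrom, chrom_len[[chrom]])
    phr_list[[chrom]] <- call_phrs(positional[[chrom]],
                                   merge_gap = merge_gap, min_len = min_len)
  }
  list(grounded = grounded, regional = regional, positional = positional,
       phrs = do.call(rbind, c(list(data.frame()), unname(phr_list))))
}
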