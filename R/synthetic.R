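# Sequence-free synthetic data with planted ground truth. The generator
# emits homology RECORDS and similarity values, not nucleotides: every
# downstream stage consumes records, so this targets exactly the analysis
# layer while staying desk-scale. Seeds are explicit arguments; no global
# random state is relied upon between calls.

#' Simulate a reference chromosome family with shared p-arm blocks
#'
#' Builds `n_chrom` acrocentric-style chromosomes (short p-arm,
#' centromere, long q-arm partitioning `[0, length)`) and places
#' `n_shared_blocks` near-identical homology blocks on the p-arms, nearer
#' the distal (telomeric) end. Each block occupies the same coordinates
#' on every chromosome of its sharing set (>= 2 chromosomes); q-arms
#' share no blocks. Block bounds snap to a placement granularity so that
#' untangle segments nest cleanly inside blocks.
#'
#' @param n_chrom number of chromosomes (>= 2; default 5).
#' @param chrom_len chromosome length in bases (default 3e6).
#' @param n_shared_blocks number of shared blocks (default 2).
#' @param block_len block length in bases (default 3e5).
#' @param divergence_within_block substitution rate separating sharing
#'   chromosomes inside a block, in `[0, 0.1]` (default 0.01).
#' @param sharing `"mixed"` (first block's sharing set has >= 3
#'   chromosomes, the rest are random), `"pairs"` (all size 2), or an
#'   explicit list of chromosome-index vectors, one per block.
#' @param p_frac,cen_frac fractions of the chromosome taken by the p-arm
#'   and the centromere (defaults 0.3 and 0.05).
#' @param granularity placement grid for block bounds (default 5e4, the
#'   untangle segment size).
#' @param seed integer seed; the result is deterministic given it.
#' @return A `phr_refset` list: `chroms` (name, length, p_end, q_start),
#'   `arms` (see [reference_arms()]), `blocks` (block_id, start, end,
#'   divergence, sharing as a `+`-joined name list), and the call
#'   parameters.
#' @export
simulate_reference_set <- function(n_chrom = 5, chrom_len = 3e6,
                                   n_shared_blocks = 2, block_len = 3e5,
                                   divergence_within_block = 0.01,
                                   sharing = "mixed",
                                   p_frac = 0.3, cen_frac = 0.05,
                                   granularity = 5e4, seed = 1) {
  stopifnot(n_chrom >= 2, divergence_within_block >= 0,
            divergence_within_block <= 0.1)
  set.seed(seed)
  names <- sprintf("chr%02d", seq_len(n_chrom))
  p_end <- floor(p_frac * chrom_len / granularity) * granularity
  q_start <- p_end + ceiling(cen_frac * chrom_len / granularity) * granularity
  if (n_shared_blocks * block_len >= p_end)
    stop("infeasible packing: blocks exceed the p-arm")
  chroms <- data.frame(name = names, length = chrom_len, p_end = p_end,
                       q_start = q_start, stringsAsFactors = FALSE)
  arms <- reference_arms(names, rep(p_end, n_chrom), rep(q_start, n_chrom),
                         rep(chrom_len, n_chrom))

  blocks <- data.frame(block_id = integer(), start = numeric(),
                       end = numeric(), divergence = numeric(),
                       sharing = character(), stringsAsFactors = FALSE)
  if (n_shared_blocks > 0) {
    free <- p_end - n_shared_blocks * block_len
    spacing <- floor(free / (n_shared_blocks + 1) / granularity) * granularity
    if (spacing < 0) stop("infeasible packing: blocks exceed the p-arm")
    starts <- spacing + (seq_len(n_shared_blocks) - 1) * (block_len + spacing)
    sharing_sets <- if (is.list(sharing)) {
      stopifnot(length(sharing) == n_shared_blocks)
      sharing
    } else if (identical(sharing, "pairs")) {
      lapply(seq_len(n_shared_blocks), function(i) sample(n_chrom, 2))
    } else {  # mixed: first set of size >= 3 when possible
      lapply(seq_len(n_shared_blocks), function(i) {
        size <- if (i == 1) min(3, n_chrom) else sample(2:min(3, n_chrom), 1)
        sample(n_chrom, size)
      })
    }
    blocks <- data.frame(
      block_id = seq_len(n_shared_blocks),
      start = starts, end = starts + block_len,
      divergence = divergence_within_block,
      sharing = vapply(sharing_sets, function(s)
        paste(sort(names[s]), collapse = "+"), ""),
      stringsAsFactors = FALSE)
  }
  structure(list(chroms = chroms, arms = arms, blocks = blocks,
                 params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                               block_len = block_len,
                               divergence = divergence_within_block,
                               granularity = granularity, seed = seed)),
            class = "phr_refset")
}

#' Chromosomes sharing a block
#' @param refset a `phr_refset`.
#' @param block_id block identifier.
#' @return Character vector of chromosome names.
#' @keywords internal
block_sharing <- function(refset, block_id) {
  strsplit(refset$blocks$sharing[refset$blocks$block_id == block_id],
           "+", fixed = TRUE)[[1]]
}

#' True PHR intervals implied by a reference set
#'
#' The intervals where inter-chromosomal exchange can be (and, at a
#' positive exchange rate, is) simulated: every shared block, on every
#' chromosome of its sharing set.
#'
#' @param refset a `phr_refset`.
#' @return A genomic-interval data frame.
#' @export
truth_phr_intervals <- function(refset) {
  if (nrow(refset$blocks) == 0) return(genomic_intervals())
  rows <- lapply(seq_len(nrow(refset$blocks)), function(i) {
    chroms <- block_sharing(refset, refset$blocks$block_id[i])
    genomic_intervals(chroms, rep(refset$blocks$start[i], length(chroms)),
                      rep(refset$blocks$end[i], length(chroms)))
  })
  do.call(rbind, rows)
}

# Exchange visibility: alternates from the sharing set are emitted above
# the identity floor only when exchange_rate > 0. Ongoing exchange is what
# keeps shared blocks near-identical across chromosomes; in the null the
# blocks stand for ancient homology that has diverged below the floor, so
# the null fixture carries no cross-chromosome hits and no tuple
# diversity.

# deterministic identity ladder inside a block: the donor sits at
# 1 - divergence (plus clipped noise); every other sharing chromosome at
# 1 - divergence - 0.01 * (distance from the donor in the sorted sharing
# set). Tuple order therefore depends only on the donor, so the
# no-exchange null carries no spurious tuple diversity.
.block_identities <- function(sharing_sorted, donor, divergence, noise_sd) {
  base <- 1 - divergence
  d <- abs(match(sharing_sorted, sharing_sorted) -
             match(donor, sharing_sorted))
  id <- base - 0.01 * d
  noise <- stats::rnorm(1, 0, noise_sd)
  id[d == 0] <- min(1, max(base - 0.009, base + noise))
  stats::setNames(id, sharing_sorted)
}

#' Simulate mosaic p--q contigs and their untangle records
#'
#' Emits, for each chromosome, `contigs_per_chrom` contigs spanning the
#' whole chromosome (q-arm plus p-arm), segmented into `segment_len`
#' pieces. Outside shared blocks a segment's only homologous target is
#' the contig's anchor chromosome. Inside a block shared with the anchor,
#' the segment's donor follows a Markov chain over the sharing set with
#' expected `exchange_rate` switches per block traversal; the donor is
#' the best hit, the other sharing chromosomes follow on a deterministic
#' identity ladder, so hit-tuple order reflects the donor alone.
#' Homologous identities are clipped to `[0.9 + sep_margin, 1]` and
#' non-homologous decoys (two random non-sharing chromosomes per segment,
#' centred at 0.80) to `[0, 0.9 - sep_margin]`, so the identity filter
#' separates them exactly.
#'
#' @param refset a `phr_refset`.
#' @param contigs_per_chrom contigs per anchor chromosome (default 20).
#' @param exchange_rate expected donor switches per block traversal
#'   (default 1.0; 0 disables exchange).
#' @param segment_len untangle segment length (default 5e4).
#' @param noise_sd Gaussian noise sd on the best-hit identity
#'   (default 0.002).
#' @param sep_margin separation margin around the 0.90 identity cut
#'   (default 0.05).
#' @param background_divergence anchor divergence outside blocks
#'   (default 0.002, haplotype-level variation).
#' @param seed integer seed.
#' @return A list: `records` (mapping-record data frame), `truth` (a
#'   `phr_sim_truth`: `phr` intervals, `donor_path` per contig,
#'   `switches` per contig, `seed`).
#' @export
simulate_mosaic_contigs <- function(refset, contigs_per_chrom = 20,
                                    exchange_rate = 1.0, segment_len = 5e4,
                                    noise_sd = 0.002, sep_margin = 0.05,
                                    background_divergence = 0.002,
                                    seed = 1) {
  stopifnot(exchange_rate >= 0, sep_margin > 0, sep_margin < 0.1)
  set.seed(seed)
  chroms <- refset$chroms
  L <- chroms$length[1]
  segs <- window_partition(L, segment_len)
  nseg <- nrow(segs)
  blocks <- refset$blocks
  div <- if (nrow(blocks) > 0) blocks$divergence[1] else 0
  hom_floor <- 0.9 + sep_margin
  dec_ceil <- 0.9 - sep_margin

  # which block (if any) contains each segment
  seg_block <- rep(NA_integer_, nseg)
  for (b in seq_len(nrow(blocks)))
    seg_block[segs$start >= blocks$start[b] & segs$end <= blocks$end[b]] <-
      blocks$block_id[b]

  rec_ctg <- list(); rec_seg_s <- list(); rec_seg_e <- list()
  rec_tn <- list(); rec_id <- list()
  donor_rows <- list()
  switch_rows <- list()
  for (ci in seq_len(nrow(chroms))) {
    anchor <- chroms$name[ci]
    for (k in seq_len(contigs_per_chrom)) {
      ctg <- sprintf("sim#%s_ctg%02d", anchor, k)
      donor <- rep(anchor, nseg)
      cur <- anchor
      cur_block <- NA_integer_
      for (s in seq_len(nseg)) {
        b <- seg_block[s]
        sharing <- if (!is.na(b)) block_sharing(refset, b) else character(0)
        if (!is.na(b) && anchor %in% sharing && length(sharing) >= 2 &&
            exchange_rate > 0) {
          if (!identical(b, cur_block)) cur <- anchor  # re-enter block
          n_seg_block <- sum(seg_block == b, na.rm = TRUE)
          if (stats::runif(1) < exchange_rate / n_seg_block) {
            new <- sample(setdiff(sharing, cur), 1)
            switch_rows[[length(switch_rows) + 1]] <-
              data.frame(contig = ctg, pos = segs$start[s],
                         from = cur, to = new, stringsAsFactors = FALSE)
            cur <- new
          }
          donor[s] <- cur
        } else {
          cur <- anchor
          donor[s] <- anchor
        }
        cur_block <- b
      }
      # emit records per segment
      for (s in seq_len(nseg)) {
        b <- seg_block[s]
        sharing <- if (!is.na(b)) block_sharing(refset, b) else character(0)
        in_shared <- !is.na(b) && anchor %in% sharing &&
          length(sharing) >= 2 && exchange_rate > 0
        if (in_shared) {
          ids <- .block_identities(sort(sharing), donor[s], div, noise_sd)
          ids <- pmin(pmax(ids, hom_floor), 1)
        } else {
          ids <- stats::setNames(
            min(1, max(hom_floor,
                       stats::rnorm(1, 1 - background_divergence, noise_sd))),
            anchor)
        }
        decoy_pool <- setdiff(chroms$name, names(ids))
        decoys <- if (length(decoy_pool) > 0)
          sample(decoy_pool, min(2, length(decoy_pool))) else character(0)
        dec_ids <- stats::setNames(
          pmin(dec_ceil, pmax(0, stats::rnorm(length(decoys), 0.80, 0.02))),
          decoys)
        all_ids <- c(ids, dec_ids)
        k <- length(rec_ctg) + 1
        rec_ctg[[k]] <- rep(ctg, length(all_ids))
        rec_seg_s[[k]] <- rep(segs$start[s], length(all_ids))
        rec_seg_e[[k]] <- rep(segs$end[s], length(all_ids))
        rec_tn[[k]] <- names(all_ids)
        rec_id[[k]] <- unname(all_ids)
      }
      # run-length donor path
      r <- rle(donor)
      ends <- cumsum(r$lengths) * segment_len
      ends[length(ends)] <- L
      donor_rows[[length(donor_rows) + 1]] <- data.frame(
        contig = ctg, query_start = c(0, utils::head(ends, -1)),
        query_end = ends, donor = r$values, anchor = anchor,
        stringsAsFactors = FALSE)
    }
  }
  records <- data.frame(
    query_name = unlist(rec_ctg), query_len = L,
    query_start = unlist(rec_seg_s), query_end = unlist(rec_seg_e),
    strand = "+", target_name = unlist(rec_tn), target_len = L,
    target_start = unlist(rec_seg_s), target_end = unlist(rec_seg_e),
    jaccard = jaccard_from_identity(unlist(rec_id)),
    identity = NA_real_, stringsAsFactors = FALSE)
  class(records) <- c("phr_mappings", "data.frame")
  validate_mappings(records)
  truth <- structure(list(
    phr = if (exchange_rate > 0) truth_phr_intervals(refset)
          else genomic_intervals(),
    donor_path = do.call(rbind, donor_rows),
    switches = if (length(switch_rows) > 0) do.call(rbind, switch_rows)
               else data.frame(contig = character(), pos = numeric(),
                               from = character(), to = character(),
                               stringsAsFactors = FALSE),
    seed = seed), class = "phr_sim_truth")
  list(records = records, truth = truth)
}

#' Simulate unreliable-region masks for contigs
#'
#' Places random disjoint intervals totalling approximately `fraction` of
#' each contig's length, emulating read-coverage-based unreliable-region
#' flags. Intervals are drawn on a fixed 10-kb grid, so the masked total
#' is `round(fraction * len / 1e4) * 1e4` exactly.
#'
#' @param contig_names contig names.
#' @param contig_len contig length (scalar or per-contig vector).
#' @param fraction fraction of each contig to mask, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return A genomic-interval data frame in contig coordinates.
#' @export
simulate_unreliable_mask <- function(contig_names, contig_len,
                                     fraction = 0.05, seed = 1) {
  stopifnot(fraction >= 0, fraction < 0.5)
  set.seed(seed)
  contig_len <- rep_len(contig_len, length(contig_names))
  piece <- 1e4
  rows <- lapply(seq_along(contig_names), function(i) {
    n_slots <- floor(contig_len[i] / piece)
    k <- round(fraction * contig_len[i] / piece)
    if (k == 0) return(NULL)
    slots <- sort(sample.int(n_slots, k)) - 1
    genomic_intervals(contig_names[i], slots * piece, (slots + 1) * piece)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(genomic_intervals())
  do.call(rbind, rows)
}

#' Simulate a haplotype panel by founder copying with recombination
#'
#' Founder haplotypes carry independent biallelic SNPs; each of
#' `n_generations` Wright-Fisher rounds replaces every haplotype by a
#' recombinant of two parents drawn with replacement from the previous
#' generation, with per-base crossover probability
#' `crossover_rate_q` outside the given PHR intervals and
#' `crossover_rate_q * crossover_multiplier_phr` inside. Drift under the
#' finite panel builds linkage disequilibrium; recombination erodes it
#' with distance, faster where the rate is higher. Sites with
#' minor-allele count below 2 after the final generation are dropped.
#'
#' @param chrom_len chromosome length in bases.
#' @param phr_intervals genomic intervals (one chromosome) with the
#'   elevated crossover rate; may be empty.
#' @param n_hap number of haplotypes (>= 4; default 60).
#' @param mut_density founder SNPs per base (default 1e-3).
#' @param crossover_rate_q per-base crossover probability per generation
#'   outside PHRs (default 1e-6).
#' @param crossover_multiplier_phr rate multiplier inside PHRs (>= 1;
#'   default 10).
#' @param n_generations recombination rounds (default 50).
#' @param chrom chromosome name (default `"chr01"`).
#' @param seed integer seed.
#' @return A `phr_hap_panel` list: `haplotypes`, `positions` (0-based,
#'   strictly increasing), `mat` (haplotype x site 0/1 matrix), `chrom`,
#'   `crossovers` (positions of all crossover events).
#' @export
simulate_haplotype_panel <- function(chrom_len, phr_intervals = NULL,
                                     n_hap = 60, mut_density = 1e-3,
                                     crossover_rate_q = 1e-6,
                                     crossover_multiplier_phr = 10,
                                     n_generations = 50, chrom = "chr01",
                                     seed = 1) {
  stopifnot(n_hap >= 4, crossover_multiplier_phr >= 1)
  set.seed(seed)
  n_sites <- round(chrom_len * mut_density)
  positions <- sort(sample.int(chrom_len, n_sites)) - 1
  freq <- stats::runif(n_sites, 0.2, 0.8)
  mat <- matrix(stats::rbinom(n_hap * n_sites, 1, rep(freq, each = n_hap)),
                nrow = n_hap)

  phr <- if (is.null(phr_intervals) || nrow(phr_intervals) == 0)
    genomic_intervals() else
      merge_intervals(phr_intervals, max_gap = 0, min_len = 0)
  phr_total <- if (nrow(phr) > 0) sum(phr$end - phr$start) else 0
  lam_q <- crossover_rate_q * (chrom_len - phr_total)
  lam_p <- crossover_rate_q * crossover_multiplier_phr * phr_total

  draw_crossovers <- function() {
    n_q <- stats::rpois(1, lam_q)
    n_p <- stats::rpois(1, lam_p)
    xs <- numeric(0)
    if (n_q > 0) {  # uniform over the complement of the PHR union
      u <- stats::runif(n_q, 0, chrom_len - phr_total)
      if (nrow(phr) > 0) {
        for (i in seq_len(nrow(phr)))  # shift past each PHR in order
          u <- ifelse(u >= phr$start[i], u + (phr$end[i] - phr$start[i]), u)
      }
      xs <- c(xs, u)
    }
    if (n_p > 0 && nrow(phr) > 0) {
      w <- (phr$end - phr$start) / phr_total
      iv <- sample.int(nrow(phr), n_p, replace = TRUE, prob = w)
      xs <- c(xs, stats::runif(n_p, phr$start[iv], phr$end[iv]))
    }
    sort(xs)
  }

  all_x <- numeric(0)
  for (g in seq_len(n_generations)) {
    new_mat <- mat
    # Wright-Fisher with recombination: every offspring haplotype is a
    # recombinant of two parents drawn with replacement
    par1 <- sample.int(n_hap, n_hap, replace = TRUE)
    par2 <- sample.int(n_hap, n_hap, replace = TRUE)
    for (i in seq_len(n_hap)) {
      xs <- draw_crossovers()
      if (length(xs) == 0) {
        new_mat[i, ] <- mat[par1[i], ]
        next
      }
      all_x <- c(all_x, xs)
      seg <- findInterval(positions, xs)  # parity selects the parent
      odd <- seg %% 2 == 1
      new_mat[i, !odd] <- mat[par1[i], !odd]
      new_mat[i, odd] <- mat[par2[i], odd]
    }
    mat <- new_mat
  }
  mac <- pmin(colSums(mat), n_hap - colSums(mat))
  keep <- mac >= 2
  structure(list(haplotypes = sprintf("hap%03d", seq_len(n_hap)),
                 positions = positions[keep],
                 mat = mat[, keep, drop = FALSE],
                 chrom = chrom, crossovers = all_x, seed = seed),
            class = "phr_hap_panel")
}

#' Write a haplotype panel as a ploidy-1 VCF
#'
#' One haploid sample column per haplotype, `GT`-only format; REF/ALT are
#' placeholder alleles A/C (the panel is sequence-free). POS is 1-based
#' per VCF convention.
#'
#' @param panel a `phr_hap_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", panel$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$haplotypes), collapse = "\t")), con)
  if (length(panel$positions) > 0) {
    gt <- apply(panel$mat, 2, function(col) paste(col, collapse = "\t"))
    writeLines(paste(panel$chrom, panel$positions + 1,
                     sprintf("snp%d", seq_along(panel$positions)),
                     "A", "C", ".", "PASS", ".", "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}

#' Simulate motif-occurrence hits with block enrichment
#'
#' Places motif hits uniformly along a chromosome, with an
#' `enrichment`-fold higher density inside the given intervals; each hit
#' carries a motif id and that motif's confidence. Emulates a
#' binding-motif scan whose hits concentrate in recombination-active
#' regions.
#'
#' @param chrom chromosome name.
#' @param chrom_len chromosome length.
#' @param blocks genomic intervals to enrich (may be empty).
#' @param n_motifs number of motif models (default 17); a fixed fraction
#'   get confidence below 0.7 (default 3 of 17).
#' @param base_density hits per base outside blocks (default 2e-5).
#' @param enrichment density multiplier inside blocks (default 5).
#' @param hit_len motif hit length in bases (default 17).
#' @param seed integer seed.
#' @return A data frame: `seq_name`, `start`, `end`, `motif`,
#'   `confidence`.
#' @export
simulate_motif_hits <- function(chrom, chrom_len, blocks,
                                n_motifs = 17, base_density = 2e-5,
                                enrichment = 5, hit_len = 17, seed = 1) {
  set.seed(seed)
  conf <- stats::setNames(c(stats::runif(max(0, n_motifs - 3), 0.70, 1),
                            stats::runif(min(3, n_motifs), 0.3, 0.69)),
                          sprintf("motif%02d", seq_len(n_motifs)))
  blk_total <- if (nrow(blocks) > 0) sum(blocks$end - blocks$start) else 0
  n_out <- stats::rpois(1, base_density * (chrom_len - blk_total))
  n_in <- stats::rpois(1, base_density * enrichment * blk_total)
  pos_out <- stats::runif(n_out, 0, chrom_len - blk_total)
  if (nrow(blocks) > 0) {
    b <- blocks[order(blocks$start), , drop = FALSE]
    for (i in seq_len(nrow(b)))
      pos_out <- ifelse(pos_out >= b$start[i],
                        pos_out + (b$end[i] - b$start[i]), pos_out)
  }
  pos_in <- if (blk_total > 0 && n_in > 0) {
    w <- (blocks$end - blocks$start) / blk_total
    iv <- sample.int(nrow(blocks), n_in, replace = TRUE, prob = w)
    stats::runif(n_in, blocks$start[iv], pmax(blocks$start[iv] + 1,
                                              blocks$end[iv] - hit_len))
  } else numeric(0)
  pos <- floor(c(pos_out, pos_in))
  motif <- sample(names(conf), length(pos), replace = TRUE)
  data.frame(seq_name = chrom, start = pos,
             end = pmin(pos + hit_len, chrom_len),
             motif = motif, confidence = unname(conf[motif]),
             stringsAsFactors = FALSE)
}

#' Simulate all-vs-all contig mappings from planted donor paths
#'
#' Emits contig-to-contig homology mappings for community analysis.
#' Contigs are split at the centromere into a p-part and a q-part
#' (mirroring assemblies that break across centromeres). Two contig
#' parts map to each other where they carry sequence copied from the
#' same donor chromosome at the same reference coordinates
#' (identical-by-descent); sequence from different donors is treated as
#' falling below the mapper's chain threshold. Thus with no exchange,
#' homology only links contigs of the same chromosome; with exchange,
#' p-parts of the sharing set become linked.
#'
#' @param refset a `phr_refset`.
#' @param truth a `phr_sim_truth` from [simulate_mosaic_contigs()].
#' @param identity mapping identity for identical-by-descent sequence
#'   (default 0.999).
#' @param min_mapping_len drop mappings shorter than this (default 5e4).
#' @return A list: `records` (contig-part all-vs-all mapping records),
#'   `part_lens` (named lengths), `part_labels` (part, chromosome, arm).
#' @export
simulate_contig_graph_mappings <- function(refset, truth, identity = 0.999,
                                           min_mapping_len = 5e4) {
  cen_start <- refset$chroms$p_end[1]
  cen_end <- refset$chroms$q_start[1]
  L <- refset$chroms$length[1]
  dp <- truth$donor_path
  # split each contig's donor path at the centromere into p/q parts
  parts <- list()
  for (ctg in unique(dp$contig)) {
    d <- dp[dp$contig == ctg, , drop = FALSE]
    clip <- function(lo, hi, tag) {
      dd <- d[d$query_end > lo & d$query_start < hi, , drop = FALSE]
      if (nrow(dd) == 0) return(NULL)
      dd$query_start <- pmax(dd$query_start, lo)
      dd$query_end <- pmin(dd$query_end, hi)
      dd$part <- paste0(ctg, "_", tag)
      dd
    }
    parts[[length(parts) + 1]] <- clip(0, cen_start, "p")
    parts[[length(parts) + 1]] <- clip(cen_end, L, "q")
  }
  parts <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  part_lens <- tapply(parts$query_end - parts$query_start, parts$part, sum)
  part_anchor <- tapply(parts$anchor, parts$part, `[`, 1)
  part_arm <- ifelse(grepl("_p$", names(part_lens)), "p", "q")
  part_labels <- data.frame(part = names(part_lens),
                            chromosome = unname(part_anchor[names(part_lens)]),
                            arm = part_arm, stringsAsFactors = FALSE)

  # shared (reference-coordinate, donor) runs between part pairs
  key <- paste(parts$donor, parts$part)
  part_names <- unique(parts$part)
  rec <- list()
  for (i in seq_along(part_names)) {
    pi <- parts[parts$part == part_names[i], , drop = FALSE]
    for (j in seq_along(part_names)) {
      if (j <= i) next
      pj <- parts[parts$part == part_names[j], , drop = FALSE]
      shared <- 0
      for (a in seq_len(nrow(pi))) {
        same <- pj[pj$donor == pi$donor[a], , drop = FALSE]
        if (nrow(same) > 0)
          shared <- shared +
            interval_overlap_len(pi$query_start[a], pi$query_end[a],
                                 data.frame(start = same$query_start,
                                            end = same$query_end))
      }
      if (shared >= min_mapping_len) {
        la <- part_lens[[part_names[i]]]
        lb <- part_lens[[part_names[j]]]
        rec[[length(rec) + 1]] <- data.frame(
          query_name = part_names[i], query_len = la,
          query_start = 0, query_end = shared, strand = "+",
          target_name = part_names[j], target_len = lb,
          target_start = 0, target_end = shared,
          jaccard = jaccard_from_identity(identity), identity = identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(rec) > 0) do.call(rbind, rec) else
    mapping_records(character(), numeric(), numeric(), numeric(),
                    character(), character(), numeric(), numeric(),
                    numeric(), numeric())
  class(records) <- c("phr_mappings", "data.frame")
  list(records = records,
       part_lens = stats::setNames(as.numeric(part_lens), names(part_lens)),
       part_labels = part_labels)
}
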