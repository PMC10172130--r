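# Contig homology mapping graph: construction, chromosome/arm labelling,
# Leiden community detection and community x chromosome tabulation.

#' Build the weighted contig mapping graph
#'
#' Nodes are contigs (those at least `min_contig_len` long); an
#' undirected edge joins two contigs that map to each other, with weight
#' equal to the sum over their mappings of mapping length times estimated
#' identity. Parallel mappings between the same pair accumulate into one
#' edge; self-mappings are dropped. Same-haplotype mapping exclusion is
#' the caller's duty (upstream mapping is expected to skip
#' query/target pairs from one haplotype).
#'
#' @param mappings all-vs-all mapping records between contigs; missing
#'   identities are computed from `jaccard`.
#' @param min_contig_len drop contigs shorter than this (default 1e6,
#'   mirroring the contig-length floor used to suppress spurious matches).
#' @param contig_lens optional named vector of contig lengths; contigs
#'   appearing only there are kept as isolated nodes.
#' @return An `igraph` undirected weighted graph with vertex attribute
#'   `len`.
#' @export
build_mapping_graph <- function(mappings, min_contig_len = 1e6,
                                contig_lens = NULL) {
  validate_mappings(mappings)
  if (nrow(mappings) > 0 && anyNA(mappings$identity)) {
    miss <- is.na(mappings$identity)
    mappings$identity[miss] <- identity_from_jaccard(mappings$jaccard[miss])
  }
  lens <- c(
    stats::setNames(mappings$query_len, mappings$query_name),
    stats::setNames(mappings$target_len, mappings$target_name),
    if (!is.null(contig_lens)) contig_lens
  )
  lens <- lens[!duplicated(names(lens))]
  lens <- lens[lens >= min_contig_len]
  keep <- mappings$query_name %in% names(lens) &
    mappings$target_name %in% names(lens) &
    mappings$query_name != mappings$target_name
  m <- mappings[keep, , drop = FALSE]
  if (nrow(m) > 0) {
    a <- pmin(m$query_name, m$target_name)
    b <- pmax(m$query_name, m$target_name)
    w <- (m$query_end - m$query_start) * m$identity
    agg <- stats::aggregate(w, list(a = a, b = b), sum)
    g <- igraph::graph_from_data_frame(
      data.frame(from = agg$a, to = agg$b, weight = agg$x),
      directed = FALSE,
      vertices = data.frame(name = names(lens), len = unname(lens)))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(names(lens), len = unname(lens))
  }
  g
}

#' Per-chromosome arm annotation table
#'
#' Convenience constructor for the arm structure used by anchoring and
#' labelling: one `p`, one `cen` and one `q` interval per chromosome,
#' partitioning `[0, length)`.
#'
#' @param chrom chromosome names.
#' @param p_end end of the p-arm (= start of the centromere).
#' @param q_start start of the q-arm (= end of the centromere).
#' @param chrom_len chromosome lengths.
#' @return A genomic-interval data frame with labels `p`, `cen`, `q`.
#' @export
reference_arms <- function(chrom, p_end, q_start, chrom_len) {
  stopifnot(all(p_end > 0), all(q_start >= p_end), all(chrom_len > q_start))
  genomic_intervals(
    rep(chrom, 3),
    c(rep(0, length(chrom)), p_end, q_start),
    c(p_end, q_start, chrom_len),
    rep(c("p", "cen", "q"), each = length(chrom))
  )
}

#' Label contigs by reference chromosome and arm
#'
#' Each contig is competitively assigned the chromosome with the largest
#' total identity-weighted mapped length (ties to the lexicographically
#' smallest). Within that chromosome the contig is labelled `p` or `q` by
#' which arm it covers; `pq` when it has mappings of at least `arm_min`
#' aligned bases on both arms, each lying at least `centro_margin` from
#' the centromere; `unassigned` when it has no mapping.
#'
#' @param ref_mappings mapping records of contigs against the reference.
#' @param arms arm annotation (see [reference_arms()]); an error is
#'   raised if a mapped chromosome lacks annotation.
#' @param arm_min minimum aligned bases per arm for the `pq` rule
#'   (default 1000).
#' @param centro_margin minimum distance of the qualifying arm mappings
#'   from the centromere (default 1e6).
#' @param contigs optional character vector of contigs that must appear
#'   in the output (unmapped ones come back `unassigned`).
#' @return A data frame: `contig`, `chromosome`, `arm`.
#' @export
assign_chromosome_labels <- function(ref_mappings, arms, arm_min = 1000,
                                     centro_margin = 1e6, contigs = NULL) {
  if (nrow(ref_mappings) > 0 && anyNA(ref_mappings$identity)) {
    miss <- is.na(ref_mappings$identity)
    ref_mappings$identity[miss] <-
      identity_from_jaccard(ref_mappings$jaccard[miss])
  }
  unknown <- setdiff(unique(ref_mappings$target_name), unique(arms$seq_name))
  if (length(unknown) > 0)
    stop("no arm annotation for chromosome(s): ",
         paste(unknown, collapse = ", "))
  label_one <- function(h) {
    w <- tapply((h$target_end - h$target_start) * h$identity,
                h$target_name, sum)
    chrom <- sort(names(w)[w == max(w)])[1]
    hh <- h[h$target_name == chrom, , drop = FALSE]
    a <- arms[arms$seq_name == chrom, , drop = FALSE]
    cen <- a[a$label == "cen", , drop = FALSE]
    p_iv <- a[a$label == "p", , drop = FALSE]
    q_iv <- a[a$label == "q", , drop = FALSE]
    # aligned bases per arm, and per arm at >= centro_margin from the centromere
    p_far <- genomic_intervals(chrom, p_iv$start,
                               max(p_iv$start + 1, cen$start - centro_margin))
    q_far_start <- min(q_iv$end - 1, cen$end + centro_margin)
    q_far <- genomic_intervals(chrom, q_far_start, q_iv$end)
    ol <- function(iv) sum(vapply(seq_len(nrow(hh)), function(i)
      interval_overlap_len(hh$target_start[i], hh$target_end[i], iv), 0))
    p_cov <- ol(p_iv); q_cov <- ol(q_iv)
    arm <- if (ol(p_far) >= arm_min && ol(q_far) >= arm_min) "pq"
    else if (p_cov >= q_cov && p_cov > 0) "p"
    else if (q_cov > 0) "q"
    else "unassigned"
    data.frame(contig = h$query_name[1], chromosome = chrom, arm = arm,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    list(data.frame(contig = character(), chromosome = character(),
                    arm = character(), stringsAsFactors = FALSE)),
    lapply(split(ref_mappings, ref_mappings$query_name), label_one)))
  if (!is.null(contigs)) {
    missing <- setdiff(contigs, out$contig)
    if (length(missing) > 0)
      out <- rbind(out, data.frame(contig = missing,
                                   chromosome = NA_character_,
                                   arm = "unassigned",
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Detect communities in the mapping graph
#'
#' Runs the Leiden algorithm (modularity objective, resolution 1.0 by
#' default) on the weighted mapping graph. The returned partition never
#' has lower modularity than the trivial one-community partition
#' (modularity 0); if the optimiser were ever to return less, the trivial
#' partition is returned instead. Deterministic for a fixed seed.
#'
#' @param graph an `igraph` graph from [build_mapping_graph()].
#' @param seed integer seed for the Leiden refinement.
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param n_iterations Leiden iterations (default 10).
#' @return A named integer vector: contig -> community id.
#' @export
detect_communities <- function(graph, seed = 1, resolution = 1.0,
                               n_iterations = 10) {
  stopifnot(igraph::vcount(graph) > 0)
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  memb <- igraph::membership(cl)
  if (igraph::ecount(graph) > 0 &&
      igraph::modularity(graph, memb,
                         weights = igraph::E(graph)$weight) < 0) {
    memb[] <- 1L
  }
  stats::setNames(as.integer(memb), igraph::V(graph)$name)
}

#' Tabulate community composition by chromosome
#'
#' For every (community, chromosome) cell, reports how many contigs fall
#' in it and what fraction of the total labelled sequence they carry.
#'
#' @param partition named vector contig -> community (from
#'   [detect_communities()]).
#' @param labels contig label frame (from [assign_chromosome_labels()]).
#' @param contig_lens named vector of contig lengths.
#' @return A data frame: `community`, `chromosome`, `n_contigs`,
#'   `seq_fraction` (fraction of the summed length of all contigs in the
#'   partition).
#' @export
community_contingency <- function(partition, labels, contig_lens) {
  if (length(partition) == 0)
    return(data.frame(community = integer(), chromosome = character(),
                      n_contigs = integer(), seq_fraction = numeric(),
                      stringsAsFactors = FALSE))
  lab <- stats::setNames(labels$chromosome, labels$contig)
  chroms <- lab[names(partition)]
  chroms[is.na(chroms)] <- "unassigned"
  lens <- contig_lens[names(partition)]
  total <- sum(lens)
  agg <- stats::aggregate(
    list(n_contigs = rep(1L, length(partition)), seq_len = lens),
    list(community = as.integer(partition), chromosome = unname(chroms)),
    sum)
  data.frame(community = agg$community, chromosome = agg$chromosome,
             n_contigs = agg$n_contigs,
             seq_fraction = agg$seq_len / total,
             stringsAsFactors = FALSE)
}
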