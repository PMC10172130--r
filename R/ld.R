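# Haploid linkage disequilibrium from ploidy-1 VCFs: pairwise r2 within
# a distance cap, region-class stratification, and binned decay curves
# with bootstrap confidence intervals.

#' Extract biallelic SNPs from a ploidy-1 VCF into a haplotype panel
#'
#' Reads a VCF whose genotype columns are haploid (as produced by
#' variant deconstruction of a pangenome graph with ploidy 1) and keeps
#' only biallelic single-nucleotide variants. Multi-allelic sites,
#' indels, sites with all genotypes missing, and monomorphic sites are
#' dropped; the drop counts are attached as the `dropped` attribute. A
#' diploid-encoded genotype anywhere is an error naming the sample and
#' site.
#'
#' @param path path to the VCF (plain text or bgzip).
#' @return A `phr_hap_panel` list: `haplotypes`, `positions` (0-based),
#'   `mat` (haplotype x site matrix in 0/1/`NA`), `chrom`.
#' @export
extract_biallelic_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt[, -1, drop = FALSE]
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = 1)
  samples <- colnames(v@gt)[-1]
  n_total <- nrow(fix)

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 &
    !grepl(",", alt, fixed = TRUE) & nchar(alt) == 1
  # GT is the first (here only) field of the FORMAT column
  gt <- matrix(sub(":.*$", "", gt_raw), nrow = nrow(gt_raw))
  diploid <- grepl("[/|]", gt)
  if (any(diploid)) {
    idx <- which(diploid)[1]
    row <- (idx - 1) %% nrow(gt) + 1
    col <- (idx - 1) %/% nrow(gt) + 1
    stop("ploidy-2 genotype for sample ", samples[col],
         " at ", fix[row, "CHROM"], ":", fix[row, "POS"])
  }
  mat <- suppressWarnings(matrix(as.integer(gt), nrow = nrow(gt)))
  all_missing <- rowSums(!is.na(mat)) == 0
  alt_n <- rowSums(mat == 1, na.rm = TRUE)
  ref_n <- rowSums(mat == 0, na.rm = TRUE)
  mono <- !all_missing & (alt_n == 0 | ref_n == 0)
  keep <- is_snp & !all_missing & !mono
  dropped <- c(non_snp = sum(!is_snp),
               all_missing = sum(is_snp & all_missing),
               monomorphic = sum(mono & is_snp))
  pos <- as.numeric(fix[keep, "POS"]) - 1  # to 0-based
  o <- order(pos)
  structure(list(haplotypes = samples,
                 positions = pos[o],
                 mat = t(mat[keep, , drop = FALSE])[, o, drop = FALSE],
                 chrom = if (any(keep)) fix[keep, "CHROM"][1] else NA_character_,
                 dropped = dropped),
            class = "phr_hap_panel")
}

#' Pairwise haploid r-squared within a distance cap
#'
#' For every ordered site pair within `max_dist` bases, r2 is the squared
#' Pearson correlation of the two 0/1 allele vectors over the haplotypes
#' non-missing at both sites — algebraically the standard
#' `D^2 / (p(1-p) q(1-q))` of the 2x2 haplotype table. Pairs monomorphic
#' over the shared haplotypes are skipped; by default pairs with r2 = 0
#' are dropped, reproducing the convention of haploid LD reports that
#' emit only positive r2 (set `keep_zero = TRUE` to retain them —
#' dropping zeros biases bin means upward).
#'
#' @param panel a `phr_hap_panel`.
#' @param max_dist maximum pair distance in bases (default 70000).
#' @param keep_zero retain pairs with r2 = 0 (default `FALSE`).
#' @return A data frame: `pos_a`, `pos_b`, `distance`, `r2`.
#' @export
pairwise_r2 <- function(panel, max_dist = 70000, keep_zero = FALSE) {
  stopifnot(nrow(panel$mat) >= 2)
  pos <- panel$positions
  m <- panel$mat
  n <- length(pos)
  out_a <- list(); out_b <- list(); out_r <- list()
  hi <- 1
  for (i in seq_len(n)) {
    if (i + 1 > n) break
    while (hi < n && pos[hi + 1] - pos[i] <= max_dist) hi <- hi + 1
    if (hi <= i) next
    js <- (i + 1):hi
    r <- suppressWarnings(
      stats::cor(m[, i], m[, js, drop = FALSE],
                 use = "pairwise.complete.obs"))[1, ]
    ok <- !is.na(r)
    if (any(ok)) {
      out_a[[i]] <- rep(pos[i], sum(ok))
      out_b[[i]] <- pos[js[ok]]
      out_r[[i]] <- r[ok]^2
    }
  }
  df <- data.frame(pos_a = unlist(out_a), pos_b = unlist(out_b),
                   r2 = unlist(out_r))
  if (nrow(df) == 0)
    return(data.frame(pos_a = numeric(), pos_b = numeric(),
                      distance = numeric(), r2 = numeric()))
  df$distance <- df$pos_b - df$pos_a
  if (!keep_zero) df <- df[df$r2 > 0, , drop = FALSE]
  rownames(df) <- NULL
  df[, c("pos_a", "pos_b", "distance", "r2")]
}

#' Binned LD-decay curve with bootstrap confidence intervals
#'
#' Splits pair distances into `n_bins` equal-width bins over
#' `(0, max_dist]`, reports the mean r2 per bin and a percentile
#' bootstrap confidence interval obtained by resampling pairs with
#' replacement. Empty bins are reported with `n_pairs = 0` and `NA`
#' statistics.
#'
#' @param pairs a data frame from [pairwise_r2()].
#' @param max_dist distance cap for the curve (default 4000).
#' @param n_bins number of bins (default 4).
#' @param n_boot bootstrap replicates (default 200).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return A data frame: `bin_start`, `bin_end`, `mean_r2`, `ci_low`,
#'   `ci_high`, `n_pairs`.
#' @export
binned_decay <- function(pairs, max_dist = 4000, n_bins = 4, n_boot = 200,
                         level = 0.95, seed = 1) {
  stopifnot(n_bins >= 1)
  set.seed(seed)
  width <- max_dist / n_bins
  p <- pairs[pairs$distance > 0 & pairs$distance <= max_dist, , drop = FALSE]
  bin <- pmin(n_bins, ceiling(p$distance / width))
  alpha <- (1 - level) / 2
  rows <- lapply(seq_len(n_bins), function(b) {
    r2 <- p$r2[bin == b]
    if (length(r2) == 0)
      return(data.frame(bin_start = (b - 1) * width, bin_end = b * width,
                        mean_r2 = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_pairs = 0L))
    boots <- vapply(seq_len(n_boot), function(k)
      mean(sample(r2, length(r2), replace = TRUE)), 0)
    data.frame(bin_start = (b - 1) * width, bin_end = b * width,
               mean_r2 = mean(r2),
               ci_low = unname(stats::quantile(boots, alpha)),
               ci_high = unname(stats::quantile(boots, 1 - alpha)),
               n_pairs = length(r2))
  })
  do.call(rbind, rows)
}

#' Compare binned decay between two region classes across replicates
#'
#' Tests whether two region classes show distinguishable LD decay.
#' Within one panel, pairs share genealogy, so pair-resampling intervals
#' (as in [binned_decay()]) understate the uncertainty of a class mean;
#' this comparison therefore works at the replicate level: each element
#' of `stratified_list` is an independent stratified pair set (one
#' replicate panel), the per-bin class mean is computed per replicate,
#' and a Student-t interval over the replicate means gives each class's
#' confidence interval (the t interval keeps nominal coverage at the
#' small replicate counts used here, where a percentile bootstrap
#' undercovers). Two classes are indistinguishable in a bin when the
#' intervals overlap.
#'
#' @param stratified_list list of data frames from [stratify_by_region()],
#'   one per independent replicate panel.
#' @param class_a,class_b region classes to compare (e.g. `"PHR"`,
#'   `"q_arm"`).
#' @param max_dist distance cap in bases (default 4000).
#' @param n_bins equal-width bins over `(0, max_dist]` (default 4).
#' @param level confidence level (default 0.95).
#' @return A data frame per bin: `bin_start`, `bin_end`, `mean_a`,
#'   `mean_b`, `ci_low_a`, `ci_high_a`, `ci_low_b`, `ci_high_b`,
#'   `overlap` (logical).
#' @export
compare_decay_classes <- function(stratified_list, class_a, class_b,
                                  max_dist = 4000, n_bins = 4,
                                  level = 0.95) {
  stopifnot(length(stratified_list) >= 2)
  width <- max_dist / n_bins
  class_mean <- function(st, cls, b) {
    sel <- st$distance > (b - 1) * width & st$distance <= b * width &
      st$region_class %in% cls
    mean(st$r2[sel])
  }
  ci <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    half <- stats::qt(1 - (1 - level) / 2, df = length(x) - 1) *
      stats::sd(x) / sqrt(length(x))
    mean(x) + c(-half, half)
  }
  rows <- lapply(seq_len(n_bins), function(b) {
    ma <- vapply(stratified_list, class_mean, 0, cls = class_a, b = b)
    mb <- vapply(stratified_list, class_mean, 0, cls = class_b, b = b)
    ca <- ci(ma); cb <- ci(mb)
    data.frame(bin_start = (b - 1) * width, bin_end = b * width,
               mean_a = mean(ma, na.rm = TRUE),
               mean_b = mean(mb, na.rm = TRUE),
               ci_low_a = ca[1], ci_high_a = ca[2],
               ci_low_b = cb[1], ci_high_b = cb[2],
               overlap = ca[1] <= cb[2] && cb[1] <= ca[2])
  })
  do.call(rbind, rows)
}

#' Stratify LD pairs by region class
#'
#' Classifies each variant by the labelled intervals it falls in, with
#' `PHR` taking precedence over `p_arm` (PHRs lie inside p-arms); a pair
#' belongs to a class only when BOTH variants carry that class. Pairs
#' spanning classes get `NA` and are excluded from all three sets.
#'
#' @param pairs a data frame from [pairwise_r2()].
#' @param regions genomic intervals with `label` in
#'   `{"p_arm", "q_arm", "PHR"}`.
#' @return `pairs` with a `region_class` column.
#' @export
stratify_by_region <- function(pairs, regions) {
  classify <- function(pos) {
    cls <- rep(NA_character_, length(pos))
    for (lab in c("q_arm", "p_arm", "PHR")) {  # later labels take precedence
      iv <- regions[regions$label == lab, , drop = FALSE]
      if (nrow(iv) == 0) next
      inside <- vapply(pos, function(x)
        any(x >= iv$start & x < iv$end), TRUE)
      cls[inside] <- lab
    }
    cls
  }
  ca <- classify(pairs$pos_a)
  cb <- classify(pairs$pos_b)
  pairs$region_class <- ifelse(!is.na(ca) & !is.na(cb) & ca == cb, ca,
                               NA_character_)
  pairs
}
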