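# All genomic coordinates in this package are 0-based half-open (PAF/BED
# convention). 1-based coordinates appear only at the VCF boundary.

#' Column order of a mapping record data frame
#' @keywords internal
.mapping_cols <- c(
  "query_name", "query_len", "query_start", "query_end", "strand",
  "target_name", "target_len", "target_start", "target_end",
  "jaccard", "identity"
)

#' Construct a mapping-record data frame
#'
#' A mapping record is one query-segment to target-segment homology hit
#' with a Jaccard-based similarity estimate: the atom of pangenome
#' untangling. Coordinates are 0-based half-open; `identity` is derived
#' from `jaccard` (see [identity_from_jaccard()]) and may be supplied
#' directly or left `NA` to be filled later.
#'
#' @param query_name,target_name character vectors of sequence names.
#' @param query_len,target_len total sequence lengths in bases.
#' @param query_start,query_end,target_start,target_end interval bounds.
#' @param strand `"+"` or `"-"`.
#' @param jaccard similarity estimate in `[0, 1]`.
#' @param identity optional estimated identity in `[0, 1]`.
#' @return A `data.frame` with one row per record, class `phr_mappings`.
#' @export
mapping_records <- function(query_name, query_len, query_start, query_end,
                            strand, target_name, target_len,
                            target_start, target_end, jaccard,
                            identity = NA_real_) {
  n <- length(query_name)
  strand <- rep_len(as.character(strand), n)
  jaccard <- rep_len(as.numeric(jaccard), n)
  identity <- rep_len(as.numeric(identity), n)
  df <- data.frame(
    query_name = as.character(query_name),
    query_len = as.numeric(query_len),
    query_start = as.numeric(query_start),
    query_end = as.numeric(query_end),
    strand = as.character(strand),
    target_name = as.character(target_name),
    target_len = as.numeric(target_len),
    target_start = as.numeric(target_start),
    target_end = as.numeric(target_end),
    jaccard = as.numeric(jaccard),
    identity = as.numeric(identity),
    stringsAsFactors = FALSE
  )
  validate_mappings(df)
  class(df) <- c("phr_mappings", "data.frame")
  df
}

#' Validate mapping-record invariants
#'
#' Checks the interval and similarity invariants of a mapping-record data
#' frame: `0 <= start < end <= len` on both query and target sides, and
#' `jaccard` in `[0, 1]`.
#'
#' @param df a mapping-record data frame.
#' @return `df`, invisibly.
#' @export
validate_mappings <- function(df) {
  stopifnot(all(.mapping_cols %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$query_start >= 0 & df$query_start < df$query_end &
                   df$query_end <= df$query_len))
  if (length(bad) > 0)
    stop("invalid query interval at record ", bad[1])
  bad <- which(!(df$target_start >= 0 & df$target_start < df$target_end &
                   df$target_end <= df$target_len))
  if (length(bad) > 0)
    stop("invalid target interval at record ", bad[1])
  bad <- which(!(df$jaccard >= 0 & df$jaccard <= 1))
  if (length(bad) > 0)
    stop("jaccard out of [0,1] at record ", bad[1])
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(df)
}

#' Read homology mappings from a PAF file
#'
#' Parses a tab-separated PAF file with the 12 standard columns plus a
#' `jc:f:` tag carrying the Jaccard similarity estimate (and an optional
#' `id:f:` tag with a precomputed identity). Malformed coordinates or a
#' missing similarity tag raise an error naming the offending line.
#'
#' @param path path to a PAF file.
#' @return A mapping-record data frame, rows in file order.
#' @seealso [write_paf()]
#' @export
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(mapping_records(character(), numeric(), numeric(), numeric(),
                           character(), character(), numeric(), numeric(),
                           numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  parse_line <- function(i) {
    f <- fields[[i]]
    if (length(f) < 12)
      stop("PAF line ", i, ": fewer than 12 columns")
    num <- suppressWarnings(as.numeric(f[c(2, 3, 4, 7, 8, 9)]))
    if (anyNA(num))
      stop("PAF line ", i, ": malformed coordinate")
    tags <- f[-(1:12)]
    jc <- grep("^jc:f:", tags, value = TRUE)
    if (length(jc) == 0)
      stop("PAF line ", i, ": missing jc:f: similarity tag")
    jcv <- suppressWarnings(as.numeric(sub("^jc:f:", "", jc[1])))
    if (is.na(jcv))
      stop("PAF line ", i, ": malformed jc:f: tag")
    id <- grep("^id:f:", tags, value = TRUE)
    idv <- if (length(id) > 0)
      suppressWarnings(as.numeric(sub("^id:f:", "", id[1]))) else NA_real_
    list(qn = f[1], ql = num[1], qs = num[2], qe = num[3], st = f[5],
         tn = f[6], tl = num[4], ts = num[5], te = num[6],
         jc = jcv, id = idv)
  }
  p <- lapply(seq_len(n), parse_line)
  df <- data.frame(
    query_name = vapply(p, `[[`, "", "qn"),
    query_len = vapply(p, `[[`, 0, "ql"),
    query_start = vapply(p, `[[`, 0, "qs"),
    query_end = vapply(p, `[[`, 0, "qe"),
    strand = vapply(p, `[[`, "", "st"),
    target_name = vapply(p, `[[`, "", "tn"),
    target_len = vapply(p, `[[`, 0, "tl"),
    target_start = vapply(p, `[[`, 0, "ts"),
    target_end = vapply(p, `[[`, 0, "te"),
    jaccard = vapply(p, `[[`, 0, "jc"),
    identity = vapply(p, `[[`, 0, "id"),
    stringsAsFactors = FALSE
  )
  tryCatch(validate_mappings(df), error = function(e)
    stop("PAF parse error: ", conditionMessage(e)))
  class(df) <- c("phr_mappings", "data.frame")
  df
}

#' Write homology mappings to a PAF file
#'
#' Emits 12 standard PAF columns (residue matches and block length are set
#' to the query span, mapping quality to 255) plus `jc:f:` and, when
#' identity is non-missing, `id:f:` tags. Tab-separated, newline-terminated,
#' no header.
#'
#' @param df a mapping-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(df, path) {
  validate_mappings(df)
  span <- format(df$query_end - df$query_start, scientific = FALSE, trim = TRUE)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(
    df$query_name, fmt(df$query_len), fmt(df$query_start), fmt(df$query_end),
    df$strand, df$target_name, fmt(df$target_len), fmt(df$target_start),
    fmt(df$target_end), span, span, "255",
    sprintf("jc:f:%.*g", 17, df$jaccard),
    sep = "\t"
  )
  has_id <- !is.na(df$identity)
  lines[has_id] <- paste(lines[has_id],
                         sprintf("id:f:%.*g", 17, df$identity[has_id]),
                         sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a genomic-interval data frame
#'
#' @param seq_name character vector of sequence names.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param label optional per-interval label.
#' @return A `data.frame` with columns `seq_name`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(seq_name = character(), start = numeric(),
                              end = numeric(), label = NA_character_) {
  df <- data.frame(seq_name = as.character(seq_name),
                   start = as.numeric(start), end = as.numeric(end),
                   label = rep_len(as.character(label),
                                   length(seq_name)),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$start >= df$end))
    stop("genomic interval with start >= end")
  df
}

#' Read a BED3/BED4 file
#'
#' @param path path to a tab-separated BED file (0-based half-open).
#' @return A genomic-interval data frame; column 4, if present, becomes
#'   `label`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(genomic_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  genomic_intervals(
    seq_name = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    label = ifelse(nf >= 4, vapply(fields, function(f)
      if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  )
}

#' Write a BED file
#'
#' Writes BED3, or BED4 when any label is non-missing; tab-separated,
#' newline-terminated, no header.
#'
#' @param df a genomic-interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (nrow(df) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (!is.null(df$label) && any(!is.na(df$label))) {
    lines <- paste(df$seq_name, fmt(df$start), fmt(df$end),
                   ifelse(is.na(df$label), ".", df$label), sep = "\t")
  } else {
    lines <- paste(df$seq_name, fmt(df$start), fmt(df$end), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge nearby intervals and drop short merged runs
#'
#' Sorts intervals on a single sequence, merges any two whose gap is
#' strictly less than `max_gap` (the gap between `[a,b)` and `[c,d)` with
#' `b <= c` is `c - b`; overlapping or abutting intervals always merge),
#' then removes merged intervals shorter than `min_len`. This is the
#' merge-then-filter rule used to derive pseudo-homologous regions from
#' entropy tracks: candidate runs less than 30 kb apart are merged and
#' merged regions shorter than 30 kb discarded.
#'
#' @param intervals a genomic-interval data frame on one `seq_name`.
#' @param max_gap merge two intervals iff their gap is `< max_gap` (bases).
#' @param min_len drop merged intervals shorter than this (bases).
#' @return A sorted, non-overlapping genomic-interval data frame.
#' @export
merge_intervals <- function(intervals, max_gap = 30000, min_len = 30000) {
  stopifnot(max_gap >= 0, min_len >= 0)
  if (nrow(intervals) == 0) return(genomic_intervals())
  if (length(unique(intervals$seq_name)) > 1)
    stop("merge_intervals: intervals span multiple seq_names")
  o <- order(intervals$start, intervals$end)
  s <- intervals$start[o]; e <- intervals$end[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] - me < max_gap) {  # strict: gap must be < max_gap to merge
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  keep <- (out_e - out_s) >= min_len
  genomic_intervals(rep(intervals$seq_name[1], sum(keep)),
                    out_s[keep], out_e[keep])
}

#' Partition a sequence into consecutive fixed-width windows
#'
#' Half-open windows starting at 0; the last window is truncated at
#' `seq_len`. The windows are disjoint and cover `[0, seq_len)` exactly.
#'
#' @param seq_len sequence length in bases (> 0).
#' @param window window width in bases (> 0).
#' @param seq_name optional name attached to the output intervals.
#' @return A genomic-interval data frame of windows.
#' @export
window_partition <- function(seq_len, window, seq_name = "seq") {
  if (seq_len <= 0 || window <= 0)
    stop("seq_len and window must be positive")
  starts <- seq(0, seq_len - 1, by = window)
  genomic_intervals(rep(seq_name, length(starts)), starts,
                    pmin(starts + window, seq_len))
}

#' Total overlap between an interval and a set of intervals
#'
#' @param start,end the query interval (0-based half-open).
#' @param ivs a genomic-interval data frame (same sequence assumed).
#' @return Overlapping bases (numeric scalar).
#' @keywords internal
interval_overlap_len <- function(start, end, ivs) {
  if (nrow(ivs) == 0) return(0)
  sum(pmax(0, pmin(end, ivs$end) - pmax(start, ivs$start)))
}
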