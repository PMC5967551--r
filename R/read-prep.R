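# Read preparation: QC summary, 3' quality trimming, paired-end overlap
# merging, N/length filtering, primer removal. These are the first four
# stages of the pipeline; reads rejected at any stage are counted per reason
# and never reach dereplication.

#' Configuration for the read-preparation stages
#'
#' Defaults follow the pipeline's published settings: 3' bases below Phred 10
#' are trimmed, merged reads must fall within 229 +/- 25 bp (a closed
#' interval) and contain no N, and primers are matched allowing at most three
#' base mismatches. The merge parameters (minimum overlap 10, maximum
#' mismatch fraction 0.25 in the overlap) follow the published defaults of
#' the standard overlap-merging tools.
#'
#' @param phred_floor trim 3' bases with quality below this Phred score.
#' @param expected_len,len_tol accepted merged length is
#'   `[expected_len - len_tol, expected_len + len_tol]`, inclusive.
#' @param primer_fwd,primer_rev primer sequences, 5'->3' as synthesised.
#' @param max_primer_mismatch maximum substitutions tolerated per primer.
#' @param min_overlap minimum mate overlap considered during merging.
#' @param max_overlap_mismatch_frac maximum mismatch fraction in the overlap.
#' @return a `prep_config` list.
#' @export
prep_config <- function(phred_floor = 10L, expected_len = 229L, len_tol = 25L,
                        primer_fwd = NULL, primer_rev = NULL,
                        max_primer_mismatch = 3L, min_overlap = 10L,
                        max_overlap_mismatch_frac = 0.25) {
  stopifnot(phred_floor >= 0, expected_len > 0, len_tol >= 0,
            len_tol < expected_len, max_primer_mismatch >= 0,
            min_overlap >= 1, max_overlap_mismatch_frac >= 0,
            max_overlap_mismatch_frac <= 1)
  structure(list(phred_floor = as.integer(phred_floor),
                 expected_len = as.integer(expected_len),
                 len_tol = as.integer(len_tol),
                 primer_fwd = if (!is.null(primer_fwd)) toupper(primer_fwd),
                 primer_rev = if (!is.null(primer_rev)) toupper(primer_rev),
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch_frac = max_overlap_mismatch_frac),
            class = "prep_config")
}

#' Lightweight quality-control summary of a read set
#'
#' Per-position mean qualities are averaged over the reads long enough to
#' cover each position.
#'
#' @param reads a `fastq_reads` data frame.
#' @return a list with `n_reads`, `mean_len`, `per_position_mean_q`, `gc_frac`.
#' @export
qc_summary <- function(reads) {
  if (nrow(reads) == 0L) stop("qc_summary: empty read collection")
  lens <- nchar(reads$sequence)
  maxlen <- max(lens)
  qsum <- numeric(maxlen)
  qcnt <- integer(maxlen)
  for (q in reads$quality) {
    v <- phred_decode(q)
    if (length(v)) {
      ix <- seq_along(v)
      qsum[ix] <- qsum[ix] + v
      qcnt[ix] <- qcnt[ix] + 1L
    }
  }
  bases <- paste(reads$sequence, collapse = "")
  nb <- nchar(bases)
  gc <- if (nb) (nb - nchar(gsub("[GCgc]", "", bases))) / nb else NA_real_
  list(n_reads = nrow(reads), mean_len = mean(lens),
       per_position_mean_q = ifelse(qcnt > 0L, qsum / qcnt, NA_real_),
       gc_frac = gc)
}

#' Trim low-quality 3' tails
#'
#' Each read is cut after the last position whose quality is at or above
#' `phred_floor`; reads with no such position become empty (and are dropped
#' by the pair-level wrappers). The operation is idempotent.
#'
#' @param reads a `fastq_reads` data frame.
#' @param phred_floor Phred threshold (default 10).
#' @return the trimmed `fastq_reads` data frame.
#' @export
trim_3prime <- function(reads, phred_floor = 10L) {
  stopifnot(phred_floor >= 0)
  cut <- vapply(reads$quality, function(q) {
    v <- phred_decode(q)
    keep <- which(v >= phred_floor)
    if (length(keep)) keep[length(keep)] else 0L
  }, integer(1), USE.NAMES = FALSE)
  reads$sequence <- substr(reads$sequence, 1L, cut)
  reads$quality <- substr(reads$quality, 1L, cut)
  reads
}

#' Merge one read pair by overlap consensus
#'
#' The reverse mate is reverse-complemented, then every candidate overlap of
#' length at least `min_overlap` between the forward read's 3' end and the
#' mate's 5' end is scored by mismatch fraction; the lowest fraction wins,
#' ties going to the longest overlap. The pair is rejected when the best
#' fraction exceeds `max_overlap_mismatch_frac` or no candidate exists.
#' Consensus bases: agreement keeps the base with quality `max(Q1, Q2)`;
#' disagreement keeps the higher-quality base with its own quality, quality
#' ties keeping the forward base.
#'
#' @param seq1,qual1 forward read sequence and Phred+33 quality string.
#' @param seq2,qual2 reverse mate (as sequenced; reverse-complemented
#'   internally).
#' @param cfg a [prep_config()].
#' @return list with `sequence`, `qualities` (integer), `quality` (string),
#'   `overlap_len`, or `NULL` on rejection.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, cfg = prep_config()) {
  if (nchar(seq1) == 0L || nchar(seq2) == 0L) return(NULL)
  s2 <- revcomp(seq2)
  q2 <- rev(phred_decode(qual2))
  res <- merge_overlap_cpp(toupper(seq1), phred_decode(qual1), s2, q2,
                           cfg$min_overlap, cfg$max_overlap_mismatch_frac)
  if (is.null(res)) return(NULL)
  res$quality <- phred_encode(res$qualities)
  res
}

#' Merge all pairs of a sample
#'
#' Applies 3' quality trimming to both mates, drops pairs in which either
#' mate trims to nothing, then merges each surviving pair with [merge_pair()].
#'
#' @param sample an `edna_sample` from [read_fastq_pair()].
#' @param cfg a [prep_config()].
#' @return list with `merged` (a `merged_reads` data frame: `id`, `sequence`,
#'   `quality`, `overlap_len`) and `counts` (named integer attrition vector).
#' @export
merge_sample <- function(sample, cfg = prep_config()) {
  n_in <- nrow(sample$r1)
  r1 <- trim_3prime(sample$r1, cfg$phred_floor)
  r2 <- trim_3prime(sample$r2, cfg$phred_floor)
  ok <- nchar(r1$sequence) > 0L & nchar(r2$sequence) > 0L
  n_empty <- sum(!ok)
  r1 <- r1[ok, , drop = FALSE]
  r2 <- r2[ok, , drop = FALSE]
  n <- nrow(r1)
  ids <- character(n); seqs <- character(n); quals <- character(n)
  ovls <- integer(n); keep <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_pair(r1$sequence[i], r1$quality[i], r2$sequence[i], r2$quality[i], cfg)
    if (!is.null(m)) {
      keep[i] <- TRUE
      ids[i] <- core_read_id(r1$id[i])
      seqs[i] <- m$sequence; quals[i] <- m$quality; ovls[i] <- m$overlap_len
    }
  }
  merged <- data.frame(id = ids[keep], sequence = seqs[keep],
                       quality = quals[keep], overlap_len = ovls[keep],
                       stringsAsFactors = FALSE)
  class(merged) <- c("merged_reads", "data.frame")
  list(merged = merged,
       counts = c(pairs_in = n_in, trimmed_empty = n_empty,
                  merge_failed = n - sum(keep), merged = sum(keep)))
}

#' Filter merged reads on N content and length
#'
#' A merged read is rejected if it contains an N or if its length lies
#' outside the closed interval `[expected_len - len_tol, expected_len +
#' len_tol]` (204..254 bp at defaults). The rejection reason is recorded as
#' `"N"` or `"length"` (N checked first).
#'
#' @param merged a `merged_reads` data frame.
#' @param cfg a [prep_config()].
#' @return list with `accepted` (data frame), `rejected` (data frame with a
#'   `reason` column), and `counts`.
#' @export
filter_merged <- function(merged, cfg = prep_config()) {
  lo <- cfg$expected_len - cfg$len_tol
  hi <- cfg$expected_len + cfg$len_tol
  has_n <- grepl("N", merged$sequence, fixed = TRUE)
  len <- nchar(merged$sequence)
  bad_len <- len < lo | len > hi
  reason <- rep(NA_character_, nrow(merged))
  reason[bad_len] <- "length"
  reason[has_n] <- "N"
  rej <- !is.na(reason)
  rejected <- merged[rej, , drop = FALSE]
  rejected$reason <- reason[rej]
  list(accepted = merged[!rej, , drop = FALSE],
       rejected = rejected,
       counts = c(reads_in = nrow(merged),
                  rejected_N = sum(has_n),
                  rejected_length = sum(bad_len & !has_n),
                  accepted = sum(!rej)))
}

# best substitution-only placement of `primer` at the 5' end (end = "fwd")
# or 3' end (end = "rev") of `seq`, searching a window of primer length +
# max_mm bases. Returns list(start, mismatches) or NULL if it cannot fit.
best_primer_placement <- function(seq, primer, max_mm, end) {
  n <- nchar(seq); p <- nchar(primer)
  if (p > n) return(NULL)
  offs <- 0:min(max_mm, n - p)
  if (end == "fwd") {
    starts <- 1L + offs              # outermost = start 1
  } else {
    starts <- (n - p + 1L) - offs    # outermost = flush with the 3' end
    starts <- starts[starts >= 1L]
  }
  best <- NULL
  for (st in starts) {
    mm <- hamming_cpp(substr(seq, st, st + p - 1L), primer)
    if (is.null(best) || mm < best$mismatches) best <- list(start = st, mismatches = mm)
    # ties keep the earlier (outermost) placement
  }
  best
}

trim_primers_one_orient <- function(seq, qual, fwd, rc_rev, max_mm) {
  pf <- best_primer_placement(seq, fwd, max_mm, "fwd")
  pr <- best_primer_placement(seq, rc_rev, max_mm, "rev")
  if (is.null(pf) || is.null(pr)) return(NULL)
  if (pf$mismatches > max_mm || pr$mismatches > max_mm) return(NULL)
  ins_from <- pf$start + nchar(fwd)
  ins_to <- pr$start - 1L
  if (ins_to < ins_from) return(NULL)
  list(sequence = substr(seq, ins_from, ins_to),
       quality = substr(qual, ins_from, ins_to),
       fwd_mismatches = pf$mismatches, rev_mismatches = pr$mismatches)
}

#' Locate and excise primers from a merged read
#'
#' The forward primer is expected at the 5' end and the reverse complement of
#' the reverse primer at the 3' end. Each primer slides over a terminal
#' window of `primer length + max_primer_mismatch` bases; the placement with
#' fewest substitutions wins (ties to the outermost placement). Both primers
#' must place with at most `max_primer_mismatch` substitutions or the read is
#' rejected. The reverse-complement orientation of the whole read is also
#' tried; if both orientations succeed the forward orientation is kept.
#' Matching is substitution-only (no indels).
#'
#' @param seq,qual merged read sequence and Phred+33 quality string.
#' @param cfg a [prep_config()] with `primer_fwd` and `primer_rev` set.
#' @return list with the insert `sequence`, `quality`, `orientation`
#'   (`"forward"` or `"reverse"`), and per-primer mismatch counts, or `NULL`
#'   on rejection.
#' @export
trim_primers <- function(seq, qual, cfg) {
  if (is.null(cfg$primer_fwd) || is.null(cfg$primer_rev))
    stop("trim_primers: primer_fwd and primer_rev must be set in the config")
  rc_rev <- revcomp(cfg$primer_rev)
  hit <- trim_primers_one_orient(seq, qual, cfg$primer_fwd, rc_rev,
                                 cfg$max_primer_mismatch)
  if (!is.null(hit)) { hit$orientation <- "forward"; return(hit) }
  hit <- trim_primers_one_orient(revcomp(seq),
                                 intToUtf8(rev(utf8ToInt(qual))),
                                 cfg$primer_fwd, rc_rev,
                                 cfg$max_primer_mismatch)
  if (!is.null(hit)) { hit$orientation <- "reverse"; return(hit) }
  NULL
}

#' Run all read-preparation stages on one sample
#'
#' QC summary, 3' trimming, merging, N/length filtering, primer removal, in
#' that order, with per-stage attrition counts.
#'
#' @param sample an `edna_sample`.
#' @param cfg a [prep_config()] with primers set.
#' @return list with `inserts` (data frame `id`, `sequence`, `quality`),
#'   `attrition` (data frame of per-stage counts), and `qc`.
#' @export
prep_sample <- function(sample, cfg) {
  if (nrow(sample$r1) == 0L) stop("no reads in sample '", sample$sample_id, "'")
  qc <- qc_summary(sample$r1)
  mg <- merge_sample(sample, cfg)
  fl <- filter_merged(mg$merged, cfg)
  acc <- fl$accepted
  n <- nrow(acc)
  keep <- logical(n); seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    tp <- trim_primers(acc$sequence[i], acc$quality[i], cfg)
    if (!is.null(tp)) { keep[i] <- TRUE; seqs[i] <- tp$sequence; quals[i] <- tp$quality }
  }
  inserts <- data.frame(id = acc$id[keep], sequence = seqs[keep],
                        quality = quals[keep], stringsAsFactors = FALSE)
  attrition <- data.frame(
    stage = c("input", "quality_trim", "merge", "length_N_filter", "primer_trim"),
    reads_in = c(mg$counts[["pairs_in"]], mg$counts[["pairs_in"]],
                 mg$counts[["pairs_in"]] - mg$counts[["trimmed_empty"]],
                 mg$counts[["merged"]], fl$counts[["accepted"]]),
    reads_out = c(mg$counts[["pairs_in"]],
                  mg$counts[["pairs_in"]] - mg$counts[["trimmed_empty"]],
                  mg$counts[["merged"]], fl$counts[["accepted"]], sum(keep)),
    stringsAsFactors = FALSE)
  attrition$rejected <- attrition$reads_in - attrition$reads_out
  list(inserts = inserts, attrition = attrition, qc = qc,
       reject_reasons = c(trimmed_empty = unname(mg$counts["trimmed_empty"]),
                          merge_failed = unname(mg$counts["merge_failed"]),
                          filtered_N = unname(fl$counts["rejected_N"]),
                          filtered_length = unname(fl$counts["rejected_length"]),
                          primer_not_found = n - sum(keep)))
}
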