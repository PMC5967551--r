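# Exact dereplication with count tracking, then abundance-based denoising:
# low-count uniques are remapped onto sufficiently similar high-count
# uniques, and unmapped low-count uniques are discarded.

#' Configuration for abundance-based denoising
#'
#' Uniques with fewer than `min_count` reads are treated as putative
#' sequencing errors and remapped onto uniques with at least `min_count`
#' reads when their pairwise identity reaches `similarity`.
#'
#' @param min_count abundance threshold separating high from low uniques
#'   (default 10; a count of exactly 10 is "high").
#' @param similarity identity fraction required for remapping (default 0.99).
#' @return a `denoise_config` list.
#' @export
denoise_config <- function(min_count = 10L, similarity = 0.99) {
  stopifnot(min_count >= 1, similarity > 0, similarity <= 1)
  structure(list(min_count = as.integer(min_count), similarity = similarity),
            class = "denoise_config")
}

sort_uniques <- function(df) {
  ord <- order(-df$count, df$sequence, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Dereplicate sequences exactly
#'
#' Collapses identical sequence strings (case-insensitive) into unique
#' sequences carrying read counts. Output is sorted by count descending,
#' ties broken by sequence lexicographic order, and labelled `U0001`,
#' `U0002`, ... in that order.
#'
#' @param seqs character vector of primer-trimmed insert sequences, or a
#'   data frame with a `sequence` column.
#' @return a `unique_set` data frame: `seq_id`, `sequence`, `count`,
#'   `absorbed_ids` (list column, filled by [denoise()]).
#' @export
dereplicate <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  seqs <- toupper(seqs)
  if (length(seqs) == 0L) {
    df <- data.frame(seq_id = character(0), sequence = character(0),
                     count = integer(0), stringsAsFactors = FALSE)
    df$absorbed_ids <- list()
    class(df) <- c("unique_set", "data.frame")
    return(df)
  }
  tab <- table(seqs)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- sort_uniques(df)
  df$seq_id <- sprintf("U%04d", seq_len(nrow(df)))
  df$absorbed_ids <- rep(list(character(0)), nrow(df))
  df <- df[, c("seq_id", "sequence", "count", "absorbed_ids")]
  class(df) <- c("unique_set", "data.frame")
  df
}

#' Pairwise identity between two sequences
#'
#' Global alignment with free terminal gaps (the amplicons cover the same
#' locus, so penalising terminal overhangs as internal gaps would distort
#' identity); scoring match +1, mismatch -1, gap -2. Identity is
#' matches / alignment columns, computed from the traceback over the aligned
#' region.
#'
#' @param a,b DNA strings.
#' @return identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  align_endsfree_cpp(toupper(a), toupper(b))$identity
}

#' Remap low-abundance uniques onto high-abundance uniques
#'
#' Uniques are split at `min_count`. Each low unique is aligned against
#' every high unique; if its best identity reaches `similarity`, its count
#' is added to that high unique (ties on identity go to the higher-count
#' high unique, then to the lexicographically smaller sequence; tie-breaking
#' uses the pre-absorption counts so the result does not depend on
#' processing order). Low uniques with no qualifying match are discarded.
#' Remapping is one pass: absorbed counts never promote other low uniques,
#' and low uniques are never remapped onto other low uniques.
#'
#' @param uniques a `unique_set` from [dereplicate()].
#' @param cfg a [denoise_config()].
#' @return list with `kept` (the updated high uniques, re-sorted) and
#'   `discarded` (low uniques that found no match).
#' @export
denoise <- function(uniques, cfg = denoise_config()) {
  hi <- uniques$count >= cfg$min_count
  high <- uniques[hi, , drop = FALSE]
  low <- uniques[!hi, , drop = FALSE]
  if (nrow(high) == 0L) {
    if (nrow(low) > 0L)
      warning("no unique sequence reaches the abundance threshold (",
              cfg$min_count, "); all ", nrow(low), " uniques discarded")
    rownames(low) <- NULL
    return(list(kept = high, discarded = low))
  }
  # deterministic target preference: count desc, then sequence lexicographic
  high <- sort_uniques(high)
  disc <- logical(nrow(low))
  add <- integer(nrow(high))
  absorbed <- rep(list(character(0)), nrow(high))
  for (k in seq_len(nrow(low))) {
    ids <- vapply(high$sequence, seq_identity, numeric(1), a = low$sequence[k],
                  USE.NAMES = FALSE)
    best <- which.max(ids)   # first maximum = preferred tie-break order
    if (ids[best] >= cfg$similarity) {
      add[best] <- add[best] + low$count[k]
      absorbed[[best]] <- c(absorbed[[best]], low$seq_id[k])
    } else disc[k] <- TRUE
  }
  high$count <- high$count + add
  high$absorbed_ids <- Map(c, high$absorbed_ids, absorbed)
  kept <- sort_uniques(high)
  discarded <- low[disc, , drop = FALSE]
  rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Write uniques to FASTA with size annotations
#'
#' Headers use the widespread dereplication dialect `id;size=N`.
#'
#' @param uniques a `unique_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_derep_fasta <- function(uniques, path) {
  nm <- sprintf("%s;size=%d", uniques$seq_id, uniques$count)
  write_fasta(setNames(uniques$sequence, nm), path, width = 0L)
}

#' Read a size-annotated FASTA back into a unique set
#'
#' @param path path to a `;size=N` FASTA.
#' @return a `unique_set` data frame.
#' @export
read_derep_fasta <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hpos <- grep("^>", lines)
  ends <- c(hpos[-1L] - 1L, length(lines))
  hdr <- sub("^>", "", lines[hpos])
  m <- regmatches(hdr, regexec("^([^;]+);size=(\\d+)$", hdr))
  if (any(lengths(m) != 3L)) stop("header without ';size=N' annotation")
  seqs <- vapply(seq_along(hpos), function(k)
    paste(lines[(hpos[k] + 1L):ends[k]], collapse = ""), character(1))
  df <- data.frame(seq_id = vapply(m, `[`, character(1), 2L),
                   sequence = toupper(seqs),
                   count = as.integer(vapply(m, `[`, character(1), 3L)),
                   stringsAsFactors = FALSE)
  df$absorbed_ids <- rep(list(character(0)), nrow(df))
  class(df) <- c("unique_set", "data.frame")
  df
}
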