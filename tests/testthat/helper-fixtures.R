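# Shared fixtures and independent oracles, built in code at test time.

BASES <- c("A", "C", "G", "T")

rnd_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# plant exactly k substitutions at distinct positions, optionally keeping a
# margin away from both ends (so optimal local alignments stay full-length)
mutate_subs <- function(seq, k, margin = 0L) {
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  cand <- seq.int(1L + margin, length(ch) - margin)
  pos <- sample(cand, k)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

reads_df <- function(seqs, quals, ids = NULL) {
  ids <- ids %||% sprintf("r%03d", seq_along(seqs))
  df <- data.frame(id = ids, sequence = seqs, quality = quals,
                   stringsAsFactors = FALSE)
  class(df) <- c("fastq_reads", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_q <- function(n, q = 35L) phred_encode(rep(q, n))

# build a unique_set data frame directly
uniques_df <- function(seqs, counts) {
  df <- data.frame(seq_id = sprintf("U%04d", seq_along(seqs)),
                   sequence = toupper(seqs), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$absorbed_ids <- rep(list(character(0)), nrow(df))
  class(df) <- c("unique_set", "data.frame")
  df
}

# Independent brute-force denoising oracle: all-pairs alignment, the literal
# partition/absorb/discard rules, no shortcuts. Written separately from the
# production code path.
oracle_denoise <- function(uniques, cfg) {
  high <- uniques[uniques$count >= cfg$min_count, , drop = FALSE]
  low <- uniques[uniques$count < cfg$min_count, , drop = FALSE]
  if (nrow(high) == 0L)
    return(list(kept = high, discarded_ids = low$seq_id))
  extra <- setNames(rep(0L, nrow(high)), high$seq_id)
  discarded_ids <- character(0)
  for (k in seq_len(nrow(low))) {
    id_best <- NA_character_; best <- -1
    for (h in seq_len(nrow(high))) {
      idd <- seq_identity(low$sequence[k], high$sequence[h])
      better <- idd > best + 1e-15
      tie <- abs(idd - best) <= 1e-15
      if (better ||
          (tie && high$count[h] > high$count[high$seq_id == id_best]) ||
          (tie && high$count[h] == high$count[high$seq_id == id_best] &&
             high$sequence[h] < high$sequence[high$seq_id == id_best])) {
        best <- max(idd, best); id_best <- high$seq_id[h]
      }
    }
    if (best >= cfg$similarity) extra[id_best] <- extra[id_best] + low$count[k]
    else discarded_ids <- c(discarded_ids, low$seq_id[k])
  }
  high$count <- high$count + unname(extra[high$seq_id])
  ord <- order(-high$count, high$sequence, method = "radix")
  list(kept = high[ord, c("seq_id", "sequence", "count")],
       discarded_ids = discarded_ids)
}

# random unique sample around a handful of templates (mimics post-derep data)
random_unique_sample <- function(n_templates = 3L, max_uniques = 50L,
                                 seq_len = 120L) {
  templates <- replicate(n_templates, rnd_dna(seq_len))
  n <- sample.int(max_uniques, 1L)
  seqs <- character(0)
  while (length(seqs) < n) {
    s <- mutate_subs(sample(templates, 1L), sample(0:4, 1L))
    if (!s %in% seqs) seqs <- c(seqs, s)
  }
  counts <- c(sample.int(9L, ceiling(n * 0.7), replace = TRUE),
              sample(10:200, n - ceiling(n * 0.7), replace = TRUE))
  counts <- counts[sample.int(length(counts))]
  uniques_df(seqs, counts)[order(-counts, seqs, method = "radix"), ]
}

# simulated pair for a given template and overlap length (error-free)
pair_from_template <- function(template, read_len = 150L) {
  L <- nchar(template)
  r1 <- substr(template, 1L, read_len)
  r2 <- revcomp(substr(template, L - read_len + 1L, L))
  list(r1 = r1, r2 = r2, overlap = 2L * read_len - L)
}
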