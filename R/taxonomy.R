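# Taxonomic assignment: local-alignment search of each surviving unique
# against the reference set, identity/e-value cutoffs, top-hit species call,
# and a log-ratio confidence score whenever a different species appears among
# ranks 2-5.

#' Configuration for taxonomic assignment
#'
#' Defaults follow the pipeline's published cutoffs: hits must reach 97%
#' identity and an e-value of at most 1e-5; competing species are looked for
#' among ranks 2 to `max_alt_rank` (5). Alignment scoring mirrors blastn
#' defaults (match +2, mismatch -3, gap open 5, gap extend 2; a gap of
#' length k costs open + k*extend) so aligned lengths and identities are
#' comparable to BLAST tabular output. `lambda` and `K` are the
#' Karlin-Altschul constants used for e-values and bit scores under this
#' scoring scheme.
#'
#' @param min_identity_pct minimum percent identity for a hit (default 97).
#' @param max_evalue maximum e-value for a hit (default 1e-5).
#' @param max_alt_rank deepest rank inspected for competing species.
#' @param match,mismatch,gap_open,gap_ext alignment scoring constants.
#' @param lambda,K Karlin-Altschul constants.
#' @return an `assign_config` list.
#' @export
assign_config <- function(min_identity_pct = 97, max_evalue = 1e-5,
                          max_alt_rank = 5L, match = 2, mismatch = -3,
                          gap_open = 5, gap_ext = 2,
                          lambda = 0.625, K = 0.41) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100, max_evalue > 0,
            max_alt_rank >= 1)
  structure(list(min_identity_pct = min_identity_pct, max_evalue = max_evalue,
                 max_alt_rank = as.integer(max_alt_rank), match = match,
                 mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext,
                 lambda = lambda, K = K),
            class = "assign_config")
}

#' Karlin-Altschul e-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` for query length `m` and database
#' length `n` (total residues in the reference set).
#'
#' @param raw_score raw alignment score.
#' @param query_len,db_len query length and total database residues.
#' @param lambda,K Karlin-Altschul constants for the scoring scheme.
#' @return the e-value.
#' @export
evalue_karlin <- function(raw_score, query_len, db_len,
                          lambda = 0.625, K = 0.41) {
  if (any(query_len <= 0) || any(db_len <= 0))
    stop("evalue_karlin: lengths must be positive")
  K * query_len * db_len * exp(-lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalue_karlin
#' @return the bit score.
#' @export
bit_score <- function(raw_score, lambda = 0.625, K = 0.41) {
  (lambda * raw_score - log(K)) / log(2)
}

#' Search one query against a reference set
#'
#' One best local alignment (Smith-Waterman, affine gaps) per reference,
#' searched in both orientations with the better bit score kept. Hits
#' failing the identity or e-value cutoff are excluded; survivors are ranked
#' by bit score descending, ties broken by lower e-value, higher identity,
#' then accession lexicographic order. `aligned_length` counts all alignment
#' columns including gaps; `mismatches` excludes gap columns (BLAST tabular
#' convention); `identity_pct` is `100 * matches / aligned_length`.
#'
#' @param query a DNA string (or one-row `unique_set`).
#' @param refs a `reference_set` data frame.
#' @param cfg an [assign_config()].
#' @param query_id label used in the hit table.
#' @return a `hit_table` data frame, one row per surviving hit, ranked.
#' @export
search_hits <- function(query, refs, cfg = assign_config(), query_id = "query") {
  if (is.data.frame(query)) {
    query_id <- query$seq_id[1L]
    query <- query$sequence[1L]
  }
  if (nrow(refs) == 0L) stop("search_hits: empty reference set")
  query <- toupper(query)
  qrc <- revcomp(query)
  m <- nchar(query)
  db_len <- sum(nchar(refs$sequence))
  rows <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    af <- align_local_cpp(query, refs$sequence[i], cfg$match, cfg$mismatch,
                          cfg$gap_open, cfg$gap_ext)
    ar <- align_local_cpp(qrc, refs$sequence[i], cfg$match, cfg$mismatch,
                          cfg$gap_open, cfg$gap_ext)
    a <- if (ar$score > af$score) ar else af
    strand <- if (ar$score > af$score) "-" else "+"
    if (a$aligned_length == 0L) next
    idpct <- 100 * a$matches / a$aligned_length
    ev <- evalue_karlin(a$score, m, db_len, cfg$lambda, cfg$K)
    if (idpct < cfg$min_identity_pct || ev > cfg$max_evalue) next
    rows[[i]] <- data.frame(
      query_id = query_id, accession = refs$accession[i],
      species_name = refs$species_name[i],
      identity_pct = idpct, aligned_length = a$aligned_length,
      mismatches = a$mismatches, gap_opens = a$gap_opens,
      qstart = a$qstart, qend = a$qend, sstart = a$sstart, send = a$send,
      e_value = ev, bit_score = bit_score(a$score, cfg$lambda, cfg$K),
      raw_score = a$score, strand = strand, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), accession = character(0),
               species_name = character(0), identity_pct = numeric(0),
               aligned_length = integer(0), mismatches = integer(0),
               gap_opens = integer(0), qstart = integer(0), qend = integer(0),
               sstart = integer(0), send = integer(0), e_value = numeric(0),
               bit_score = numeric(0), raw_score = numeric(0),
               strand = character(0), stringsAsFactors = FALSE)
  rank_hits(hits)
}

# rank a hit table: bit score desc, e-value asc, identity desc, accession asc
rank_hits <- function(hits) {
  if (nrow(hits)) {
    ord <- order(-hits$bit_score, hits$e_value, -hits$identity_pct,
                 hits$accession, method = "radix")
    hits <- hits[ord, , drop = FALSE]
    hits$rank <- seq_len(nrow(hits))
    rownames(hits) <- NULL
  } else hits$rank <- integer(0)
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Confidence score of a species assignment
#'
#' The log ratio of mismatch-normalised alignment quality between the top
#' hit and a competing hit:
#' `ln[ (L1 / (m1 + 1)) / (L2 / (m2 + 1)) ]`,
#' with `L` the aligned length and `m` the mismatch count of each hit. The
#' score is 0 for identical operands, positive when the top hit is better
#' per mismatch, and antisymmetric in its arguments.
#'
#' @param top,alt hit rows (one-row data frames or lists) carrying
#'   `aligned_length` and `mismatches`.
#' @return the confidence score (natural log).
#' @export
confidence_score <- function(top, alt) {
  L1 <- top$aligned_length; m1 <- top$mismatches
  L2 <- alt$aligned_length; m2 <- alt$mismatches
  if (L1 == 0 || L2 == 0) stop("confidence_score: aligned length of zero")
  log((L1 / (m1 + 1)) / (L2 / (m2 + 1)))
}

#' Call a species from a ranked hit table
#'
#' With no surviving hits the query is `"unassigned"`. Otherwise the rank-1
#' species is called. For each distinct other species among ranks 2 to
#' `max_alt_rank`, a confidence score is computed against that species'
#' best-ranked hit; the assignment's `confidence` is the minimum over those
#' alternatives (the most ambiguous competitor). When ranks 2-5 contain only
#' the top species (or do not exist), `confidence` is `NA` -- the call is
#' then unambiguous at the rank depth inspected.
#'
#' @param hits a ranked `hit_table` for one query.
#' @param cfg an [assign_config()].
#' @param query_id,count query label and read count carried through.
#' @return a one-row `species_assignment` data frame with a list column
#'   `alternatives` of per-competitor `(species, confidence)` entries.
#' @export
assign_species <- function(hits, cfg = assign_config(),
                           query_id = NULL, count = NA_integer_) {
  query_id <- query_id %||% (if (nrow(hits)) hits$query_id[1L] else "query")
  if (nrow(hits) == 0L) {
    out <- data.frame(query_id = query_id, count = count,
                      species = "unassigned", identity_pct = NA_real_,
                      e_value = NA_real_, confidence = NA_real_,
                      stringsAsFactors = FALSE)
    out$alternatives <- list(data.frame(species = character(0),
                                        confidence = numeric(0)))
    class(out) <- c("species_assignment", "data.frame")
    return(out)
  }
  top <- hits[1L, ]
  window <- hits[hits$rank >= 2L & hits$rank <= cfg$max_alt_rank, , drop = FALSE]
  alt_sp <- unique(window$species_name[window$species_name != top$species_name])
  alts <- data.frame(species = character(0), confidence = numeric(0),
                     stringsAsFactors = FALSE)
  for (sp in alt_sp) {
    best_alt <- window[window$species_name == sp, ][1L, ]  # best-ranked of sp
    alts <- rbind(alts, data.frame(species = sp,
                                   confidence = confidence_score(top, best_alt),
                                   stringsAsFactors = FALSE))
  }
  conf <- if (nrow(alts)) min(alts$confidence) else NA_real_
  out <- data.frame(query_id = query_id, count = count,
                    species = top$species_name,
                    identity_pct = top$identity_pct, e_value = top$e_value,
                    confidence = conf, stringsAsFactors = FALSE)
  out$alternatives <- list(alts)
  class(out) <- c("species_assignment", "data.frame")
  out
}

#' Assign species to every unique sequence
#'
#' @param uniques a `unique_set` (typically the `kept` set from [denoise()]).
#' @param refs a `reference_set`.
#' @param cfg an [assign_config()].
#' @return list with `assignments` (one row per unique) and `hits` (all
#'   ranked hit tables row-bound).
#' @export
assign_all <- function(uniques, refs, cfg = assign_config()) {
  res <- vector("list", nrow(uniques))
  allhits <- vector("list", nrow(uniques))
  for (i in seq_len(nrow(uniques))) {
    h <- search_hits(uniques$sequence[i], refs, cfg, query_id = uniques$seq_id[i])
    allhits[[i]] <- h
    res[[i]] <- assign_species(h, cfg, query_id = uniques$seq_id[i],
                               count = uniques$count[i])
  }
  assignments <- if (length(res)) do.call(rbind, res) else
    assign_species(rank_hits(data.frame()), cfg)[0, ]
  hits <- if (length(allhits)) do.call(rbind, allhits) else NULL
  list(assignments = assignments, hits = hits)
}

outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Export hits as BLAST outfmt-6 TSV
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. No header row, per the BLAST convention.
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_outfmt6 <- function(hits, path) {
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$accession,
                   pident = sprintf("%.3f", hits$identity_pct),
                   length = hits$aligned_length, mismatch = hits$mismatches,
                   gapopen = hits$gap_opens, qstart = hits$qstart,
                   qend = hits$qend, sstart = hits$sstart, send = hits$send,
                   evalue = format(hits$e_value, digits = 3, scientific = TRUE),
                   bitscore = sprintf("%.1f", hits$bit_score),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import externally produced BLAST outfmt-6 hits
#'
#' Lets the assignment and confidence logic run on real BLAST output.
#' Species names are resolved from the subject id via the reference set;
#' cutoffs are applied and hits re-ranked per query.
#'
#' @param path a 12-column outfmt-6 TSV (no header).
#' @param refs a `reference_set` mapping accession to species.
#' @param cfg an [assign_config()].
#' @return a named list of ranked `hit_table`s, one per query.
#' @export
read_outfmt6 <- function(path, refs, cfg = assign_config()) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12L) stop("expected 12 outfmt-6 columns, got ", ncol(df))
  names(df) <- outfmt6_cols
  sp <- setNames(refs$species_name, refs$accession)
  unknown <- setdiff(unique(df$sseqid), names(sp))
  if (length(unknown))
    stop("subject id not in reference set: '", unknown[1L], "'")
  hits <- data.frame(query_id = df$qseqid, accession = df$sseqid,
                     species_name = unname(sp[df$sseqid]),
                     identity_pct = df$pident, aligned_length = df$length,
                     mismatches = df$mismatch, gap_opens = df$gapopen,
                     qstart = df$qstart, qend = df$qend,
                     sstart = df$sstart, send = df$send,
                     e_value = df$evalue, bit_score = df$bitscore,
                     raw_score = NA_real_, strand = NA_character_,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$identity_pct >= cfg$min_identity_pct &
                 hits$e_value <= cfg$max_evalue, , drop = FALSE]
  lapply(split(hits, hits$query_id), rank_hits)
}
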