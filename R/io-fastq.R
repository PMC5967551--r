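# FASTQ / FASTA readers and writers.
#
# Reads are held as plain data frames with columns id, sequence, quality
# (quality kept as the raw Phred+33 string and decoded on demand), which keeps
# I/O fast and the containers inspectable. Quality encoding is fixed to Sanger
# Phred+33 -- there is no auto-detection. Gzip input is accepted by extension.

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

new_fastq_reads <- function(id, sequence, quality) {
  df <- data.frame(id = id, sequence = sequence, quality = quality,
                   stringsAsFactors = FALSE)
  class(df) <- c("fastq_reads", "data.frame")
  df
}

#' Read a FASTQ file
#'
#' Strict 4-line FASTQ, Sanger Phred+33. Malformed records raise an error
#' naming the offending line. `.gz` paths are decompressed transparently.
#'
#' @param path path to a FASTQ (optionally gzipped) file.
#' @return a `fastq_reads` data frame with columns `id`, `sequence`
#'   (uppercase), and `quality` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ (", path, "): ", n,
         " lines is not a multiple of 4; truncated record near line ", n)
  if (n == 0L) return(new_fastq_reads(character(0), character(0), character(0)))
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ (", path, "): header does not start with '@' at line ",
         idx[bad[1L]])
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop("malformed FASTQ (", path, "): separator does not start with '+' at line ",
         idx[bad[1L]] + 2L)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ (", path, "): sequence/quality length mismatch at line ",
         idx[bad[1L]] + 1L)
  new_fastq_reads(sub("^@", "", hdr), toupper(seqs), qual)
}

#' Write reads to a FASTQ file
#'
#' @param reads a `fastq_reads` data frame (columns `id`, `sequence`, `quality`).
#' @param path output path; `.gz` compresses.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

# strip mate suffixes ("/1", "/2", or a space-delimited mate field)
core_read_id <- function(id) sub("/[12]$", "", sub("\\s.*$", "", id))

#' Read a pair of FASTQ files as one sample
#'
#' Both files must contain the same number of records, in the same order,
#' with matching identifiers up to a `/1`/`/2` (or space-delimited mate
#' field) suffix.
#'
#' @param path_r1,path_r2 paths to the forward and reverse FASTQ files.
#' @param sample_id sample label; defaults to the R1 file name stem.
#' @return an `edna_sample`: list with `sample_id`, `r1`, `r2`.
#' @export
read_fastq_pair <- function(path_r1, path_r2, sample_id = NULL) {
  r1 <- read_fastq(path_r1)
  r2 <- read_fastq(path_r2)
  if (nrow(r1) != nrow(r2))
    stop("pairing error: ", path_r1, " has ", nrow(r1), " records but ",
         path_r2, " has ", nrow(r2))
  c1 <- core_read_id(r1$id)
  c2 <- core_read_id(r2$id)
  bad <- which(c1 != c2)
  if (length(bad))
    stop("pairing error: read ids disagree at record ", bad[1L], " ('",
         r1$id[bad[1L]], "' vs '", r2$id[bad[1L]], "')")
  sample_id <- sample_id %||%
    sub("(_R?1)?\\.(fastq|fq)(\\.gz)?$", "", basename(path_r1))
  structure(list(sample_id = sample_id, r1 = r1, r2 = r2),
            class = "edna_sample")
}

#' @export
print.edna_sample <- function(x, ...) {
  cat("<edna_sample> ", x$sample_id, ": ", nrow(x$r1), " read pairs\n", sep = "")
  invisible(x)
}

#' Read a reference FASTA with species labels in headers
#'
#' Two header dialects are supported and must be named explicitly:
#' `"pipe"` (`>accession|Genus species`) and `"whitespace"` (`>accession
#' Genus species ...`, first token the accession, the remainder the species
#' label, trailing tokens kept). Anything else is an error rather than a
#' guess. Sequences are uppercased and RNA `U` is converted to `T`.
#'
#' @param path path to a FASTA (optionally gzipped) file.
#' @param header_format `"pipe"` or `"whitespace"`.
#' @return a `reference_set` data frame with columns `accession`,
#'   `species_name`, `sequence`.
#' @export
read_reference_fasta <- function(path, header_format = c("pipe", "whitespace")) {
  header_format <- match.arg(header_format)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hpos <- grep("^>", lines)
  if (!length(hpos)) stop("no FASTA records in ", path)
  if (hpos[1L] != 1L) stop("malformed FASTA (", path, "): data before first header")
  ends <- c(hpos[-1L] - 1L, length(lines))
  headers <- sub("^>", "", lines[hpos])
  seqs <- vapply(seq_along(hpos), function(k) {
    if (ends[k] < hpos[k] + 1L) return("")
    paste(lines[(hpos[k] + 1L):ends[k]], collapse = "")
  }, character(1))
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  if (any(seqs == "")) stop("empty sequence for record '", headers[seqs == ""][1L], "'")
  if (header_format == "pipe") {
    parts <- strsplit(headers, "|", fixed = TRUE)
    if (any(lengths(parts) < 2L))
      stop("header not in 'accession|species' format: '",
           headers[lengths(parts) < 2L][1L], "'")
    accession <- vapply(parts, `[`, character(1), 1L)
    species <- vapply(parts, function(p) paste(p[-1L], collapse = "|"), character(1))
  } else {
    accession <- sub("\\s.*$", "", headers)
    species <- trimws(sub("^\\S+\\s*", "", headers))
  }
  if (any(species == ""))
    stop("empty species field in header '", headers[species == ""][1L], "'")
  dup <- accession[duplicated(accession)]
  if (length(dup)) stop("duplicate accession in reference set: '", dup[1L], "'")
  refs <- data.frame(accession = accession, species_name = species,
                     sequence = seqs, stringsAsFactors = FALSE)
  class(refs) <- c("reference_set", "data.frame")
  refs
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector, or a data frame with `accession`,
#'   `species_name`, `sequence` (headers become `accession|species`).
#' @param path output path.
#' @param width line-wrap width; 0 disables wrapping.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) {
    nm <- paste0(seqs$accession, "|", seqs$species_name)
    seqs <- setNames(seqs$sequence, nm)
  }
  stopifnot(!is.null(names(seqs)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (width > 0L && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}
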