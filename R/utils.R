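#' Reverse-complement DNA strings
#'
#' Vectorised over `x`. Understands A/C/G/T/N (case-insensitive; output is
#' uppercase). IUPAC ambiguity codes other than N are not supported.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")  # "NACGT"
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(comp, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Decode a Sanger Phred+33 quality string to integer scores
#'
#' @param q a single quality string.
#' @return integer vector of Phred scores.
#' @export
phred_decode <- function(q) {
  stopifnot(is.character(q), length(q) == 1L)
  if (nchar(q) == 0L) return(integer(0))
  v <- utf8ToInt(q) - 33L
  if (any(v < 0L | v > 93L))
    stop("quality characters outside the Sanger Phred+33 range (0..93)")
  v
}

#' Encode integer Phred scores as a Sanger Phred+33 string
#'
#' @param scores integer vector of Phred scores in 0..93.
#' @return a single quality string.
#' @export
phred_encode <- function(scores) {
  if (length(scores) == 0L) return("")
  scores <- as.integer(scores)
  if (any(is.na(scores)) || any(scores < 0L | scores > 93L))
    stop("Phred scores must be integers in 0..93")
  intToUtf8(scores + 33L)
}

# decode many quality strings at once -> list of integer vectors
phred_decode_all <- function(q) lapply(q, phred_decode)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
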