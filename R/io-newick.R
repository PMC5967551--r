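# Newick serialisation. Parsing goes through ape::read.tree; writing is a
# small serialiser of our own because species labels contain spaces and must
# be single-quoted, which ape::write.tree does not do.

needs_quote <- function(lab) grepl("[^A-Za-z0-9_.|-]", lab)

quote_label <- function(lab) {
  ifelse(needs_quote(lab),
         paste0("'", gsub("'", "''", lab), "'"),
         lab)
}

fmt_len <- function(x) sprintf("%.15g", x)

#' Serialise a phylogenetic tree to a Newick string
#'
#' Branch lengths are written at full double precision; labels containing
#' spaces or other Newick metacharacters are single-quoted (internal quotes
#' doubled, per the Newick standard).
#'
#' @param tree an [ape] `phylo` object with `edge.length`.
#' @return a single Newick string terminated by `;`.
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- quote_label(tree$tip.label[node])
    } else {
      ki <- kids[[as.character(node)]]
      s <- paste0("(", paste(vapply(ki, function(e)
        rec(tree$edge[e, 2L], e), character(1)), collapse = ","), ")")
    }
    if (!is.na(edge_idx) && !is.null(tree$edge.length))
      s <- paste0(s, ":", fmt_len(tree$edge.length[edge_idx]))
    s
  }
  paste0(rec(root, NA_integer_), ";")
}

#' Write a tree to a Newick file
#'
#' @param tree an [ape] `phylo` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' Read a Newick file
#'
#' Single-quoted labels (the standard's escape for labels containing spaces
#' or metacharacters) are supported by substituting placeholders before the
#' `ape` parser runs and restoring the unquoted text afterwards.
#'
#' @param path path to a Newick file.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick_string(txt)
}

parse_newick_string <- function(txt) {
  labs <- character(0)
  repeat {
    m <- regexpr("'(?:[^']|'')*'", txt, perl = TRUE)
    if (m == -1L) break
    labs <- c(labs, regmatches(txt, m))
    regmatches(txt, m) <- sprintf("zQUOTEDLABEL%dz", length(labs))
  }
  tree <- ape::read.tree(text = txt)
  if (length(labs)) {
    unq <- function(s) gsub("''", "'", substr(s, 2L, nchar(s) - 1L))
    ph <- sprintf("zQUOTEDLABEL%dz", seq_along(labs))
    ix <- match(tree$tip.label, ph)
    tree$tip.label[!is.na(ix)] <- unq(labs[ix[!is.na(ix)]])
    if (!is.null(tree$node.label)) {
      ixn <- match(tree$node.label, ph)
      tree$node.label[!is.na(ixn)] <- unq(labs[ixn[!is.na(ixn)]])
    }
  }
  tree
}
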