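# Per-sample phylogenetics: center-star multiple alignment, p-distance, and
# canonical (Saitou-Nei) neighbor-joining. Amplicon-scale inputs are short
# and near-identical, so a center-star alignment with "once a gap, always a
# gap" column merging is adequate and exactly testable.

#' Center-star multiple sequence alignment
#'
#' The center is the sequence maximising the summed pairwise global-alignment
#' score (match +1, mismatch -1, gap -2) against all others -- equivalently,
#' minimising the summed alignment distance. Every other sequence is aligned
#' pairwise to the ungapped center and merged into the growing alignment
#' with "once a gap, always a gap" column insertion.
#'
#' @param seqs named character vector of DNA sequences (>= 2).
#' @return named character vector of equal-length aligned rows (class `msa`).
#' @export
align_msa <- function(seqs) {
  if (length(seqs) < 2L) stop("align_msa: need at least 2 sequences")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  n <- length(seqs)
  # choose the center
  scores <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- align_global_cpp(seqs[[i]], seqs[[j]])$score
    scores[i] <- scores[i] + s
    scores[j] <- scores[j] + s
  }
  center <- which.max(scores)   # first maximum on ties
  others <- setdiff(seq_len(n), center)
  # master alignment as character vectors of columns
  master_center <- strsplit(seqs[[center]], "")[[1]]
  rows <- list()                # aligned others, in master coordinates
  # map from master columns to center residue index (0 for gap columns)
  for (k in others) {
    al <- align_global_cpp(seqs[[center]], seqs[[k]])
    c_aln <- strsplit(al$a, "")[[1]]
    s_aln <- strsplit(al$b, "")[[1]]
    # walk master and the new pairwise alignment simultaneously
    new_master <- character(0)
    new_row <- character(0)
    grow <- function(mcol, scol) {
      new_master <<- c(new_master, mcol)
      new_row <<- c(new_row, scol)
    }
    i <- 1L; j <- 1L
    nm <- length(master_center); np <- length(c_aln)
    patch <- vector("list", 0)  # positions where master gains new gap columns
    new_cols <- integer(0)
    while (i <= nm || j <= np) {
      m_res <- if (i <= nm) master_center[i] else NULL
      p_res <- if (j <= np) c_aln[j] else NULL
      if (!is.null(m_res) && m_res == "-") {
        # existing master gap column: new row gets a gap
        grow(m_res, "-"); i <- i + 1L
      } else if (!is.null(p_res) && p_res == "-") {
        # pairwise alignment inserts a gap into the center: new master column
        grow("-", s_aln[j]); new_cols <- c(new_cols, length(new_master))
        j <- j + 1L
      } else if (!is.null(m_res) && !is.null(p_res)) {
        grow(m_res, s_aln[j]); i <- i + 1L; j <- j + 1L
      } else stop("internal error: center-star merge walk out of sync")
    }
    # back-insert the new gap columns into previously merged rows
    if (length(new_cols) && length(rows)) {
      total <- length(new_master)
      rows <- lapply(rows, function(r) {
        out <- rep("-", total)
        out[setdiff(seq_len(total), new_cols)] <- r
        out
      })
    }
    rows[[length(rows) + 1L]] <- new_row
    master_center <- new_master
  }
  aligned <- vector("character", n)
  aligned[center] <- paste(master_center, collapse = "")
  for (t in seq_along(others))
    aligned[others[t]] <- paste(rows[[t]], collapse = "")
  names(aligned) <- names(seqs)
  stopifnot(length(unique(nchar(aligned))) == 1L)
  class(aligned) <- "msa"
  aligned
}

#' Pairwise p-distance matrix of an alignment
#'
#' Proportion of mismatching sites among columns where neither row has a gap
#' or N (pairwise deletion), computed through `ape::dist.dna(model = "raw")`.
#' A pair with no comparable columns is an error.
#'
#' @param msa named character vector of equal-length aligned rows.
#' @return a symmetric numeric matrix with zero diagonal, labelled rows and
#'   columns.
#' @export
p_distance <- function(msa) {
  msa <- unclass(msa)
  stopifnot(length(msa) >= 2L, length(unique(nchar(msa))) == 1L)
  mat <- do.call(rbind, strsplit(tolower(msa), ""))
  rownames(mat) <- names(msa)
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                     pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  if (any(!is.finite(dm)))
    stop("p_distance: a pair of rows has no comparable (gap/N-free) columns")
  dm
}

# --- canonical neighbor-joining -------------------------------------------

nj_subtree_newick <- function(node) {
  if (is.character(node$label)) return(quote_label(node$label))
  parts <- vapply(seq_along(node$children), function(k)
    paste0(nj_subtree_newick(node$children[[k]]), ":", fmt_len(node$lens[k])),
    character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: at each step the pair minimising
#' the Q criterion is joined, with ties broken by the smallest (i, j) index
#' pair in the current node order (tips first, in input order, then internal
#' nodes in creation order). Branch lengths use the standard formulas; the
#' last three nodes are joined to a single internal node, yielding an
#' unrooted tree. Negative branch-length estimates are clamped to zero and
#' flagged in the `negative_branch_clamped` attribute.
#'
#' @param dm a symmetric distance matrix with labelled rows (>= 3 taxa).
#' @return an [ape] `phylo` object (unrooted, basal trifurcation).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("nj_tree: need at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  stopifnot(isSymmetric(unname(dm)), all(is.finite(dm)))
  labels <- rownames(dm)
  # internal placeholder leaf names; real labels (which may contain spaces)
  # are restored on the finished phylo object
  nodes <- lapply(seq_len(n), function(i) list(label = sprintf("zL%dz", i)))
  d <- unname(dm)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (length(nodes) > 3L) {
    N <- length(nodes)
    r <- rowSums(d)
    # Q(i,j) = (N-2) d_ij - r_i - r_j; first strict minimum over i<j
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in 1:(N - 1L)) for (j in (i + 1L):N) {
      q <- (N - 2) * d[i, j] - r[i] - r[j]
      if (q < bq - 1e-12) { bq <- q; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- d[i, j] - li
    newnode <- list(children = list(nodes[[i]], nodes[[j]]),
                    lens = c(clamp(li), clamp(lj)))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], list(newnode))
  }
  # final three-way join
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  root <- list(children = nodes, lens = c(clamp(la), clamp(lb), clamp(lc)))
  tree <- ape::read.tree(text = paste0(nj_subtree_newick(root), ";"))
  tree$tip.label <- labels[as.integer(sub("^zL(\\d+)z$", "\\1", tree$tip.label))]
  attr(tree, "negative_branch_clamped") <- clamped
  tree
}

#' Build per-sample phylogenetic trees
#'
#' An all-species tree uses the highest-count unique assigned to each species
#' as that species' representative (labelled by species name); within-species
#' trees use all uniques assigned to one species (labelled by unique id).
#' Trees require at least three leaves; groups with fewer are skipped.
#'
#' @param uniques a `unique_set` (the denoised survivors).
#' @param assignments the assignment table from [assign_all()].
#' @return list with `all_species` (a `phylo` or `NULL`) and `within_species`
#'   (named list of `phylo`).
#' @export
sample_trees <- function(uniques, assignments) {
  asg <- assignments[assignments$species != "unassigned", , drop = FALSE]
  out <- list(all_species = NULL, within_species = list())
  if (nrow(asg) == 0L) return(out)
  seqs <- setNames(uniques$sequence, uniques$seq_id)
  counts <- setNames(uniques$count, uniques$seq_id)
  # species representatives: highest-count unique (unique_set order breaks ties)
  by_sp <- split(asg$query_id, asg$species)
  reps <- vapply(by_sp, function(ids) ids[which.max(counts[ids])], character(1))
  if (length(reps) >= 3L) {
    msa <- align_msa(setNames(seqs[reps], names(reps)))
    out$all_species <- nj_tree(p_distance(msa))
  }
  for (sp in names(by_sp)) {
    ids <- by_sp[[sp]]
    if (length(ids) >= 3L) {
      msa <- align_msa(setNames(seqs[ids], ids))
      out$within_species[[sp]] <- nj_tree(p_distance(msa))
    }
  }
  out
}
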