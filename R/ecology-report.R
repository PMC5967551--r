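# Community table assembly, diversity indices, and report rendering.
# Unassigned reads are tracked in the table but excluded from diversity
# indices; Shannon entropy uses natural log.

#' Build a species-by-sample community table
#'
#' Aggregates unique-sequence read counts by assigned species. The
#' `"unassigned"` category is kept as its own row (and excluded from
#' diversity downstream); all-zero species rows are dropped.
#'
#' @param assignments_by_sample named list (one entry per sample) of
#'   assignment tables from [assign_all()].
#' @return an integer matrix, species rows by sample columns (class
#'   `community_table`).
#' @export
build_table <- function(assignments_by_sample) {
  stopifnot(is.list(assignments_by_sample), length(assignments_by_sample) > 0,
            !is.null(names(assignments_by_sample)))
  samples <- names(assignments_by_sample)
  agg <- lapply(assignments_by_sample, function(a) {
    if (nrow(a) == 0L) return(integer(0))
    tapply(a$count, a$species, sum)
  })
  species <- sort(unique(unlist(lapply(agg, names))))
  tab <- matrix(0L, nrow = length(species), ncol = length(samples),
                dimnames = list(species, samples))
  for (s in samples) {
    v <- agg[[s]]
    if (length(v)) tab[names(v), s] <- as.integer(v)
  }
  tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
  if (!any(rownames(tab) != "unassigned"))
    warning("community table contains no assigned species")
  class(tab) <- c("community_table", class(tab))
  tab
}

# drop the unassigned row before computing diversity
assigned_counts <- function(counts) {
  if (!is.null(names(counts))) counts <- counts[names(counts) != "unassigned"]
  counts
}

#' Shannon diversity (alpha diversity)
#'
#' `H = -sum p_i ln p_i` over species with positive counts (natural log,
#' consistent with the assignment confidence score). Computed through
#' `vegan::diversity`.
#'
#' @param counts one sample's species counts (named or not; an
#'   `"unassigned"` entry is excluded).
#' @return the Shannon index.
#' @export
shannon <- function(counts) {
  counts <- assigned_counts(counts)
  if (sum(counts) <= 0) stop("shannon: zero total count")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Bray-Curtis dissimilarity (beta diversity)
#'
#' `BC = 1 - 2 sum min(a_i, b_i) / (sum a_i + sum b_i)`, in `[0, 1]`.
#' Computed through `vegan::vegdist`.
#'
#' @param a,b species count vectors on the same species index.
#' @return the Bray-Curtis dissimilarity.
#' @export
bray_curtis <- function(a, b) {
  a <- assigned_counts(a); b <- assigned_counts(b)
  if (length(a) != length(b)) stop("bray_curtis: unequal species vectors")
  if (sum(a) + sum(b) <= 0) stop("bray_curtis: both samples empty")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' External database URL templates for a species
#'
#' Static search-URL templates (FishBase, Barcode of Life, GBIF) built from
#' the URL-encoded binomial. No network access is involved.
#'
#' @param species a species name.
#' @return named character vector of URLs.
#' @export
species_links <- function(species) {
  q <- URLencode(species, reserved = TRUE)
  c(fishbase = paste0("https://www.fishbase.se/Nomenclature/ScientificNameSearchList.php?crit2=contains&crit1_fieldname=SYNONYMS.SynGenus&crit1_fieldtype=CHAR&crit1_operator=EQUAL&crit1_fieldvalue=", q),
    bold = paste0("https://www.boldsystems.org/index.php/Public_SearchTerms?query=", q),
    gbif = paste0("https://www.gbif.org/species/search?q=", q))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render per-sample reports
#'
#' Writes, per sample, a TSV of species assignments (count, percentage of
#' the sample total, confidence) and a static HTML report with the species
#' table, attrition summary, tree file links, and database links; plus one
#' community-table TSV across samples. Percentages within a sample sum to
#' 100 (up to rounding).
#'
#' @param results a `pipeline_result` from [run_pipeline()], or a list with
#'   elements `table` (community table) and per-sample `samples` entries
#'   carrying `assignments`, `attrition`, `trees`.
#' @param out_dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  tab <- results$table
  tpath <- file.path(out_dir, "community_table.tsv")
  tdf <- data.frame(species = rownames(tab), unclass(tab),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tdf, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, tpath)
  for (sid in names(results$samples)) {
    sm <- results$samples[[sid]]
    a <- sm$assignments
    total <- sum(a$count)
    pct <- if (total > 0) 100 * a$count / total else rep(0, nrow(a))
    adf <- data.frame(query_id = a$query_id, count = a$count,
                      pct = round(pct, 4), species = a$species,
                      identity_pct = round(a$identity_pct, 3),
                      e_value = a$e_value, confidence = a$confidence,
                      stringsAsFactors = FALSE)
    apath <- file.path(out_dir, paste0(sid, ".assignments.tsv"))
    write.table(adf, apath, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, apath)
    # per-species aggregation for the HTML table
    agg <- tapply(a$count, a$species, sum)
    sp_pct <- if (total > 0) 100 * agg / total else agg * 0
    conf_by_sp <- tapply(a$confidence, a$species, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    rows <- vapply(names(agg), function(sp) {
      links <- if (sp == "unassigned") "" else
        paste(sprintf("<a href=\"%s\">%s</a>", species_links(sp),
                      names(species_links(sp))), collapse = " ")
      sprintf("<tr><td><i>%s</i></td><td>%d</td><td>%.2f</td><td>%s</td><td>%s</td></tr>",
              html_escape(sp), as.integer(agg[[sp]]), sp_pct[[sp]],
              ifelse(is.na(conf_by_sp[[sp]]), "&mdash;",
                     sprintf("%.3f", conf_by_sp[[sp]])),
              links)
    }, character(1))
    attr_rows <- if (!is.null(sm$attrition)) vapply(seq_len(nrow(sm$attrition)),
      function(i) sprintf("<tr><td>%s</td><td>%d</td><td>%d</td><td>%d</td></tr>",
                          sm$attrition$stage[i], sm$attrition$reads_in[i],
                          sm$attrition$reads_out[i], sm$attrition$rejected[i]),
      character(1)) else character(0)
    tree_links <- character(0)
    if (!is.null(sm$tree_files))
      tree_links <- sprintf("<li><a href=\"%s\">%s</a></li>",
                            basename(sm$tree_files), basename(sm$tree_files))
    body <- if (total > 0) paste(rows, collapse = "\n") else
      "<tr><td colspan=\"5\">zero assignments</td></tr>"
    html <- paste0(
      "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
      "<title>", html_escape(sid), "</title></head><body>\n",
      "<h1>Sample ", html_escape(sid), "</h1>\n",
      "<h2>Species assignments</h2>\n",
      "<table border=\"1\"><tr><th>species</th><th>reads</th>",
      "<th>% of total</th><th>confidence</th><th>links</th></tr>\n",
      body, "\n</table>\n",
      "<h2>Read attrition</h2>\n",
      "<table border=\"1\"><tr><th>stage</th><th>in</th><th>out</th>",
      "<th>rejected</th></tr>\n",
      paste(attr_rows, collapse = "\n"), "\n</table>\n",
      "<h2>Trees</h2>\n<ul>\n", paste(tree_links, collapse = "\n"),
      "\n</ul>\n</body></html>\n")
    hpath <- file.path(out_dir, paste0(sid, ".report.html"))
    writeLines(html, hpath)
    written <- c(written, hpath)
  }
  invisible(written)
}
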