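test_that("Karlin-Altschul e-value and bit score follow the closed form", {
  # S = 0: E = K * m * n
  expect_equal(evalue_karlin(0, 181, 1e5), 0.41 * 181 * 1e5)
  # linear in database length
  expect_equal(evalue_karlin(60, 181, 2e5), 2 * evalue_karlin(60, 181, 1e5))
  # direct re-evaluation of the formula
  expect_equal(evalue_karlin(60, 181, 1e5),
               0.41 * 181 * 1e5 * exp(-0.625 * 60), tolerance = 1e-12)
  expect_equal(bit_score(60), (0.625 * 60 - log(0.41)) / log(2),
               tolerance = 1e-12)
  expect_error(evalue_karlin(10, 0, 100), "positive")
})

test_that("confidence score evaluates the log ratio exactly", {
  h <- function(L, m) list(aligned_length = L, mismatches = m)
  expect_equal(confidence_score(h(100, 0), h(100, 0)), 0)
  expect_equal(confidence_score(h(170, 0), h(170, 5)), log(6))
  expect_equal(confidence_score(h(200, 2), h(180, 2)), log(200 / 180))
  expect_error(confidence_score(h(0, 0), h(100, 1)), "zero")

  # identity and antisymmetry on random operands
  set.seed(301)
  for (k in 1:50) {
    a <- h(sample(50:500, 1), sample(0:20, 1))
    b <- h(sample(50:500, 1), sample(0:20, 1))
    expect_equal(confidence_score(a, a), 0)
    expect_equal(confidence_score(a, b), -confidence_score(b, a))
  }
  # monotonicity: more alternative mismatches -> higher score;
  # more top-hit mismatches -> lower score
  s0 <- confidence_score(h(170, 2), h(170, 4))
  expect_gt(confidence_score(h(170, 2), h(170, 5)), s0)
  expect_lt(confidence_score(h(170, 3), h(170, 4)), s0)
})

test_that("search applies cutoffs and deterministic ranking", {
  set.seed(302)
  seqs <- character(4)
  seqs[1] <- rnd_dna(181)
  for (k in 2:4) {                         # panel diverged well beyond 5%
    repeat {
      s <- mutate_subs(seqs[1], 20)
      if (all(vapply(seqs[1:(k - 1)], function(x)
        ednapipe:::hamming_cpp(x, s), integer(1)) >= 15)) break
    }
    seqs[k] <- s
  }
  refs <- data.frame(accession = paste0("R", 1:4),
                     species_name = paste("Sp", 1:4),
                     sequence = seqs, stringsAsFactors = FALSE)

  hits <- search_hits(seqs[1], refs, assign_config(), "q1")
  expect_equal(hits$accession[1], "R1")
  expect_equal(hits$identity_pct[1], 100)
  expect_equal(hits$mismatches[1], 0L)
  expect_equal(hits$aligned_length[1], 181L)
  expect_lt(hits$e_value[1], 1e-5)

  # a query below 97% identity to everything yields zero hits:
  # ceiling(0.031 * 181) = 6 substitutions -> 175/181 = 96.7%
  q <- mutate_subs(seqs[1], 6, margin = 5)
  expect_equal(nrow(search_hits(q, refs, assign_config(), "q2")), 0L)

  # identical references tie and rank by accession
  refs2 <- rbind(refs, data.frame(accession = "A0", species_name = "Sp 5",
                                  sequence = seqs[1], stringsAsFactors = FALSE))
  h2 <- search_hits(seqs[1], refs2, assign_config(), "q3")
  expect_equal(h2$accession[1:2], c("A0", "R1"))
  expect_equal(h2$rank, seq_len(nrow(h2)))

  # reverse-complement queries are found on the minus strand
  h3 <- search_hits(revcomp(seqs[1]), refs, assign_config(), "q4")
  expect_equal(h3$accession[1], "R1")
  expect_equal(h3$strand[1], "-")
  expect_equal(h3$bit_score[1], hits$bit_score[1])

  expect_error(search_hits("ACGT", refs[0, ], assign_config()), "empty")
})

test_that("assignment inspects ranks 2-5 for competing species", {
  mk <- function(rank, sp, L = 181L, mm = 0L) {
    data.frame(query_id = "q", accession = paste0("a", rank), species_name = sp,
               identity_pct = 100 * (L - mm) / L, aligned_length = L,
               mismatches = mm, gap_opens = 0L, qstart = 1L, qend = L,
               sstart = 1L, send = L, e_value = 1e-30, bit_score = 300 - rank,
               raw_score = 0, strand = "+", rank = rank,
               stringsAsFactors = FALSE)
  }
  cfg <- assign_config()
  # single hit: assigned, no confidence
  a1 <- assign_species(mk(1, "A"), cfg, count = 50L)
  expect_equal(a1$species, "A")
  expect_true(is.na(a1$confidence))

  # ranks 1-3 species A, 4-5 species B: scored against the rank-4 hit
  hits <- do.call(rbind, list(mk(1, "A", mm = 0L), mk(2, "A", mm = 1L),
                              mk(3, "A", mm = 2L), mk(4, "B", mm = 4L),
                              mk(5, "B", mm = 5L)))
  a2 <- assign_species(hits, cfg, count = 50L)
  expect_equal(a2$species, "A")
  expect_equal(a2$confidence, log((181 / 1) / (181 / 5)))
  expect_equal(a2$alternatives[[1]]$species, "B")

  # rank 6 is different but 2-5 are all the top species: no confidence
  hits3 <- do.call(rbind, c(lapply(1:5, function(r) mk(r, "A", mm = r - 1L)),
                            list(mk(6, "B", mm = 6L))))
  a3 <- assign_species(hits3, cfg)
  expect_true(is.na(a3$confidence))
  expect_equal(nrow(a3$alternatives[[1]]), 0L)

  # several competitors: confidence is the minimum (most ambiguous)
  hits4 <- do.call(rbind, list(mk(1, "A", mm = 0L), mk(2, "B", mm = 1L),
                               mk(3, "C", mm = 5L)))
  a4 <- assign_species(hits4, cfg)
  expect_equal(nrow(a4$alternatives[[1]]), 2L)
  expect_equal(a4$confidence, log(2))      # vs B: ln((181/1)/(181/2))

  # no hits: unassigned
  a5 <- assign_species(mk(1, "A")[0, ], cfg, query_id = "qx", count = 3L)
  expect_equal(a5$species, "unassigned")
})

test_that("planted-truth queries recover their source species", {
  set.seed(303)
  scfg <- sim_config(n_species = 8, n_pairs = 10, seed = 41)
  refs <- make_references(scfg)
  acfg <- assign_config()
  for (k in 1:20) {
    src <- sample.int(8, 1)
    q <- mutate_subs(refs$sequence[src], sample(0:4, 1), margin = 5)
    res <- assign_all(uniques_df(q, 50L), refs, acfg)
    expect_equal(res$assignments$species, refs$species_name[src])
  }
})

test_that("local alignment scores match Biostrings exactly", {
  skip_if_not_installed("Biostrings")
  set.seed(304)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (k in 1:25) {
    a <- rnd_dna(sample(40:180, 1))
    b <- if (k %% 2) rnd_dna(sample(40:180, 1)) else
      paste0(rnd_dna(10), mutate_subs(a, 3), rnd_dna(10))
    s1 <- ednapipe:::align_local_cpp(a, b)$score
    s2 <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2))
    expect_equal(s1, s2)
  }
})

test_that("outfmt-6 export/import reproduces the assignment decision", {
  set.seed(305)
  scfg <- sim_config(n_species = 5, n_pairs = 10, seed = 43)
  refs <- make_references(scfg)
  q <- mutate_subs(refs$sequence[2], 2, margin = 5)
  hits <- search_hits(q, refs, assign_config(), "qz")
  d <- withr::local_tempdir()
  f <- file.path(d, "hits.tsv")
  write_outfmt6(hits, f)
  raw <- readLines(f)
  expect_equal(length(raw), nrow(hits))
  expect_equal(length(strsplit(raw[1], "\t")[[1]]), 12L)

  back <- read_outfmt6(f, refs, assign_config())
  expect_named(back, "qz")
  expect_equal(back$qz$accession, hits$accession)
  a_direct <- assign_species(hits, assign_config(), count = 10L)
  a_import <- assign_species(back$qz, assign_config(), count = 10L)
  expect_equal(a_import$species, a_direct$species)
})
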