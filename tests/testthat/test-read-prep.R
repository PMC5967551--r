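test_that("qc_summary averages per position over covering reads", {
  r <- reads_df(c("GGCC"), phred_encode(rep(30L, 4)))
  q <- qc_summary(r)
  expect_equal(q$gc_frac, 1.0)
  expect_equal(q$per_position_mean_q, rep(30, 4))

  r2 <- reads_df(c("AT", "ATGC"),
                 c(phred_encode(c(10L, 20L)), phred_encode(c(30L, 40L, 20L, 20L))))
  q2 <- qc_summary(r2)
  expect_length(q2$per_position_mean_q, 4L)
  expect_equal(q2$per_position_mean_q, c(20, 30, 20, 20))
  expect_equal(q2$mean_len, 3)
  expect_error(qc_summary(reads_df(character(0), character(0))), "empty")
})

test_that("3' trimming cuts after the last base at or above the floor", {
  r <- reads_df("ACGTA", phred_encode(c(30L, 30L, 30L, 9L, 8L)))
  tr <- trim_3prime(r, 10L)
  expect_equal(tr$sequence, "ACG")
  expect_equal(nchar(tr$quality), 3L)
  # untouched when nothing is below the floor
  r2 <- reads_df("ACG", phred_encode(c(30L, 30L, 30L)))
  expect_identical(trim_3prime(r2, 10L), r2)
  # all below the floor -> empty read
  r3 <- reads_df("AC", phred_encode(c(5L, 5L)))
  expect_equal(trim_3prime(r3, 10L)$sequence, "")
  # idempotent, never longer than input
  expect_identical(trim_3prime(tr, 10L), tr)
})

test_that("pair merging finds the true overlap and applies the consensus rule", {
  set.seed(101)
  template <- rnd_dna(229)
  p <- pair_from_template(template)
  m <- merge_pair(p$r1, flat_q(150), p$r2, flat_q(150))
  expect_equal(m$overlap_len, 71L)
  expect_equal(nchar(m$sequence), 229L)        # 150 + 150 - 71
  expect_equal(m$sequence, template)

  # non-overlapping random mates are rejected
  expect_null(merge_pair(rnd_dna(150), flat_q(150),
                         rnd_dna(150), flat_q(150)))

  # single disagreement: the higher-quality base wins with its own quality
  r1 <- p$r1
  q1 <- phred_encode(c(rep(35L, 120), 40L, rep(35L, 29)))
  ch <- strsplit(r1, "")[[1]]
  truth_base <- ch[121]
  ch[121] <- setdiff(BASES, ch[121])[1]        # corrupt r2's copy instead
  r2ch <- strsplit(revcomp(p$r2), "")[[1]]     # r2 in forward orientation
  pos_in_r2 <- 121 - 79                        # r2 covers template 80..229
  r2ch[pos_in_r2] <- ch[121]
  r2_bad <- revcomp(paste(r2ch, collapse = ""))
  q2 <- phred_encode(rep(20L, 150))
  m2 <- merge_pair(r1, q1, r2_bad, q2)
  expect_equal(substr(m2$sequence, 121, 121), truth_base)
  expect_equal(phred_decode(m2$quality)[121], 40L)
})

test_that("merging recovers the template for every overlap length", {
  set.seed(102)
  for (ov in c(10L, 20L, 50L, 71L, 100L, 130L, 150L)) {
    template <- rnd_dna(300L - ov)
    p <- pair_from_template(template)
    m <- merge_pair(p$r1, flat_q(150), p$r2, flat_q(150))
    expect_false(is.null(m))
    expect_equal(m$sequence, template)
    expect_equal(m$overlap_len, ov)
  }
})

test_that("length/N filter accepts exactly the closed window [204, 254]", {
  set.seed(103)
  lens <- 200:260
  seqs <- vapply(lens, rnd_dna, character(1))
  md <- data.frame(id = as.character(lens), sequence = seqs,
                   quality = vapply(lens, flat_q, character(1)),
                   overlap_len = 50L, stringsAsFactors = FALSE)
  fl <- filter_merged(md, prep_config())
  expect_setequal(as.integer(fl$accepted$id), 204:254)
  expect_true(all(fl$rejected$reason == "length"))

  # an N anywhere rejects, even at the ideal length
  withN <- data.frame(id = "n1", sequence = paste0(rnd_dna(100), "N", rnd_dna(128)),
                      quality = flat_q(229), overlap_len = 50L,
                      stringsAsFactors = FALSE)
  fl2 <- filter_merged(withN, prep_config())
  expect_equal(nrow(fl2$accepted), 0L)
  expect_equal(fl2$rejected$reason, "N")
})

test_that("primer trimming honours the three-mismatch maximum", {
  set.seed(104)
  fwd <- rnd_dna(21); rev <- rnd_dna(27)
  cfg <- prep_config(primer_fwd = fwd, primer_rev = rev)
  insert <- rnd_dna(181)
  merged <- paste0(fwd, insert, revcomp(rev))
  expect_equal(nchar(merged), 229L)
  q <- flat_q(229)

  tp <- trim_primers(merged, q, cfg)
  expect_equal(tp$sequence, insert)            # exact excision arithmetic
  expect_equal(tp$orientation, "forward")

  # 3 substitutions in the forward primer: still trimmed
  bad3 <- paste0(mutate_subs(fwd, 3), insert, revcomp(rev))
  expect_equal(trim_primers(bad3, q, cfg)$sequence, insert)
  # 4 substitutions: rejected
  repeat {
    f4 <- mutate_subs(fwd, 4)
    # ensure no alternative placement in the window scores <= 3
    if (is.null(trim_primers(paste0(f4, insert, revcomp(rev)), q, cfg))) break
  }
  expect_null(trim_primers(paste0(f4, insert, revcomp(rev)), q, cfg))

  # reverse orientation of the whole read is recognised
  tpr <- trim_primers(revcomp(merged), q, cfg)
  expect_equal(tpr$orientation, "reverse")
  expect_equal(tpr$sequence, insert)

  # no double trimming: primers are gone from the insert
  expect_null(trim_primers(tp$sequence, substr(q, 1, 181), cfg))
})

test_that("prep_sample telescopes counts across stages", {
  set.seed(105)
  fwd <- rnd_dna(21); rev <- rnd_dna(27)
  cfg <- prep_config(primer_fwd = fwd, primer_rev = rev)
  template <- paste0(fwd, rnd_dna(181), revcomp(rev))
  n <- 40L
  p <- pair_from_template(template)
  r1 <- reads_df(rep(p$r1, n), rep(flat_q(150), n), sprintf("p%d/1", 1:n))
  r2 <- reads_df(rep(p$r2, n), rep(flat_q(150), n), sprintf("p%d/2", 1:n))
  s <- structure(list(sample_id = "t", r1 = r1, r2 = r2), class = "edna_sample")
  pr <- prep_sample(s, cfg)
  expect_equal(nrow(pr$inserts), n)
  att <- pr$attrition
  expect_equal(att$reads_in[-1], att$reads_out[-nrow(att)])
  expect_equal(sum(pr$reject_reasons), att$reads_in[1] - att$reads_out[nrow(att)])
})
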