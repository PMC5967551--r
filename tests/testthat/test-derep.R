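test_that("dereplication collapses exact duplicates and keeps counts", {
  set.seed(201)
  s1 <- rnd_dna(60); s2 <- rnd_dna(60)
  u <- dereplicate(c(rep(s1, 5), rep(s2, 3)))
  expect_equal(u$count, c(5L, 3L))
  expect_equal(u$sequence[1], s1)
  expect_equal(u$seq_id, c("U0001", "U0002"))

  expect_equal(dereplicate("ACGT")$count, 1L)
  # case-insensitive
  expect_equal(dereplicate(c("acgt", "ACGT"))$count, 2L)
  expect_equal(nrow(dereplicate(character(0))), 0L)
  # counts sum to input size; ties ordered lexicographically
  set.seed(202)
  seqs <- sample(replicate(6, rnd_dna(30)), 40, replace = TRUE)
  u2 <- dereplicate(seqs)
  expect_equal(sum(u2$count), 40L)
  ties <- split(u2$sequence, u2$count)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})

test_that("identity arithmetic drives absorb-or-discard at the 99% default", {
  set.seed(203)
  base <- rnd_dna(181)
  u <- uniques_df(c(base, mutate_subs(base, 1), mutate_subs(base, 3)),
                  c(100L, 9L, 9L))
  # planted identities: 180/181 ~ 99.45% and 178/181 ~ 98.34%
  expect_equal(seq_identity(u$sequence[1], u$sequence[2]), 180 / 181)
  expect_equal(seq_identity(u$sequence[1], u$sequence[3]), 178 / 181)
  dn <- denoise(u, denoise_config())
  expect_equal(nrow(dn$kept), 1L)
  expect_equal(dn$kept$count, 109L)                 # 100 + 9 absorbed
  expect_equal(dn$kept$absorbed_ids[[1]], "U0002")
  expect_equal(dn$discarded$seq_id, "U0003")

  # a count of exactly 10 is high and is retained regardless of similarity
  u2 <- uniques_df(c(base, rnd_dna(181)), c(100L, 10L))
  dn2 <- denoise(u2, denoise_config())
  expect_equal(nrow(dn2$kept), 2L)
})

test_that("denoising conserves counts, is idempotent, and obeys the extremes", {
  set.seed(204)
  for (rep in 1:20) {
    u <- random_unique_sample()
    dn <- suppressWarnings(denoise(u, denoise_config()))
    # conservation with leakage accounting
    expect_equal(sum(dn$kept$count) + sum(dn$discarded$count), sum(u$count))
    # idempotent on its own output
    dn2 <- denoise(dn$kept, denoise_config())
    expect_equal(dn2$kept$count, dn$kept$count)
    expect_equal(nrow(dn2$discarded), 0L)
  }
  u <- random_unique_sample()
  has_high <- any(u$count >= 10L)
  # similarity 0: every low unique is absorbed when a high unique exists
  dn0 <- suppressWarnings(denoise(u, denoise_config(similarity = 1e-9)))
  if (has_high) expect_equal(nrow(dn0$discarded), 0L)
  # similarity 1: exact duplicates are impossible post-derep, all lows dropped
  dn1 <- suppressWarnings(denoise(u, denoise_config(similarity = 1)))
  expect_equal(nrow(dn1$discarded), sum(u$count < 10L))

  # empty high set: everything discarded, loudly
  ul <- uniques_df(c("ACGTACGT", "ACGTACGA"), c(3L, 2L))
  expect_warning(dnl <- denoise(ul, denoise_config()), "discarded")
  expect_equal(nrow(dnl$kept), 0L)
  expect_equal(nrow(dnl$discarded), 2L)
})

test_that("denoising matches the brute-force all-pairs oracle", {
  set.seed(205)
  cfg <- denoise_config()
  for (rep in 1:30) {
    u <- random_unique_sample()
    mine <- suppressWarnings(denoise(u, cfg))
    ref <- oracle_denoise(u, cfg)
    expect_equal(mine$kept$seq_id, ref$kept$seq_id)
    expect_equal(mine$kept$count, ref$kept$count)
    expect_setequal(mine$discarded$seq_id, ref$discarded_ids)
  }
})

test_that("size-annotated FASTA round-trips a unique set", {
  set.seed(206)
  u <- dereplicate(sample(replicate(5, rnd_dna(80)), 60, replace = TRUE))
  d <- withr::local_tempdir()
  f <- file.path(d, "u.fasta")
  write_derep_fasta(u, f)
  back <- read_derep_fasta(f)
  expect_equal(back$seq_id, u$seq_id)
  expect_equal(back$sequence, u$sequence)
  expect_equal(back$count, u$count)
})
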