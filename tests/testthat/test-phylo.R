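test_that("center-star alignment handles gaps and identical inputs", {
  a <- align_msa(c(x = "ACGT", y = "ACT"))
  expect_equal(unique(nchar(a)), 4L)
  expect_equal(sum(strsplit(a[["y"]], "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", a[["y"]]), "ACT")

  b <- align_msa(c(p = "ACGTACGT", q = "ACGTACGT", r = "ACGTACGT"))
  expect_equal(unname(unclass(b)), rep("ACGTACGT", 3))

  set.seed(401)
  seqs <- setNames(vapply(1:6, function(i) mutate_subs(rnd_dna(90), 4),
                          character(1)), paste0("s", 1:6))
  m <- align_msa(seqs)
  expect_equal(length(unique(nchar(m))), 1L)
  expect_equal(unclass(gsub("-", "", m)), seqs)  # rows preserve their sequences
  expect_error(align_msa(c(a = "ACGT")), "at least 2")
})

test_that("p-distance skips gap/N columns and errors on empty overlap", {
  m <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_true(all(p_distance(m) == 0))

  set.seed(402)
  s <- rnd_dna(100)
  s2 <- mutate_subs(s, 2)
  d <- p_distance(c(a = s, b = s2))
  expect_equal(d["a", "b"], 0.02)

  gappy <- c(a = "ACGT----", b = "----ACGT")
  expect_error(p_distance(gappy), "comparable")

  # N columns are excluded from the comparison
  dn <- p_distance(c(a = "ACGTACGTAC", b = paste0("NNGTACGTAC")))
  expect_equal(dn["a", "b"], 0)
})

test_that("neighbor joining reproduces closed-form and additive trees", {
  # 3 taxa: d(A,B)=2, d(A,C)=4, d(B,C)=4 -> branches 1, 1, 3
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  # 4 taxa with additive distances from a known tree ((A,B),(C,D)):
  # external branches 1,2,3,4 and internal branch 5
  d4 <- matrix(c(0, 3, 9, 10,
                 3, 0, 10, 11,
                 9, 10, 0, 7,
                 10, 11, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(t4)[LETTERS[1:4], LETTERS[1:4]], d4,
               tolerance = 1e-12)
  # the internal split separates {A,B} from {C,D}
  un <- ape::unroot(ape::read.tree(text = "((A:1,B:2):5,(C:3,D:4));"))
  expect_equal(as.numeric(ape::dist.topo(t4, un)), 0)

  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees and matches ape's NJ topology", {
  set.seed(403)
  for (k in 1:25) {
    ntax <- sample(4:12, 1)
    gen <- ape::rtree(ntax, br = function(n) stats::runif(n, 0.05, 1))
    dm <- ape::cophenetic.phylo(gen)
    tr <- nj_tree(dm)
    # additivity verifier: path distances on the result equal the input
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)] - dm)),
              1e-9)
    expect_equal(as.numeric(ape::dist.topo(tr, ape::unroot(gen))), 0)
    # independent cross-check against ape's NJ
    expect_equal(as.numeric(ape::dist.topo(tr, ape::nj(dm))), 0)
  }
})

test_that("NJ is invariant to label order and clamps negative estimates", {
  set.seed(404)
  gen <- ape::rtree(8, br = function(n) stats::runif(n, 0.05, 1))
  dm <- ape::cophenetic.phylo(gen)
  perm <- sample(rownames(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_equal(sort(t1$edge.length), sort(t2$edge.length), tolerance = 1e-9)

  # non-additive matrix known to produce a negative NJ estimate
  dneg <- matrix(c(0, 1, 10, 10,
                   1, 0, 10, 10,
                   10, 10, 0, 0.1,
                   10, 10, 0.1, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  tn <- nj_tree(dneg)
  expect_true(all(tn$edge.length >= 0))
})

test_that("trees round-trip through Newick on disk", {
  set.seed(405)
  gen <- ape::rtree(7, br = function(n) stats::runif(n, 0.05, 1))
  dm <- ape::cophenetic.phylo(gen)
  tr <- nj_tree(dm)
  d <- withr::local_tempdir()
  f <- file.path(d, "t.nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(as.numeric(ape::dist.topo(back, tr)), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-12)
})

test_that("sample trees use species representatives and within-species uniques", {
  set.seed(406)
  base <- replicate(4, rnd_dna(120))
  seqs <- c(base, mutate_subs(base[1], 1), mutate_subs(base[1], 2))
  u <- uniques_df(seqs, c(100L, 80L, 60L, 40L, 20L, 15L))
  asg <- data.frame(query_id = u$seq_id, count = u$count,
                    species = c("Sp a", "Sp b", "Sp c", "Sp d", "Sp a", "Sp a"),
                    stringsAsFactors = FALSE)
  tr <- sample_trees(u, asg)
  expect_equal(sort(tr$all_species$tip.label),
               sort(c("Sp a", "Sp b", "Sp c", "Sp d")))
  expect_named(tr$within_species, "Sp a")
  expect_equal(sort(tr$within_species[["Sp a"]]$tip.label),
               sort(u$seq_id[c(1, 5, 6)]))
})
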