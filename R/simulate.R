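# Synthetic-data module: builds 12S-like reference panels (a hypervariable
# insert flanked by conserved primer-binding regions) and simulates
# paired-end amplicon sequencing of a community of known composition, so the
# whole pipeline can be validated against a planted ground truth.

# fixed synthetic conserved flanks, 21 bp forward / 27 bp reverse (the real
# assay's primers are of these lengths; the sequences here are arbitrary)
default_primer_fwd <- "ACGGTCTAGCATGGTACCGTA"
default_primer_rev <- "TGCACGTTAGCCTAGGATCCGTTACGA"

#' Configuration for community simulation
#'
#' Defaults emulate a 150-bp paired-end run over amplicons whose
#' hypervariable insert (171 bp by default) sits between conserved
#' primer-binding flanks, with species-level divergence of at least 8%
#' between panel members and an i.i.d. substitution error rate of 0.5% per
#' sequenced base.
#'
#' @param n_species number of species in the panel.
#' @param n_pairs number of read pairs to simulate.
#' @param proportions per-species community proportions (default equal);
#'   must sum to 1.
#' @param insert_len insert length between the primers (default 171).
#' @param divergence minimum pairwise p-distance between species inserts.
#' @param read_len read length (default 150).
#' @param sub_error_rate per-base substitution error rate (default 0.005).
#' @param quality_profile integer Phred per cycle (default a monotone
#'   decrease from 38 to 28 across the read).
#' @param degrade_frac fraction of reads given a low-quality (Phred 5) 3'
#'   tail of `degrade_len` bases (default 0).
#' @param degrade_len length of the degraded tail.
#' @param contaminant_frac fraction of pairs drawn from an off-panel species
#'   absent from the reference set (default 0).
#' @param primer_fwd,primer_rev conserved flank sequences.
#' @param seed integer seed; every simulation quantity is deterministic
#'   under it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species, n_pairs, proportions = NULL,
                       insert_len = 171L, divergence = 0.08,
                       read_len = 150L, sub_error_rate = 0.005,
                       quality_profile = NULL, degrade_frac = 0,
                       degrade_len = 20L, contaminant_frac = 0,
                       primer_fwd = default_primer_fwd,
                       primer_rev = default_primer_rev, seed = 1L) {
  proportions <- proportions %||% rep(1 / n_species, n_species)
  stopifnot(n_species >= 1, n_pairs >= 1, length(proportions) == n_species,
            abs(sum(proportions) - 1) < 1e-9, insert_len > 0,
            divergence >= 0, divergence < 1, read_len > 0,
            sub_error_rate >= 0, sub_error_rate < 1,
            degrade_frac >= 0, degrade_frac <= 1,
            contaminant_frac >= 0, contaminant_frac < 1)
  quality_profile <- quality_profile %||%
    as.integer(round(seq(38, 28, length.out = read_len)))
  stopifnot(length(quality_profile) == read_len,
            read_len <= insert_len + nchar(primer_fwd) + nchar(primer_rev))
  structure(list(n_species = as.integer(n_species),
                 n_pairs = as.integer(n_pairs), proportions = proportions,
                 insert_len = as.integer(insert_len), divergence = divergence,
                 read_len = as.integer(read_len),
                 sub_error_rate = sub_error_rate,
                 quality_profile = as.integer(quality_profile),
                 degrade_frac = degrade_frac,
                 degrade_len = as.integer(degrade_len),
                 contaminant_frac = contaminant_frac,
                 primer_fwd = toupper(primer_fwd),
                 primer_rev = toupper(primer_rev),
                 seed = as.integer(seed)),
            class = "sim_config")
}

mutate_seq <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  chars
}

hamming_frac <- function(a, b) hamming_cpp(a, b) / nchar(a)

#' Generate a synthetic reference panel
#'
#' A random ancestral insert is mutated independently per species (per-site
#' substitution probability equal to `divergence`, which makes expected
#' pairwise divergence comfortably above the floor); proposals whose
#' p-distance to an already-accepted species falls below `divergence` are
#' rejection-resampled. Conserved flanks (the primer-binding sites) are
#' identical across species, so each reference sequence is
#' `flank_fwd + insert + revcomp(primer_rev)` -- the full amplicon. Species
#' are named `Species_001`, ...; sequences are deterministic under the seed.
#'
#' @param cfg a [sim_config()].
#' @return a `reference_set` data frame with attribute `inserts` (the bare
#'   insert per species).
#' @export
make_references <- function(cfg) {
  set.seed(cfg$seed)
  ancestor <- strsplit(random_dna(cfg$insert_len), "")[[1]]
  inserts <- character(cfg$n_species)
  for (s in seq_len(cfg$n_species)) {
    ok <- FALSE
    for (try in 1:200) {
      prop <- paste(mutate_seq(ancestor, cfg$divergence), collapse = "")
      if (s == 1L ||
          all(vapply(inserts[1:(s - 1L)], hamming_frac, numeric(1), a = prop) >=
              cfg$divergence)) { ok <- TRUE; break }
    }
    if (!ok) stop("make_references: could not achieve pairwise divergence ",
                  cfg$divergence, " at insert length ", cfg$insert_len)
    inserts[s] <- prop
  }
  refs <- data.frame(
    accession = sprintf("SYN%04d", seq_len(cfg$n_species)),
    species_name = sprintf("Species_%03d", seq_len(cfg$n_species)),
    sequence = paste0(cfg$primer_fwd, inserts, revcomp(cfg$primer_rev)),
    stringsAsFactors = FALSE)
  class(refs) <- c("reference_set", "data.frame")
  attr(refs, "inserts") <- inserts
  refs
}

apply_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  todo <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a community of known composition
#'
#' Each pair draws its species from `proportions`; the amplicon is the full
#' reference sequence (conserved flanks included); R1 is its first
#' `read_len` bases and R2 the reverse complement of its last `read_len`
#' bases. Substitution errors are i.i.d. per sequenced base at
#' `sub_error_rate` (independently in each mate, as sequencer errors are).
#' Qualities follow `quality_profile`, with an optional Phred-5 3' tail on a
#' `degrade_frac` fraction of reads. With `contaminant_frac > 0` that
#' fraction of pairs is drawn from an extra off-panel species absent from
#' `refs`. Fully deterministic under `cfg$seed`.
#'
#' @param refs a `reference_set` from [make_references()].
#' @param cfg the same [sim_config()].
#' @return list with `sample` (an `edna_sample`), `truth` (data frame
#'   `read_id`, `species`), `proportions` (named true proportions including
#'   any contaminant), and `refs`.
#' @export
simulate_reads <- function(refs, cfg) {
  set.seed(cfg$seed + 1L)
  pool <- refs$sequence
  pool_names <- refs$species_name
  probs <- cfg$proportions
  if (cfg$contaminant_frac > 0) {
    contaminant <- paste0(cfg$primer_fwd, random_dna(cfg$insert_len),
                          revcomp(cfg$primer_rev))
    pool <- c(pool, contaminant)
    pool_names <- c(pool_names, "Contaminant_sp")
    probs <- c(probs * (1 - cfg$contaminant_frac), cfg$contaminant_frac)
  }
  n <- cfg$n_pairs
  sp_idx <- sample.int(length(pool), n, replace = TRUE, prob = probs)
  amp <- pool[sp_idx]
  alen <- nchar(amp)
  r1 <- substr(amp, 1L, cfg$read_len)
  r2 <- revcomp(substr(amp, alen - cfg$read_len + 1L, alen))
  r1 <- apply_read_errors(r1, cfg$sub_error_rate)
  r2 <- apply_read_errors(r2, cfg$sub_error_rate)
  qual_ok <- phred_encode(cfg$quality_profile)
  qd <- cfg$quality_profile
  tail_ix <- seq(max(1L, cfg$read_len - cfg$degrade_len + 1L), cfg$read_len)
  qd[tail_ix] <- 5L
  qual_bad <- phred_encode(qd)
  degraded1 <- stats::runif(n) < cfg$degrade_frac
  degraded2 <- stats::runif(n) < cfg$degrade_frac
  ids <- sprintf("sim%06d", seq_len(n))
  sample <- structure(list(
    sample_id = "simulated",
    r1 = new_fastq_reads(paste0(ids, "/1"), r1,
                         ifelse(degraded1, qual_bad, qual_ok)),
    r2 = new_fastq_reads(paste0(ids, "/2"), r2,
                         ifelse(degraded2, qual_bad, qual_ok))),
    class = "edna_sample")
  truth <- data.frame(read_id = ids, species = pool_names[sp_idx],
                      stringsAsFactors = FALSE)
  emp <- table(factor(truth$species, levels = pool_names))
  list(sample = sample, truth = truth,
       proportions = setNames(as.numeric(emp) / n, pool_names),
       refs = refs)
}

#' Simulate a complete experiment to disk
#'
#' Writes `refs.fasta`, `reads_R1.fastq.gz`, `reads_R2.fastq.gz`, and
#' `truth.tsv` under `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return the `simulate_reads()` result, invisibly.
#' @export
simulate_to_dir <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- make_references(cfg)
  sim <- simulate_reads(refs, cfg)
  write_fasta(refs, file.path(out_dir, "refs.fasta"))
  write_fastq(sim$sample$r1, file.path(out_dir, "reads_R1.fastq.gz"))
  write_fastq(sim$sample$r2, file.path(out_dir, "reads_R2.fastq.gz"))
  write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sim)
}
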