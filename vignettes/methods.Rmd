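---
title: "From raw eDNA amplicon reads to species tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw eDNA amplicon reads to species tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`ednapipe` turns raw paired-end 12S amplicon reads from environmental DNA
(eDNA) surveys into per-sample species tables with assignment confidence
scores, neighbor-joining trees, and community diversity indices. The marker
targeted is the hypervariable region of the fish mitochondrial 12S rRNA gene
that sits between two highly conserved primer-binding regions; amplicons are
short enough (roughly 170 bp of insert, about 220-230 bp with primers) that
150-bp paired-end reads overlap substantially and can be merged into
full-length amplicon sequences.

The pipeline runs six stages in a fixed order:

1. **Quality trimming.** Each read's 3' tail is cut after the last base
   whose Phred score reaches the floor (10 by default). This is the literal
   trimming rule; we deliberately implement it as stated rather than a
   windowed or longest-segment algorithm, because it is exactly testable
   and adequate for the monotone quality decay typical of short reads.
   Quality encoding is fixed to Sanger Phred+33 with no auto-detection:
   modern instruments emit nothing else, and silent misdetection is worse
   than a loud error.
2. **Paired-end merging.** The reverse mate is reverse-complemented and
   every candidate overlap of at least `min_overlap` (10) bases is scored
   by mismatch fraction; the smallest fraction wins, ties going to the
   longest overlap, and the pair is rejected above a mismatch fraction of
   0.25. At agreeing positions the consensus keeps the base with the higher
   of the two qualities; at disagreeing positions the higher-quality base
   wins with its own quality, ties keeping the forward base. The two merge
   parameters follow the published defaults of the standard overlap
   mergers and are configurable.
3. **N/length filtering.** Merged reads containing any `N`, or whose length
   falls outside 229 ± 25 bp, are removed. The window is a *closed*
   interval — [204, 254] at defaults — applied to the merged read before
   primer removal, following the pipeline's stage order. Both the center
   and the tolerance are configurable.
4. **Primer removal.** The forward primer is sought at the 5' end and the
   reverse complement of the reverse primer at the 3' end, each sliding
   over a terminal window of primer length + 3 bases. Matching is
   substitution-only: amplicon primers are terminal and the mismatch
   allowance (3 bases at the maximum, inclusive) is counted as
   substitutions. The best placement wins, ties going outermost; the whole
   read is also tried in reverse-complement orientation, the forward
   orientation winning ties. Reads whose primers cannot be placed within
   the allowance are discarded and counted.
5. **Dereplication and abundance denoising.** Identical inserts collapse
   into unique sequences carrying read counts. Uniques with at least 10
   reads are "high"; the rest are putative error sequences and are
   remapped onto the best-matching high unique when their pairwise
   identity reaches 99%, otherwise discarded. A count of exactly 10 is
   high.
6. **Taxonomic assignment.** Each surviving unique is aligned locally
   against every reference; hits must reach 97% identity and an e-value of
   at most 1e-5. The top hit's species is called, and whenever a
   *different* species occurs among ranks 2-5 a confidence score is
   computed (below).

Per-sample outputs are a community table, Shannon alpha diversity and
Bray-Curtis beta diversity (natural log throughout), all-species and
within-species neighbor-joining trees, and TSV/HTML reports with external
database links.

## The confidence score

When competing species appear among ranks 2-5 of a query's hit list, the
assignment's confidence is

$$ C = \ln\frac{L_1/(m_1+1)}{L_2/(m_2+1)} $$

where $L$ is the aligned length and $m$ the mismatch count of the top hit
(subscript 1) and of the competing hit (subscript 2). The score is zero for
identical operands, positive when the top hit is better per mismatch, and
antisymmetric. Two readings of "the second hit" are possible: the rank-2
hit overall, or the best-ranked hit of each competing species. We compute
one score per competing species in the rank 2-5 window (against that
species' best-ranked hit) and report the minimum as the assignment's
confidence — the most ambiguous competitor is the one that matters. The
logarithm is natural; the notation supports this and the diversity indices
use the same base for consistency.

## Alignment machinery and numerical choices

All dynamic programming is full-matrix, with no banding or seeding
heuristics, so results are exactly reproducible and directly comparable to
brute-force oracles in the test suite.

- **Search** uses Smith-Waterman local alignment with affine gaps and
  blastn-like scoring: match +2, mismatch −3, gap open 5, gap extend 2,
  where a gap of length $k$ costs $5 + 2k$. `aligned_length` counts all
  alignment columns including gaps; `mismatches` excludes gap columns (the
  BLAST tabular convention), so exported hit tables are comparable to
  `outfmt 6` output, and externally produced BLAST tables can be imported
  to drive the assignment logic. Both query orientations are searched and
  the better bit score kept. One best local alignment is retained per
  reference; ranking is by bit score, then e-value, identity, and
  accession (lexicographic), which makes tie-breaking fully deterministic.
- **E-values** use the Karlin-Altschul form $E = Kmn\,e^{-\lambda S}$ with
  $\lambda = 0.625$ and $K = 0.41$ for this scoring scheme, $m$ the query
  length and $n$ the total residues in the reference set; bit scores are
  $(\lambda S - \ln K)/\ln 2$.
- **Denoising identity** is matches / alignment columns from a global
  alignment with free terminal gaps (match +1, mismatch −1, gap −2).
  Amplicons cover the same locus, so penalising terminal overhangs as
  internal gaps would distort identity; columns are counted over the
  aligned region only. Identity is computed from the traceback, not from
  the score. Remapping is a single pass: absorbed counts never promote
  other low uniques, lows never absorb lows, and the tie-break (higher
  count, then lexicographically smaller sequence) uses pre-absorption
  counts so the outcome is independent of processing order.
- **Multiple alignment** is center-star: the center is the sequence with
  the best summed pairwise alignment score, and other sequences merge in
  under "once a gap, always a gap". For near-identical amplicon-scale
  inputs this is essentially exact and, unlike progressive aligners, fully
  deterministic and testable.
- **Distances** are p-distances with pairwise deletion of gap/N columns
  (computed through `ape::dist.dna`); the pipeline names no substitution
  model on purpose — at within-species divergences a correction is
  negligible, and a Jukes-Cantor hook would be straightforward to add.
- **Neighbor joining** is the canonical Saitou-Nei algorithm: Q-matrix
  selection with ties broken by the smallest index pair, standard branch
  lengths, final three-way join (unrooted, basal trifurcation), negative
  branch-length estimates clamped to zero with a flag. The all-species
  tree uses the highest-count unique per species as its representative;
  within-species trees use all uniques assigned to that species (three
  leaves minimum).
- **Degenerate inputs** fail loudly rather than silently: empty read sets,
  empty reference sets, pairs of alignment rows with no comparable
  columns, and zero-count diversity inputs are errors; merge or primer
  failures are normal, counted outcomes.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `phred_floor` | 10 | trim 3' bases below this Phred score |
| `expected_len` ± `len_tol` | 229 ± 25 bp | accepted merged length (closed interval) |
| `max_primer_mismatch` | 3 | substitutions tolerated per primer |
| `min_overlap`, `max_overlap_mismatch_frac` | 10, 0.25 | merge candidate constraints |
| `min_count` | 10 | abundance threshold (≥ 10 is "high") |
| `similarity` | 0.99 | identity needed to remap a low unique |
| `min_identity_pct` | 97 | identity cutoff for hits |
| `max_evalue` | 1e-5 | e-value cutoff for hits |
| `max_alt_rank` | 5 | deepest rank inspected for competitors |

## What the simulator emulates — and what it does not

The `sim_config()`/`make_references()`/`simulate_reads()` module builds a
synthetic reference panel (a random ancestral insert mutated per species
until all pairwise p-distances reach the divergence floor, 8% by default,
between identical conserved flanks) and simulates a 150-bp paired-end run:
species drawn per read pair from the community proportions, substitution
errors i.i.d. at 0.5% per sequenced base independently in each mate, a
monotone-decreasing quality profile (Phred 38 down to 28), optional
degraded 3' tails below the trimming floor, and optional off-panel
contaminants. Everything is deterministic under the seed.

The insert defaults to 171 bp, giving a 219-bp amplicon with the bundled
21/27-bp synthetic flanks — inside the default length window. The flank
sequences are arbitrary placeholders of realistic lengths, not the real
assay's primers; users supply their own primers for real data.

Deliberately *not* modelled: indel sequencing errors (substitution-only is
a reasonable short-read approximation, and the primer matcher is also
substitution-only), PCR chimeras and amplification bias, quality-dependent
error probabilities, and length variation among species. Passing the
simulation-based tests therefore demonstrates the pipeline's correctness
under its own stated model, not robustness to chimeric or indel-rich real
libraries — chimera detection is explicitly out of scope.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: alignment
scores against `Biostrings::pairwiseAlignment`, denoising against a
brute-force all-pairs re-implementation (100-200 random samples of up to
50 uniques), hit ranking against a full-DP search over a 100-species
panel, neighbor joining against additive distance matrices from random
trees (up to 12 taxa, 200 replicates, path-distance recovery to 1e-9, with
`ape::nj` as a topology cross-check), and the confidence formula against
direct evaluation on 1,000 random operand tuples (1e-12 relative). The
end-to-end check simulates 10 species at known proportions with 20,000
read pairs and 0.5% substitution errors, and requires the pipeline to
report exactly the true species with per-species read percentages within
±2 percentage points of truth; with zero simulated errors every read must
survive every stage and every merged amplicon must equal its template.
These sizes keep the full suite around a minute on one core while
exercising each code path many times; `scripts/acceptance.R` re-runs the
same computations from scratch and writes the measured quantities as JSON.

## Known limitations

- Species can only be assigned if the reference set resolves them; the
  97% cutoff implies that references diverged by less than ~3% from a
  query compete, and very recently diverged species may be inseparable at
  this locus.
- The denoiser is abundance-based, not error-model-based: a true rare
  haplotype below the count threshold that sits within 99% identity of an
  abundant one is absorbed into it.
- Center-star alignment is not a substitute for progressive aligners on
  divergent sequences; it is used here only on amplicon-scale,
  near-identical inputs.
- The e-value constants are fixed for the default scoring scheme; users
  changing match/mismatch/gap scores should supply matching
  Karlin-Altschul parameters.
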