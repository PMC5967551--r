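# ednapipe

A self-contained R implementation of an environmental-DNA (eDNA)
metabarcoding pipeline for fish 12S amplicons. It takes raw paired-end
FASTQ reads and a reference FASTA of 12S sequences with species labels,
and produces per-sample species tables with assignment confidence scores,
neighbor-joining phylogenetic trees, and community diversity indices —
with every stage (quality trimming, paired-end merging, N/length
filtering, primer removal, dereplication, abundance-based denoising,
local-alignment taxonomic assignment, tree building, reporting)
implemented natively and deterministically rather than delegated to
external tools.

Intended users are ecologists and molecular biologists running fish eDNA
surveys (or any short-amplicon metabarcoding with the same structure) who
want a scriptable, exactly reproducible desk pipeline whose every
threshold is visible and testable.

## The method

Reads are 3'-trimmed at a Phred floor (< 10 by default), merged by
best-overlap consensus, filtered to 229 ± 25 bp with no Ns, and stripped
of primers allowing at most three base mismatches per primer. Identical
inserts are dereplicated with read counts; uniques with fewer than 10
reads are remapped onto high-count uniques at ≥ 99% identity or
discarded. Each survivor is then aligned (Smith–Waterman, blastn-like
scoring, Karlin–Altschul e-values) against the reference set with cutoffs
of 97% identity and e-value 1e-5, and the top hit's species is called.
When a different species occurs among hit ranks 2–5, the assignment's
confidence is scored as

```
C = ln[ (L1 / (m1 + 1)) / (L2 / (m2 + 1)) ]
```

with `L` the aligned length and `m` the mismatch count of the top hit (1)
and the competing hit (2): zero for equally good hits, positive when the
top hit is better per mismatch. Per-sample outputs include Shannon alpha
diversity, Bray–Curtis beta diversity, and all-species / within-species
neighbor-joining trees. A simulation module generates reference panels
and error-bearing read pairs with known composition, so the whole
pipeline can be validated against planted ground truth. See
`vignettes/methods.Rmd` for the full methods account.

## Worked example

Simulate a five-species community and run the pipeline on it:

```r
library(ednapipe)
cfg  <- sim_config(n_species = 5, n_pairs = 5000,
                   proportions = c(0.35, 0.25, 0.2, 0.15, 0.05), seed = 3)
refs <- make_references(cfg)
sim  <- simulate_reads(refs, cfg)
res  <- run_pipeline(sim$sample,
                     pipeline_config(refs, cfg$primer_fwd, cfg$primer_rev))
print(res)
#> <pipeline_result> 1 sample(s), 5 species
#>             simulated
#> Species_001      1407
#> Species_002       985
#> Species_003       774
#> Species_004       597
#> Species_005       180
round(res$diversity$shannon, 4)
#> simulated
#>    1.4605
```

The table counts denoised, assigned reads per species (the simulation's
0.5% per-base error rate means a fraction of reads is discarded by the
filters, proportionally across species — the recovered composition
1407:985:774:597:180 ≈ 35.6%:24.9%:19.6%:15.1%:4.6% matches the planted
35.3%:25.1%:19.6%:15.3%:4.6% within a few tenths of a percentage point).
The per-unique assignment table carries identities, e-values and
confidence scores (`NA` when no competing species occurs among hit ranks
2–5, i.e. the call is unambiguous at that depth). With an output
directory set in `pipeline_config()`, the run also writes TSV tables, an
HTML report with FishBase/BOLD/GBIF links, Newick trees, and a JSON run
manifest with telescoping per-stage read counts.

A thin command-line wrapper is installed with the package
(`exec/ednapipe`): `ednapipe simulate --out simdir` and `ednapipe run
--r1 ... --r2 ... --refs ... --primer-fwd ... --primer-rev ... --out outdir`.

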