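# longamp

Long-read rDNA amplicon barcoding toolkit for R: demultiplexing of
dual-indexed Nanopore amplicon reads, consensus calling, and the distance
and community statistics used in long-amplicon DNA barcoding and
metabarcoding studies.

## The problem

DNA barcoding with long (3–4.5 kb) ribosomal-cluster amplicons
(18S–ITS1–5.8S–ITS2–28S) on Nanopore sequencers is attractive — one
amplicon spans both conserved genes and fast-evolving spacers — but raw
long reads carry 12–22% error. Two computational steps make the approach
workable, and this package implements both from first principles:

1. **Demultiplexing noisy reads.** Each PCR primer carries a sample-specific
   15-bp index on its 5' tail, so a read looks like

   ```
   fwd_index + fwd_primer + insert + revcomp(rev_primer) + revcomp(rev_index)
   ```

   in random orientation. Reads are assigned by bounded semi-global
   (infix) edit-distance search: an index hit counts when its minimum edit
   distance (substitutions + indels) within the read end is at most a
   threshold *e*, optionally confirmed by finding the primer within its
   own threshold immediately interior to the index. A read is assigned iff
   a unique best forward and reverse index are found and the pair occurs
   in the barcode table; ties are `ambiguous`, everything else
   `unassigned`.

2. **Consensus calling.** Per-sample reads are quality/length filtered
   (mean quality > 13 in the probability domain, length > 3 kb),
   subsampled to a target coverage (minimum 30), strand-normalized,
   aligned to a median-length seed read, and polished by two rounds of
   realign-and-majority-vote — gap is a votable state and insertions need
   strict majority support — which collapses per-read error to a
   near-perfect consensus.

Around this core the package provides the analytics such studies report:
percent p-distance matrices (indels excluded, or gap-as-fifth-state),
intra/interspecific partitioning and barcode-gap detection, the Mantel
permutation test (add-one rule, one-sided), metabarcoding log2 fold change
between input DNA proportion and read proportion (0 ⇔ 1:1 recovery),
qualitative recovery percentages, and Levene/Brown–Forsythe variance
tests. A dual-index designer (pairwise Levenshtein distance ≥ 10,
homopolymer cap 3) and a Nanopore-like read simulator with per-read ground
truth make every stage testable without sequencing data.

## Worked example

Design indexes, simulate a run, demultiplex it, and call a consensus:

```r
library(longamp)

# four 15-bp indexes, every pair >= 10 edits apart
idx <- design_indexes(4, length = 15, min_dist = 10, seed = 42)
#> "AAACCTCCATGTGTA" "CGTGCCGTATTAGAA" "CTTATTCAACAAAGA" "TAAAGGACGGAGCAA"

# four samples on a 2x2 dual-index grid, degenerate 27-bp primers
specs <- index_grid_specs(idx[1:2], idx[3:4],
                          fwd_primer = "TACACACCGCCCGTCRCTACTACCGAT",
                          rev_primer = "GGTTAGTTTCTTTTCCTCCGCTTAYTG")
set.seed(1)
refs <- setNames(replicate(4, random_dna(3500)), specs$sample_name)

# 60 reads/sample at 12% raw error (6% sub, 3% ins, 3% del), random strand
sim <- simulate_reads(specs, refs, 60, error_model(), seed = 7)
res <- demultiplex(sim$records, specs, demux_config(index_max_edits = 2))
res$summary
#>   sample     n_reads
#> 1 s1              36
#> 2 s2              42
#> 3 s3              36
#> 4 s4              35
#> 5 unassigned      91
#> 6 ambiguous        0

cs <- consensus_pipeline(res$groups$s1, min_coverage = 30, rounds = 2, seed = 7)
cs
#> <consensus_result> 3501 bp from 36 reads (2 polish rounds); mean support 0.913
alignment_identity(cs$sequence, refs[["s1"]])
#> 99.86
```

The summary shows the expected behaviour at a strict index threshold of 2
edits: roughly 60% of reads are recovered (an error-laden index misses the
threshold), none are assigned to a wrong sample, and the polished
consensus is within 0.14% of the true insert. Raising `index_max_edits`
recovers more reads at the cost of eventual cross-sample bleed — the
trade-off explored in the test suite.

A thin command-line front end wraps the same functions
(`inst/exec/longamp`): `simulate`, `filter`, `demux`, `consensus`, `dist`,
`mantel`, `community`, `design-indexes`, each with `--help`.

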