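---
title: "Methods: demultiplexing, consensus and statistics for long-amplicon barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demultiplexing, consensus and statistics for long-amplicon barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

longamp implements the computational core of long-read rDNA amplicon
barcoding: assigning noisy dual-indexed Nanopore reads back to their
samples, collapsing per-read error into consensus sequences, and the
distance and community statistics used to interpret the results. This
vignette records the models, the parameters that matter, and the design
decisions taken where more than one defensible choice existed.

## The read model

A sequenced molecule is

```
fwd_index (15 bp) + fwd_primer (27 bp) + insert (3-4.5 kb)
  + revcomp(rev_primer) + revcomp(rev_index)
```

observed on a random strand with per-base errors. The simulator
(`simulate_reads()`, `error_model()`) draws errors independently per base:
deletion with probability `del_rate`, substitution to a uniform different
base with `sub_rate`, insertion of a uniform base after the position with
`ins_rate`. Defaults are 0.06/0.03/0.03 — a 12% raw error rate, the lower
end of the range reported for Nanopore chemistry; raising the rates toward
0.22 emulates older pores. Degenerate primer positions are resolved to a
concrete base per molecule, since every physical molecule is concrete.
Quality strings are constant at `Q = round(-10*log10(sub+ins+del))`
(Q9 at the 12% default), matching the expected error profile; a real run
has per-base quality variation that the toolkit's filters — which use the
probability-domain mean only — would not exploit anyway.

What the simulator does *not* emulate: homopolymer-biased indel clustering
(available as an opt-in `homopolymer_factor`, default off), chimeras,
adapter remnants, quality-error correlation along the read, and
length-dependent coverage dropout. Tests passing on simulated reads
therefore demonstrate the algorithmic contracts (assignment correctness,
convergence of polishing, calibration of tests), not performance on any
particular flow cell.

## Demultiplexing

`assign_read()` searches the first and last `search_window` bases (default
100 = index 15 + primer 27 + generous insertion slack; clipped to half the
read length for short reads) of each read under both orientation
hypotheses. Candidate indexes are located by bounded semi-global (infix)
alignment — flanking gaps in the window are free, edits inside the matched
span cost 1 — implemented in C++ with IUPAC-aware matching so that
degenerate primer bases align free. Among equal-distance hits the leftmost
start and then the shortest span wins; this tie-break is arbitrary but
deterministic and stated.

Assignment requires a *unique* best forward index and a unique best
reverse index, each within `index_max_edits` (default 2), with the
`(fwd, rev)` pair present in the barcode table. When `require_primer` is
on (default), an index hit only counts if its primer is found within
`primer_max_edits` (default 11) in the sub-window immediately interior to
the index. A tie between two different indexes at the best distance at
either end, or conflicting valid assignments from the two orientations,
yields `ambiguous` — the read is never resolved arbitrarily. Everything
else is `unassigned`.

Two consequences of this contract are worth stating explicitly:

* **Recovery at a strict threshold is bounded.** At a 12% per-base error
  rate a 15-bp index carries on average 1.8 errors, so the probability
  that one index region stays within 2 edits is about 0.75, and both ends
  jointly about 0.6. Raising the threshold to 3 or 4 recovers most of the
  remainder — the monotone recovery the test suite checks — but, when
  index sets are poorly separated, eventually admits cross-sample
  misassignment. With well-separated indexes (pairwise distance ≥ 10),
  misassignment requires ≥ 5 coincident edits pushing one index onto
  another and is effectively absent at thresholds ≤ 4.
* **Percent mode rounds down.** `percent_mode` converts a fraction into a
  per-pattern allowance as `floor(fraction * pattern length)`; the
  conservative direction, since the alternative (rounding) silently grants
  an extra edit to 15-bp indexes at typical settings.

Read filtering (`filter_reads()`) applies the published cutoffs strictly:
mean quality > 13 and length > 3000, where mean quality is the
probability-domain mean `-10*log10(mean(10^(-Q/10)))`, not the arithmetic
mean of Phred scores. Filtering commutes with demultiplexing (both are
per-read predicates); filtering first is cheaper and is the default
composition in the CLI.

Assigned reads are emitted strand-normalized (reverse-complemented to the
template strand when found in `-` orientation), so each per-sample group
is directly usable for consensus calling; the assignments table keeps the
original orientation of every read.

## Consensus calling

`consensus_pipeline()` refuses to run below `min_coverage` (default 30)
reads, subsamples uniformly without replacement to `coverage_cap` (default
300 — accuracy plateaus well before that, and capping bounds run time;
the slight accuracy dip sometimes seen at very high coverages is not
modelled), and proceeds in rounds:

1. **Seed**: the read of median length (ties to the earlier read) — robust
   against truncated reads pulling the draft short.
2. **Orientation**: every read is put on the seed strand by a shared
   8-mer count against the reverse complement; at long-read error rates
   the true strand shares far more 8-mers than the opposite one, and the
   test suite exercises this on mixed-orientation input.
3. **Vote**: each read is aligned to the current reference by unit-cost
   glocal alignment (read end-to-end, reference flanks free; C++ with full
   traceback). Each reference column is re-called by majority over the
   aligned bases, gap being a votable state whose majority deletes the
   column. An insertion between two columns is emitted only when strictly
   more than 50% of the covering reads support one (the strict inequality
   prevents spurious homopolymer growth at 50/50 splits); the modal
   inserted string is used. Column ties keep the current reference base
   when it is among the winners, otherwise the alphabetically first —
   again arbitrary but deterministic.
4. **Polish**: the vote is repeated `rounds` times (default 2, matching
   standard minimap+RACON practice; round 1 removes most seed-read error,
   round 2 cleans up alignment artefacts near indels).

The result records per-column support — the fraction of covering reads
agreeing with the called base — in a sidecar table. Heterozygous positions
are collapsed to the majority base; the support column is the intended
way to spot them afterwards. Degenerate inputs behave predictably:
identical error-free reads reproduce their sequence exactly for any
coverage ≥ 1, a single read is its own draft, and `rounds = 0` returns the
draft unchanged.

## Distance statistics

`pdistance()` is the uncorrected p-distance in percent, with two indel
policies: `exclude` (pairwise deletion — only columns where both sequences
have a base are compared) and `include` (gap as a fifth character state,
columns gapped in both excluded). Column-coding was chosen for the include
mode because it is deterministic and order-free; event-coding (one indel
event = one difference) would require an alignment-dependent gap grouping.
No substitution-model correction is applied anywhere — all downstream
quantities (barcode gap, Mantel r) are rank-like and the uncorrected scale
matches how such distances are conventionally printed.

`barcode_gap()` is `min(inter) - max(intra)`, present iff strictly
positive — a zero gap is no gap. `mantel_test()` correlates lower
triangles with Pearson's r and permutes rows+columns of the second matrix
jointly; the p-value uses the add-one rule
`(1 + #{r_perm >= r_obs}) / (1 + n_perm)` with a one-sided positive
alternative, the directional hypothesis relevant when comparing two
markers on the same specimens. The default 9,999 permutations resolve
p = 0.001; the calibration test (200 independent-matrix replicates at 999
permutations) checks the rejection rate at the nominal 5%.

`levene_test()` computes the classic W statistic from absolute deviations
to the group center — median by default (Brown–Forsythe), the robust
choice for the skewed fold-change distributions it is applied to — with
`W ~ F(k-1, N-k)`. When all deviations are equal, both sums of squares
vanish and W is defined as 0 (p = 1).

## Community statistics

Fold change is `log2(read_proportion / input_proportion)`; zero anchors
1:1 recovery in any base, and base 2 is the bioinformatics convention (the
anchor, not the base, is the substantive choice). A taxon with zero reads
is a *dropout*, reported as a flag and excluded (`NA`) from fold-change
summaries rather than entering as -Inf. Without dropouts the fold changes
of one community conserve read mass: `sum(input_i * 2^F_i) = 1`.
`simulate_community()` draws multinomial read counts with an optional
power-law length bias `share ∝ p * (len/min_len)^(-exponent)` — a
single-knob stand-in for preferential amplification of shorter templates;
the exponent is a user-facing hypothesis dial, default off.

## Index design

`design_indexes()` produces ACGT-only indexes (homopolymer runs ≤ 3, a
sequencer-realism constraint) with every pairwise *Levenshtein* distance
≥ `min_dist` (default 10 at length 15). Levenshtein was chosen over
Hamming deliberately: reads suffer indels, Hamming distance is an upper
bound on Levenshtein, so the guarantee made is the stronger one.

Pure random-candidate greedy acceptance stalls: the probability that a
fresh random 15-mer clears a distance-10 floor against *k* accepted
indexes decays roughly geometrically in *k*, and a 1e5-candidate budget
plateaus near a dozen indexes. The designer therefore repairs rejected
candidates by hill-climbing single-base mutations that reduce the total
distance violation (each mutation counted against the same attempt
budget), which roughly doubles the achievable set size at identical cost.
All pairwise distances are re-verified after the search — the
verification is part of the operation's contract, not a test nicety.

## Problem sizes and determinism

Every stochastic routine takes an explicit `seed` and restores the
caller's RNG state, so whole pipelines replay byte-identically. The test
suite runs at desk scale by choice: demultiplexing benchmarks use 4
samples × 250 reads with 400-bp inserts, consensus benchmarks a 3.5-kb
amplicon at coverages 10 and 30 over 10 subsampling seeds, Mantel
calibration 200 replicates of 10-label matrices at 999 permutations, and
community simulations 10,000 reads over short templates. These sizes
exercise every contract while keeping the full suite in a few minutes;
none of the algorithms has size-dependent behaviour beyond run time.

## Known limitations

* Reads with index/primer tags in their interior (chimeras, concatemers)
  are not split; they demultiplex by their ends or fall out as unassigned.
* Consensus calling is haploid: within-specimen variants are collapsed
  and only visible through the support table.
* The demultiplexer does not use base qualities in matching; an error-rich
  index region is simply missed at strict thresholds rather than rescued.
* Terminal colour marking of tag regions is not implemented — marking is
  case-based (FASTA only), since colour is presentation, not data.
* The aligner is plain dynamic programming: exact and fast enough for
  amplicon-scale sequences, but not a general-purpose long-read mapper.
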