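---
title: "Adapter trimming, read merging and adapter inference: methods and design"
author: "adaptrim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapter trimming, read merging and adapter inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrim)
```

# The problem

When the DNA insert of a sequencing library is shorter than the read length,
the sequencer reads through the insert into the adapter ligated to its 3'
end. Downstream analyses treat those adapter bases as genomic sequence unless
they are removed. Short inserts are the rule rather than the exception in
degraded-material libraries (ancient DNA, FFPE), where read pairs also
overlap heavily, so the same alignment that locates the adapter can be reused
to *collapse* the two mates into one full-length, higher-quality
reconstruction of the template molecule.

`adaptrim` implements the complete pre-processing tool around one
computational kernel — exhaustive ungapped overlap alignment — plus a read
simulator with per-read ground truth and the confusion-matrix machinery
needed to measure trimming and merging accuracy against that truth.

# The alignment kernel

`alignOverlap(A, B, minOffset)` scans every offset of `B` relative to `A`
with at least one overlapping position. At each offset it counts matches,
mismatches and *ambiguous* positions (either base `N`), and scores the
overlap as

$$ S = \text{matches} - \text{mismatches}, $$

with `N` contributing zero. The best offset maximises $S$; ties prefer the
longer overlap, then the smaller offset. The scan is linear and gapless by
construction: a read containing an indel relative to the adapter is scored as
a run of mismatches, never bridged. This restricts the method to platforms
with low indel rates (Illumina-type data); it is a deliberate trade of
generality for speed and determinism.

## Acceptance: when is an alignment evidence of adapter?

An alignment is only acted on if it passes `isAcceptable()`:

1. its score must reach `minScore` (default 1 — zero or negative score
   carries no evidence);
2. its mismatches must not exceed a budget derived from the `mm` parameter:
   `mm > 1` means a maximum error rate of `1/mm` (so the default `mm = 3`
   tolerates one mismatch per three aligned bases), while `mm` in `(0, 1]` is
   the rate itself. The budget is `floor(called * rate)` over the *called*
   (unambiguous) positions — `N` runs, such as the six-base index placeholder
   in the standard mate-1 adapter, neither help nor hurt;
3. short alignments get a tightened budget: below 6 called bases no mismatch
   is tolerated, below 10 at most one.

Rule 3 deserves explanation because it shapes the method's operating
characteristics. Selection happens *before* acceptance: the single globally
best alignment is chosen across all offsets (and all configured adapters),
and only that candidate is tested. Without rule 3, a 3-base overlap with two
matches and one mismatch is "within a 1/3 error rate" and would be accepted,
and on adapter-free reads such candidates win the best-alignment contest
often enough to push single-end specificity down to about 0.62. With the
tightened budget the same benchmark lands at a specificity of ~0.815 at
sensitivity ~0.98, and adding a 3-base minimum adapter overlap
(`minAdapterOverlap = 3`) moves it to ~0.96/~0.96 — the characteristic
behaviour of this family of trimmers. The residual specificity loss at
default settings comes from *perfect* 1–3-base 3' matches, which are
indistinguishable from genuine minimal read-through; `minAdapterOverlap`
exists precisely to veto them when the application warrants.

The select-then-test order also means an unacceptable best alignment causes
*no* trimming even when a lesser, acceptable alignment exists. This is
intentional: accepting runner-up alignments would reintroduce exactly the
short spurious matches rule 3 exists to reject.

# Single-end and paired-end trimming

Single-end: each adapter's 5' end is aligned against the read at offsets
`>= 0` (the adapter may run past the read's 3' end), and an accepted
alignment truncates sequence and qualities at the alignment offset. A read
consisting entirely of adapter is truncated to length zero and kept — length
filtering is a separate concern left to downstream tools.

Paired-end: for each adapter pair the aggregates

```
A = revcomp(adapter2) + seq1
B = revcomp(seq2)     + adapter1
```

are aligned, allowing negative offsets down to
`-(nchar(adapter2) + maxShift)` (`maxShift` defaults to 5), so that mates may
slide past each other through the adapter padding. The best offset directly
implies the insert length, `L = offset - nchar(adapter2) + nchar(seq2)`, and
each mate is truncated at its insert boundary when `L` is shorter than the
read. This is the key advantage of paired-end trimming: the evidence for the
trim point is the full mate-mate overlap (typically tens of bases), not a
short read-adapter match, which is why its accuracy is essentially limited
only by insert lengths so close to twice the read length that the true
overlap is one or two bases — at that point no scoring scheme can distinguish
signal from the best of ~200 random offsets.

With several adapter pairs configured the pair whose aggregate alignment
scores highest wins; ties go to list order, making output deterministic.

# Collapsing overlapping pairs

A pair whose accepted alignment spans at least `minOverlap` positions
(default 11) is collapsed into one read covering the inferred insert.
`minOverlap` is compared against the *alignment* overlap, which includes
adapter read-through positions: a 5 bp insert read at 2x100 bp yields over a
hundred aligned positions and is confidently collapsed, while a 195 bp insert
yields five and is refused. Gating on the alignment overlap rather than on
double-covered insert positions is what gives the collapse step its
characteristic sensitivity (~0.94 at insert Normal(150, 75) and 2x100 bp:
the refused mass is the insert band just under 200 bp where `2R - L <
minOverlap`).

Single-covered positions copy base and quality from the covering mate
(mate 2 reverse-complemented, qualities reversed in lockstep). Double-covered
positions combine the two observations by treating the quality scores as a
position-specific scoring matrix: Phred scores are log-likelihoods, so
agreeing observations add, `q = min(cap, q1 + q2)`, and disagreeing
observations keep the higher-quality base at the difference,
`q = q_hi - q_lo`, with an exact tie between different bases emitting `N` at
quality 0 and an `N` observation contributing a flat likelihood. A full
four-base posterior with mismatch likelihood `p/3` gives the same base call
everywhere and nearly the same quality at disagreements; at agreements it
adds a constant `10*log10(3) ≈ 4.8` to the summed score. We emit the plain
sum: it is the PSSM reading, it is what the field's tools emit, and the cap
(`qualityCap = 41`, the Illumina 1.8+ maximum) usually absorbs the
difference anyway.

# Reconstructing unknown adapters

For poorly documented libraries the adapters themselves can be inferred.
Here no adapter anchor exists, so the raw mates are aligned against each
other (`seq1` vs `revcomp(seq2)`, no padding) under a *stricter* acceptance
— error rate 1/10 and a minimum overlap of 11 by default — because a false
overlap would contaminate the consensus. Each accepted pair whose inferred
insert is shorter than the reads contributes its mate-1 suffix beyond the
insert as an adapter-1 fragment and its mate-2 suffix as an adapter-2
fragment. Fragments are stacked into per-position counts of `A/C/G/T/N` and
a majority-rule consensus is called: ties emit `N`; a column observed only as
`N` (the index placeholder positions of standard adapters) emits `N` and the
consensus continues; the consensus ends at the first column no fragment
reaches. Reconstruction quality is scored as the number of correct leading
bases, with `N` matching `N`.

Because coverage of adapter position $k$ requires an insert of length at most
`readLength - k`, the expected reconstructed length falls as the insert-size
distribution moves right; with mean 150 bp and sd 75 bp at 2x100 bp, a few
percent of pairs read deeply into the adapter and 10^4 pairs comfortably
recover both full adapters. The method assumes a single adapter pair per
library: consensus building averages over whatever is present, so mixed
adapters degrade it — single-end data, which provide no overlap evidence at
all, are out of scope.

# Demultiplexing

Barcode assignment is a simple maximum-mismatch comparison: the 5' prefix of
each mate is compared against every barcode (Hamming distance; `N` in the
read counts as a mismatch; distances summed over mates when double-indexed),
and a read is assigned to the unique sample within `maxMismatches` (default
1). Ties at the minimal distance go to "unidentified" rather than to the
first-listed sample — silent misassignment is worse than an unassigned read.
Barcode bases are stripped before trimming, and each sample's adapters gain
the reverse-complemented barcode of the *other* mate as a prefix, because a
read-through pair is terminated by exactly that barcode remnant followed by
adapter. With this construction, demultiplexing-then-trimming commutes with
trimming pre-split files (tested).

# The read simulator

The simulator provides ground truth for the benchmark and emulates a
short-insert Illumina library:

* insert lengths `round(Normal(insertMean, insertSd))`, redrawn until
  `>= 1` — i.e. a truncated normal. Note that at the default (150, 75) the
  2.3% of redraws shift the realised mean to 154.2 and sd to 70.6; the
  defaults are the *parent* parameters, matching how such benchmarks are
  specified;
* inserts sampled from a uniform-random reference (default 10^6 bp at GC
  0.41, human-like), random strand. Trimming accuracy is driven by
  insert-length geometry and the error model, not by genomic content, so a
  random reference stands in for a real chromosome; repeats and
  low-complexity regions of real genomes are *not* emulated;
* `read = first readLength bases of insert + adapter`, the adapter cycled if
  the read runs past its end (64/58 bp adapters vs 100 bp reads); at the true
  pair-alignment offset the cycled pad falls outside the compared region, so
  this padding choice does not perturb the trimming truth;
* substitution errors injected *after* adapter appending, with probability
  rising linearly from 0.001 at the first cycle to 0.010 at the last, the
  substituted base uniform over the three alternatives, and the emitted
  Phred score `round(-10 log10 p)` per position (30 down to 20). `N` bases
  are left untouched. Indels, GC bias, quality transition matrices and
  machine-specific profiles are not simulated.

All randomness flows from the config seed; identical seeds give bit-identical
output (regression-tested). The last point about scope matters for
interpreting green tests: they demonstrate correctness of the algorithms
under a clean substitution-only error model, not performance on any
particular instrument's error profile. Empirically, the benchmark statistics
most sensitive to this are merge *specificity* (wrong-length merges at short
overlaps are driven by terminal error rates, which real profiles place
several-fold higher than our ramp) and multi-adapter sensitivity; both come
out *better* under the stand-in model than published figures obtained with
instrument-derived profiles.

# Benchmark classification

Per trimmed read: an adapter-containing read (insert < read length) is TP
when trimmed exactly to the insert length, FP when trimmed further, FN when
adapter bases remain; an adapter-free read is TN untouched, FP otherwise.
Per pair for merging: an overlapping pair (insert < 2x read length) is TP
when merged to exactly the insert length, FN when unmerged, FP when merged
to any other length; non-overlapping pairs are TN unmerged, FP merged. From
the tallies: SEN = TP/(TP+FN), SPC = TN/(FP+TN), PPV = TP/(TP+FP),
NPV = TN/(TN+FN), and MCC with the standard product-of-marginals
denominator; a zero denominator yields NaN for the affected ratio and 0 for
MCC. Paired-end trimming classifies each mate separately; merging classifies
each pair once.

# Numerical and design choices

* `floor(called * rate)` is computed with a `1e-9` epsilon so that exact
  multiples (9 called bases at rate 1/3) are not truncated by floating-point
  representation.
* Tie-breaks everywhere are deterministic (longer overlap, smaller offset,
  adapter list order), so identical inputs give identical outputs,
  single- or multi-threaded alike.
* Degenerate inputs: empty reads are written and re-read faithfully
  (`@id / <empty> / + / <empty>`); paired-end trimming rejects zero-length
  mate sequences; inferred insert lengths are clamped at 0; quality encoding
  is fixed Phred+33 and any quality character below `!` is an error, not a
  guess at an offset.
* The `mm` dual convention (rate or reciprocal) mirrors the established
  flag semantics; only 3 and 5 are exercised by the benchmarks but any
  positive value is accepted.
* The identification-mode stringency (rate 1/10, overlap 11) and the merge
  threshold (`minOverlap = 11`) are exposed as settings; their defaults are
  the values that reproduce the published operating points of this method
  family under the simulator's study conditions.

# Problem sizes

The test suite exercises the full benchmark at 10^5 read pairs per condition
(paired-end, single-end and five-adapter runs) plus 10^4-case property
checks of the alignment kernel against a brute-force oracle; the
`scripts/acceptance.R` driver recomputes all headline figures at the same
10^5 scale in well under a minute on one core. Unit tests use hundreds to
thousands of reads — sizes at which every statistic asserted is separated
from its threshold by several standard errors.

# Known limitations

* No indel awareness: one sequencing indel inside the overlap can shift the
  inferred trim point.
* Inserts within a few bases of twice the read length cannot be reliably
  recovered by any ungapped best-alignment scheme (one to five bases of true
  overlap against ~200 candidate offsets); expect the last ~5 bp below
  `2 * readLength` to be missed at realistic rates.
* Adapter identification requires paired-end data and a single adapter pair.
* Phred+64 input, multi-line FASTQ, and SAM/BAM are out of scope.
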