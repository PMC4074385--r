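---
title: "Adapter trimming by bit-masked k-difference matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapter trimming by bit-masked k-difference matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdtrim)
```

## The problem

When a sequencing library contains DNA fragments shorter than the read
length, the sequencer reads through the insert into the ligated adapter
(and past it into noise). Downstream analyses — alignment, assembly,
small-RNA quantification — need those adapter bases removed, and removed
*exactly*: over-trimming destroys signal, under-trimming injects adapter
sequence into the data. For Nextera long-mate-pair (LMP) libraries the
problem is harder still: every properly constructed fragment carries a
junction adapter in the *middle* of the read, which must be located and
used to split the read.

kdtrim models adapter detection as approximate string matching under the
Levenshtein distance and layers three decision modes on top: single-end
3' trimming, paired-end (PE) joint trimming, and LMP junction splitting.

## The matching kernel

### The k-difference problem and its extension

Given a read of length n and an adapter pattern of length m, the search
reports every substring of the read within k unit-cost differences
(substitutions, insertions, deletions) of the full pattern, with
k = ⌊n·e⌋ for an error ratio e ∈ [0, 1), capped at m − 1. Because a
partial adapter at the 3' end of a read is the common case, the search is
extended to read *suffixes*: a suffix of aligned length L matching a
pattern prefix is reported when its difference count is at most ⌊L·e⌋.
Floors are taken with a 10⁻⁹ guard so that L·e values that are integers
up to floating-point error round the intended way.

The textbook dynamic programming matrix C has C[0, j] = 0 (a match may
begin anywhere in the read) and C[i, 0] = i, with the usual three-way
recurrence. Two structural facts make the fast search possible:

* values along every diagonal are monotonically non-decreasing, and
* the last active cell (the deepest row of a column still ≤ k, `lac`)
  moves down by at most one row per column.

The implementation (`find_matches()`, in C++) keeps only the active cells
of the current column in a queue-like O(m) buffer. Per read base it looks
up a precomputed mismatch bit-vector for that base against the pattern:
*matched* cells copy their diagonal predecessor without recomputation,
and cells whose value exceeds k are marked in a dead mask and never
touched again (their whole diagonal is dead by monotonicity). On random
sequence the expected number of live cells per column is O(k), giving
expected O(kn) time; the test suite asserts a generous version of this
(mean live cells ≤ 5(k + 1)).

A full-matrix reference implementation (`oracle_find()`, plain R, no
cutoff) is retained permanently as the independent oracle; the suite
checks candidate-set equality on thousands of randomized instances and
verifies both structural facts on every oracle matrix.

### Alignment starts

Reporting a trim position requires each candidate's alignment *start*,
which classical formulations recover by traceback. Here start positions
propagate forward along the DP paths: a matched cell inherits its
diagonal's start, and a mismatched cell takes the first value-achieving
predecessor in the fixed order diagonal, up, left. The convention is
shared by the oracle and the cutoff search, making candidate tuples
(start, end, differences) deterministic and comparable. It also keeps the
start bookkeeping O(1) per cell, which is what lets the final
suffix-overlap check read L = n − start straight off the queue.

### Base-call qualities

Differences are not equally believable: a mismatch under a Phred-40 call
is strong evidence against an occurrence, a mismatch under Phred-5 is
noise. Each mismatch against a base of quality q is charged

P(q) = P_min for q ≤ 0, P_min + q/40·(P_max − P_min) for 0 < q < 40,
P_max for q ≥ 40,

with P_min = −log10(1/3) and P_max = −log10(10^(40/−10)/3). On (0, 40)
this equals −log10(10^(q/−10)/3), the negative log probability that the
base truly matches given error probability 10^(−q/10) (uniform over the
three alternative bases). Indels cost a flat delta = P_max. An 'N' call
carries no evidence either way and is treated as a mismatch at the floor
P_min; degenerate IUPAC codes in the *adapter* match their whole
degeneracy set.

Admissibility is always governed by the unit-cost difference count — the
quality penalty only ranks candidates. The weighted search therefore
returns exactly the unweighted candidate set (a tested invariant), each
candidate carrying the minimum penalty among equal-difference alignments
to its endpoint.

## Decision layers

### Error ratio over the aligned span

The enumeration bound k = ⌊n·e⌋ is deliberately permissive (n is the read
length), so the decision layer re-screens candidates with the error ratio
over the **aligned span**: a candidate spanning s read bases is admissible
when differences ≤ ⌊s·e⌋. This is the same rule the extended problem
already applies to suffix overlaps, extended uniformly to full
occurrences. The alternative — accepting ⌊100·0.1⌋ = 10 differences in a
19 nt adapter hit — would false-trim a large fraction of clean reads,
which is incompatible with the specificity this class of trimmer is
expected to achieve.

### Single-end mode

`trim_single()` ranks admissible candidates by the span fitness
s·P_max − penalty (ties: longer matched pattern, then smaller start) and
truncates the read at the winner's start. The default `min_overlap` is
3 nt: a 1–2 nt exact 3' overlap matches random sequence with probability
≥ 1/16, so shorter overlaps are not acted on without further evidence.

### Paired-end mode

A read-through pair has a special geometry: both mates contain the
(mate-specific) adapter starting at the same index idx = insert length,
and the retained prefixes are reverse complements of each other *in
register*. `trim_pair()` scores each candidate idx with

score(idx) = pscore(read1[idx..], adapter1) + pscore(read2[idx..],
adapter2) + pscore(read1[0..idx), revcomp(read2[0..idx))),

where pscore(x, y) = |x|·P_max − penalty(x, y) and penalty(x, y) is the
minimum quality-weighted cost of aligning all of x against a prefix of y
(y's tail free; mismatches between two read bases are charged at the
smaller of the two qualities — the lower-confidence call most plausibly
explains a disagreement). The maximal-score candidate is accepted only if
all three component alignments individually satisfy the error ratio over
their spans, and is then applied to both mates.

Two deliberate choices here:

* **Candidate generation relaxes `min_overlap` to 1.** A single
  error-free adapter base at the 3' end is meaningless alone but becomes
  decisive when both mates show it at the same idx *and* idx bases of
  prefix are reverse-complementary. This is what lets PE mode recover
  inserts of read_length − 1 exactly, where SE mode must stay silent.
* **The complementarity check is positionwise (Hamming), not
  indel-tolerant.** Inserts a few bases *longer* than the read produce
  mate prefixes that are shifted near-copies of each other; an
  indel-tolerant check reads the shift as a handful of cheap gaps and
  false-trims such pairs. True read-through prefixes are complementary in
  register, so in-register comparison is both stricter and correct. The
  `pscore` ranking term keeps the penalty DP.

### LMP mode

`trim_lmp()` first runs the PE stage unchanged, then searches each
processed mate independently for the junction adapter and keeps the
prefix before the junction start, labelling each mate `junction_found`,
`no_junction` or `empty_after_trim`. Which side of the junction to keep
is a convention (mate orientation fix-ups are an assembler concern); the
prefix is kept here. A single pass is made: re-running the junction
search can only act on chance ≥ 3 nt 3'-end matches of the retained
genomic prefix with the junction prefix (probability ≈ 1/64 per read),
which are not junction detections — the tested idempotence property is
that *no admissible full junction occurrence* remains after splitting.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws fragments with uniform positions and
truncated-normal lengths from a uniform-random reference; mate 1 reads
the fragment forward, mate 2 its reverse complement, and any fragment
shorter than the read length runs through into the adapter and then
random filler. `solve_contamination_fraction()` places the fragment mean
so that P(fragment < read length) hits a target; fragment lengths are
floored, making the target exact under the normal model. The defaults —
5,000 pairs of 100 bp reads, fragment sd 50, 36% contaminated reads,
flat Q25 with quality-driven substitution errors (probability
10^(−q/10) per base, applied to insert, adapter and filler alike) —
emulate the design of the paired-end simulation study this class of
trimmers is benchmarked on, at a desk scale chosen so the full test
suite runs in minutes. In LMP mode each mate carries the junction at a
uniform position at which it fits entirely inside the read (the
enrichment step of the protocol selects junction-containing fragments).

Deliberately not emulated: empirical sequencer error profiles (the
trimming math consumes only per-base Phred values), indel sequencing
errors by default (Illumina substitution-dominated; the DP's indel path
is exercised by constructed fixtures instead), real genomic repeat
structure, and multi-million-read scale. Consequently, passing tests
demonstrate correctness of the *method* under its stated model, not
performance on any particular instrument's quirks; homology-driven false
positives can be studied separately by planting adapter-like motifs in
the reference (`motif` option).

## Evaluation

Each read is classified against the manifest at tolerance 0 by default
(the boundary must be exact): TP, FP_ft (clean but trimmed), FP_ot
(over-trimmed), FN_fr (untrimmed contaminant), FN_ut (under-trimmed),
TN. The derived metrics are

* PPV = TP / (TP + FP_ft + FP_ot + FN_ut) — note the denominator
  includes under-trimmed reads: any read whose boundary was moved
  wrongly counts against precision, which differs from the textbook PPV
  and is kept exactly as defined;
* Sen = TP / (TP + FN_fr + FN_ut + FP_ot);
* Spec = TN / (TN + FP_ft);
* mCC with FP = FP_ft + FP_ot and FN = FN_fr + FN_ut.

Metrics with zero denominators are reported as missing rather than 0/0.
Pairs are evaluated per read (two rows per pair). `roc_sweep()` re-runs
the trimmer over a grid of error ratios and reports FPR/TPR per
stringency.

## Numerical and degenerate-input choices

* Thresholds use ⌊x + 10⁻⁹⌋ so that products like 10 × 0.1 floor to 1.
* `max_differences` fixes k directly; it also caps suffix-overlap
  differences, because the cutoff search cannot see cells beyond k.
* An insert of length 0 (adapter dimer) trims to an empty read — the
  record is kept in the stream and left to the length filter.
* Ties in PE scoring go to the larger idx (trim less); ties in SE go to
  the longer matched pattern, then the smaller start.
* Phred+33 is the default quality dialect; detection
  (`detect_quality_offset()`) never overrides an explicit choice.
  Multi-line FASTQ is rejected rather than silently joined.

## A worked example

```{r example}
set.seed(1)
cfg <- sim_config(n_pairs = 300, error_model = "error_free",
                  mean_quality = 40, seed = 8)
sim <- simulate_dataset(cfg)
res <- trim_pairs(sim$reads1, sim$reads2, cfg$adapter1, cfg$adapter2)
obs <- rbind(res$decisions1[, c("read_id", "output_length")],
             res$decisions2[, c("read_id", "output_length")])
compute_metrics(classify_reads(sim$manifest, obs, cfg$read_length))
```

On error-free reads the pair geometry pins every boundary exactly, so
all four metrics are 1 — the exact-recovery property the acceptance
suite verifies at 5,000 pairs.

## Known limitations

* 5' adapter trimming, barcode demultiplexing, read merging and quality
  trimming are out of scope.
* The SE ranking score is the span fitness of the matched region; it does
  not model the unmatched read tail beyond the candidate, which is
  adequate for 3' contaminants but would need revisiting for internal
  multi-adapter screens.
* PE mode trims both mates to a single idx; structurally discordant
  pairs (different per-mate boundaries) are not modelled.
* The simulator's flat quality model understates quality heterogeneity
  within real reads; sensitivity near the error-ratio boundary will
  differ on real data.
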