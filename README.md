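# kdtrim

Quality-aware adapter trimming for next-generation sequencing reads,
built on a bit-masked k-difference matching kernel.

## The problem

When a library fragment is shorter than the read length, the sequencer
reads through the insert into the ligated adapter; those bases must be
removed at exactly the right boundary before alignment or assembly. In
Nextera long-mate-pair (LMP) libraries a junction adapter additionally
sits in the middle of every proper read and must be found to split the
read. kdtrim is for anyone who needs exact, reproducible 3'-adapter,
paired-end read-through and LMP junction trimming in R, plus the
simulation and benchmarking machinery to measure a trimmer's accuracy.

## The method

**Matching.** Adapter detection is semi-global approximate matching under
the Levenshtein distance: all substrings P' of a read S with
‖P', P‖_lev ≤ k = ⌊n·e⌋ for error ratio e, plus all read suffixes S'
matching a pattern prefix with ≤ ⌊|S'|·e⌋ differences (the partial
adapter at the 3' end). The DP matrix (C[0,j] = 0, C[i,0] = i) is
computed column-wise with the Ukkonen cutoff; per-base mismatch
bit-vectors are precomputed so matched cells copy their diagonal
precursor untouched, and cells exceeding k are masked dead forever
(values along a diagonal never decrease). Expected O(kn) time, O(m)
space. A full-matrix reference implementation is kept as a permanent
test oracle.

**Qualities.** A mismatch under Phred quality q costs
P(q) = −log10(10^(q/−10)/3) clamped to [P_min, P_max] =
[−log10(1/3), −log10(10⁻⁴/3)] — the negative log probability that the
base truly matches; indels cost delta = P_max.

**Paired ends.** For a read-through pair both mates contain their adapter
from the same index idx and the retained prefixes are reverse
complements. Candidates are scored with

```
score(idx) = pscore(read1[idx..], adapter1)
           + pscore(read2[idx..], adapter2)
           + pscore(read1[0..idx), revcomp(read2[0..idx)))
```

with pscore(x, y) = |x|·P_max − penalty(x, y); the best idx is accepted
only if all three component alignments stay within the error ratio, and
is applied to both mates. LMP reads get PE trimming first, then a
per-read junction search.

**Evaluation.** Reads are classified against a ground-truth manifest into
TP, FP_ft, FP_ot, FN_fr, FN_ut, TN, with PPV, sensitivity, specificity
and Matthews correlation computed from the printed formulas, plus ROC
sweeps over stringency.

## Worked example

Find a partial adapter at a 3' end — the read ends in a 16 nt exact
prefix of the TruSeq adapter starting at position 8:

```r
library(kdtrim)
adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
find_weighted_matches("TTGCCATAAGATCGGAAGAGCACA", rep(30L, 24), adapter)
#>   start end differences  penalty matched_pattern_length
#> 1     8  24           1 4.477121                     15
#> 2     8  24           0 0.000000                     16
#> 3     8  24           1 4.477121                     17
```

The exact 16 nt suffix/prefix overlap (0 differences, penalty 0) is
found along with its two 1-difference indel variants; the decision layer
trims at start 8.

Simulate a Q25 paired-end experiment with 36% contaminated reads, trim
it jointly, and score against the ground truth:

```r
cfg <- sim_config(n_pairs = 300, error_model = "quality_driven",
                  mean_quality = 25, seed = 8)
sim <- simulate_dataset(cfg)
res <- trim_pairs(sim$reads1, sim$reads2, cfg$adapter1, cfg$adapter2)
obs <- rbind(res$decisions1[, c("read_id", "output_length")],
             res$decisions2[, c("read_id", "output_length")])
compute_metrics(classify_reads(sim$manifest, obs, cfg$read_length))
#> PPV = 1.0000  Sen = 0.9906  Spec = 1.0000  mCC = 0.9927
```

Of 600 reads, 210 contaminated reads are trimmed at exactly the true
boundary, 388 clean reads are left untouched, and 2 contaminated reads
(adapter tails of a base or two hit by errors) are missed — no read is
trimmed wrongly.

The same workflows are available from the shell via the bundled script:

```sh
Rscript inst/scripts/kdtrim simulate --n-pairs 5000 --seed 7 --out-prefix sim
Rscript inst/scripts/kdtrim trim --mode pe --in1 sim-pair1.fastq \
    --in2 sim-pair2.fastq --out-prefix trimmed
Rscript inst/scripts/kdtrim evaluate --manifest sim-manifest.tsv \
    --report trimmed-report.tsv
```

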