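---
title: "Calling CpG methylation from nanopore signal: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CpG methylation from nanopore signal: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(nanomethr)
```

## The problem

Nanopore sequencers report the ionic current through a pore as a DNA strand
translocates. The current level depends on the k bases in the pore at a
time, and 5-methylcytosine (5mC) perturbs that level relative to unmodified
cytosine. This makes read-level methylation calling possible directly from
signal: compare the likelihood of the observed signal under the unmethylated
reference sequence against the same sequence with CpG cytosines replaced by
the methylated base symbol `M`, using a pore model with entries for both.

`nanomethr` implements this workflow in four stages per read:

1. **Event detection** — segment the raw current trace into *events*
   (approximately one or more per k-mer residency).
2. **Alignment** — align events to the read's k-mer sequence with a banded
   dynamic program.
3. **Calibration** — re-fit the per-read affine scaling between pore-model
   currents and the read's observed currents.
4. **Methylation scoring** — for each CpG group, fill a profile HMM twice
   (unmethylated and methylated haplotype) and report the log-likelihood
   ratio.

Batches of reads flow through these stages under a pipelined executor with a
bounded window of in-flight batches.

## The scoring HMM

For a scored haplotype of K k-mers, the probability matrix has one row per
event (plus an initial row) and **three state columns per k-mer**, in the
order `KMER_SKIP`, `BAD_EVENT`, `MATCH`; the three columns of one k-mer form
a *block*, so the matrix has 3K columns. The states mean:

* `MATCH` — the event was emitted by this k-mer; emission is the Gaussian
  `N(scale * level_mean + shift, var * level_stdv)` from the pore model after
  per-read calibration.
* `BAD_EVENT` — the event is unexplained by the model (an artifact); it
  emits a flat probability (default 0.01) rather than a density.
* `KMER_SKIP` — the k-mer was traversed without any event.

The fill is forward-style in natural-log space. For row r (event r) and
block b:

* `MATCH(r, b)` combines, through the stable log-sum `add_log`, *step*
  transitions from the three states of `(r-1, b-1)` and *stay* transitions
  from the three states of `(r-1, b)`, then adds the match emission.
* `BAD_EVENT(r, b)` combines the three states of `(r-1, b)` and adds the
  flat penalty.
* `KMER_SKIP(r, b)` combines the three states of `(r, b-1)` — a
  **same-row** dependency on the previous block.
* After the last block of each row, the end accumulator gains
  `fm[r][last, MATCH] + lp_end`; the final accumulator is the returned
  log-likelihood.

Transition probabilities default to `p_stay = 0.1`, `p_skip = 0.01`,
`p_bad = 0.01`, with `p_step` the remainder and `lp_end = log(p_step)`;
these are order-of-magnitude typical for nanopore event streams and are
fully configurable through `trans_params()`.

### Boundary conditions

Row 0 is the "no events consumed" row. `MATCH` of block 0 is seeded with
`lp_start = 0`, and `KMER_SKIP` of row 0 is filled left-to-right so leading
k-mers can be skipped (at `lp_skip` each) before the first event. Transitions
*out of row 0* are begin transitions and carry no stay/step/bad cost: with
one event and one block the score reduces exactly to
`lp_start + lp_emit + lp_end`. Termination is allowed only from `MATCH` of
the last block, after any row; skipping the final k-mer does not terminate.
All arithmetic is double-precision natural log; impossible cells hold the
floating `-Inf`, never a sentinel.

One consequence of accumulating the end state at every row is worth noting:
appending an extra trailing event adds a (small) positive term to the end
accumulator, so "more data" can only be guaranteed not to raise the score
when the extra event is inserted *inside* the stream; the package's property
tests check monotone degradation in that form.

### Two-phase parallel fill

Within a row, `MATCH` and `BAD_EVENT` of every block depend only on the
previous row, so they are mutually independent; only `KMER_SKIP` chains
along the row. The parallel engine exploits exactly this: per row, **phase
A** computes `MATCH` and `BAD_EVENT` for all blocks, with blocks assigned
round-robin to a worker pool; a barrier separates it from **phase B**, in
which one designated worker scans blocks left-to-right filling `KMER_SKIP`
and accumulating the end state. Both engines share a single `add_log`
routine and a fixed operand order in every log-sum chain, which makes the
parallel fill **bit-identical** to the serial fill for every worker count —
a property the test suite asserts with exact float equality.

R's runtime has no shared-memory threads, so the phase-A chunks execute in
sequence inside one process. This does not weaken the contract being
modelled: phase-A cells are disjoint and read only frozen inputs, so *no*
chunk schedule can change any value, and the barrier is an explicit program
point. A true threaded or GPU backend could drop into the same two-phase
structure unchanged.

### CpG groups and the likelihood ratio

CG dinucleotides whose start positions lie within `group_distance`
(default 10 bp) are merged into one group and scored jointly with a single
matrix. The scored window spans the first CG minus `flank` to one past the
last CG plus `flank`; the default flank of 5 bp (k − 1 for k = 6) keeps
every k-mer overlapping a CpG inside the window. The call records
`log_lik_ratio = log_lik_methylated − log_lik_unmethylated` (natural log);
positive supports methylation. A window with no CpG scores the same
haplotype twice and yields exactly zero by construction.

Reverse-strand reads are scored against the reverse complement of the
forward reference window, with CpG methylation re-applied on the reverse
complement — the CG motif is strand-symmetric, so no complement rule for
`M` is ever needed. Coordinates in the output stay on the forward strand,
one call per (read, group), with no strand merging.

## Upstream stages

**Event detection** places boundaries at local maxima of the two-window
Welch t-statistic (window 4 samples, threshold 4.0, minimum event length 3
samples by default) and summarizes each segment by its mean and standard
deviation. The defaults suit the synthetic signal's noise scale and are
exposed in `seg_params()`.

**Alignment** is a banded Viterbi DP over (event, k-mer) cells with stay,
step and skip moves, the band a fixed width (default 200 cells) centred on
the ideal diagonal. This is a deliberate simplification of adaptive banded
event alignment: the band does not move with the warping path, which is
adequate at the simulator's stay/skip rates (the expected diagonal drift
over 2000 k-mers is far smaller than the half-band of 100). The aligner is
seeded with a moment-matching scaling estimate.

**Calibration** is a least-squares fit of aligned event means against model
level means: slope = `scale`, intercept = `shift`, and `var` the residual
standard deviation over the mean model `level_stdv`, floored at 0.01. The
fit is exact on noiseless affine data; drift is not estimated.

## The pipelined executor

Reads are split into batches; the executor enforces (i) a window of at most
`batch_count` batches in flight between stage-1 entry and stage-4 exit,
(ii) per-stage exclusivity, and (iii) in-order stage entry — the next batch
waits until the previous one has finished that stage. With four stages and
the default window of 3, the steady state is the classic picture of batch
*n* in calibration while *n + 1* aligns and *n + 2* detects events; the
trace's maximum in-flight count is exactly 3.

The schedule is computed in closed form on a **logical clock** (default one
time unit per stage) and the four stage functions — pure per-batch
transformations handed isolated workspaces — are executed in schedule
order within one process. All pipeline invariants (window bound, stage
exclusivity, order preservation) hold structurally on the trace, and the
combined output is byte-identical to a serial run for every window size and
worker count, which the tests assert via file checksums. OS-level
concurrency would change only the wall-clock timestamps, not any output, so
the deterministic scheduler is the portable realization of the design.
Data loading is a stage-0 producer outside the window accounting.

## The synthetic-data generator

The generator mirrors the HMM's own assumptions, no more: per k-mer it
emits `1 + Geometric(p_stay)` events with means
`N(scale * mu_kmer + shift, noise_sd)`, skips the k-mer with `p_skip`,
injects a uniform outlier with `p_bad`, and concatenates per-event constant
segments plus per-sample Gaussian noise. Methylated CpG k-mers use the
M-substituted model entry, whose level mean sits `m_shift` above the
unmethylated version (a constant offset — real pore models differ per
k-mer, but a constant gives a controllable effect size). The synthetic pore
model derives each k-mer's mean deterministically from base composition
(range roughly 100–150 pA, `level_stdv` 1.0).

Default conditions: 50 reads of 2000 bp on a 10 kb reference, CpG density
0.02/bp, methylation rate 0.5, `p_stay` 0.1, `p_skip` 0.01, `p_bad` 0.01,
`noise_sd` 1.0 pA, `m_shift` 4.0 pA, true scaling (shift 10, scale 1.2,
var 1), seed 42. Choices the generator makes beyond those conditions, fixed
once: a 10 kb reference (five read lengths, so reads overlap), 20% of reads
on the reverse strand, event lengths of `3 + Poisson(5)` samples (~8
samples/event), and methylation drawn per (read, CpG-group) so that sites
within a group share a state — mimicking locally coherent CpG methylation
and keeping group-level truth unambiguous. The truth table still records
every site individually.

What the generator does **not** emulate: dwell-time distributions, within-
read drift, k-mer-specific methylation shifts, basecalling errors, or
indels in the alignment (reads map with a pure-match CIGAR). Passing
end-to-end tests therefore demonstrates correctness of the algorithms under
the model's own assumptions — not calling accuracy on real flow-cell data.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_reads = 10, read_length = 800, ref_length = 4000)
model <- synthetic_pore_model(k = 6, m_shift = cfg$m_shift)
ref <- simulate_reference(cfg)
sim <- simulate_reads(ref, model, cfg)

res <- call_methylation(sim$reads, ref$sequences, model,
                        config = pipeline_config(batch_size = 2))
glance(res)
head(res$calls)
autoplot(res)             # LLR histogram
autoplot(res$trace)       # pipeline Gantt chart
```

## Numerical and design notes

* `add_log(a, b)` is `max + log1p(exp(-|a - b|))` with `-Inf` as identity;
  a single shared implementation serves both fill engines and the end
  accumulator, fixing operand order for bit-reproducibility.
* Emissions far below the floating-point exponent range are handled
  entirely in log space; the test oracle enumerates paths in log space and
  combines them with one log-sum-exp for the same reason.
* Alignment tie-breaks prefer step over stay over skip; ties are
  measure-zero for continuous emissions but the rule keeps the traceback
  deterministic.
* Degenerate inputs: zero events reject the fill; an empty band or
  unreachable DP terminus fails the read's alignment (the read is skipped
  and counted); an all-equal-means calibration fit falls back to identity
  scaling with a warning; a zero-read fixture is valid and empty.
* Scored problem sizes in the tests and the acceptance script are the
  default conditions above; the path-enumeration oracle runs on instances
  of up to 4 events × 4 blocks, where exhaustive enumeration is exact and
  fast.

## Limitations

* The caller handles CpG methylation only — no GpC or dam/dcm motifs, no
  duplex or strand-combined calls.
* The fixed band is not adaptive banded event alignment; highly warped
  reads (far beyond the simulator's rates) could escape the band.
* FAST5/POD5 ingestion is out of scope; raw signal enters through the
  plain-text signal table.
* The executor models the pipeline's scheduling contract; it does not
  attempt to reproduce wall-clock speedups of heterogeneous hardware.
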