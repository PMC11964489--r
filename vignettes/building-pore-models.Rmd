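---
title: "Building de novo k-mer pore models from move tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building de novo k-mer pore models from move tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremodel)
```

## The problem

Nanopore sequencing reports a time series of ionic current. At any instant
the current is set mainly by the short stretch of nucleotides occupying the
pore, so signal-level analyses — event alignment, modification detection,
squiggle visualization — all consult a *k-mer model* (pore model): a table
giving, for each of the $4^k$ possible k-mers, the expected current level
and, optionally, its spread. When no official model exists for a chemistry,
or the official model is inconveniently large, one can be estimated
empirically. The only ingredient needed is a crude signal-to-sequence
alignment, and every modern basecaller already emits one as a by-product:
the *move table*, which marks, at a fixed stride of raw samples, the
neural-network steps at which a new base was called.

This package implements that estimation pipeline: segment the raw signal
along the alignment, collect up to a cap of current samples per k-mer,
summarise them into a model, find which base positions inside the k-mer
actually drive the current, and optionally collapse a large model onto
those positions to obtain a lightweight one. A simulator generates signal
with known ground truth so the entire pipeline is testable in isolation.

## Signal model and normalization

Raw samples are integers from the device ADC; they are converted to
picoamps with the calibration carried in the signal container,

$$\mathrm{pA} = (\mathrm{raw} + \mathrm{offset}) \cdot
  \frac{\mathrm{range}}{\mathrm{digitisation}},$$

and then normalized per read by median/MAD scaling,
$z = (x - \mathrm{median}(x))/\mathrm{MAD}(x)$. The raw MAD (no 1.4826
Gaussian consistency factor) is the default: the factor is a global scale
shared by every read, and the final model is re-anchored to picoamps by an
affine transform anyway, so it cancels; a `consistency` flag restores it
for users who want MAD on the standard-deviation scale. Reads whose MAD is
zero (stuck signal) are rejected rather than normalized into nonsense.

After model construction the normalized levels are mapped back to real
current values with the dataset's global statistics,

$$\mathrm{pA\ level} = z \cdot \sigma_{\mathrm{global}} +
  \mu_{\mathrm{global}},$$

where $\mu$ and $\sigma$ are the mean and standard deviation of the pooled
pA samples of the read set. Because this transform is affine, Pearson
correlations between models are unchanged by it — a property the test
suite asserts exactly.

## Event sampling

The alignment dialect is the run-length **ss** string: `7,2D3,4I,5` means
seven matched signal samples, two deleted bases, three matched samples,
four inserted samples, five matched samples. A move table converts to this
form losslessly (each run of steps beginning at a 1-move becomes one match
run of `run length × stride` samples), so both alignment sources flow
through one code path. Coordinates are 0-based and signal intervals
half-open throughout.

Each k-mer window of the read is paired with one *event*: the signal
segment of the window's anchor base, i.e. the segment the move table
attributes to that base — not the concatenation of k segments. This
matches move-table semantics (one segment per emitted base); the
`move_offset` parameter then shifts the pairing by whole bases so the
anchor can be aligned with whichever position in the k-mer dominates the
current. Events are filtered by:

* **dwell time** — duration strictly between `min_dur = 20` and
  `max_dur = 40` samples by default. The defaults bracket the expected
  ~30 samples/base of RNA004 chemistry (130 bases/s at 4 kHz); the strict
  inequality follows the sampling rule as stated, and an `inclusive_dur`
  switch gives closed bounds.
* **stability** — events whose within-event standard deviation exceeds
  `max_event_stddev` are dropped. No default threshold is imposed: the
  filter is off unless a value is supplied, because a useful cutoff
  depends on the normalization scale and chemistry.
* **indel neighborhoods** — bases within `indel_skip = 2` positions of a
  deletion run or an insertion boundary are excluded, and any window
  overlapping an excluded base is dropped. Segment boundaries near indels
  are the least trustworthy part of a crude alignment.

Per k-mer, at most `num_samples = 5000` events are stored. The cap counts
*stored* (post-filter) samples by default, which maximizes usable data; a
`strict_counter` mode reproduces the alternative bookkeeping in which
every observation — stored or rejected — advances the counter. The
difference only matters for k-mers whose observation count straddles the
cap; both modes are tested.

For direct RNA, the molecule translocates 3'→5', so the signal visits
bases in reverse sequence order. With `rna_mode = TRUE` the sampler
traverses the read backwards so event order matches signal order, while
emitted k-mer strings stay written 5'→3'.

## Model construction

Per k-mer the model level is the mean (or median) of the stored event
means. The spread column is, by default, the mean of the per-event
standard deviations; a `sd_of_means` variant (the spread of the event
means themselves) and a raw-MAD variant are provided, because both
conventions exist among published models and the choice is not settled.
K-mers with no stored samples are omitted rather than imputed — silent
imputation would corrupt downstream alignment invisibly — and coverage is
reported separately (`completeness_report()`: k-mers with ≥1, ≥100 and
≥cap stored samples).

Normalized spreads span a wider numeric range than event aligners expect
of a pore model, so `rescale_stddev()` maps them linearly onto the
heuristic interval $[2.5, 4]$, preserving their order; all-equal spreads
map to the midpoint 3.25.

## Significant base positions and model collapsing

Within a k-mer, not every position influences the current equally. For
each position $i$, the model's levels are partitioned by the base at $i$
into four "1-mer" collections of $4^{k-1}$ values each. If the position is
irrelevant, the four collections are (near-)identical; if it matters, they
separate. The comparison is histogram-based: for each of the 12 ordered
base pairs, 10 evenly spaced numbers spanning the pooled range of the two
collections define shared bins (read as bin *edges*, giving 9 bins — the
alternative bin-count reading is available via `bins_as_count`), and the
Pearson correlation of the two count vectors is the pair's similarity. A
position whose mean similarity falls below 0.96 is *significant*. Counts
rather than densities are correlated; for a complete model every
collection has the same total, so the distinction is immaterial there, and
for incomplete models the counts are reported as-is. Degenerate cases
(zero-variance count vectors, all-equal levels) define similarity 1 with a
warning: an undistinguishable pair is evidence of irrelevance, not of
signal.

A model can then be collapsed onto a *contiguous* run of significant
positions: each reduced k-mer's level is the mean over its $4^{k-k'}$
parents. Contiguity is enforced because a gap would make the register of
the reduced k-mer ambiguous to downstream aligners. Collapsing also
reconciles models of different k for comparison — e.g. a 9-mer model
collapsed to its central five positions is directly correlated with a
5-mer model, and 9-mer models hold $4^9/4^5 = 256$ times more k-mers than
5-mer ones, which is the point of going lightweight.

## Evaluation: model correlation and the tolerance F1

Two models of equal k are compared by the Pearson correlation of their
levels over shared k-mers. Alignments are compared by a signal-point F1:
expand each alignment into a per-sample map (sample → base, or unmapped),
then classify every sample — both mapped within a base tolerance of 1 is a
true positive (a signal point attributed one base left or right of the
correct one still counts), query-mapped-but-wrong or
query-mapped-where-truth-isn't a false positive, truth-mapped-but-query-
unmapped a false negative, both unmapped a true negative. The
both-unmapped rule is this package's operational definition of a true
negative (samples that *should* map to no base); the tolerance applies
only to mapped–mapped pairs. F1 is reported pooled over reads
(micro-average) by default, with per-read scores alongside, since either
convention is defensible and they differ on heterogeneous read sets.

## The simulator

`simulate_dataset()` draws, for each base, an integer dwell from a
truncated normal (mean 30, sd 5, bounded to $[20, 40]$ — matching the
expected samples/base and kept inside the default filter window so a
noise-free simulation loses no events), then emits
$\mathrm{Normal}(\mathrm{level}, \mathrm{sd})$ samples for the k-mer
window anchored at that base, places them on the pA scale, and quantizes
to ADC counts, so the forward pipeline sees realistic input. The exact
segmentation is emitted as ss strings — the ground truth for both
rebuilding and F1 experiments. A truncated normal was chosen for the dwell
family because its bounded support matches the filter window; real dwell
distributions are heavier-tailed, which the filters would clip anyway.

Sequences come either from uniform random draws or from a **de Bruijn**
template in which every k-mer occurs exactly `depth` times with minimal
bases. The de Bruijn cycle used is a *random Euler tour* of the de Bruijn
graph, not the classic lexicographic sequence: the lexicographic cycle is
globally balanced but locally skewed (A-rich start, T-rich end), and
because normalization is per read, chunking it into reads hands each read
a different affine scale and visibly corrupts the rebuilt model. A random
tour mixes rapidly, so any few-kilobase read is composition-balanced, like
real reads. This mattered in practice and is the reason the generator is
seeded per dataset.

`corrupt_alignment()` injects deletion and insertion operations and
boundary jitter at chosen rates while conserving signal consumption, to
exercise indel masking and sub-perfect F1 paths.

What the simulator does *not* emulate: pore-level flicker and stalls,
adapter/polyA signal, basecaller miscalls (sequences are exact), and
dwell-level autocorrelation. Passing recovery tests on simulated data
therefore demonstrates the estimator's correctness given an alignment of
stated quality, not robustness to every artifact of real signal; on real
data the quality filters carry that burden.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run entirely on simulated
data at deliberately modest scale: 5-mer recovery uses a de Bruijn depth
of 110 (≈113 kb of sequence, ≈3.4 M samples), chosen so that every k-mer
clears 100 stored samples after dwell filtering — the saturation depth at
which model quality stops improving — and 9-mer significance recovery uses
depth 3 (≈786 kb, ≈24 M samples), enough to beat estimation noise at
$4^9$ k-mers while keeping a laptop-scale runtime. Recovery is judged by
Pearson correlation ≥ 0.99 against the truth, with the per-read med-MAD
affine freedom absorbed by the correlation itself.

Ties and degenerate inputs are resolved conservatively: zero-MAD reads
error out; empty accumulators refuse to summarise; models with fewer than
three shared k-mers refuse to correlate; non-contiguous collapse index
sets are rejected. Histogram bin edges include both range endpoints
(`findInterval` with closed rightmost bin) so no level falls outside the
shared bins.

## Known limitations

* The significance algorithm's bin construction ("10 evenly spaced
  numbers") admits two readings — edges or bin count; both are
  implemented, edges being the default, and neither is asserted to be the
  one true reading.
* Event extent is one segment per anchor base. Aggregating the k segments
  a window spans is a defensible alternative the sampler does not
  implement.
* SLOW5/BLOW5 binary containers are not read natively; signals travel in
  a documented plain-text TSV container with the same calibration
  semantics. BAM/SAM move tables and PAF+ss are supported.
* Iterative refinement of a built model through an external event-aligner
  (re-align with the new model, resample, rebuild) is a documented
  workflow, not a function of this package.
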