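---
title: "Self-training de novo repeat detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-training de novo repeat detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repdetect)
```

## The problem

Repeats — transposable elements, tandem repeats, low-complexity tracts —
make up large fractions of most genomes, and they are species-specific:
a newly sequenced genome's repeats are largely absent from curated
libraries such as RepBase. A de novo detector must therefore find repeats
using nothing but the repetitive structure of the input itself. The
additional twist in this package is *self-training*: the detector labels
its own training data on each genome and then trains a probabilistic
segmentation model on those labels, so no annotation of any kind is
required.

`repdetect` follows the classic R modelling idiom: `repeat_detector()` is
the fitting function, returning a classed object with `print`, `summary`,
`coef`, `predict`, `plot` and `simulate` methods. `predict()` decodes a
genome into repeat intervals; `mask_repeats()` wraps fit, decode and
FASTA masking into one call.

## The model, stage by stage

### Scoring: background-adjusted k-mer counts

Every position of the genome is scored by the genome-wide count of the
k-mer starting there, adjusted against what a Markov chain trained on the
same genome would expect. A k-mer is indexed by its quaternary number
(A, C, G, T as digits 0–3); the indices of consecutive windows are
computed incrementally by Horner's rule, restarting after any non-ACGT
base. With observed count $o_w$ and chain expectation $e_w$ the adjusted
count is

$$
a_w = \begin{cases}
0 & o_w \le 2\\
0 & o_w \le e_w\\
o_w - e_w & \text{otherwise.}
\end{cases}
$$

The $o_w \le 2$ clause screens out single-copy sequence and simple
duplications (a genome that is two exact copies of unique text adjusts to
an all-zero table). The expectation clause subtracts compositional bias:
the chain expectation of a word is
$e_w = N \cdot \hat P(\text{prefix}) \prod_j \hat P(b_j \mid \text{context}_j)$
with $N$ the number of valid k-windows and $\hat P$ maximum-likelihood
frequencies. An order-6 chain can even absorb whole-genome duplication:
in a tetraploid genome a 4-copy gene word has both observed and expected
count near 4, so its adjusted count is near 0.

### Labeling: Gaussian smoothing and the second-derivative test

High scores cluster inside repeats but are noisy, so the score track is
smoothed by a Gaussian-weighted moving mean (mask width about $7\sigma$,
rounded odd; at the sequence ends the mask is truncated and its weight
sum renormalized, so constant tracks are fixed points everywhere).
Discrete derivative approximations over a flank window of $w$ positions —
$f'_i = \sum_{j=i-w}^{i-1} \bar s_j - \sum_{j=i+1}^{i+w} \bar s_j$ and
$f''_i = \sum_{j=i-w}^{i-1} \bar s_j + \sum_{j=i+1}^{i+w} \bar s_j - 2w\bar s_i$
— drive a local-maximum test: a maximum lies where $f'$ changes sign
between consecutive positions and $f''$ there is negative. An exact zero
of $f'$ counts as a sign change on both sides; without this a perfectly
symmetric peak, whose $f'$ passes through 0 exactly at the apex, would be
missed. Of the two positions flanking a crossing the one with the more
negative $f''$ is reported, the left on ties.

Candidate repetitive regions are maximal runs of smoothed scores at or
above a threshold $t$, bridged across sub-threshold gaps shorter than the
mask width and kept only if they contain a detected maximum. Potential
non-repetitive regions are the remaining sub-threshold runs of at least
one mask width. Short ambiguous leftovers are unlabeled and take no part
in training. These delineation rules (run threshold, bridge length,
minimum non-repeat length) are this package's own reconstruction of the
"expand the core until a non-repetitive region is encountered" idea; all
three constants are configurable.

### Self-trained HMM and Viterbi scanning

Scores are treated as a time series: a two-track hidden Markov model has
one *repeat* and one *non-repeat* state per logarithmic output level
$\mathrm{output}(s) = \lceil \log_t s \rceil$ (0 for $s \le 0$), levels
$0..L$ with $L = \lceil \log_t(\max \text{score}) \rceil$. Each state
emits exactly its own level (output probability 1), so the state count is
twice the number of levels. Level 0 gets states on both tracks — the
output map sends every zero-score position there, so it must be
generable; this is why the smallest non-degenerate model has four states.

Priors are the frequencies of the first state of each auto-labeled
region; transitions are frequencies of successive state pairs within
regions, plus one transition between the adjoining states of each pair of
consecutive labeled regions — without those cross-boundary counts the
repeat/non-repeat switching rows would be pure pseudocount and the
segmentation arbitrary. Add-one pseudocounts keep every log-probability
finite. Viterbi decoding (in log space, ties broken toward the
non-repeat track and lower level, so output is deterministic) then
segments the *raw* score track; because each position's level pins the
path to two states, the dynamic program carries just two live states per
position and runs in linear time. Maximal repeat-state runs become the
final regions, each extended by $k-1$ positions on the right (those bases
belong to the region's final k-mer) and merged when extension makes them
abut. The HMM acts as a noise filter in both directions: an isolated
high score inside a long low run decodes as non-repeat, and short low
gaps inside repeats are bridged.

Decoding deliberately uses the raw scores, not the smoothed track: the
smoothed track exists only to delineate training labels, and the scanning
stage consumes the scoring stage's output directly.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | $\lfloor \log_4(\text{valid bases}) \rfloor$, clamped to [8, 16] | word length; at this default a random word's expected count is about 1, so genuine repetition stands out |
| `order` | 6 | background chain order; must be < k. Order 6 is strong enough to capture local composition and polyploidy |
| `sigma` | 40/7 | Gaussian mask standard deviation, giving the canonical mask width of about 40 positions |
| `w` | 10 | derivative flank window |
| `t` | 2 | low-score threshold for labeling, and the HMM log base; base 2 gives the finest level granularity on integer-scale scores |
| `mode` | "genome" | "reads" records that the fit pooled unassembled reads; the machinery is identical, with k derived from the pooled base count and each read scored independently |
| `max_table` | $4^{12}$ | dense-table capacity cap; counting refuses a k whose table would exceed it |

`t = 2`, the mask width, and the delineation constants are design choices
documented above, not values taken from elsewhere; they are exposed so a
user can calibrate them per genome.

## The synthetic study genome

`simulation_spec()` defines the package's standard test conditions: a
1-Mb sequence sampled from an order-3 Markov background (per-context
Dirichlet conditionals around a stated GC composition, concentration 50 —
mild local compositional structure of the kind real genomes show), one
interspersed family of 200 copies of a 500-bp consensus at 5% per-base
divergence and 0.001 indel rate (~10% of the genome, a realistic repeat
load), 50 tandem arrays (motifs of 2–8 bp, 20–100 copies, 2%
divergence), and 20 unique "exon" stretches of 300–1500 bp
(rejection-sampled against 15-mer reuse so exon avoidance has a
meaningful ceiling). All planted intervals are returned as ground truth;
everything is determined by the seed. `scaled_simulation_spec()` holds
this planting density fixed while the length varies, which is how the
linear-time property is checked (detection time at 1 Mb is required to be
at most 2.5 times that at 0.5 Mb).

What the simulator does *not* emulate: real TE structure (LTRs, target
site duplications, nesting), repeat families of mixed age, sequencing
error profiles, and reverse-complement copies (copies are planted on the
forward strand by default, matching the detector's strand-separate
counting; a reverse-complement option exists). Passing the synthetic
recovery tests therefore shows the machinery works as designed, not that
the sensitivity numbers transfer to any particular real genome.

## Numerical choices and degenerate inputs

* All interval arithmetic is 0-based half-open internally and in BED
  output; the human-readable `coords` dialect is 1-based inclusive.
* Ambiguity codes other than N are treated like N: invalid for counting,
  scoring and background training; such positions score 0.
* Smoothing uses exact windowed sums (`stats::filter`), not FFT
  convolution, so the constant-track fixed-point identity holds to
  machine precision.
* `ceiling(log_t s)` is evaluated with a 1e-9 downward tolerance so exact
  powers of t land on their exact level.
* A genome whose maximum score is 0 yields the two-state degenerate
  model; a track shorter than k scores all zero; sequences shorter than
  the chain order contribute nothing to the background.
* If labeling finds no regions at all, training stops with an error
  asking for parameter review; if it finds only non-repeat regions, the
  repeat track keeps pseudocount mass and decoding returns no repeats
  rather than failing.
* Derivative values within w of a sequence end are undefined and excluded
  from the maxima test.

## Evaluation measures

`evaluation_report()` mirrors the standard masking-benchmark table:
class-wise and overall sensitivity $SN = 100\,O/R$ (classes pooled by
interval union, never by summed lengths, so overlapping classes are not
double-counted), exon specificity $SP = 100 - 100\,O/E$, percentage
predicted, false-positive length (total detection on a
composition-matched random genome generated per sequence by an order-6
chain trained on that sequence; subtracting a reference masker's calls on
the random genome is supported but optional, so the unfiltered value is
what the package reports by itself), and potential-repeat content
(predicted bases outside the reference annotation). Ratios with empty
denominators are reported as `NA`, never 0.

## Known limitations

* Pure R with no compiled code: throughput is roughly a megabase per
  second or two for the full pipeline, ample for the bundled study sizes
  but not tuned for gigabase genomes.
* No repeat classification into families; detection only.
* Forward-strand counting means a repeat present only as scattered
  reverse complements is seen as two separate word families.
* The candidate delineation constants are reconstructions (see above);
  on genomes very unlike the study conditions they may need adjustment
  via `t`, `sigma` and the mask width.
* Because candidates on the synthetic study genome already cover ~99.9%
  of planted truth, the HMM's defragmentation mainly reduces region
  count; its base-coverage gain over candidates materializes only when
  candidates are genuinely fragmented.
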