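---
title: "Conservation-state annotation: model, algorithms and design choices"
author: "ConsStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation-state annotation: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConsStates)
```

# The model

ConsStates annotates every base of a reference genome with one of *K*
*conservation states*, learned without supervision from a
reference-anchored multiple-species alignment. At reference position *i*,
each non-reference species *j* contributes exactly one of three
observations: it aligns with a nucleotide equal to the reference base
(align + match), it aligns with a different nucleotide (align +
mismatch), or it contributes no nucleotide (unaligned). The package
encodes these as a binary align indicator $y_{ij}$ and a match indicator
$z_{ij}$ that is *missing* whenever $y_{ij}=0$.

Observations are modelled by a hidden Markov chain along the genome.
Conditional on state *k*, species are independent and each follows a
three-way multinomial parameterized by two Bernoullis:

$$
f_{k,j} = P(y_{ij}=1 \mid s_i=k), \qquad
g_{k,j} = P(z_{ij}=1 \mid y_{ij}=1,\ s_i=k),
$$

giving outcome probabilities $(f g,\; f(1-g),\; 1-f)$. The two
parameterizations are interchangeable (`emissionMultinomial()` performs
the conversion; the third probability is computed as the complement of
the first two so the triple sums to one exactly in floating point).
A length-$K$ initial distribution $a$ applies at the first base of each
independently modelled sequence and a $K \times K$ row-stochastic matrix
$b$ governs transitions between adjacent bases. The likelihood is the
product over sequences of the usual sum over hidden paths.

Key modelling assumptions, stated explicitly:

* **Species independence given the state.** No phylogenetic tree enters
  the emission model; clade structure is *discovered* as correlated
  (f, g) profiles across states, not imposed.
* **Per-species information is reference-relative.** A variant private to
  the reference changes all match observations at that base; the
  annotation is deliberately asymmetric in the reference.
* **Slices are independent sequences.** Genomes are partitioned into
  fixed slices (default 200 kb; `GenomePartition`). Training, decoding
  and the train/test split all operate on slices, and each slice receives
  the initial distribution at its first base. Whether a chain should be
  carried across slice boundaries is unknowable from the annotation
  semantics alone; independence is the simpler contract, it makes
  decoding embarrassingly parallel, and its only cost is an
  $O(K \log K)$-bit loss of information per boundary.

# Encoding alignments

`parseMAF()` reads the 'a'/'s' dialect of MAF (plain or gzip), requires
reference rows on the '+' strand, and projects every block onto reference
coordinates: columns where the reference row carries a gap contribute no
reference position. `encodeObservations()` then fills a per-slice
$T \times (N-1)$ pair of indicator matrices. Rules that the format itself
does not dictate, chosen once and applied everywhere:

* Nucleotide comparison is case-insensitive over A/C/G/T, so soft-masked
  bases are ordinary observations.
* A species 'N' or other ambiguity code is treated as **unaligned**: it
  carries no usable match information, and treating it as aligned would
  force an arbitrary match value.
* A reference 'N' is encoded normally from the other species' rows;
  assembly gaps thus still receive a state downstream rather than being
  masked out.
* Positions covered by no block are all-unaligned — never dropped, so the
  observation matrix always tiles the slice.
* If two blocks assign one species two nucleotides at one position, the
  first block in file order wins and a warning counts the conflicts.
  Reference-anchored alignments are expected to be single-coverage, so
  this is a recovery path, not a feature.
* Species rows absent from a block (including 'e' lines) are unaligned
  there; only 's' rows carry nucleotides.

The binarized slice format (`writeBinarized()` / `readBinarized()`) is a
TSV with a two-line header (reference genome and `chrom.start.end` slice
identifier; then paired `<species>_aligned` / `<species>_matched`
columns) and one row per base, with missing match encoded as `2`. The
round trip is the identity.

# Inference and training

`forwardBackward()` computes exact marginal posteriors and the
log-likelihood with per-position scaling in linear space. Per-position
log emissions are computed in R as three indicator-matrix BLAS products
against the per-state log parameters, then shifted by their row maximum
before exponentiation inside the C++ recursion — with ~100 species a raw
emission product can reach $10^{-300}$, so both safeguards are needed.
The scaled backward pass reuses the forward scaling constants; a second,
independently scaled backward recursion recomputes the log-likelihood as
a numerical cross-check (`@loglikBackward`, tested to 1e-6 relative).
Emission parameters are floored at 1e-300 inside logs to avoid
`0 * -Inf` contamination, and all probabilities are clamped to
[1e-10, 1-1e-10] after each M-step so a subsampled iteration can never
create an absorbing zero.

`baumWelch()` runs an exact number of EM iterations with no
likelihood-based stopping rule. Each iteration samples
`min(segmentsPerIteration, #slices)` slices uniformly without replacement
using the seeded RNG and accumulates expected counts over the sample
only; with subsampling the likelihood legitimately moves both ways
between iterations, which is why no stopping criterion is applied. The
conditional match probability $g$ is re-estimated only from expected
aligned counts — unaligned positions contribute no match information.
With the full data used every iteration, the log-likelihood trajectory is
non-decreasing (verified to 1e-8 per step in the tests). Identical seeds
give bitwise-identical trajectories.

**Initialization.** A single random start (f, g ~ Uniform(0.2, 0.8),
uniform $a$, 0.9-diagonal $b$) is available as `randomModel()`, but EM on
sticky-transition HMMs has strong local optima: on the 4-state clade
preset roughly half of random starts converge ~4.5e4 nats below the
global basin and merge two states. `fitModel()` therefore uses short-run
restarts — by default eight 20-iteration bursts from seeds derived
deterministically from the user seed, keeping the start with the best
burn-in log-likelihood before continuing. The burn-in log-likelihood
separates the basins by orders of magnitude more than its own noise, so
the selection is reliable, and the whole procedure remains reproducible
from one seed. This is the package's deliberate deviation from the
simpler one-start scheme; `baumWelch()` keeps the one-start contract for
callers that want it.

**Model selection.** `bic()` implements
$-2\log L + P \log T$ with $P = (K-1) + K(K-1) + 2K(N-1)$ free
parameters. On real genomes BIC tends to keep decreasing over any
tractable range of $K$, so it is a diagnostic, not an oracle;
`posteriorConfidence()` (mean assigned posterior per state) is the
complementary internal check.

# Decoding, segmentation, enrichment

`decode()` assigns each base the maximum-posterior state, ties broken
toward the lower state index (a deterministic, order-independent rule).
`mergeSegmentation()` concatenates per-slice paths and merges runs across
boundaries, so the result is provably independent of where slice
boundaries fall. `uniformTransitionModel()` replaces $b$ with $1/K$
everywhere — removing the learned self-transition smoothing — and
`annotationAgreement()` / `countSegments()` quantify the effect: on
simulated data the uniform-transition decoding produces several-fold more
segments (the tests check the direction, not a magnitude, since the
magnitude is data-dependent).

Fold enrichment of a state for an annotation is the percentage of
annotation bases in the state divided by the percentage of the background
universe in the state. A base counts once (annotations are merged), and
restricting the universe implements every background-restricted analysis
(non-coding backgrounds, motif-discovery backgrounds) with one code path;
`relativeEnrichment()` divides foreground by background folds where a
two-step normalization is wanted. `neighborhoodEnrichment()` computes the
same quantity per signed offset around anchor points at single-base
spacing, mirroring offsets on minus-strand anchors so positive offsets
are always downstream; each offset is normalized by the anchors actually
contributing there (anchors whose offset leaves the segmented extent are
skipped, a choice the underlying definition leaves open).
`rankGenesByState()` counts in-state bases in a symmetric window around
each gene's TSS; the window includes both endpoints (2·window + 1 bases —
endpoint inclusion is stated here precisely because conventions differ)
and ties rank lexicographically by gene id so top-gene sets are
deterministic.

# Precision–recall machinery

`splitTrainTest()` halves the slices at random (sizes within one).
`prByStates()` orders states by training-half fold enrichment for the
target and accumulates test-half bases state by state; precision of an
empty cumulative set is reported missing rather than invented.
`binScore()` turns a per-base score into equal-occupancy bins: undefined
bases form one bin, defined bases are split as evenly as possible among
the remaining bins in descending score order, and a run of equal scores
straddling a boundary is split *proportionally*, assigning its individual
bases uniformly at random under the seeded RNG — the one place
randomness enters evaluation, chosen because any deterministic
base-order rule would bias bins spatially. `prByRawScore()` thresholds
at every distinct score with undefined bases last; `prPointElements()`
reduces an element set to one precision/recall point;
`topFractionSet()` picks the distinct-score threshold whose top set is
closest in size to the requested fraction (ties to the smaller set,
which makes the sets nest across fractions), counting score-undefined
bases toward the universe but ranking them below everything.
`concatTargets()` / `replicateAcrossSamples()` build the concatenated
pseudo-genome (chromosome#sample) used to pool targets across many
samples without changing any downstream code.

# State clustering

States are clustered on the concatenated $[f, f \cdot g]$ vectors
(align probability and joint align-and-match probability per species)
with distance one minus Pearson correlation. The linkage is complete —
the default of the classic R implementation this analysis style comes
from; the choice is recorded in the output object since the literature
rarely states it. Leaves are reordered by an exact dynamic program over
the dendrogram that minimizes the summed distance between adjacent
leaves among all $2^{K-1}$ tree-consistent orders; the tests verify
optimality against exhaustive search up to $K = 8$. A zero-variance
feature vector makes correlation undefined and is reported as an error
naming the state rather than silently patched.
`clusterEnrichmentMatrix()` retains states with at least a 2-fold
enrichment in some sample, log2-transforms (flooring folds at 0.01 so
zeros stay finite and rank-preserving), z-normalizes each state across
samples, and clusters rows and columns by correlation distance.

# The synthetic-data generator

`simulateAlignment()` draws state paths from $(a, b)$ per slice and
observations from $(f, g)$ — exactly the model's own generative
assumptions. `emitMAF()` realizes observations as alignment text:
reference bases uniform over A/C/G/T, matching species copying the
reference, mismatching species drawing uniformly from the other three
bases, unaligned species as gaps or omitted rows, blocks broken at
all-unaligned runs and at 10 kb. Ambiguity codes are never emitted, so
`encodeMAF(emitMAF(truth))` reproduces the simulated observations
bit-exactly — the property that ties the whole I/O path together.

`presetCladeModel()` is the fixed truth used in recovery experiments:
species in three nested clades, states mimicking the canonical patterns
of vertebrate alignments (conserved everywhere, inner-clades only,
close-clade only, align-without-match, essentially unaligned, plus
graded intermediates), sticky 0.99 self-transitions. For $K \le 5$ every
state pair differs by at least 2 in emission-vector L1 distance, which
is what makes ≥95% decoding accuracy a fair expectation. Recovery tests
match EM's arbitrary labels to truth by exhaustive minimum-cost
assignment on the (f, g) rows (`matchStates()`; labels are not
identifiable in EM).

What the generator deliberately does **not** emulate: phylogenetic
substitution processes (no tree, no rate matrices, no branch lengths),
indels in the reference, sequencing or assembly error, N's, and spatial
autocorrelation beyond what the Markov chain provides. Passing the
recovery and round-trip tests therefore demonstrates that the
implementation is faithful to its own model — not that the model
captures everything in real alignments.

# Problem sizes and tolerances

The test suite works at sizes chosen to make each property sharp yet
quick: brute-force path enumeration up to $K^T = 3^8$; emission-form
agreement to 1e-12 on $10^4$ random observations; EM monotonicity over
50 full-data iterations on 50 kb; parameter recovery (≤ 0.05 max
absolute error on f, g, b after matching, ≥ 95% decoding agreement) from
500 kb and 300 iterations; enrichment and precision–recall checked
exactly against per-base counting on 30–1000-base toys; leaf ordering
against exhaustive search up to $K = 8$; and a 100 kb end-to-end run of
the command-line pipeline. `scripts/acceptance.R` re-runs the 500 kb
recovery experiment and the other headline computations from a single
seed.

# Known limitations

* Pure-R per-base expansion in `binScore()`/`topFractionSet()` is meant
  for evaluation-scale regions (megabases), not whole mammalian genomes.
* `parseMAF()` reads a file into memory; genome-scale MAFs should be
  pre-split by chromosome.
* Reverse-strand reference rows and HAL/chain inputs are out of scope.
* BIC and posterior confidence guide but do not decide $K$; on rich real
  data both favor large models, and the choice of $K$ remains the
  analyst's.
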