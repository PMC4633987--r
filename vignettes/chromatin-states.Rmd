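---
title: "Window-based chromatin-state analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based chromatin-state analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstates)
```

# The analysis in one paragraph

`chromstates` implements a window-based analysis of histone-mark ChIP-seq
across cell-differentiation stages. Tag counts in sliding 1 kb windows
(0.5 kb step) are library-normalized and converted into a pseudo-count
log2 enrichment over input; thresholded windows are merged into regions.
Promoter-distal, H3K4me3-depleted H3K4me1 regions are putative enhancers,
classified as **active** (H3K27ac), **poised** (H3K27me3) or **primed**
(H3K4me1 only). Enhancers are assigned to their closest promoter within
500 kb, active enhancers first. Cross-stage dynamics are measured by
re-scoring one stage's regions in another stage's tracks at fixed
coordinates. Broad H3K9me2 heterochromatin is segmented on a 5 kb tiling
grid with a two-state Gaussian-emission hidden Markov model trained by
Baum–Welch on the first chromosome and decoded genome-wide with Viterbi.
A synthetic-data generator draws a full ground truth (states, domains,
expression classes) and the corresponding noisy observables, so the whole
analysis runs self-contained with known answers.

# The enrichment statistic

For a window with library-normalized counts $c$ (ChIP) and $i$ (input),

$$ e = \log_2 \frac{c + 8}{i + 8}. $$

Normalization scales each sample's counts by (mean raw total) / (its raw
total), so all samples are brought to the mean library size before the
pseudo-count is added; normalized counts are non-integer, and the
pseudo-count of 8 tags applies to the scaled values. The pseudo-count
keeps $e$ finite everywhere and shrinks low-count windows towards zero,
which suppresses spurious high ratios in sparse regions. Replicate tracks
are averaged per window (arithmetic mean of log2 values).

Thresholds are inclusive (`>= cutoff`): the calling cutoff for H3K4me1,
H3K27ac and H3K27me3 is 1.5 on the log2 scale (roughly 3-fold);
H3K4me3 below 1 counts as depleted and above 3 as positive. Boundary
windows are measure-zero on continuous scores, so the inclusive choice is
a tie-break, not a sensitivity knob.

Coordinates are 0-based, half-open everywhere (BED convention), including
overlap tests: intervals that share only a boundary do not overlap, so
book-ended windows are *not* merged and a region ending where a domain
starts does not count as overlapping it.

# Enhancer identification and classification

1. H3K4me1 windows at or above 1.5 are merged into regions (maximal unions
   of coordinate-intersecting windows).
2. A region's score on any track is the **maximum** over the windows that
   overlap it. A region exists because at least one window passed the
   cutoff, so max-aggregation keeps calling and scoring consistent: a
   merged run of called windows always scores at or above the calling
   cutoff. Mean-aggregation would not have this property (edge windows
   dilute it).
3. Regions sharing any base with a promoter (non-overlapping
   TSS ± 1 kb intervals; first-kept-wins de-overlapping in coordinate
   order) are excluded, as are regions with H3K4me3 score ≥ 1. Scores in
   the ambiguous H3K4me3 band (1, 3) are excluded too — conservative, and
   configurable.
4. Classification is a total three-way rule: H3K27ac ≥ 1.5 → active;
   otherwise H3K27me3 ≥ 1.5 → poised; otherwise primed. A region above
   both cutoffs is classified **active** — acetylation is the activity
   mark and the bivalent combination is rare — and flagged in a
   `bivalent_flag` audit column rather than made a fourth class.

# Enhancer–promoter assignment

Distance is |enhancer midpoint − TSS| (the edge-to-TSS alternative differs
only for very wide regions); ties go to the lower genomic coordinate so
the assignment is deterministic. Pass 1 links each active enhancer to its
nearest promoter within 500 kb; promoters that received an active link are
then removed, and pass 2 links primed and poised enhancers to the nearest
remaining promoter. Consumption is per promoter interval that actually
received a link, not per gene. Enhancers with no promoter in range stay
unassigned. Gene expression is the exonic read count scaled to the mean
library total and to the mean unique exonic length (the union of exon
intervals across transcripts). Binarization into expressed/silent uses,
by default, the antimode of the bimodal log2 distribution — the density
minimum between the two largest modes — and can be overridden with a fixed
threshold.

# Cross-stage dynamics

Transitions are evaluated at **fixed source-stage coordinates**: the
source regions are re-scored in the target stage's tracks with the same
max-over-windows rule, not re-called, so region drift and resizing are
deliberately ignored. The outcome rule is a quadrant assignment: K4me1
and K27ac both above cutoff → active; K4me1 only → primed (or poised when
a target K27me3 track is supplied and passes its cutoff); K4me1 below
cutoff → closed, regardless of K27ac. K4me1⁻/K27ac⁺ regions are real but
unnamed in the field's scatter plots; they are counted closed here and
reported separately in an `acetyl_retained` audit column. With several
target stages the table also reports the union outcome ("active in any
later stage"). Poised-outcome tracking is enabled only when a target
K27me3 track exists; without it the pipeline warns and completes.

# Heterochromatin segmentation

The H3K9me2 log2 enrichment on the 5 kb tiling grid separates into broad
positive and negative domains, modelled as a two-state HMM with Gaussian
emissions. The standard starting model is: initial probability 1 of the
enriched state, symmetric transitions with stay-probability 0.9, emissions
$\mathcal N(-1, 0.5)$ (depleted) and $\mathcal N(+1, 0.5)$ (enriched).
Training runs Baum–Welch on the first chromosome of the genome
(configurable); decoding runs Viterbi per chromosome genome-wide **with
the fitted model**, including the fitted initial distribution — the
printed starting values are an EM initialization, not the decoding model.

Numerical choices:

* log-space forward/backward (no scaling underflow); the contract is
  exactness of Viterbi and monotone EM, not a particular scheme — Viterbi
  is tested against exhaustive enumeration over all $2^n$ paths for
  $n \le 12$, EM against its monotonicity guarantee;
* relative log-likelihood tolerance $10^{-6}$, at most 500 iterations;
* variance floor $10^{-3}$; all-identical input returns a floored model
  with a warning instead of collapsing;
* label switching after EM is resolved by calling the larger-mean state
  "enriched";
* only windows with at least one read in any K9me2 or input sample of any
  stage are retained; the state sequence is defined over retained windows
  only, so a domain spans the genomic gap between its first and last
  retained window — an enriched run bridges dropped windows. This matches
  training on the gapped sequence and is stated loudly because it can
  bridge assembly holes.

Domain statistics are base-level: the multi-stage Venn partition is built
by disjoining the union of all domain sets and classifying each disjoint
piece by stage membership, so the cells sum to the union size exactly.

# What the generator emulates — and what it does not

The generator draws the latent truth first and the observables from it:

* **Genome**: 2 chromosomes × 20 Mb. Sizing matters: marked features must
  occupy only a few percent of the genome, as in real chromatin. On a
  much smaller toy genome the same feature counts would cover ~15% of the
  sequence, and normalizing every library to the mean total then visibly
  compresses the enrichment scale (ChIP libraries would carry a large
  signal mass that input lacks). That is a property of dense toys, not of
  the method, so the default keeps density realistic.
* **Features**: 300 genes on a jittered lattice (promoters never overlap);
  500 enhancers of 2 kb placed ≥ 3.5 kb from every TSS and ≥ 3 kb apart,
  so a called enhancer can never chain into a promoter region during
  merging (the stored truth invariant is the weaker ≥ 2 kb).
* **States**: stage-1 enhancer states drawn from
  (active .40, primed .45, poised .05, closed .10); later stages follow a
  4×4 transition chain whose defaults encode rare priming-to-activation
  (primed→active 0.04), predominant closing (primed→closed 0.80) and
  mostly de novo establishment of later active enhancers.
* **Counts**: tags are Poisson at the 0.5 kb step-bin level with mean =
  background (20 per 1 kb window) × fold (8 for a carried mark, 12 for
  promoter H3K4me3), then summed into sliding windows, so overlapping
  windows share tags and library totals are exact. A negative-binomial
  switch adds overdispersion if wanted. Promoters carry H3K4me1 + H3K4me3;
  active enhancers H3K4me1 + H3K27ac; poised H3K4me1 + H3K27me3; primed
  H3K4me1 only.
* **Heterochromatin**: one two-state Markov chain (stay 0.9, stationary
  at 1/2) shared by all stages by default — the observed landscape is
  largely stage-invariant — with independent Gaussian noise
  (SD $\sqrt{0.5}$) per stage. Sharing plus independent noise gives a
  between-stage track correlation with closed form
  $\rho = \mathrm{Var}(S)/(\mathrm{Var}(S) + 0.5) = 1/1.5 = 2/3$
  for states at ±1; the tests assert the empirical correlation against
  this derived value. Each enhancer lies inside a true domain with
  probability 0.15 (otherwise strictly outside, with a 5 kb margin on
  both conditions so decoding wobble at domain edges cannot blur the
  truth assignment).
* **Expression**: negative binomial (dispersion 0.1), mean proportional
  to exonic length, expressed-state probability 0.95/0.60/0.25 for genes
  whose truly linked enhancers include an active one / only primed or
  poised ones / none, and mean increasing with the number of truly active
  linked enhancers. Silent genes sit near zero.
* **Seeds**: one master seed; every sub-simulation derives its own child
  stream from the seed and a component tag, so outputs are byte-identical
  across re-runs and robust to re-ordering of components.

Not emulated: raw reads (no FASTQ), mappability and GC bias, duplicate
reads, diploidy, region drift between stages (truth enhancers keep fixed
coordinates), and any coupling between heterochromatin and the point
marks beyond the placement probability. Passing tests therefore
demonstrate the correctness of the computations and the recoverability of
a clean truth at realistic SNR — not robustness to alignment artifacts or
copy-number structure.

# Problem sizes

The test suite runs the full default design (40 Mb, 500 enhancers) once
and shares the result across tests; module tests use a quarter-size
configuration with the same feature sparsity. The EM recovery check uses
5,000 windows; Viterbi exactness uses 100 random sequences of up to 12
windows; assignment is checked against a brute-force oracle on 200 random
layouts of up to 30×30. The whole suite completes in about a minute on
one CPU, and the acceptance script in well under one.

# Known limitations

* The antimode threshold assumes a clearly bimodal expression
  distribution; unimodal data fall back to the mid-range, and a fixed
  threshold should be preferred there.
* Max-aggregation makes region scores grow slowly with region width
  (extreme-value effect); comparisons should stay within similarly sized
  regions.
* The HMM assumes homoscedastic Gaussian emissions per state; heavy-tailed
  enrichment noise would call for a t emission or a third state, which is
  out of scope.
* Sliding-window counts are correlated between overlapping windows by
  construction; downstream inferences treat windows as exchangeable only
  where grids are non-overlapping (the 5 kb tiling grid).
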