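# chromstates

Window-based chromatin-state analysis of enhancers and heterochromatin
across cell-differentiation stages.

During differentiation — for example from haematopoietic stem/progenitor
cells through committed progenitors to mature effector cells — the
regulatory genome is rewritten: distal enhancers appear, switch state and
close, while megabase-scale heterochromatin stays comparatively stable.
`chromstates` is for computational biologists who want a tested, fully
reproducible implementation of the classic window-based recipe for
quantifying this from histone-mark ChIP-seq:

* **Enrichment scoring.** Tags (shifted ±60 bp towards the fragment
  midpoint) are counted in sliding 1 kb windows at a 0.5 kb step,
  libraries are normalized to the mean total, and each window is scored as
  `e = log2((chip + 8) / (input + 8))`, with replicate tracks averaged.
  Windows with `e ≥ 1.5` are merged into regions.
* **Enhancer classification.** Promoter-distal (TSS ± 1 kb excluded),
  H3K4me3-depleted H3K4me1 regions are putative enhancers:
  H3K4me1⁺/H3K27ac⁺ = **active**, H3K4me1⁺/H3K27me3⁺ = **poised**,
  H3K4me1 only = **primed**.
* **Gene linking.** Each enhancer is assigned to its closest promoter
  within 500 kb — active enhancers first, and promoters taken by an active
  enhancer are withheld from primed/poised assignment. Expression is
  exonic counts normalized to library size and unique exonic length.
* **Dynamics.** A stage's regions are re-scored in another stage's tracks
  at fixed coordinates and classified active / primed / closed (poised
  when H3K27me3 is supplied), yielding transition tables and
  presence/absence repertoire matrices with base-level Jaccard
  similarities.
* **Heterochromatin.** H3K9me2 log2 enrichment on a 5 kb tiling grid is
  segmented by a two-state Gaussian-emission HMM — Baum–Welch training on
  chromosome 1 starting from π = (0, 1), stay-probability 0.9 and
  emissions N(−1, 0.5) / N(+1, 0.5), then genome-wide Viterbi decoding —
  into enriched/depleted domains, with genome fractions, cross-stage Venn
  partitions, track correlations and enhancer-domain overlap.

A synthetic-data generator simulates a toy genome with ground-truth
enhancer states per stage, heterochromatin domains, expression classes and
all ChIP/input/RNA observables, so the complete analysis runs end-to-end
with known answers and no downloads.

## Worked example

```r
library(chromstates)
bundle <- run_pipeline(sim_config(seed = 1))
```

```
[chromstates] simulate: genome + truth (seed 1)
[chromstates] simulate: 300 genes, 500 enhancers on 2 chromosome(s)
[chromstates] windows: enrichment tracks (K4me1, K4me3, K27ac, K27me3)
[chromstates] enhancer_calling: per-stage classification
[chromstates]   HSC: 456 enhancers (active 44.3%, primed 51.3%, poised 4.4%)
[chromstates]   ProB: 172 enhancers (active 62.2%, primed 29.1%, poised 8.7%)
[chromstates]   MatB: 116 enhancers (active 69.0%, primed 25.0%, poised 6.0%)
[chromstates] gene_linking: expression + assignment
[chromstates] dynamics: transitions from HSC
[chromstates] heterochromatin_hmm: K9me2 segmentation
[chromstates]   HSC: 343 domains, 48.9% of retained genome, 97.0% base accuracy
[chromstates]   ProB: 369 domains, 48.8% of retained genome, 97.5% base accuracy
[chromstates]   MatB: 343 domains, 49.0% of retained genome, 97.2% base accuracy
[chromstates] dynamics x heterochromatin: 14.8% of closed enhancers in K9me2 domains
```

Reading the log: of the 500 simulated enhancers, 456 are marked (not
closed) at the first stage and all are recovered with their correct state
(the configured stage-1 mix is 40/45/5% of all 500, i.e. 44/50/6% of the
marked ones). The HMM covers ~49% of the genome with domains (the truth
chain is stationary at 50%) at ~97% per-window accuracy, and 14.8% of the
enhancers that close between the first two stages fall inside decoded
heterochromatin domains (the generator places 15% of enhancers inside
true domains). The transition table from first-stage primed enhancers:

```r
tt <- bundle$transitions$primed
round(tt[tt$target != "any", c("n", "frac_active", "frac_primed", "frac_closed")], 3)
#>     n frac_active frac_primed frac_closed
#> 1 234       0.043       0.141       0.816
#> 2 234       0.068       0.077       0.855
```

Row 1 is the second stage: 4.3% of primed enhancers become active and
81.6% close — recovering the generator's configured 0.04 and 0.80.

The numbered scripts under `analysis/` run the same study step by step
(simulation, enrichment, enhancer states, expression linking, transitions,
heterochromatin) and write their tables under `results/`.

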