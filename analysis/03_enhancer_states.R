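#!/usr/bin/env Rscript
# Enhancer identification and three-state classification per stage, with
# recovery scored against the simulated ground truth.

source("analysis/00_common.R")

bundle <- get_bundle(seed = 1)
truth <- bundle$truth

comp <- do.call(rbind, lapply(names(bundle$state_counts), function(st) {
  sc <- bundle$state_counts[[st]]
  data.frame(stage = st, state = sc$state, n = sc$n,
             pct = round(100 * sc$fraction, 1))
}))
print(comp)
write_tsv(comp, "enhancer_state_fractions.tsv")

for (st in names(bundle$enhancers)) {
  es <- bundle$enhancers[[st]]
  gr_es <- GenomicRanges::GRanges(es$chrom,
                                  IRanges::IRanges(es$start + 1, es$end))
  gr_tr <- GenomicRanges::GRanges(
    truth$enhancers$chrom,
    IRanges::IRanges(truth$enhancers$start + 1, truth$enhancers$end))
  hits <- GenomicRanges::findOverlaps(gr_es, gr_tr)
  ts <- truth$enhancers[[paste0("state_", st)]][S4Vectors::subjectHits(hits)]
  cs <- as.character(es$state)[S4Vectors::queryHits(hits)]
  message(sprintf(
    "%s: %d called, %.1f%% of matched regions in the true state",
    st, nrow(es), 100 * mean(cs == ts)))
  es$name <- as.character(es$state)
  write_bed(es, file.path(RESULTS, sprintf("enhancers_%s.bed", st)))
}
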