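#!/usr/bin/env Rscript
# H3K9me2 heterochromatin: two-state Gaussian-HMM segmentation per stage,
# genome fractions, cross-stage stability, and overlap of closed enhancers
# with the decoded domains.

source("analysis/00_common.R")

bundle <- get_bundle(seed = 1)
stages <- names(bundle$k9)

fit_tab <- do.call(rbind, lapply(stages, function(st) {
  k <- bundle$k9[[st]]
  data.frame(stage = st,
             mean_depleted = round(k$model$means[1], 3),
             mean_enriched = round(k$model$means[2], 3),
             stay_prob = round(mean(diag(k$model$trans)), 3),
             em_iterations = length(k$model$loglik),
             n_domains = nrow(k$domains),
             genome_pct = round(100 * k$fraction, 1),
             base_accuracy_pct = round(100 * k$accuracy, 1))
}))
print(fit_tab)
write_tsv(fit_tab, "k9_model_fits.tsv")

for (st in stages) {
  write_bed(bundle$k9[[st]]$domains,
            file.path(RESULTS, sprintf("k9_domains_%s.bed", st)))
}

venn <- bundle$k9_venn
venn$Mb <- round(venn$bases / 1e6, 2)
print(venn)
write_tsv(venn, "k9_domain_venn.tsv")

corr <- bundle$k9_correlations
write_tsv(data.frame(stage = rownames(corr), round(corr, 3)),
          "k9_correlations.tsv")
message(sprintf("pairwise track correlations: HSC-ProB %.2f, ProB-MatB %.2f",
                corr["HSC", "ProB"], corr["ProB", "MatB"]))

co <- bundle$closed_enhancer_overlap
message(sprintf(
  "enhancers marked in HSC but closed in ProB: %.1f%% fall in ProB K9me2 domains (n=%d)",
  100 * co$fraction_overlapping, co$n))
write_tsv(data.frame(n_closed = co$n, n_in_domain = co$n_overlapping,
                     pct_in_domain = round(100 * co$fraction_overlapping, 1)),
          "closed_enhancer_k9_overlap.tsv")
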