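#!/usr/bin/env Rscript
# Cross-stage enhancer dynamics: transition tables at fixed first-stage
# coordinates, and the presence/absence repertoire matrix across stages.

source("analysis/00_common.R")

bundle <- get_bundle(seed = 1)

tp <- bundle$transitions$primed
ta <- bundle$transitions$active
print(tp)
write_tsv(tp, "transitions_primed_HSC.tsv")
write_tsv(ta, "transitions_active_HSC.tsv")

row2 <- tp[tp$target == "ProB", ]
message(sprintf(
  "primed (HSC) -> ProB: %.1f%% active, %.1f%% still primed, %.1f%% closed (n=%d)",
  100 * row2$frac_active, 100 * row2$frac_primed, 100 * row2$frac_closed,
  row2$n))
any_row <- tp[tp$target == "any", ]
message(sprintf("primed (HSC) active in ANY later stage: %.1f%%",
                100 * any_row$frac_active))

pm <- bundle$presence
jac <- attr(pm, "jaccard")
write_tsv(pm, "presence_matrix.tsv")
write_tsv(data.frame(stage = rownames(jac), round(jac, 3)),
          "repertoire_jaccard.tsv")
message(sprintf(
  "repertoire similarity (Jaccard): ProB-MatB %.2f vs HSC-ProB %.2f",
  jac["ProB", "MatB"], jac["HSC", "ProB"]))
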