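#!/usr/bin/env Rscript
# Enhancer-promoter assignment (two-pass, active first) and the relation
# between expression, enhancer class and active-enhancer count.

source("analysis/00_common.R")

bundle <- get_bundle(seed = 1)

for (st in names(bundle$links)) {
  links <- bundle$links[[st]]
  expr <- bundle$expression[[st]]
  message(sprintf("%s: %d of %d enhancers assigned to a promoter (<500 kb)",
                  st, nrow(links), nrow(bundle$enhancers[[st]])))
  by_cls <- expression_by_class(links, expr)
  print(by_cls)
  write_tsv(by_cls, sprintf("expression_by_class_%s.tsv", st))
  by_cnt <- expression_by_active_count(links, expr)
  write_tsv(by_cnt, sprintf("expression_by_active_count_%s.tsv", st))
  write_tsv(links, sprintf("links_%s.tsv", st))
}

# the headline ordering at the first stage
by_cls <- bundle$expr_by_class$HSC
med <- setNames(by_cls$median, by_cls$class)
message(sprintf(
  "HSC median expression: active-linked %.0f > primed-linked %.0f > unlinked %.0f",
  med["active"], med["primed"], med["none"]))
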