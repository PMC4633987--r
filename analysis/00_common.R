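# Shared setup for the numbered analysis scripts: one pipeline run on the
# default study design, cached on disk so each script can be re-run alone.

suppressMessages(library(chromstates))

RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

get_bundle <- function(seed = 1) {
  cache <- file.path(RESULTS, sprintf("bundle_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  bundle <- run_pipeline(sim_config(seed = seed))
  saveRDS(bundle, cache)
  bundle
}

write_tsv <- function(x, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
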