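# End-to-end orchestration on a synthetic dataset: simulate, score, call,
# link, compare stages, segment heterochromatin, and write all tables.

#' Replicate-averaged enrichment track for one mark and stage
#'
#' Simulates ChIP and input counts, normalizes all libraries of the
#' mark/stage jointly to their mean total, averages the normalized input
#' replicates into one reference, scores each ChIP replicate with the
#' pseudo-count log2 enrichment and averages the replicate tracks.
#'
#' @param truth,genome,config See [simulate_chip_counts()].
#' @param mark,stage Mark and stage name.
#' @return An [enrichment_track()].
#' @export
stage_track <- function(truth, genome, mark, stage, config) {
  sim <- simulate_chip_counts(truth, genome, mark, stage, config)
  joint <- count_matrix(sim$grid,
                        cbind(sim$chip$counts, sim$input$counts),
                        c(sim$chip$totals, sim$input$totals))
  joint <- normalize_libraries(joint)
  n_chip <- ncol(sim$chip$counts)
  chip_n <- joint$counts[, seq_len(n_chip), drop = FALSE]
  input_n <- joint$counts[, -seq_len(n_chip), drop = FALSE]
  input_ref <- rowMeans(input_n)
  reps <- lapply(seq_len(n_chip), function(r) {
    enrichment_track(sim$grid,
                     enrichment(chip_n[, r], input_ref, config$pseudo),
                     mark = mark, stage = stage)
  })
  average_replicates(reps)
}

#' Run the complete analysis on a synthetic dataset
#'
#' Simulates the truth and all observables for every stage, then runs the
#' full window/enhancer/linking/dynamics/heterochromatin analysis and
#' (optionally) writes every result table plus a run manifest to
#' `out_dir`. Stages of the computation are logged with counts. If
#' `"K27me3"` is excluded from `marks`, poised classification is disabled
#' with a warning and the run completes.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (`NULL` = return results only).
#' @param marks ChIP marks to simulate and use.
#' @return Invisibly, a list bundle: `truth`, `tracks`, `enhancers`,
#'   `state_counts`, `expression`, `links`, `expr_by_class`, `transitions`,
#'   `presence`, `k9` (model, paths, domains, fractions, overlap, venn,
#'   correlations) and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         marks = c("K4me1", "K4me3", "K27ac", "K27me3")) {
  t0 <- Sys.time()
  log_step <- function(...) message("[chromstates] ", sprintf(...))
  stages <- config$stages
  use_k27me3 <- "K27me3" %in% marks
  if (!use_k27me3) {
    warning("H3K27me3 not supplied: poised classification disabled",
            call. = FALSE)
  }

  log_step("simulate: genome + truth (seed %d)", config$seed)
  genome <- simulate_genome(config)
  truth <- simulate_truth(genome, config)
  promoters <- truth$promoters
  log_step("simulate: %d genes, %d enhancers on %d chromosome(s)",
           nrow(truth$genes), nrow(truth$enhancers), length(genome))

  log_step("windows: enrichment tracks (%s)", paste(marks, collapse = ", "))
  tracks <- lapply(stages, function(st) {
    tr <- lapply(marks, function(mk)
      stage_track(truth, genome, mk, st, config))
    names(tr) <- marks
    tr
  })
  names(tracks) <- stages

  log_step("enhancer_calling: per-stage classification")
  enhancers <- lapply(stages, function(st) {
    es <- call_enhancers(tracks[[st]]$K4me1, tracks[[st]]$K4me3,
                         tracks[[st]]$K27ac,
                         if (use_k27me3) tracks[[st]]$K27me3 else NULL,
                         promoters, stage = st)
    es$id <- sprintf("%s_enh%04d", st, seq_len(nrow(es)))
    es
  })
  names(enhancers) <- stages
  counts_tab <- lapply(enhancers, state_counts)
  for (st in stages) {
    log_step("  %s: %d enhancers (%s)", st, nrow(enhancers[[st]]),
             paste(sprintf("%s %.1f%%", counts_tab[[st]]$state,
                           100 * counts_tab[[st]]$fraction),
                   collapse = ", "))
  }

  log_step("gene_linking: expression + assignment")
  expr <- lapply(stages, function(st) {
    rna <- simulate_rnaseq(truth, config, st)
    q <- quantify_expression(rna$count, rna$exonic_length, rna$gene)
    q$value <- q$norm_sample1
    q$class <- binarize_expression(q$value)
    q
  })
  names(expr) <- stages
  links <- lapply(stages, function(st)
    assign_enhancers(enhancers[[st]], promoters))
  names(links) <- stages
  expr_by_class <- lapply(stages, function(st)
    expression_by_class(links[[st]], expr[[st]]))
  names(expr_by_class) <- stages

  transitions <- NULL
  presence <- NULL
  if (length(stages) > 1) {
    log_step("dynamics: transitions from %s", stages[1])
    target_list <- lapply(stages[-1], function(st) {
      tl <- list(k4me1 = tracks[[st]]$K4me1, k27ac = tracks[[st]]$K27ac)
      if (use_k27me3) tl$k27me3 <- tracks[[st]]$K27me3
      tl
    })
    names(target_list) <- stages[-1]
    transitions <- list(
      primed = transition_fractions(enhancers[[stages[1]]], "primed",
                                    target_list),
      active = transition_fractions(enhancers[[stages[1]]], "active",
                                    target_list))
    presence <- presence_matrix(lapply(enhancers, function(e)
      e[, c("chrom", "start", "end")]))
  }

  log_step("heterochromatin_hmm: K9me2 segmentation")
  k9 <- lapply(stages, function(st) {
    sim <- simulate_k9me2_track(genome, config, truth, st)
    train_chrom <- names(genome)[1]
    fit <- em_fit(sim$track$score[sim$track$chrom == train_chrom])
    path <- unlist(lapply(names(genome), function(chr)
      viterbi(fit, sim$track$score[sim$track$chrom == chr])))
    domains <- states_to_domains(path, sim$track)
    list(track = sim$track, true_states = sim$states,
         true_domains = sim$domains, model = fit, path = path,
         domains = domains, fraction = genome_fraction(path),
         accuracy = mean(path == sim$states))
  })
  names(k9) <- stages
  for (st in stages) {
    log_step("  %s: %d domains, %.1f%% of retained genome, %.1f%% base accuracy",
             st, nrow(k9[[st]]$domains), 100 * k9[[st]]$fraction,
             100 * k9[[st]]$accuracy)
  }
  venn <- if (length(stages) > 1)
    domain_overlap(lapply(k9, `[[`, "domains")) else NULL
  correlations <- if (length(stages) > 1) {
    m <- matrix(1, length(stages), length(stages),
                dimnames = list(stages, stages))
    for (i in seq_along(stages)[-length(stages)]) {
      for (j in (i + 1):length(stages)) {
        m[i, j] <- m[j, i] <- correlate_tracks(k9[[i]]$track, k9[[j]]$track)
      }
    }
    m
  } else NULL

  closed_overlap <- NULL
  if (length(stages) > 1) {
    src <- enhancers[[stages[1]]]
    sc2 <- rescore_in_stage(src, tracks[[stages[2]]]$K4me1,
                            tracks[[stages[2]]]$K27ac)
    closed <- src[classify_transition(sc2$k4me1, sc2$k27ac) == "closed", ,
                  drop = FALSE]
    closed_overlap <- enhancer_domain_overlap(closed,
                                              k9[[stages[2]]]$domains)
    log_step("dynamics x heterochromatin: %.1f%% of closed enhancers in K9me2 domains",
             100 * closed_overlap$fraction_overlapping)
  }

  manifest <- list(
    package = "chromstates",
    version = as.character(utils::packageVersion("chromstates")),
    seed = config$seed,
    stages = stages,
    parameters = list(window_size = config$window_size, step = config$step,
                      k9_window = config$k9_window, pseudo = config$pseudo,
                      background = config$background,
                      n_enhancers = config$n_enhancers,
                      n_genes = config$n_genes),
    steps = stats::setNames(
      rep("completed", 7),
      c("synthetic_data", "windows", "enhancer_calling", "gene_linking",
        "dynamics", "heterochromatin_hmm", "io")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(truth = truth, tracks = tracks, enhancers = enhancers,
                 state_counts = counts_tab, expression = expr,
                 links = links, expr_by_class = expr_by_class,
                 transitions = transitions, presence = presence, k9 = k9,
                 k9_venn = venn, k9_correlations = correlations,
                 closed_enhancer_overlap = closed_overlap,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, config)
    log_step("io: results written to %s", out_dir)
  }
  invisible(bundle)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Serialize every table of a pipeline bundle under out_dir.
write_bundle <- function(bundle, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  write_gene_models(bundle$truth$genes, file.path(out_dir, "genes.refgene"))
  tb <- bundle$truth$enhancers
  tb$name <- tb[[paste0("state_", stages[1])]]
  write_bed(tb, file.path(out_dir, "truth_enhancers.bed"))
  for (st in stages) {
    es <- bundle$enhancers[[st]]
    es$name <- as.character(es$state)
    write_bed(es, file.path(out_dir, sprintf("enhancers_%s.bed", st)))
    write_tsv(as.data.frame(es)[, c("id", "chrom", "start", "end", "k4me1",
                                    "k4me3", "k27ac", "k27me3", "state")],
              file.path(out_dir, sprintf("enhancer_scores_%s.tsv", st)))
    write_tsv(bundle$expression[[st]][, c("gene", "value", "class")],
              file.path(out_dir, sprintf("expression_%s.tsv", st)))
    write_tsv(bundle$links[[st]],
              file.path(out_dir, sprintf("links_%s.tsv", st)))
    write_bed(bundle$k9[[st]]$domains,
              file.path(out_dir, sprintf("k9_domains_%s.bed", st)))
    write_bedgraph(bundle$k9[[st]]$track,
                   file.path(out_dir, sprintf("k9_track_%s.bedgraph", st)))
  }
  if (!is.null(bundle$transitions)) {
    write_tsv(bundle$transitions$primed,
              file.path(out_dir, "transitions_primed.tsv"))
    write_tsv(bundle$transitions$active,
              file.path(out_dir, "transitions_active.tsv"))
  }
  if (!is.null(bundle$presence)) {
    write_tsv(bundle$presence, file.path(out_dir, "presence_matrix.tsv"))
    write_tsv(as.data.frame(attr(bundle$presence, "jaccard")),
              file.path(out_dir, "jaccard.tsv"))
  }
  if (!is.null(bundle$k9_venn)) {
    write_tsv(bundle$k9_venn, file.path(out_dir, "k9_venn.tsv"))
  }
  write_config(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
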