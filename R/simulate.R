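# Synthetic-data generator: toy genome, gene annotation, ground-truth
# chromatin states, ChIP/input window counts, H3K9me2 tracks and RNA counts.
#
# The generator exists so the complete analysis runs with known-answer
# inputs: every latent quantity the pipeline is supposed to recover (enhancer
# states per stage, state transitions, heterochromatin domains, expression
# classes) is drawn first and stored, and the observable counts are drawn
# conditional on it.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study design with defaults that
#' emulate a three-stage differentiation experiment on a small toy genome.
#'
#' @param stages Stage names, ordered along differentiation.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_enhancers,n_genes Numbers of enhancers and genes to place.
#' @param enhancer_width Enhancer interval width (bp).
#' @param window_size,step Sliding-window geometry for the point marks (bp).
#' @param k9_window Tiling-window size for H3K9me2 (bp).
#' @param pseudo Pseudo-count for enrichment scoring.
#' @param background Mean background tag count per `window_size` window.
#' @param fold Named list of fold-enrichments over background for a window
#'   carrying each mark.
#' @param replicates Named vector of ChIP replicate counts per mark.
#' @param input_replicates Input replicate count.
#' @param chip_dispersion Negative-binomial dispersion for tag counts
#'   (`NULL` = Poisson).
#' @param state_probs Stage-1 enhancer state probabilities over
#'   active/primed/poised/closed.
#' @param transitions 4x4 row-stochastic matrix of stage-to-stage enhancer
#'   state transition probabilities (rows/cols in the order
#'   active, primed, poised, closed).
#' @param k9_stay Stay-probability of the two-state heterochromatin Markov
#'   chain over consecutive 5 kb windows.
#' @param k9_means,k9_sd Gaussian emission means (depleted, enriched) and
#'   common SD for the H3K9me2 log2-enrichment track.
#' @param k9_shared Share one true domain chain across stages (the observed
#'   heterochromatin landscape is largely stage-invariant).
#' @param enh_domain_prob Probability that an enhancer is placed inside a
#'   true heterochromatin domain (vs. strictly outside).
#' @param domain_margin Safety margin (bp) kept between an enhancer and the
#'   nearest domain boundary on either side of the placement condition.
#' @param rna_depth Expected total RNA-seq read count per stage.
#' @param rna_dispersion Negative-binomial dispersion of RNA counts.
#' @param expr_active_prob,expr_primed_prob,expr_base_prob Probability that
#'   a gene is expressed given that its truly linked enhancers include an
#'   active one / include only primed or poised ones / include none.
#'   Expression tracks enhancer class, strongest for active enhancers.
#' @param active_boost Multiplicative expression gain per associated truly
#'   active enhancer.
#' @param silent_mean Mean count of a silent gene (before length scaling).
#' @param seed Master seed; all sub-simulations derive child streams from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(stages = c("HSC", "ProB", "MatB"),
                       chrom_lengths = c(chr1 = 20000000L,
                                         chr2 = 20000000L),
                       n_enhancers = 500,
                       n_genes = 300,
                       enhancer_width = 2000,
                       window_size = 1000,
                       step = 500,
                       k9_window = 5000,
                       pseudo = 8,
                       background = 20,
                       fold = list(K4me1 = 8, K4me3 = 12, K27ac = 8,
                                   K27me3 = 8),
                       replicates = c(K4me1 = 2, K4me3 = 1, K27ac = 2,
                                      K27me3 = 2),
                       input_replicates = 2,
                       chip_dispersion = NULL,
                       state_probs = c(active = 0.40, primed = 0.45,
                                       poised = 0.05, closed = 0.10),
                       transitions = default_transitions(),
                       k9_stay = 0.9,
                       k9_means = c(-1, 1),
                       k9_sd = sqrt(0.5),
                       k9_shared = TRUE,
                       enh_domain_prob = 0.15,
                       domain_margin = 5000,
                       rna_depth = 3e5,
                       rna_dispersion = 0.1,
                       expr_active_prob = 0.95,
                       expr_primed_prob = 0.6,
                       expr_base_prob = 0.25,
                       active_boost = 1,
                       silent_mean = 1,
                       seed = 1L) {
  cfg <- list(stages = stages, chrom_lengths = chrom_lengths,
              n_enhancers = n_enhancers, n_genes = n_genes,
              enhancer_width = enhancer_width, window_size = window_size,
              step = step, k9_window = k9_window, pseudo = pseudo,
              background = background, fold = fold, replicates = replicates,
              input_replicates = input_replicates,
              chip_dispersion = chip_dispersion, state_probs = state_probs,
              transitions = transitions, k9_stay = k9_stay,
              k9_means = k9_means, k9_sd = k9_sd, k9_shared = k9_shared,
              enh_domain_prob = enh_domain_prob,
              domain_margin = domain_margin, rna_depth = rna_depth,
              rna_dispersion = rna_dispersion,
              expr_active_prob = expr_active_prob,
              expr_primed_prob = expr_primed_prob,
              expr_base_prob = expr_base_prob, active_boost = active_boost,
              silent_mean = silent_mean, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Default enhancer state transition matrix
#'
#' Stage-to-stage transition probabilities of the latent enhancer state,
#' chosen to emulate the dynamics observed across haematopoietic
#' differentiation: priming rarely leads to activation (primed to active
#' 0.04), most primed enhancers close (0.80), and most stage-specific
#' active enhancers are established de novo (from the closed state).
#'
#' @return A 4x4 row-stochastic matrix with dimnames
#'   active/primed/poised/closed.
#' @export
default_transitions <- function() {
  s <- c("active", "primed", "poised", "closed")
  m <- matrix(c(
    0.50, 0.05, 0.00, 0.45,   # active ->
    0.04, 0.16, 0.00, 0.80,   # primed ->
    0.10, 0.10, 0.50, 0.30,   # poised ->
    0.05, 0.04, 0.01, 0.90    # closed ->
  ), nrow = 4, byrow = TRUE, dimnames = list(s, s))
  m
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$stages) >= 1, !anyDuplicated(cfg$stages))
  validate_genome(cfg$chrom_lengths)
  probs <- c(cfg$state_probs, cfg$transitions, cfg$k9_stay,
             cfg$enh_domain_prob, cfg$expr_base_prob,
             cfg$expr_primed_prob, cfg$expr_active_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$state_probs) - 1) > 1e-8) {
    stop("state_probs must sum to 1", call. = FALSE)
  }
  if (any(abs(rowSums(cfg$transitions) - 1) > 1e-8)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  if (any(unlist(cfg$fold) < 1)) {
    stop("fold enrichments must be >= 1", call. = FALSE)
  }
  if (cfg$k9_sd <= 0) stop("k9_sd must be positive", call. = FALSE)
  if (cfg$k9_stay <= 0) stop("k9_stay must be in (0, 1]", call. = FALSE)
  invisible(cfg)
}

validate_genome <- function(genome) {
  if (length(genome) < 1) stop("at least one chromosome required",
                               call. = FALSE)
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    stop("chromosome names must be present and unique", call. = FALSE)
  }
  if (any(genome <= 0)) stop("chromosome lengths must be positive",
                             call. = FALSE)
  invisible(genome)
}

#' Simulate (instantiate) the toy genome
#'
#' @param config A [sim_config()].
#' @return Named integer vector of chromosome lengths.
#' @export
simulate_genome <- function(config) {
  validate_genome(config$chrom_lengths)
  g <- config$chrom_lengths
  storage.mode(g) <- "integer"
  g
}

#' Simulate the ground truth: annotation, states, domains, expression
#'
#' Draws, in order: (1) the per-stage heterochromatin-domain chains over
#' consecutive `k9_window` bins; (2) gene models on a jittered lattice
#' (promoters are placed first); (3) per-enhancer state sequences across
#' stages from the configured transition chain; (4) enhancer positions,
#' rejected until they sit at least 2 kb from every TSS, at least 3 kb from
#' every other enhancer, and on the configured side of the domain boundary
#' (inside a true domain with probability `enh_domain_prob`, strictly
#' outside otherwise, with a `domain_margin` buffer); (5) per-stage
#' expression classes, where a gene is expressed whenever its truly linked
#' enhancers include an active one and otherwise with probability
#' `expr_base_prob`.
#'
#' @param genome Named chromosome-length vector from [simulate_genome()].
#' @param config A [sim_config()].
#' @return A `truth_set` list with elements `genes`, `promoters`,
#'   `enhancers` (with one `state_<stage>` column per stage), `domains`
#'   and `k9_states` (per stage), `expression` (per stage), and `meta`
#'   (seed and config echo).
#' @export
simulate_truth <- function(genome, config) {
  validate_genome(genome)
  stages <- config$stages
  set.seed(child_seed(config$seed, "truth"))

  ## 1. heterochromatin domain truth ------------------------------------
  gen_chain <- function() {
    out <- lapply(names(genome), function(chr) {
      nb <- floor(genome[[chr]] / config$k9_window)
      simulate_markov_chain(nb, config$k9_stay, p_start_enriched = 0.5)
    })
    names(out) <- names(genome)
    out
  }
  k9_states <- if (config$k9_shared) {
    shared <- gen_chain()
    stats::setNames(lapply(stages, function(s) shared), stages)
  } else {
    stats::setNames(lapply(stages, function(s) gen_chain()), stages)
  }
  domains <- lapply(k9_states, function(per_chrom) {
    states_to_domain_df(per_chrom, config$k9_window)
  })

  ## 2. gene models ------------------------------------------------------
  genes <- place_genes(genome, config)
  promoters <- define_promoters(genes, flank = 1000)

  ## 3. enhancer state sequences ----------------------------------------
  states <- matrix(NA_character_, nrow = config$n_enhancers,
                   ncol = length(stages),
                   dimnames = list(NULL, stages))
  state_names <- colnames(config$transitions)
  states[, 1] <- sample(names(config$state_probs), config$n_enhancers,
                        replace = TRUE, prob = config$state_probs)
  if (length(stages) > 1) {
    for (s in 2:length(stages)) {
      for (from in state_names) {
        idx <- which(states[, s - 1] == from)
        if (length(idx)) {
          states[idx, s] <- sample(state_names, length(idx), replace = TRUE,
                                   prob = config$transitions[from, ])
        }
      }
    }
  }

  ## 4. enhancer placement -----------------------------------------------
  in_domain <- stats::runif(config$n_enhancers) < config$enh_domain_prob
  ref_stage <- if (length(stages) > 1) stages[2] else stages[1]
  enh <- place_enhancers(genome, genes, domains[[ref_stage]],
                         in_domain, config)
  enh$in_domain <- in_domain
  for (s in seq_along(stages)) {
    enh[[paste0("state_", stages[s])]] <- states[, s]
  }

  ## 5. true enhancer-gene links and expression classes -------------------
  enh$true_gene <- nearest_tss_gene(enh, genes, max_distance = 500000)
  expression <- stats::setNames(lapply(seq_along(stages), function(s) {
    linked <- !is.na(enh$true_gene)
    act <- enh$true_gene[linked & states[, s] == "active"]
    oth <- enh$true_gene[linked & states[, s] %in% c("primed", "poised")]
    n_active <- as.integer(table(factor(act, levels = genes$gene)))
    p <- ifelse(n_active >= 1, config$expr_active_prob,
                ifelse(genes$gene %in% oth, config$expr_primed_prob,
                       config$expr_base_prob))
    expressed <- stats::runif(nrow(genes)) < p
    data.frame(gene = genes$gene, n_active = n_active,
               class = ifelse(expressed, "expressed", "silent"),
               stringsAsFactors = FALSE)
  }), stages)

  structure(list(genes = genes, promoters = promoters, enhancers = enh,
                 domains = domains, k9_states = k9_states,
                 expression = expression,
                 meta = list(seed = config$seed, stages = stages,
                             config = config)),
            class = "truth_set")
}

# Two-state Markov chain over n bins; returns integer vector, 1 = depleted,
# 2 = enriched.
simulate_markov_chain <- function(n, stay, p_start_enriched = 0.5) {
  if (n <= 0) return(integer(0))
  s <- integer(n)
  s[1] <- if (stats::runif(1) < p_start_enriched) 2L else 1L
  if (n > 1) {
    flips <- stats::runif(n - 1) >= stay
    for (i in 2:n) {
      s[i] <- if (flips[i - 1]) 3L - s[i - 1] else s[i - 1]
    }
  }
  s
}

# Per-chromosome state vectors -> data.frame of enriched-state intervals.
states_to_domain_df <- function(per_chrom, window) {
  pieces <- lapply(names(per_chrom), function(chr) {
    s <- per_chrom[[chr]]
    if (!length(s)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    }
    r <- rle(s == 2L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = rep(chr, length(keep)),
               start = as.integer((starts[keep] - 1L) * window),
               end = as.integer(ends[keep] * window),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Gene models on a jittered lattice so promoters are well separated.
place_genes <- function(genome, config) {
  total <- sum(as.numeric(genome))
  n_per <- pmax(1L, round(config$n_genes * as.numeric(genome) / total))
  # adjust rounding drift on the largest chromosome
  n_per[which.max(genome)] <- n_per[which.max(genome)] +
    (config$n_genes - sum(n_per))
  rows <- list()
  gid <- 0L
  for (ci in seq_along(genome)) {
    chr <- names(genome)[ci]
    n <- n_per[ci]
    slot <- genome[[ci]] / n
    for (i in seq_len(n)) {
      gid <- gid + 1L
      tss <- round((i - 1 + stats::runif(1, 0.3, 0.7)) * slot)
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(2:6, 1)
      ex_len <- round(stats::runif(n_ex, 200, 1200))
      introns <- if (n_ex > 1) round(stats::runif(n_ex - 1, 500, 2500)) else numeric(0)
      span <- sum(ex_len) + sum(introns)
      if (strand == "+") {
        starts <- tss + cumsum(c(0, ex_len[-n_ex] + introns))
      } else {
        tx_start <- tss - span
        starts <- tx_start + cumsum(c(0, ex_len[-n_ex] + introns))
      }
      ends <- starts + ex_len
      rows[[gid]] <- data.frame(
        gene = sprintf("gene%03d", gid), chrom = chr, strand = strand,
        tx_start = as.integer(min(starts)), tx_end = as.integer(max(ends)),
        stringsAsFactors = FALSE)
      rows[[gid]]$exon_starts <- I(list(as.integer(starts)))
      rows[[gid]]$exon_ends <- I(list(as.integer(ends)))
    }
  }
  genes <- do.call(rbind, rows)
  genes$exonic_length <- vapply(seq_len(nrow(genes)), function(i) {
    exonic_union_length(genes$exon_starts[[i]], genes$exon_ends[[i]])
  }, numeric(1))
  rownames(genes) <- NULL
  genes
}

# Rejection-sample enhancer intervals subject to TSS distance, mutual
# spacing and the heterochromatin-domain placement condition.
place_enhancers <- function(genome, genes, ref_domains, in_domain, config,
                            max_tries = 4000L) {
  w <- config$enhancer_width
  margin <- config$domain_margin
  tss_by_chrom <- split(tss_position(genes), genes$chrom)
  dom_by_chrom <- split(ref_domains, ref_domains$chrom)
  placed <- stats::setNames(
    lapply(names(genome), function(x) matrix(numeric(0), ncol = 2)),
    names(genome))
  n <- length(in_domain)
  out <- data.frame(id = sprintf("enh%04d", seq_len(n)),
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      g <- genes[sample.int(nrow(genes), 1), ]
      tss <- tss_position(g)
      offset <- stats::runif(1, 5000, 150000) * sample(c(-1, 1), 1)
      s <- round(tss + offset - if (offset < 0) w else 0)
      e <- s + w
      chr <- g$chrom
      if (s < 0 || e > genome[[chr]]) next
      tt <- tss_by_chrom[[chr]]
      # 3.5 kb clearance: keeps the enhancer's called windows from ever
      # chaining into a promoter's on the 1 kb / 0.5 kb grid
      if (min(pmax(0, pmax(s - tt, tt - e))) < 3500) next
      pl <- placed[[chr]]
      if (nrow(pl) && any(s < pl[, 2] + 3000 & e > pl[, 1] - 3000)) next
      dd <- dom_by_chrom[[chr]]
      if (is.null(dd)) dd <- data.frame(start = numeric(0), end = numeric(0))
      if (in_domain[i]) {
        if (!nrow(dd) ||
            !any(s >= dd$start + margin & e <= dd$end - margin)) next
      } else {
        if (nrow(dd) && any(s < dd$end + margin & e > dd$start - margin)) next
      }
      out$chrom[i] <- chr
      out$start[i] <- as.integer(s)
      out$end[i] <- as.integer(e)
      placed[[chr]] <- rbind(pl, c(s, e))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("failed to place enhancer ", i, " after ", max_tries,
           " attempts; genome too small for the requested layout",
           call. = FALSE)
    }
  }
  out
}

tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
}

# Nearest TSS (midpoint distance) within max_distance; NA if none.
nearest_tss_gene <- function(enh, genes, max_distance = 500000) {
  vapply(seq_len(nrow(enh)), function(i) {
    same <- genes$chrom == enh$chrom[i]
    if (!any(same)) return(NA_character_)
    mid <- (enh$start[i] + enh$end[i]) / 2
    d <- abs(tss_position(genes[same, ]) - mid)
    j <- which.min(d)
    if (d[j] > max_distance) NA_character_ else genes$gene[same][j]
  }, character(1))
}

#' Simulate per-window ChIP and input tag counts for one mark and stage
#'
#' Tags are drawn at the resolution of the step-size bins (so overlapping
#' sliding windows share tags, as they would with real reads) and summed
#' into windows. A bin's expected ChIP count is the background rate times
#' the fold-enrichment of the mark carried at that position: promoters carry
#' H3K4me1 and H3K4me3; enhancers carry H3K4me1 plus H3K27ac when active or
#' H3K27me3 when poised; closed enhancers and plain background are at fold
#' 1. Input bins are always at fold 1. Counts are Poisson (or negative
#' binomial when `chip_dispersion` is set) and each replicate has its own
#' deterministic child stream.
#'
#' @param truth A `truth_set` from [simulate_truth()].
#' @param genome Named chromosome-length vector.
#' @param mark One of `"K4me1"`, `"K4me3"`, `"K27ac"`, `"K27me3"`.
#' @param stage One of `config$stages`.
#' @param config A [sim_config()].
#' @param depth_factors Optional per-ChIP-replicate library-depth
#'   multipliers (default all 1).
#' @return List with `chip` and `input` [count_matrix()] objects on the
#'   sliding grid, plus the `grid`.
#' @export
simulate_chip_counts <- function(truth, genome, mark, stage, config,
                                 depth_factors = NULL) {
  marks <- c("K4me1", "K4me3", "K27ac", "K27me3")
  if (!mark %in% marks) {
    stop("unknown mark '", mark, "'; expected one of ",
         paste(marks, collapse = ", "), call. = FALSE)
  }
  if (!stage %in% config$stages) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  k <- config$window_size / config$step
  stopifnot(k == round(k))
  grid <- make_windows(genome, config$window_size, config$step)
  fold_bins <- mark_fold_bins(truth, genome, mark, stage, config)
  bg_bin <- config$background / k
  n_rep <- config$replicates[[mark]] %||% 2
  if (is.null(depth_factors)) depth_factors <- rep(1, n_rep)
  stopifnot(length(depth_factors) == n_rep)

  draw <- function(mu, seed) {
    set.seed(seed)
    if (is.null(config$chip_dispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$chip_dispersion)
    }
  }
  chip_bins <- lapply(seq_len(n_rep), function(r) {
    draw(bg_bin * fold_bins * depth_factors[r],
         child_seed(config$seed, "chip", mark, stage, r))
  })
  input_bins <- lapply(seq_len(config$input_replicates), function(r) {
    draw(rep(bg_bin, length(fold_bins)),
         child_seed(config$seed, "input", stage, r))
  })

  bins_to_cm <- function(bin_list, prefix) {
    counts <- vapply(bin_list, function(b) bins_to_windows(b, genome, config),
                     numeric(nrow(grid)))
    colnames(counts) <- paste0(prefix, seq_along(bin_list))
    totals <- vapply(bin_list, sum, numeric(1))
    names(totals) <- colnames(counts)
    count_matrix(grid, counts, totals)
  }
  list(chip = bins_to_cm(chip_bins, paste0(mark, "_", stage, "_rep")),
       input = bins_to_cm(input_bins, paste0("input_", stage, "_rep")),
       grid = grid)
}

# Fold-enrichment per step-size bin, concatenated across chromosomes in
# genome order. A bin carries a feature's fold if it overlaps the feature.
mark_fold_bins <- function(truth, genome, mark, stage, config) {
  step <- config$step
  feats <- list()
  fold <- config$fold
  if (mark %in% c("K4me1", "K4me3")) {
    feats[[length(feats) + 1L]] <-
      cbind(truth$promoters[c("chrom", "start", "end")],
            fold = fold[[mark]])
  }
  st <- truth$enhancers[[paste0("state_", stage)]]
  carry <- switch(mark,
                  K4me1 = st %in% c("active", "primed", "poised"),
                  K4me3 = rep(FALSE, length(st)),
                  K27ac = st == "active",
                  K27me3 = st == "poised")
  if (any(carry)) {
    feats[[length(feats) + 1L]] <-
      cbind(truth$enhancers[carry, c("chrom", "start", "end")],
            fold = fold[[mark]])
  }
  out <- lapply(names(genome), function(chr) {
    nb <- floor(genome[[chr]] / step)
    f <- rep(1, nb)
    for (fe in feats) {
      fe_c <- fe[fe$chrom == chr, , drop = FALSE]
      for (j in seq_len(nrow(fe_c))) {
        b1 <- floor(fe_c$start[j] / step) + 1L
        b2 <- min(nb, ceiling(fe_c$end[j] / step))
        if (b1 <= b2) f[b1:b2] <- pmax(f[b1:b2], fe_c$fold[j])
      }
    }
    f
  })
  unlist(out)
}

# Sum step-size bins into sliding windows (k = size/step bins per window).
bins_to_windows <- function(bins, genome, config) {
  k <- as.integer(config$window_size / config$step)
  out <- lapply(names(genome), function(chr) {
    nb <- floor(genome[[chr]] / config$step)
    offset <- sum(vapply(names(genome)[seq_len(match(chr, names(genome)) - 1)],
                         function(c2) floor(genome[[c2]] / config$step),
                         numeric(1)))
    b <- bins[(offset + 1):(offset + nb)]
    n_win <- floor((genome[[chr]] - config$window_size) / config$step) + 1L
    if (n_win <= 0) return(numeric(0))
    cs <- cumsum(c(0, b))
    cs[seq_len(n_win) + k] - cs[seq_len(n_win)]
  })
  unlist(out)
}

#' Simulate the H3K9me2 log2-enrichment track for one stage
#'
#' Emits one Gaussian value per consecutive `k9_window` window: mean
#' `k9_means[1]` in depleted windows, `k9_means[2]` in enriched windows,
#' SD `k9_sd`. When a `truth_set` is supplied the hidden states are taken
#' from its per-stage domain truth (so stages share domains when the truth
#' was simulated with `k9_shared = TRUE`); otherwise a fresh two-state
#' Markov chain with stay-probability `k9_stay` is drawn.
#'
#' @param genome Named chromosome-length vector.
#' @param config A [sim_config()].
#' @param truth Optional `truth_set`.
#' @param stage Stage name (used for the truth lookup and the random
#'   stream).
#' @return List with `track` (an [enrichment_track()] on the tiling grid),
#'   `states` (integer vector, 1 depleted / 2 enriched), and `domains`
#'   (data.frame of true enriched intervals).
#' @export
simulate_k9me2_track <- function(genome, config, truth = NULL,
                                 stage = config$stages[1]) {
  if (config$k9_sd <= 0) stop("emission SD must be positive", call. = FALSE)
  grid <- make_windows(genome, config$k9_window, config$k9_window)
  if (is.null(truth)) {
    set.seed(child_seed(config$seed, "k9chain", stage))
    per_chrom <- lapply(names(genome), function(chr) {
      nb <- floor(genome[[chr]] / config$k9_window)
      simulate_markov_chain(nb, config$k9_stay, 0.5)
    })
    names(per_chrom) <- names(genome)
  } else {
    per_chrom <- truth$k9_states[[stage]]
  }
  states <- unlist(per_chrom, use.names = FALSE)
  stopifnot(length(states) == nrow(grid))
  set.seed(child_seed(config$seed, "k9emit", stage))
  values <- stats::rnorm(length(states),
                         mean = config$k9_means[states], sd = config$k9_sd)
  list(track = enrichment_track(grid, values, mark = "K9me2", stage = stage),
       states = states,
       domains = states_to_domain_df(per_chrom, config$k9_window))
}

#' Simulate per-gene RNA-seq counts for one stage
#'
#' Expressed genes draw negative-binomial counts with mean proportional to
#' exonic length and increasing with the number of truly active linked
#' enhancers (`mu0 * (1 + active_boost * n_active)`, where `mu0` is
#' `rna_depth / n_genes`); silent genes draw from a near-zero negative
#' binomial (`silent_mean`, length-scaled).
#'
#' @param truth A `truth_set`.
#' @param config A [sim_config()].
#' @param stage Stage name.
#' @return Data.frame with `gene`, `count`, `exonic_length`.
#' @export
simulate_rnaseq <- function(truth, config, stage = config$stages[1]) {
  ex <- truth$expression[[stage]]
  genes <- truth$genes
  stopifnot(identical(ex$gene, genes$gene))
  mu0 <- config$rna_depth / nrow(genes)
  len_factor <- genes$exonic_length / mean(genes$exonic_length)
  mu <- ifelse(ex$class == "expressed",
               mu0 * (1 + config$active_boost * ex$n_active),
               config$silent_mean) * len_factor
  set.seed(child_seed(config$seed, "rna", stage))
  counts <- stats::rnbinom(length(mu), mu = mu,
                           size = 1 / config$rna_dispersion)
  data.frame(gene = genes$gene, count = counts,
             exonic_length = genes$exonic_length, stringsAsFactors = FALSE)
}
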