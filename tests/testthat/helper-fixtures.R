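# Shared fixtures: tiny genomes, hand-built tracks, and brute-force oracles
# kept deliberately independent of the package's own interval machinery.

tiny_genome <- function(len = 10000L, chroms = "chr1") {
  stats::setNames(rep(as.integer(len), length(chroms)), chroms)
}

# Build an enrichment track directly from window coordinates and scores.
track_from_windows <- function(chrom, starts, size, scores) {
  grid <- data.frame(chrom = chrom, start = as.integer(starts),
                     end = as.integer(starts + size),
                     stringsAsFactors = FALSE)
  attr(grid, "window_size") <- as.integer(size)
  attr(grid, "step") <- if (length(starts) > 1)
    as.integer(starts[2] - starts[1]) else as.integer(size)
  enrichment_track(grid, scores)
}

regions_df <- function(chrom, starts, ends) {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends), stringsAsFactors = FALSE)
}

# Brute-force union of intervals via base-level bitmask (0-based half-open).
oracle_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    span <- max(d$end)
    mask <- logical(span)
    for (i in seq_len(nrow(d))) mask[(d$start[i] + 1):d$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exhaustive Viterbi: argmax of the joint log-probability over all 2^n
# state paths.
oracle_viterbi <- function(model, values) {
  n <- length(values)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  lp <- apply(paths, 1, function(p) {
    l <- log(model$init[p[1]]) +
      dnorm(values[1], model$means[p[1]], sqrt(model$vars[p[1]]), log = TRUE)
    if (n > 1) {
      for (t in 2:n) {
        l <- l + log(model$trans[p[t - 1], p[t]]) +
          dnorm(values[t], model$means[p[t]], sqrt(model$vars[p[t]]),
                log = TRUE)
      }
    }
    l
  })
  as.integer(paths[which.max(lp), ])
}

# Exhaustive two-pass nearest-promoter assignment with the active-first
# exclusion rule and lower-coordinate tie-break.
oracle_assign <- function(enh, prom, max_distance = 500000) {
  mids <- (enh$start + enh$end) / 2
  closest <- function(i, prom_idx) {
    cand <- prom_idx[prom$chrom[prom_idx] == enh$chrom[i]]
    if (!length(cand)) return(NA_integer_)
    d <- abs(prom$tss[cand] - mids[i])
    cand <- cand[d <= max_distance]
    d <- d[d <= max_distance]
    if (!length(cand)) return(NA_integer_)
    best <- cand[d == min(d)]
    best[which.min(prom$tss[best])]
  }
  res <- data.frame(enhancer = character(0), gene = character(0),
                    distance = numeric(0), state = character(0),
                    stringsAsFactors = FALSE)
  consumed <- integer(0)
  for (i in which(enh$state == "active")) {
    j <- closest(i, seq_len(nrow(prom)))
    if (!is.na(j)) {
      consumed <- union(consumed, j)
      res <- rbind(res, data.frame(enhancer = enh$id[i], gene = prom$gene[j],
                                   distance = abs(prom$tss[j] - mids[i]),
                                   state = "active",
                                   stringsAsFactors = FALSE))
    }
  }
  avail <- setdiff(seq_len(nrow(prom)), consumed)
  for (i in which(enh$state != "active")) {
    j <- closest(i, avail)
    if (!is.na(j)) {
      res <- rbind(res, data.frame(enhancer = enh$id[i], gene = prom$gene[j],
                                   distance = abs(prom$tss[j] - mids[i]),
                                   state = as.character(enh$state[i]),
                                   stringsAsFactors = FALSE))
    }
  }
  res[order(match(res$enhancer, enh$id)), , drop = FALSE]
}

# Base-by-base exon union length.
oracle_exonic_length <- function(starts, ends) {
  sum(tabulate(unlist(mapply(function(s, e) (s + 1):e, starts, ends,
                             SIMPLIFY = FALSE)),
               nbins = max(ends)) > 0)
}

# One full pipeline run on the default study design, shared (lazily) by the
# tests that inspect end-to-end behaviour.
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <-
      suppressMessages(run_pipeline(sim_config(seed = seed)))
  }
  .bundle_cache[[key]]
}

# Small config for fast tests: same feature sparsity as the default design
# (marked features cover a few percent of the genome) at a quarter of the
# size.
fast_config <- function(...) {
  sim_config(chrom_lengths = c(chr1 = 4000000L, chr2 = 4000000L),
             n_enhancers = 100, n_genes = 60, ...)
}
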