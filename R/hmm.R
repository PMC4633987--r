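# Two-state Gaussian-emission HMM for heterochromatin-domain segmentation:
# Baum-Welch (EM) training in log space, exact Viterbi decoding, and
# domain-level statistics.

#' Construct / validate a two-state Gaussian HMM
#'
#' State 1 is the depleted state, state 2 the enriched state (the state
#' with the larger mean is always "enriched"; [em_fit()] re-labels after
#' fitting if necessary).
#'
#' @param init Initial state probabilities (length-2, sums to 1).
#' @param trans 2x2 row-stochastic transition matrix.
#' @param means,vars Per-state Gaussian emission means and variances.
#' @param loglik Optional training log-likelihood trace.
#' @return An `hmm_model` list.
#' @export
hmm_model <- function(init, trans, means, vars, loglik = numeric(0)) {
  trans <- matrix(trans, 2, 2)
  stopifnot(length(init) == 2, length(means) == 2, length(vars) == 2)
  if (abs(sum(init) - 1) > 1e-8 || any(init < 0)) {
    stop("init must be a probability 2-vector", call. = FALSE)
  }
  if (any(abs(rowSums(trans) - 1) > 1e-8) || any(trans < 0)) {
    stop("trans rows must be probability vectors", call. = FALSE)
  }
  if (any(vars <= 0)) stop("variances must be positive", call. = FALSE)
  structure(list(init = as.numeric(init), trans = trans,
                 means = as.numeric(means), vars = as.numeric(vars),
                 loglik = loglik),
            class = "hmm_model")
}

#' The standard starting model for H3K9me2 segmentation
#'
#' Initial probability 1 of starting in the enriched state, symmetric
#' transitions with stay-probability 0.9, and Gaussian emissions
#' N(-1, 0.5) for the depleted and N(1, 0.5) for the enriched state.
#'
#' @return An `hmm_model`.
#' @export
k9_init_model <- function() {
  hmm_model(init = c(0, 1),
            trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
            means = c(-1, 1), vars = c(0.5, 0.5))
}

# log emission density matrix: n x 2
log_emission <- function(model, values) {
  cbind(stats::dnorm(values, model$means[1], sqrt(model$vars[1]),
                     log = TRUE),
        stats::dnorm(values, model$means[2], sqrt(model$vars[2]),
                     log = TRUE))
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

# log-space forward/backward; returns list(log_alpha, log_beta, loglik)
forward_backward <- function(model, values) {
  n <- length(values)
  le <- log_emission(model, values)
  lA <- log(model$trans)
  la <- matrix(-Inf, n, 2)
  lb <- matrix(0, n, 2)
  la[1, ] <- log(model$init) + le[1, ]
  if (n > 1) {
    for (t in 2:n) {
      la[t, 1] <- log_sum_exp(la[t - 1, 1] + lA[1, 1],
                              la[t - 1, 2] + lA[2, 1]) + le[t, 1]
      la[t, 2] <- log_sum_exp(la[t - 1, 1] + lA[1, 2],
                              la[t - 1, 2] + lA[2, 2]) + le[t, 2]
    }
    for (t in (n - 1):1) {
      lb[t, 1] <- log_sum_exp(lA[1, 1] + le[t + 1, 1] + lb[t + 1, 1],
                              lA[1, 2] + le[t + 1, 2] + lb[t + 1, 2])
      lb[t, 2] <- log_sum_exp(lA[2, 1] + le[t + 1, 1] + lb[t + 1, 1],
                              lA[2, 2] + le[t + 1, 2] + lb[t + 1, 2])
    }
  }
  list(log_alpha = la, log_beta = lb,
       loglik = log_sum_exp(la[n, 1], la[n, 2]), log_e = le)
}

#' Fit the HMM by Baum-Welch expectation maximization
#'
#' Standard EM updates of the initial distribution, transition matrix and
#' Gaussian emission parameters, run on one ordered value sequence
#' (training is conventionally done on the first chromosome). Iteration
#' stops when the relative log-likelihood improvement falls below `tol` or
#' after `max_iter` iterations. Variances are floored at `var_floor`;
#' degenerate input (all values identical) returns a floored model with a
#' warning. After fitting, states are re-labelled if needed so that state 2
#' has the larger mean.
#'
#' @param values Ordered log2 enrichment values (>= 10).
#' @param init Starting `hmm_model` (default [k9_init_model()]).
#' @param tol Relative log-likelihood tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param var_floor Variance floor (default 1e-3).
#' @return The fitted `hmm_model` with the log-likelihood trace in
#'   `$loglik`.
#' @export
em_fit <- function(values, init = k9_init_model(), tol = 1e-6,
                   max_iter = 500, var_floor = 1e-3) {
  stopifnot(inherits(init, "hmm_model"))
  n <- length(values)
  if (n < 10) stop("need at least 10 values to train", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("degenerate input: all values identical; variances floored")
    m <- init
    m$means <- c(values[1], values[1])
    m$vars <- c(var_floor, var_floor)
    return(m)
  }
  model <- init
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(model, values)
    trace <- c(trace, fb$loglik)
    # posterior state probabilities
    lg <- fb$log_alpha + fb$log_beta - fb$loglik
    gamma <- exp(lg)
    # expected transitions
    lA <- log(model$trans)
    xi <- matrix(0, 2, 2)
    if (n > 1) {
      for (i in 1:2) for (j in 1:2) {
        lx <- fb$log_alpha[1:(n - 1), i] + lA[i, j] +
          fb$log_e[2:n, j] + fb$log_beta[2:n, j] - fb$loglik
        xi[i, j] <- sum(exp(lx))
      }
    }
    new_init <- gamma[1, ] / sum(gamma[1, ])
    denom <- rowSums(xi)
    new_trans <- model$trans
    for (i in 1:2) if (denom[i] > 0) new_trans[i, ] <- xi[i, ] / denom[i]
    cs <- colSums(gamma)
    new_means <- colSums(gamma * values) / cs
    new_vars <- pmax(var_floor,
                     colSums(gamma * (outer(values, new_means, `-`))^2) / cs)
    model <- hmm_model(new_init, new_trans, new_means, new_vars)
    if (iter > 1) {
      rel <- (trace[iter] - trace[iter - 1]) / abs(trace[iter - 1])
      if (is.finite(rel) && rel < tol) break
    }
    if (is.infinite(tol)) break
  }
  # canonical labelling: state 2 = enriched = larger mean
  if (model$means[1] > model$means[2]) {
    model$init <- rev(model$init)
    model$means <- rev(model$means)
    model$vars <- rev(model$vars)
    model$trans <- model$trans[2:1, 2:1]
  }
  model$loglik <- trace
  model
}

#' Viterbi decoding of the most likely state path
#'
#' Exact maximum-a-posteriori joint state sequence for one chromosome's
#' ordered values. Chromosomes are decoded independently.
#'
#' @param model An `hmm_model`.
#' @param values Ordered log2 enrichment values.
#' @return Integer vector of states (1 depleted, 2 enriched).
#' @export
viterbi <- function(model, values) {
  n <- length(values)
  if (n == 0) stop("empty value sequence", call. = FALSE)
  le <- log_emission(model, values)
  lA <- log(model$trans)
  delta <- matrix(-Inf, n, 2)
  back <- matrix(1L, n, 2)
  delta[1, ] <- log(model$init) + le[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in 1:2) {
        cand <- delta[t - 1, ] + lA[, j]
        back[t, j] <- which.max(cand)
        delta[t, j] <- cand[back[t, j]] + le[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  path
}

#' Retain windows covered by reads in any sample of any stage
#'
#' A window is retained iff its raw count is positive in at least one of
#' the ChIP or input samples of at least one stage.
#'
#' @param count_matrices List of [count_matrix()] objects on an identical
#'   tiling grid (all K9me2 and input samples across stages).
#' @return Logical vector over windows (TRUE = retained).
#' @export
retain_covered_windows <- function(count_matrices) {
  ref <- count_matrices[[1]]$grid
  covered <- rep(FALSE, nrow(ref))
  for (cm in count_matrices) {
    if (nrow(cm$grid) != nrow(ref) ||
        !identical(cm$grid$start, ref$start) ||
        !identical(cm$grid$chrom, ref$chrom)) {
      stop("count matrices must share one grid", call. = FALSE)
    }
    covered <- covered | rowSums(cm$counts > 0) > 0
  }
  covered
}

#' Convert a decoded state path to domains
#'
#' Maximal runs of the enriched state over the retained-window sequence are
#' merged into intervals spanning the first to the last window of the run.
#' Because the path is defined over retained windows only, a run crossing a
#' gap of unretained (coverage-less) windows bridges that gap.
#'
#' @param path Integer state path from [viterbi()] (over retained windows).
#' @param grid The retained windows (data.frame `chrom`, `start`, `end`),
#'   same length and order as `path`.
#' @return Data.frame of enriched domains (`chrom`, `start`, `end`,
#'   `n_windows`), non-overlapping and sorted.
#' @export
states_to_domains <- function(path, grid) {
  stopifnot(length(path) == nrow(grid))
  pieces <- lapply(split(seq_len(nrow(grid)), grid$chrom), function(idx) {
    p <- path[idx]
    r <- rle(p == 2L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = rep(grid$chrom[idx[1]], length(keep)),
               start = grid$start[idx[starts[keep]]],
               end = grid$end[idx[ends[keep]]],
               n_windows = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  sort_intervals(out)
}

#' Fraction of the retained genome in the enriched state
#'
#' @param path Decoded state path over retained windows.
#' @return Enriched-window count / retained-window count.
#' @export
genome_fraction <- function(path) {
  if (length(path) == 0) stop("no retained windows", call. = FALSE)
  mean(path == 2L)
}

#' Base-level Venn partition of domain sets
#'
#' For k >= 2 stages, partitions the union of all domain sets into cells by
#' stage membership and reports the base count of every cell; the cells sum
#' exactly to the union size.
#'
#' @param domain_sets Named list of domain data.frames.
#' @return Data.frame with one row per non-empty membership signature:
#'   logical columns per stage, and `bases`.
#' @export
domain_overlap <- function(domain_sets) {
  if (length(domain_sets) < 2) stop("need >= 2 domain sets", call. = FALSE)
  if (is.null(names(domain_sets))) {
    names(domain_sets) <- paste0("stage", seq_along(domain_sets))
  }
  grs <- lapply(domain_sets, function(d)
    GenomicRanges::reduce(as_gr(d), min.gapwidth = 0L))
  all_gr <- GenomicRanges::disjoin(do.call(c, unname(grs)))
  member <- vapply(grs, function(g)
    GenomicRanges::countOverlaps(all_gr, g, minoverlap = 1L) > 0,
    logical(length(all_gr)))
  member <- matrix(member, nrow = length(all_gr),
                   dimnames = list(NULL, names(domain_sets)))
  sig <- apply(member, 1, paste, collapse = "/")
  w <- IRanges::width(all_gr)
  agg <- tapply(w, sig, sum)
  sig_rows <- do.call(rbind, strsplit(names(agg), "/"))
  out <- as.data.frame(sig_rows == "TRUE")
  names(out) <- names(domain_sets)
  out$bases <- as.numeric(agg)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of two enrichment tracks
#'
#' @param track_a,track_b [enrichment_track()]s on the same windows, or
#'   numeric vectors of paired values.
#' @param at Optional data.frame of intervals (e.g. promoters); when given,
#'   both tracks are first summarized per interval with the region-score
#'   rule and the correlation is computed across intervals.
#' @return Pearson r.
#' @export
correlate_tracks <- function(track_a, track_b, at = NULL) {
  if (!is.null(at)) {
    a <- score_regions(at, track_a, na_value = NA)
    b <- score_regions(at, track_b, na_value = NA)
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
  } else if (is.data.frame(track_a)) {
    stopifnot(nrow(track_a) == nrow(track_b))
    a <- track_a$score; b <- track_b$score
  } else {
    a <- track_a; b <- track_b
  }
  if (length(a) < 3) stop("need >= 3 paired points", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in one of the tracks", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Fraction of regions overlapping heterochromatin domains
#'
#' A region counts as overlapping iff it shares at least one base with any
#' domain (half-open convention: a region ending where a domain starts does
#' not overlap).
#'
#' @param regions Region data.frame (`chrom`, `start`, `end`).
#' @param domains Domain data.frame.
#' @return List with `n`, `n_overlapping`, `fraction_overlapping`,
#'   `fraction_outside` and the per-region logical `overlaps`.
#' @export
enhancer_domain_overlap <- function(regions, domains) {
  if (nrow(regions) == 0) {
    return(list(n = 0L, n_overlapping = 0L,
                fraction_overlapping = NaN, fraction_outside = NaN,
                overlaps = logical(0)))
  }
  ov <- GenomicRanges::countOverlaps(as_gr(regions), as_gr(domains),
                                     minoverlap = 1L) > 0
  list(n = nrow(regions), n_overlapping = sum(ov),
       fraction_overlapping = mean(ov), fraction_outside = mean(!ov),
       overlaps = ov)
}
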