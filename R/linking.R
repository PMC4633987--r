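# Expression quantification, binarization, and two-pass enhancer-promoter
# assignment.

#' Unique exonic length of a gene
#'
#' Length of the union of all exon intervals across a gene's transcripts
#' (overlapping exons are counted once).
#'
#' @param starts,ends Integer vectors of exon starts/ends (0-based,
#'   half-open), pooled across transcripts.
#' @return Union length in bp.
#' @examples
#' exonic_union_length(c(0, 50), c(100, 150))  # 150
#' @export
exonic_union_length <- function(starts, ends) {
  if (length(starts) == 0) stop("gene has no exons", call. = FALSE)
  stopifnot(length(starts) == length(ends), all(ends > starts))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(ir))
}

#' Quantify and normalize gene expression
#'
#' Raw exonic counts are scaled to the mean library total across samples and
#' to the average exonic length across genes:
#' `normalized = count * (mean_total / sample_total) *
#' (mean_exonic_length / exonic_length)`.
#'
#' @param counts Matrix or data.frame of raw per-gene counts (genes x
#'   samples), or a vector for a single sample.
#' @param exonic_lengths Per-gene unique exonic lengths (bp), same order as
#'   rows of `counts`.
#' @param genes Optional gene identifiers.
#' @return Data.frame with `gene`, `exonic_length` and one
#'   `norm_<sample>` column per sample (plus the raw columns).
#' @export
quantify_expression <- function(counts, exonic_lengths, genes = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1,
                                          dimnames = list(NULL, "sample1"))
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  if (any(exonic_lengths <= 0)) {
    stop("exonic lengths must be positive", call. = FALSE)
  }
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("sample totals must be positive", call. = FALSE)
  lib_sf <- mean(totals) / totals
  len_sf <- mean(exonic_lengths) / exonic_lengths
  norm <- sweep(counts, 2, lib_sf, `*`) * len_sf
  colnames(norm) <- paste0("norm_", colnames(counts))
  out <- data.frame(gene = genes %||% paste0("gene", seq_len(nrow(counts))),
                    exonic_length = exonic_lengths, counts, norm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binarize expression into expressed/silent
#'
#' A gene is expressed iff its normalized value is at or above the
#' threshold. With `threshold = NULL` the threshold is placed at the
#' antimode of the bimodal `log2(x + 1)` distribution (the density minimum
#' between the two largest modes), which separates the silent and expressed
#' populations.
#'
#' @param values Normalized expression values.
#' @param threshold Threshold on the normalized scale, or `NULL` for the
#'   antimode heuristic.
#' @return Character vector `"expressed"`/`"silent"`, with the threshold
#'   used as attribute `threshold`.
#' @export
binarize_expression <- function(values, threshold = NULL) {
  if (is.null(threshold)) threshold <- antimode_threshold(values)
  stop_if_not_scalar_number(threshold, "threshold")
  out <- ifelse(values >= threshold, "expressed", "silent")
  attr(out, "threshold") <- threshold
  out
}

# Density minimum between the two largest modes of log2(x+1); falls back to
# the midpoint of the log range if the distribution is not bimodal.
antimode_threshold <- function(values) {
  lx <- log2(values + 1)
  d <- stats::density(lx, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) >= 2) {
    top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
    valley <- seq(top2[1], top2[2])
    xmin <- d$x[valley[which.min(y[valley])]]
  } else {
    xmin <- mean(range(lx))
  }
  2^xmin - 1
}

#' Assign enhancers to promoters (two-pass, active first)
#'
#' Pass 1 links each active enhancer to its closest promoter (midpoint-to-
#' TSS distance) within `max_distance`. Promoters that received at least
#' one active enhancer are then removed from the candidate list, and pass 2
#' links primed and poised enhancers to the closest remaining promoter.
#' Equidistant promoters are broken towards the lower genomic coordinate.
#' Enhancers with no promoter in range stay unassigned.
#'
#' @param enhancers An `enhancer_set` (needs `chrom`, `start`, `end`,
#'   `state`; an `id` column is used if present).
#' @param promoters Promoter set from [define_promoters()].
#' @param max_distance Maximum midpoint-to-TSS distance in bp (default
#'   500000).
#' @return Data.frame with one row per assigned enhancer: `enhancer`,
#'   `gene`, `distance`, `state`.
#' @export
assign_enhancers <- function(enhancers, promoters, max_distance = 500000) {
  ids <- enhancers$id %||% sprintf("enh%04d", seq_len(nrow(enhancers)))
  mids <- (enhancers$start + enhancers$end) / 2
  nearest <- function(rows, prom) {
    # returns index into prom or NA, per enhancer row
    vapply(rows, function(i) {
      same <- which(prom$chrom == enhancers$chrom[i])
      if (!length(same)) return(NA_integer_)
      d <- abs(prom$tss[same] - mids[i])
      ok <- which(d <= max_distance)
      if (!length(ok)) return(NA_integer_)
      dmin <- min(d[ok])
      cand <- same[ok[d[ok] == dmin]]
      cand[which.min(prom$tss[cand])]  # tie: lower coordinate wins
    }, integer(1))
  }
  act <- which(enhancers$state == "active")
  rest <- which(enhancers$state != "active")
  promoters$.row <- seq_len(nrow(promoters))
  hit1 <- nearest(act, promoters)
  consumed <- unique(stats::na.omit(hit1))
  prom2 <- if (length(consumed)) promoters[-consumed, , drop = FALSE] else
    promoters
  hit2_local <- nearest(rest, prom2)
  # map pass-2 indices back into the full promoter table
  hit2 <- rep(NA_integer_, length(rest))
  if (nrow(prom2)) {
    hit2[!is.na(hit2_local)] <- prom2$.row[hit2_local[!is.na(hit2_local)]]
  }
  rows <- c(act, rest)
  hits <- c(hit1, hit2)
  keep <- !is.na(hits)
  out <- data.frame(
    enhancer = ids[rows[keep]],
    gene = promoters$gene[hits[keep]],
    distance = abs(promoters$tss[hits[keep]] - mids[rows[keep]]),
    state = as.character(enhancers$state[rows[keep]]),
    stringsAsFactors = FALSE)
  out[order(match(out$enhancer, ids)), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Summarize expression by best-associated enhancer class
#'
#' Genes are grouped by the strongest enhancer class linked to them
#' (active > primed > poised > none) and per-group distribution summaries
#' are returned.
#'
#' @param links Link table from [assign_enhancers()].
#' @param expr Data.frame with `gene` and a normalized expression column
#'   (`value` or the first `norm_` column).
#' @return Data.frame with `class`, `n`, `median`, `q1`, `q3`.
#' @export
expression_by_class <- function(links, expr) {
  val <- expr_values(expr)
  rank <- c(active = 1, primed = 2, poised = 3)
  best <- rep("none", nrow(expr))
  names(best) <- expr$gene
  if (nrow(links)) {
    agg <- tapply(rank[links$state], links$gene, min)
    best[names(agg)] <- names(rank)[agg]
  }
  cls <- factor(best, levels = c("active", "primed", "poised", "none"))
  summarize_groups(val, cls, "class")
}

#' Summarize expression by number of associated active enhancers
#'
#' @param links Link table from [assign_enhancers()].
#' @param expr Expression data.frame (see [expression_by_class()]).
#' @param max_count Counts at or above this value are pooled (default 3,
#'   i.e. groups 0, 1, 2, 3+).
#' @return Data.frame with `n_active`, `n`, `median`, `q1`, `q3`.
#' @export
expression_by_active_count <- function(links, expr, max_count = 3) {
  val <- expr_values(expr)
  n_active <- rep(0L, nrow(expr))
  names(n_active) <- expr$gene
  act <- links[links$state == "active", , drop = FALSE]
  if (nrow(act)) {
    tab <- table(act$gene)
    n_active[names(tab)] <- as.integer(tab)
  }
  capped <- pmin(n_active, max_count)
  labels <- c(as.character(seq(0, max_count - 1)),
              paste0(max_count, "+"))
  grp <- factor(labels[capped + 1L], levels = labels)
  summarize_groups(val, grp, "n_active")
}

expr_values <- function(expr) {
  if ("value" %in% names(expr)) return(expr$value)
  nc <- grep("^norm_", names(expr), value = TRUE)
  if (!length(nc)) stop("no normalized expression column found",
                        call. = FALSE)
  expr[[nc[1]]]
}

summarize_groups <- function(val, grp, grp_name) {
  qs <- tapply(val, grp, function(v) {
    stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  })
  out <- data.frame(group = levels(grp),
                    n = as.integer(table(grp)),
                    stringsAsFactors = FALSE)
  out$q1 <- vapply(qs, function(q) if (is.null(q)) NA_real_ else q[1],
                   numeric(1))
  out$median <- vapply(qs, function(q) if (is.null(q)) NA_real_ else q[2],
                       numeric(1))
  out$q3 <- vapply(qs, function(q) if (is.null(q)) NA_real_ else q[3],
                   numeric(1))
  names(out)[1] <- grp_name
  out
}
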