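# Promoter definition and enhancer identification/classification.

#' Define non-overlapping promoter intervals around TSSs
#'
#' The TSS is `tx_start` on the plus strand and `tx_end` on the minus
#' strand; the promoter is `[TSS - flank, TSS + flank)`. Transcripts are
#' processed in coordinate order and an interval overlapping a previously
#' accepted one is dropped, so the result is non-overlapping.
#'
#' @param genes Gene models as returned by [read_gene_models()] or
#'   [simulate_truth()]: columns `gene`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`.
#' @param flank Half-width in bp (default 1000, i.e. -1 to +1 kb).
#' @return Data.frame with `chrom`, `start`, `end`, `gene`, `strand`,
#'   `tss`, sorted and non-overlapping.
#' @export
define_promoters <- function(genes, flank = 1000) {
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  tss <- tss_position(genes)
  pr <- data.frame(chrom = genes$chrom,
                   start = as.integer(pmax(0, tss - flank)),
                   end = as.integer(tss + flank),
                   gene = genes$gene, strand = genes$strand,
                   tss = as.integer(tss), stringsAsFactors = FALSE)
  pr <- sort_intervals(pr)
  keep <- logical(nrow(pr))
  last_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(pr))) {
    if (pr$chrom[i] != last_chrom || pr$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- pr$end[i]
      last_chrom <- pr$chrom[i]
    }
  }
  out <- pr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify putative enhancers among H3K4me1 regions
#'
#' Keeps H3K4me1-enriched regions that (i) share no base with any promoter
#' and (ii) are depleted of H3K4me3 (region score below
#' `k4me3_depleted_cutoff`, default 1 on the log2 scale).
#'
#' @param k4me1_regions Merged H3K4me1 regions from [merge_regions()].
#' @param k4me3_track H3K4me3 [enrichment_track()].
#' @param promoters Promoter set from [define_promoters()].
#' @param k4me3_depleted_cutoff Log2 cutoff below which a region counts as
#'   H3K4me3-depleted.
#' @return The retained subset of `k4me1_regions`, with a `k4me3` score
#'   column appended.
#' @export
identify_putative_enhancers <- function(k4me1_regions, k4me3_track,
                                        promoters,
                                        k4me3_depleted_cutoff = 1.0) {
  if (nrow(k4me1_regions) == 0) return(k4me1_regions)
  ov <- GenomicRanges::countOverlaps(as_gr(k4me1_regions),
                                     as_gr(promoters), minoverlap = 1L)
  k4me3 <- score_regions(k4me1_regions, k4me3_track, na_value = -Inf)
  keep <- ov == 0 & k4me3 < k4me3_depleted_cutoff
  out <- k4me1_regions[keep, , drop = FALSE]
  out$k4me3 <- k4me3[keep]
  rownames(out) <- NULL
  out
}

#' Classify putative enhancers as active, primed or poised
#'
#' The rule follows the mark combinatorics of the three enhancer states:
#' H3K27ac at or above the cutoff makes an enhancer active; otherwise
#' H3K27me3 at or above the cutoff makes it poised; otherwise it is primed
#' (H3K4me1 only). A region carrying both H3K27ac and H3K27me3 above the
#' cutoff is classified active (acetylation is the activity mark) and
#' flagged in the `bivalent_flag` audit column.
#'
#' @param candidates Promoter-excluded, H3K4me3-depleted regions from
#'   [identify_putative_enhancers()].
#' @param k27ac,k27me3 [enrichment_track()]s for the two classifying marks;
#'   `k27me3` may be `NULL`, in which case the poised state is unavailable
#'   and candidates without H3K27ac are all primed.
#' @param cutoff Log2 enrichment cutoff (default 1.5).
#' @param stage Optional stage label stored on the result.
#' @return An `enhancer_set` data.frame: the candidate regions with score
#'   columns `k27ac`, `k27me3`, a `state` factor and `bivalent_flag`.
#' @export
classify_enhancers <- function(candidates, k27ac, k27me3, cutoff = 1.5,
                               stage = NA_character_) {
  ac <- score_regions(candidates, k27ac, na_value = -Inf)
  me3 <- if (is.null(k27me3)) rep(-Inf, nrow(candidates)) else
    score_regions(candidates, k27me3, na_value = -Inf)
  state <- ifelse(ac >= cutoff, "active",
                  ifelse(me3 >= cutoff, "poised", "primed"))
  out <- candidates
  out$k27ac <- ac
  out$k27me3 <- me3
  out$state <- factor(state, levels = c("active", "primed", "poised"))
  out$bivalent_flag <- ac >= cutoff & me3 >= cutoff
  attr(out, "stage") <- stage
  attr(out, "cutoff") <- cutoff
  class(out) <- c("enhancer_set", "data.frame")
  out
}

#' Count and summarize enhancer states
#'
#' @param enhancers An `enhancer_set` (or any data.frame with a `state`
#'   column).
#' @return Data.frame with `state`, `n` and `fraction`; fractions sum to 1.
#' @export
state_counts <- function(enhancers) {
  if (nrow(enhancers) == 0) stop("empty enhancer set", call. = FALSE)
  tab <- table(factor(enhancers$state,
                      levels = c("active", "primed", "poised")))
  data.frame(state = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(enhancers),
             stringsAsFactors = FALSE)
}

#' Call enhancers for one stage from the four mark tracks
#'
#' Convenience composition of the full calling path: H3K4me1 windows are
#' thresholded and merged into regions, promoter-overlapping and
#' H3K4me3-positive regions are removed, and the remainder is classified
#' from H3K27ac/H3K27me3.
#'
#' @param k4me1,k4me3,k27ac,k27me3 Replicate-averaged
#'   [enrichment_track()]s (`k27me3` may be `NULL`).
#' @param promoters Promoter set.
#' @param k4me1_cutoff,class_cutoff,k4me3_depleted_cutoff Log2 cutoffs.
#' @param stage Stage label.
#' @return An `enhancer_set`.
#' @export
call_enhancers <- function(k4me1, k4me3, k27ac, k27me3, promoters,
                           k4me1_cutoff = 1.5, class_cutoff = 1.5,
                           k4me3_depleted_cutoff = 1.0,
                           stage = NA_character_) {
  called <- call_enriched_windows(k4me1, k4me1_cutoff)
  regions <- merge_regions(called)
  if (nrow(regions)) {
    regions$k4me1 <- score_regions(regions, k4me1)
  } else {
    regions$k4me1 <- numeric(0)
  }
  cand <- identify_putative_enhancers(regions, k4me3, promoters,
                                      k4me3_depleted_cutoff)
  classify_enhancers(cand, k27ac, k27me3, cutoff = class_cutoff,
                     stage = stage)
}
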