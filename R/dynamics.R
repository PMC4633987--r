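# Cross-stage enhancer-state transition analysis at fixed coordinates, and
# presence/absence matrices of region repertoires across stages.

#' Re-score stage-A regions in stage-B tracks
#'
#' Region scores are computed with the same max-over-overlapping-windows
#' rule used at calling time, but on the target stage's tracks at the fixed
#' source-stage coordinates (regions are not re-called in the target
#' stage).
#'
#' @param regions Regions (e.g. an `enhancer_set`) from the source stage.
#' @param k4me1,k27ac Target-stage [enrichment_track()]s.
#' @param k27me3 Optional target-stage H3K27me3 track; when supplied a
#'   `k27me3` column is added and the poised outcome becomes available in
#'   [classify_transition()].
#' @return Data.frame of the regions with `k4me1`, `k27ac` (and optionally
#'   `k27me3`) score columns.
#' @export
rescore_in_stage <- function(regions, k4me1, k27ac, k27me3 = NULL) {
  out <- regions[, intersect(c("id", "chrom", "start", "end"),
                             names(regions)), drop = FALSE]
  out$k4me1 <- score_regions(regions, k4me1)
  out$k27ac <- score_regions(regions, k27ac)
  if (!is.null(k27me3)) out$k27me3 <- score_regions(regions, k27me3)
  out
}

#' Classify a cross-stage outcome from re-scored marks
#'
#' Quadrant rule on the target-stage scores: H3K4me1 and H3K27ac both at or
#' above their cutoffs is `active`; H3K4me1 only is `primed` (or `poised`
#' when an H3K27me3 score is supplied and passes its cutoff); H3K4me1 below
#' its cutoff is `closed` regardless of acetylation (loss of H3K4me1
#' dominates). K4me1-negative/K27ac-positive regions are additionally
#' flagged in the `acetyl_retained` attribute-free audit column returned by
#' [transition_fractions()].
#'
#' @param k4me1,k27ac Numeric score vectors (same length).
#' @param k27me3 Optional score vector enabling the poised outcome.
#' @param k4me1_cutoff,k27ac_cutoff,k27me3_cutoff Log2 cutoffs (default
#'   1.5).
#' @return Character vector of outcomes in
#'   `{active, primed, poised, closed}`.
#' @export
classify_transition <- function(k4me1, k27ac, k27me3 = NULL,
                                k4me1_cutoff = 1.5, k27ac_cutoff = 1.5,
                                k27me3_cutoff = 1.5) {
  stopifnot(length(k4me1) == length(k27ac))
  out <- rep("closed", length(k4me1))
  marked <- k4me1 >= k4me1_cutoff
  out[marked & k27ac >= k27ac_cutoff] <- "active"
  if (!is.null(k27me3)) {
    out[marked & k27ac < k27ac_cutoff & k27me3 >= k27me3_cutoff] <- "poised"
    out[marked & k27ac < k27ac_cutoff & k27me3 < k27me3_cutoff] <- "primed"
  } else {
    out[marked & k27ac < k27ac_cutoff] <- "primed"
  }
  out
}

#' Cross-stage transition fractions for one source state
#'
#' Takes the source-stage enhancers of one state, re-scores them in one or
#' more target stages, classifies the outcome per target stage, and when
#' several target stages are given also reports the union outcome (e.g.
#' "becomes active in ANY later stage"). An `acetyl_retained` audit column
#' counts closed regions that nevertheless keep H3K27ac.
#'
#' @param source An `enhancer_set` (or region data.frame with a `state`
#'   column) from the source stage.
#' @param source_state State to follow (e.g. `"primed"`).
#' @param targets Named list of target stages, each a list with elements
#'   `k4me1`, `k27ac` and optionally `k27me3`
#'   ([enrichment_track()]s).
#' @param k4me1_cutoff,k27ac_cutoff,k27me3_cutoff Log2 cutoffs.
#' @return A `transition_table` data.frame with one row per target stage
#'   (plus `"any"` when >1 target): columns `target`, `n`, one count and
#'   one fraction column per outcome, and `acetyl_retained`.
#' @export
transition_fractions <- function(source, source_state, targets,
                                 k4me1_cutoff = 1.5, k27ac_cutoff = 1.5,
                                 k27me3_cutoff = 1.5) {
  src <- source[source$state == source_state, , drop = FALSE]
  if (nrow(src) == 0) {
    stop("no source enhancers in state '", source_state, "'", call. = FALSE)
  }
  if (!is.null(targets$k4me1)) targets <- list(target = targets)
  outcomes <- c("active", "primed", "poised", "closed")
  per_stage <- lapply(targets, function(tr) {
    sc <- rescore_in_stage(src, tr$k4me1, tr$k27ac, tr$k27me3)
    cls <- classify_transition(sc$k4me1, sc$k27ac, sc$k27me3,
                               k4me1_cutoff, k27ac_cutoff, k27me3_cutoff)
    list(class = cls,
         acetyl_retained = sum(cls == "closed" & sc$k27ac >= k27ac_cutoff))
  })
  rows <- lapply(names(per_stage), function(nm) {
    cls <- per_stage[[nm]]$class
    tab <- table(factor(cls, levels = outcomes))
    data.frame(target = nm, n = length(cls),
               t(as.matrix(tab)),
               t(as.matrix(tab / length(cls))) |>
                 `colnames<-`(paste0("frac_", outcomes)),
               acetyl_retained = per_stage[[nm]]$acetyl_retained,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(per_stage) > 1) {
    # union outcome: active if active anywhere; else primed/poised if ever
    # marked; else closed
    mat <- matrix(unlist(lapply(per_stage, `[[`, "class")),
                  nrow = nrow(src))
    union_cls <- apply(mat, 1, function(r) {
      if (any(r == "active")) "active"
      else if (any(r == "poised")) "poised"
      else if (any(r == "primed")) "primed"
      else "closed"
    })
    tab <- table(factor(union_cls, levels = outcomes))
    out <- rbind(out, data.frame(
      target = "any", n = nrow(src), t(as.matrix(tab)),
      t(as.matrix(tab / nrow(src))) |>
        `colnames<-`(paste0("frac_", outcomes)),
      acetyl_retained = NA_integer_,
      stringsAsFactors = FALSE, check.names = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "source_state") <- source_state
  class(out) <- c("transition_table", "data.frame")
  out
}

#' Presence/absence matrix of region repertoires across stages
#'
#' Rows are the merged union of all stages' regions; an entry is marked iff
#' the row region overlaps at least one called region of that stage.
#' Pairwise base-level Jaccard similarities of the stage repertoires are
#' attached as attribute `jaccard`.
#'
#' @param region_sets Named list (>= 2) of per-stage region data.frames.
#' @return Data.frame with `chrom`, `start`, `end` and one logical column
#'   per stage; attribute `jaccard` holds the stages-x-stages similarity
#'   matrix.
#' @export
presence_matrix <- function(region_sets) {
  if (length(region_sets) < 2) stop("need >= 2 stages", call. = FALSE)
  if (is.null(names(region_sets))) {
    names(region_sets) <- paste0("stage", seq_along(region_sets))
  }
  all_df <- do.call(rbind, lapply(region_sets, function(r)
    r[, c("chrom", "start", "end")]))
  union_gr <- GenomicRanges::reduce(as_gr(all_df), min.gapwidth = 0L)
  out <- gr_to_df(union_gr)
  for (nm in names(region_sets)) {
    out[[nm]] <- GenomicRanges::countOverlaps(
      union_gr, as_gr(region_sets[[nm]]), minoverlap = 1L) > 0
  }
  k <- length(region_sets)
  jac <- matrix(1, k, k, dimnames = list(names(region_sets),
                                         names(region_sets)))
  grs <- lapply(region_sets, function(r)
    GenomicRanges::reduce(as_gr(r), min.gapwidth = 0L))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      inter <- sum(IRanges::width(GenomicRanges::intersect(grs[[i]],
                                                           grs[[j]])))
      uni <- sum(IRanges::width(GenomicRanges::union(grs[[i]], grs[[j]])))
      jac[i, j] <- jac[j, i] <- if (uni == 0) 0 else inter / uni
    }
  }
  out <- sort_intervals(out)
  rownames(out) <- NULL
  attr(out, "jaccard") <- jac
  out
}
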