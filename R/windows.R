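# Window grids, tag counting, normalization, enrichment scoring and
# threshold-and-merge region calling.

#' Build a sliding- or tiling-window grid over a genome
#'
#' Windows of fixed `size` start every `step` bases from position 0 on each
#' chromosome; a terminal window that would extend beyond the chromosome end
#' is dropped, so all windows have identical size. `size == step` yields a
#' consecutive (non-overlapping) tiling, as used for the 5 kb H3K9me2 grid;
#' the enhancer analyses use 1 kb windows with a 0.5 kb step.
#'
#' @param genome Named integer vector of chromosome lengths (bp), as returned
#'   by [simulate_genome()].
#' @param size Window size in bp.
#' @param step Step between window starts in bp; must satisfy
#'   `0 < step <= size`.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), ordered by chromosome then start, with attributes
#'   `window_size` and `step`.
#' @examples
#' g <- c(chr1 = 10000L)
#' w <- make_windows(g, 1000, 500)
#' nrow(w)  # 19
#' @export
make_windows <- function(genome, size, step = size) {
  validate_genome(genome)
  stop_if_not_scalar_number(size, "size")
  stop_if_not_scalar_number(step, "step")
  if (step <= 0 || step > size) {
    stop("'step' must satisfy 0 < step <= size", call. = FALSE)
  }
  pieces <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    if (len < size) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    }
    starts <- seq.int(0L, len - size, by = step)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(starts + size), stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "window_size") <- as.integer(size)
  attr(grid, "step") <- as.integer(step)
  grid
}

#' Count shifted tags in each window
#'
#' Each tag position is shifted towards the fragment midpoint: `+shift` on
#' the plus strand, `-shift` on the minus strand (pass `strand_aware = FALSE`
#' for a uniform `+shift`). The shifted position is then assigned to every
#' window containing it, so on an overlapping sliding grid one tag can
#' contribute to two windows. On a non-overlapping tiling, column sums equal
#' the per-sample tag totals.
#'
#' @param tags A list of data.frames (one per sample) with columns `chrom`,
#'   `pos` (0-based bp) and `strand` (`"+"`/`"-"`), or a single such
#'   data.frame.
#' @param grid Window grid from [make_windows()].
#' @param shift Shift in bp (the study design uses 60, half the estimated
#'   120 bp fragment length).
#' @param strand_aware Shift in opposite directions on the two strands
#'   (default) or uniformly downstream.
#' @return A `count_matrix`: list with elements `grid`, `counts` (windows x
#'   samples) and `totals` (per-sample tag totals).
#' @export
count_tags <- function(tags, grid, shift = 60, strand_aware = TRUE) {
  if (is.data.frame(tags)) tags <- list(sample1 = tags)
  if (is.null(names(tags)) || any(names(tags) == "")) {
    names(tags) <- paste0("sample", seq_along(tags))
  }
  chroms <- unique(grid$chrom)
  gr_win <- as_gr(grid)
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(tags),
                   dimnames = list(NULL, names(tags)))
  totals <- numeric(length(tags))
  names(totals) <- names(tags)
  for (i in seq_along(tags)) {
    tg <- tags[[i]]
    stopifnot(all(c("chrom", "pos", "strand") %in% names(tg)))
    bad <- setdiff(unique(tg$chrom), chroms)
    if (length(bad)) {
      stop("tags on chromosomes absent from the grid: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    delta <- if (strand_aware) ifelse(tg$strand == "-", -shift, shift) else shift
    pos <- tg$pos + delta
    gr_tag <- GenomicRanges::GRanges(tg$chrom,
                                     IRanges::IRanges(pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr_tag, gr_win)
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(grid))
    counts[, i] <- tab
    totals[i] <- nrow(tg)
  }
  count_matrix(grid, counts, totals)
}

#' Construct a window count matrix
#'
#' @param grid Window grid from [make_windows()].
#' @param counts Numeric matrix, one row per window, one column per sample.
#' @param totals Per-sample raw library totals; defaults to column sums
#'   (exact for non-overlapping grids).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(grid, counts, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(grid)) {
    stop("counts must have one row per window", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(grid = grid, counts = counts, totals = totals),
            class = "count_matrix")
}

#' Normalize libraries to the mean total
#'
#' Each sample column is scaled by (mean of raw totals) / (its raw total),
#' so every post-normalization total equals the mean raw total across
#' samples. Normalized counts are generally non-integer.
#'
#' @param cm A `count_matrix`.
#' @return The `count_matrix` with scaled counts and an attribute
#'   `scale_factors`.
#' @export
normalize_libraries <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- cm$totals
  if (any(totals <= 0)) {
    stop("samples with zero library total cannot be normalized: ",
         paste(names(totals)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sf <- mean(totals) / totals
  cm$counts <- sweep(cm$counts, 2, sf, `*`)
  attr(cm, "scale_factors") <- sf
  cm
}

#' Pseudo-count log2 enrichment of ChIP over input
#'
#' `log2((chip + pseudo) / (input + pseudo))` with a pseudo-count of 8 tags,
#' applied after library-size normalization. The pseudo-count shrinks
#' enrichments at low counts towards zero and keeps the score finite for
#' empty windows.
#'
#' @param chip,input Non-negative normalized counts (vectorized).
#' @param pseudo Pseudo-count, default 8.
#' @return log2 enrichment value(s).
#' @examples
#' enrichment(24, 8)   # 1
#' enrichment(0, 0)    # 0
#' @export
enrichment <- function(chip, input, pseudo = 8) {
  if (any(chip < 0) || any(input < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  log2((chip + pseudo) / (input + pseudo))
}

#' Build an enrichment track from a window grid and scores
#'
#' @param grid Window grid.
#' @param score Per-window log2 enrichment values.
#' @param mark,stage Optional metadata labels.
#' @return An `enrichment_track` data.frame (`chrom`, `start`, `end`,
#'   `score`) carrying the grid attributes.
#' @export
enrichment_track <- function(grid, score, mark = NA_character_,
                             stage = NA_character_) {
  stopifnot(length(score) == nrow(grid), all(is.finite(score)))
  tr <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   score = as.numeric(score), stringsAsFactors = FALSE)
  attr(tr, "window_size") <- attr(grid, "window_size")
  attr(tr, "step") <- attr(grid, "step")
  attr(tr, "mark") <- mark
  attr(tr, "stage") <- stage
  class(tr) <- c("enrichment_track", "data.frame")
  tr
}

#' Average replicate enrichment tracks
#'
#' Per-window arithmetic mean of log2 enrichments across replicate tracks on
#' identical grids.
#'
#' @param tracks List of `enrichment_track` objects (a single track is
#'   returned unchanged).
#' @return One `enrichment_track`.
#' @export
average_replicates <- function(tracks) {
  if (inherits(tracks, "enrichment_track")) return(tracks)
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (nrow(tr) != nrow(ref) ||
        !identical(tr$start, ref$start) ||
        !identical(tr$chrom, ref$chrom)) {
      stop("replicate tracks must share an identical window grid",
           call. = FALSE)
    }
  }
  scores <- rowMeans(vapply(tracks, function(tr) tr$score,
                            numeric(nrow(ref))))
  out <- ref
  out$score <- scores
  out
}

#' Select windows at or above an enrichment cutoff
#'
#' The comparison is inclusive: a window exactly at the cutoff is called.
#'
#' @param track An `enrichment_track`.
#' @param cutoff Log2 enrichment cutoff (1.5 for H3K4me1/H3K27ac/H3K27me3 in
#'   the study design).
#' @return The subset of track rows passing the cutoff.
#' @export
call_enriched_windows <- function(track, cutoff) {
  stop_if_not_scalar_number(cutoff, "cutoff")
  track[track$score >= cutoff, , drop = FALSE]
}

#' Merge overlapping windows into regions
#'
#' Maximal unions of coordinate-intersecting windows. Book-ended windows
#' (sharing only a boundary under the half-open convention) are kept
#' separate.
#'
#' @param windows Data.frame with `chrom`, `start`, `end` (typically the
#'   output of [call_enriched_windows()]).
#' @return Data.frame of non-overlapping sorted regions with a
#'   `n_windows` column counting constituent windows.
#' @export
merge_regions <- function(windows) {
  if (nrow(windows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      stringsAsFactors = FALSE))
  }
  gr <- as_gr(windows)
  # min.gapwidth = 0L merges only true overlaps, not book-ended intervals
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  out <- gr_to_df(red)
  out$n_windows <- GenomicRanges::countOverlaps(red, gr, minoverlap = 1L)
  sort_intervals(out)
}

#' Score regions on an enrichment track
#'
#' A region's score is the maximum enrichment over all track windows that
#' overlap it by at least one base; this makes scoring consistent with
#' calling (a merged run of called windows scores at or above the calling
#' cutoff).
#'
#' @param regions Data.frame of regions (`chrom`, `start`, `end`).
#' @param track An `enrichment_track`.
#' @param na_value Value returned for a region overlapping no window
#'   (default `NA`; use e.g. `-Inf` guarded callers). With the default an
#'   error is raised instead.
#' @return Numeric vector of per-region scores.
#' @export
score_regions <- function(regions, track, na_value = NULL) {
  if (nrow(regions) == 0) return(numeric(0))
  hits <- GenomicRanges::findOverlaps(as_gr(regions), as_gr(track))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  scores <- rep(NA_real_, nrow(regions))
  if (length(q)) {
    mx <- tapply(track$score[s], q, max)
    scores[as.integer(names(mx))] <- as.numeric(mx)
  }
  if (anyNA(scores)) {
    if (is.null(na_value)) {
      stop("region(s) overlap no window of the track: rows ",
           paste(which(is.na(scores)), collapse = ", "), call. = FALSE)
    }
    scores[is.na(scores)] <- na_value
  }
  scores
}

#' @rdname score_regions
#' @param region A single-row region data.frame.
#' @export
score_region <- function(region, track) {
  score_regions(region[1, , drop = FALSE], track)
}
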