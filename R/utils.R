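# Internal helpers shared across modules.

#' Derive a child random seed from a master seed and a string tag
#'
#' Every stochastic component of the simulator draws from its own stream,
#' seeded deterministically from the master seed and a component tag, so that
#' adding or re-ordering components does not perturb the others.
#'
#' @param seed Master seed (integer).
#' @param ... Character tags identifying the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit integer seed
  x <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) {
    x <- (x * 131 + code) %% m
  }
  as.integer(x)
}

# data.frame (chrom/start/end, 0-based half-open) -> GRanges (1-based closed)
as_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> data.frame in 0-based half-open coordinates
gr_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Sort an interval data.frame by chromosome then start.
sort_intervals <- function(df) {
  out <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
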