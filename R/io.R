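# Readers/writers for the plain-text formats the pipeline touches: BED,
# bedGraph, refGene-style gene models, window-count tables and YAML
# configuration. All interval files are 0-based half-open (BED dialect).

#' Read a BED file
#'
#' Accepts 3-6 columns (chrom, start, end, name, score, strand). Records
#' are validated line by line (field count, numeric coordinates,
#' `start < end`) and malformed lines are reported with their line number.
#' Unsorted input is sorted on load with a warning.
#'
#' @param path File path.
#' @return Data.frame with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 fields", call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]],
         ": coordinates must be numeric with start < end", call. = FALSE)
  }
  out <- data.frame(chrom = vapply(fields, `[`, "", 1),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  if (any(nf >= 4)) out$name <- vapply(fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, "")
  if (any(nf >= 5)) out$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_,
           "")))
  if (any(nf >= 6)) out$strand <- vapply(fields, function(f)
    if (length(f) >= 6) f[6] else NA_character_, "")
  if (is.unsorted(order(out$chrom, out$start))) {
    sorted <- sort_intervals(out)
    if (!identical(sorted$start, out$start) ||
        !identical(sorted$chrom, out$chrom)) {
      warning("input BED was not sorted; sorting on load")
      out <- sorted
    }
  }
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any of `name`, `score`, `strand`
#' columns present, tab-separated without header.
#'
#' @param intervals Data.frame of intervals.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  # BED column order is positional: stop at the first absent column
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- max(which(want %in% cols & cumsum(!want %in% cols) == 0))
  utils::write.table(intervals[, want[seq_len(upto)], drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' Four tab-separated columns (chrom, start, end, value). Records must not
#' overlap within a chromosome (a track partitions its windows); overlap
#' or malformed lines raise an error naming the first offending line.
#'
#' @param path File path.
#' @return An [enrichment_track()]-shaped data.frame.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    stop("malformed bedGraph line ", lineno[which(nf != 4)[1]],
         ": expected 4 fields", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(score) | start >= end)
  if (length(bad)) {
    stop("malformed bedGraph line ", lineno[bad[1]], call. = FALSE)
  }
  out <- data.frame(chrom = m[, 1], start = as.integer(start),
                    end = as.integer(end), score = score,
                    stringsAsFactors = FALSE)
  out <- sort_intervals(out)
  by_chrom <- split(out, out$chrom)
  for (ch in names(by_chrom)) {
    d <- by_chrom[[ch]]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping bedGraph records on ", ch,
           ": a track must partition its windows", call. = FALSE)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_track", "data.frame")
  out
}

#' Write an enrichment track as bedGraph
#'
#' @param track An [enrichment_track()] (for an overlapping sliding grid
#'   the track is exported as-is; genome browsers requiring a partition
#'   should be fed the tiling grid).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read refGene-style gene models
#'
#' Accepts either a headered tab file with columns `name`, `chrom`,
#' `strand`, `txStart`, `txEnd`, `exonStarts`, `exonEnds` (optionally
#' `name2`), or the headerless UCSC refGene.txt layout (bin, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds, ...). Exon coordinate strings are comma-separated with an
#' optional trailing comma (the refGene dialect). Transcripts of the same
#' gene (by `name2` when present, else `name`) are grouped and their exons
#' pooled.
#'
#' @param path File path.
#' @return Gene-model data.frame: `gene`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, list-columns `exon_starts`/`exon_ends` (pooled across
#'   transcripts), `exonic_length`.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("txStart", first, fixed = TRUE)
  if (has_header) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE)
    ucsc <- c("bin", "name", "chrom", "strand", "txStart", "txEnd",
              "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
    names(tab)[seq_len(min(ncol(tab), length(ucsc)))] <-
      ucsc[seq_len(min(ncol(tab), length(ucsc)))]
    if (ncol(tab) >= 13) names(tab)[13] <- "name2"
  }
  need <- c("name", "chrom", "strand", "txStart", "txEnd", "exonStarts",
            "exonEnds")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene model file lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(tab$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'; offending rows: ",
         paste(utils::head(which(!tab$strand %in% c("+", "-"))),
               collapse = ", "), call. = FALSE)
  }
  parse_coords <- function(s) {
    lapply(strsplit(s, ","), function(v) as.integer(v[nzchar(v)]))
  }
  ex_s <- parse_coords(tab$exonStarts)
  ex_e <- parse_coords(tab$exonEnds)
  mismatch <- which(lengths(ex_s) != lengths(ex_e))
  if (length(mismatch)) {
    stop("exonStarts/exonEnds count mismatch in transcript(s): ",
         paste(tab$name[mismatch], collapse = ", "), call. = FALSE)
  }
  group <- if ("name2" %in% names(tab)) tab$name2 else tab$name
  idx <- split(seq_len(nrow(tab)), group)
  rows <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    starts <- unlist(ex_s[i])
    ends <- unlist(ex_e[i])
    df <- data.frame(gene = g, chrom = tab$chrom[i[1]],
                     strand = tab$strand[i[1]],
                     tx_start = min(tab$txStart[i]),
                     tx_end = max(tab$txEnd[i]), stringsAsFactors = FALSE)
    df$exon_starts <- I(list(starts))
    df$exon_ends <- I(list(ends))
    df$exonic_length <- exonic_union_length(starts, ends)
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$tx_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models in refGene-like format
#'
#' One transcript per gene, headered dialect readable by
#' [read_gene_models()], with trailing-comma exon coordinate strings.
#'
#' @param genes Gene-model data.frame (as from [simulate_truth()]).
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  tab <- data.frame(
    name = genes$gene, chrom = genes$chrom, strand = genes$strand,
    txStart = genes$tx_start, txEnd = genes$tx_end,
    exonStarts = vapply(genes$exon_starts, function(v)
      paste0(paste(v, collapse = ","), ","), ""),
    exonEnds = vapply(genes$exon_ends, function(v)
      paste0(paste(v, collapse = ","), ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a window count table
#'
#' Tab-separated with header: chrom, start, end, one column per sample.
#'
#' @param cm A [count_matrix()].
#' @param path File path.
#' @export
write_counts <- function(cm, path) {
  tab <- cbind(cm$grid[, c("chrom", "start", "end")],
               as.data.frame(cm$counts))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param window_size,step Grid metadata to restore (defaults inferred
#'   from the first rows).
#' @export
read_counts <- function(path, window_size = NULL, step = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  grid <- tab[, c("chrom", "start", "end")]
  attr(grid, "window_size") <- window_size %||% (grid$end[1] - grid$start[1])
  attr(grid, "step") <- step %||%
    if (nrow(grid) > 1) grid$start[2] - grid$start[1] else
      grid$end[1] - grid$start[1]
  counts <- as.matrix(tab[, -(1:3), drop = FALSE])
  count_matrix(grid, counts)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$transitions <- apply(config$transitions, 1, as.list, simplify = FALSE)
  x$chrom_lengths <- as.list(config$chrom_lengths)
  x$state_probs <- as.list(config$state_probs)
  x$replicates <- as.list(config$replicates)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  tr <- do.call(rbind, lapply(x$transitions, unlist))
  x$transitions <- tr
  x$chrom_lengths <- unlist(x$chrom_lengths)
  x$state_probs <- unlist(x$state_probs)
  x$replicates <- unlist(x$replicates)
  do.call(sim_config, x)
}
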