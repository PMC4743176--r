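#' Count alignments in peaks
#'
#' A record falls in a peak when its 5' position lies in `[start, end)`;
#' since peaks are disjoint after merging, each record is counted at most
#' once. Reads model insertion sites, so only the 5' position — not a read
#' body — decides membership. The fraction of all alignments inside peaks
#' is the FRiP-style capture-efficiency statistic.
#'
#' @param records Alignment records.
#' @param S A [peak_set()].
#' @return An object of class `PeakCountTable`: `peaks` (`data.frame` with
#'   `contig`, `start`, `end`, `length`, `alignment_count`), plus totals
#'   `alignments_in_peaks`, `alignments_total`, `fraction_in_peaks`.
#' @export
count_alignments_in_peaks <- function(records, S) {
  stopifnot(inherits(S, "PeakSet"))
  rec <- as.data.frame(records)
  p <- S$peaks
  counts <- integer(nrow(p))
  if (nrow(rec) && nrow(p)) {
    for (cn in unique(p$contig)) {
      pi <- which(p$contig == cn)
      pos <- rec$position[rec$contig == cn]
      if (!length(pos)) next
      j <- findInterval(pos, p$start[pi])
      hit <- j > 0L
      hit[hit] <- pos[hit] < p$end[pi][j[hit]]
      if (any(hit)) {
        counts[pi] <- counts[pi] +
          tabulate(j[hit], nbins = length(pi))
      }
    }
  }
  tab <- data.frame(contig = p$contig, start = p$start, end = p$end,
                    length = p$end - p$start, alignment_count = counts)
  total <- nrow(rec)
  in_peaks <- sum(counts)
  structure(
    list(peaks = tab,
         alignments_in_peaks = in_peaks,
         alignments_total = total,
         fraction_in_peaks = if (total > 0) in_peaks / total else 0),
    class = "PeakCountTable"
  )
}

#' @export
print.PeakCountTable <- function(x, ...) {
  cat(sprintf(paste0("PeakCountTable: %d peak(s); %s of %s alignments in ",
                     "peaks (%.1f%%)\n"),
              nrow(x$peaks), format(x$alignments_in_peaks, big.mark = ","),
              format(x$alignments_total, big.mark = ","),
              100 * x$fraction_in_peaks))
  invisible(x)
}

#' Normalize per-peak counts to reads per 100 bp
#'
#' Peaks with zero alignments are removed first; the remaining counts are
#' normalized either per length (`count / (length / 100)`, the default,
#' giving true reads per 100 bp) or literally (`count / 100`, the plain
#' divide-by-100 reading). The mode is recorded in the result.
#'
#' @param table A `PeakCountTable` from [count_alignments_in_peaks()].
#' @param mode `"per_length"` or `"literal"`.
#' @return The table with zero-count peaks dropped and a
#'   `reads_per_100bp` column added to `$peaks`; `$mode` records the
#'   normalization used.
#' @export
normalize_reads_per_100bp <- function(table,
                                      mode = c("per_length", "literal")) {
  stopifnot(inherits(table, "PeakCountTable"))
  mode <- match.arg(mode)
  p <- table$peaks[table$peaks$alignment_count > 0, , drop = FALSE]
  p$reads_per_100bp <- switch(
    mode,
    per_length = p$alignment_count / (p$length / 100),
    literal = p$alignment_count / 100
  )
  rownames(p) <- NULL
  out <- table
  out$peaks <- p
  out$mode <- mode
  out
}

#' Mean and SEM of normalized counts per peak-length bin
#'
#' Groups normalized peaks by length bin (upper-edge labels, default
#' 100 bp increments) and reports the mean and standard error of the mean
#' (sample standard deviation over the square root of the group size) of
#' `reads_per_100bp`. Single-peak bins report `sem = 0` so the summary
#' stays total.
#'
#' @param table A normalized `PeakCountTable`
#'   (see [normalize_reads_per_100bp()]).
#' @param bin_width Length-bin width in bp (default 100).
#' @return A `data.frame` of class `BinnedSEMTable`: `length_bin`,
#'   `n_peaks`, `mean_reads_per_100bp`, `sem`.
#' @export
binned_mean_sem <- function(table, bin_width = 100) {
  stopifnot(inherits(table, "PeakCountTable"))
  p <- table$peaks
  if (is.null(p$reads_per_100bp)) {
    stop("normalize the table with `normalize_reads_per_100bp()` first",
         call. = FALSE)
  }
  if (!nrow(p)) {
    out <- data.frame(length_bin = numeric(), n_peaks = integer(),
                      mean_reads_per_100bp = numeric(), sem = numeric())
    class(out) <- c("BinnedSEMTable", class(out))
    return(out)
  }
  bin <- .length_bin(p$length, bin_width)
  bins <- sort(unique(bin))
  n <- as.integer(table(bin)[as.character(bins)])
  mu <- as.numeric(tapply(p$reads_per_100bp, bin, mean)[as.character(bins)])
  sdv <- as.numeric(tapply(p$reads_per_100bp, bin, stats::sd)[
    as.character(bins)])
  sem <- ifelse(n > 1, sdv / sqrt(n), 0)
  out <- data.frame(length_bin = bins, n_peaks = n,
                    mean_reads_per_100bp = mu, sem = sem)
  class(out) <- c("BinnedSEMTable", class(out))
  out
}

#' Larger-30 percent / smaller-70 percent capture-bias split
#'
#' Sorts peaks by length, largest first (ties broken stably by contig then
#' start), takes the top `ceiling(split_fraction * n)` peaks as the
#' "larger" class, and reports what percentage of *all* alignments (in and
#' out of peaks) fall in each class. The two percentages sum to the
#' fraction of alignments in peaks times 100.
#'
#' @param table A `PeakCountTable` from [count_alignments_in_peaks()]
#'   (normalization not required).
#' @param split_fraction Fraction of peaks in the "larger" class
#'   (default 0.30).
#' @return An object of class `RankSplitResult`:
#'   `pct_alignments_in_larger`, `pct_alignments_in_smaller`,
#'   `split_index` (number of peaks in the larger class).
#' @export
rank_split <- function(table, split_fraction = 0.30) {
  stopifnot(inherits(table, "PeakCountTable"),
            split_fraction > 0, split_fraction <= 1)
  p <- table$peaks
  if (!nrow(p)) stop("peak set must be non-empty", call. = FALSE)
  o <- order(-p$length, p$contig, p$start)
  k <- as.integer(ceiling(split_fraction * nrow(p)))
  larger <- o[seq_len(k)]
  total <- table$alignments_total
  in_larger <- sum(p$alignment_count[larger])
  in_smaller <- table$alignments_in_peaks - in_larger
  structure(
    list(pct_alignments_in_larger =
           if (total > 0) 100 * in_larger / total else 0,
         pct_alignments_in_smaller =
           if (total > 0) 100 * in_smaller / total else 0,
         split_index = k),
    class = "RankSplitResult"
  )
}

#' @export
print.RankSplitResult <- function(x, ...) {
  cat(sprintf(paste0("RankSplitResult: larger class (%d peaks) holds ",
                     "%.2f%% of alignments; smaller class holds %.2f%%\n"),
              x$split_index, x$pct_alignments_in_larger,
              x$pct_alignments_in_smaller))
  invisible(x)
}

#' Unique transposition events per cell
#'
#' Every unique read under linear every-end capture represents one
#' transposon insertion event on a single chromosomal molecule, so unique
#' alignments divided by input cells estimates transposition events
#' captured per cell.
#'
#' @param summary A `LibrarySummary` from [summarize_library()].
#' @param n_cells Number of input cells (>= 1).
#' @return An object of class `TranspositionEventEstimate`:
#'   `unique_alignments`, `n_cells`, `events_per_cell`.
#' @export
events_per_cell <- function(summary, n_cells) {
  stopifnot(inherits(summary, "LibrarySummary"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) {
    stop("`n_cells` must be a positive integer", call. = FALSE)
  }
  structure(
    list(unique_alignments = summary$unique_alignments,
         n_cells = n_cells,
         events_per_cell = summary$unique_alignments / n_cells),
    class = "TranspositionEventEstimate"
  )
}

#' @export
print.TranspositionEventEstimate <- function(x, ...) {
  cat(sprintf(paste0("TranspositionEventEstimate: %s unique alignments / ",
                     "%d cells = %.1f events per cell\n"),
              format(x$unique_alignments, big.mark = ","), x$n_cells,
              x$events_per_cell))
  invisible(x)
}
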