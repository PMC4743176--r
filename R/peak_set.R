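#' Construct a peak set
#'
#' A peak set is a named collection of half-open genomic intervals
#' (0-based) called significant. On construction, peaks are sorted by
#' (contig, start) and overlapping or bookended peaks are merged; the score
#' of a merged peak is the sum of its members' scores. All overlap
#' statistics in the package operate on this container.
#'
#' @param peaks `data.frame` with columns `contig`, `start`, `end` and
#'   optionally `score` (defaults to 0). Must satisfy `start < end`.
#' @param name Label for the set (used in reports).
#' @return An object of class `PeakSet`.
#' @examples
#' ps <- peak_set(data.frame(contig = "chr1", start = c(0, 50),
#'                           end = c(100, 150)))
#' ps  # one merged peak [0, 150)
#' @export
peak_set <- function(peaks, name = "peaks") {
  p <- as.data.frame(peaks)
  if (!nrow(p)) {
    p <- data.frame(contig = character(), start = numeric(),
                    end = numeric(), score = numeric())
    return(structure(list(name = name, peaks = p), class = "PeakSet"))
  }
  stopifnot(all(c("contig", "start", "end") %in% names(p)))
  if (is.null(p$score)) p$score <- 0
  p <- p[, c("contig", "start", "end", "score")]
  p$contig <- as.character(p$contig)
  p$start <- as.numeric(p$start)
  p$end <- as.numeric(p$end)
  if (any(p$start < 0) || any(p$start >= p$end)) {
    stop("peaks must satisfy 0 <= start < end", call. = FALSE)
  }
  p <- p[order(p$contig, p$start, p$end), , drop = FALSE]
  # merge overlapping or bookended neighbours on the same contig
  new_run <- c(TRUE, p$contig[-1] != p$contig[-nrow(p)] |
                 p$start[-1] > cummax_by(p$end, p$contig)[-nrow(p)])
  grp <- cumsum(new_run)
  merged <- data.frame(
    contig = tapply(p$contig, grp, `[`, 1L),
    start = as.numeric(tapply(p$start, grp, min)),
    end = as.numeric(tapply(p$end, grp, max)),
    score = as.numeric(tapply(p$score, grp, sum))
  )
  merged <- merged[order(merged$contig, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  structure(list(name = name, peaks = merged), class = "PeakSet")
}

# Running maximum of x within runs of the (sorted) grouping vector g.
cummax_by <- function(x, g) {
  out <- x
  n <- length(x)
  if (n < 2L) return(out)
  for (i in 2:n) {
    if (g[i] == g[i - 1L] && out[i - 1L] > out[i]) out[i] <- out[i - 1L]
  }
  out
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peak(s), %s bp total\n",
              x$name, n_peaks(x), format(total_bp(x), big.mark = ",")))
  invisible(x)
}

#' Number of peaks in a set
#' @param x A [peak_set()].
#' @return Integer count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "PeakSet"))
  nrow(x$peaks)
}

#' Total base pairs covered by a peak set
#' @param x A [peak_set()].
#' @return Total bp (peaks are disjoint after construction).
#' @export
total_bp <- function(x) {
  stopifnot(inherits(x, "PeakSet"))
  sum(x$peaks$end - x$peaks$start)
}

#' Peak lengths
#' @param x A [peak_set()].
#' @return Numeric vector of peak lengths in bp.
#' @export
peak_lengths <- function(x) {
  stopifnot(inherits(x, "PeakSet"))
  x$peaks$end - x$peaks$start
}

# bp of B's (disjoint, sorted) intervals covered below coordinate x,
# evaluated per contig with a prefix-sum + findInterval lookup.
.covered_below <- function(x, b_start, b_end) {
  if (!length(b_start)) return(numeric(length(x)))
  cum <- cumsum(b_end - b_start)
  i <- findInterval(x, b_start)
  out <- numeric(length(x))
  hit <- i > 0L
  prev <- ifelse(i[hit] > 1L, cum[pmax(i[hit] - 1L, 1L)], 0)
  prev[i[hit] == 1L] <- 0
  out[hit] <- prev + pmin(pmax(x[hit] - b_start[i[hit]], 0),
                          b_end[i[hit]] - b_start[i[hit]])
  out
}

#' Per-peak overlap with another set
#'
#' For each peak of `A`, the number of its base pairs covered by the union
#' of `B`'s peaks, computed with a prefix-sum sweep over `B`'s sorted
#' disjoint intervals.
#'
#' @param A,B [peak_set()] objects.
#' @return Numeric vector, one value per peak of `A` (in `A$peaks` order).
#' @export
overlap_bp_per_peak <- function(A, B) {
  stopifnot(inherits(A, "PeakSet"), inherits(B, "PeakSet"))
  a <- A$peaks
  out <- numeric(nrow(a))
  if (!nrow(a) || !nrow(B$peaks)) return(out)
  for (cn in unique(a$contig)) {
    ai <- which(a$contig == cn)
    b <- B$peaks[B$peaks$contig == cn, , drop = FALSE]
    if (!nrow(b)) next
    out[ai] <- .covered_below(a$end[ai], b$start, b$end) -
      .covered_below(a$start[ai], b$start, b$end)
  }
  out
}
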