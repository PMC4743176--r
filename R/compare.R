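#' Base-pair overlap between two peak sets
#'
#' Computes the total intersection in base pairs by a linear sweep over the
#' sorted, disjoint intervals of both sets, plus coverage fractions in both
#' directions and the number of peaks sharing at least one base pair.
#' "Overlap of X with reference R" throughout the package means the
#' fraction of X's base pairs covered by R (coverage-style convention).
#'
#' @param A,B [peak_set()] objects.
#' @return An object of class `OverlapSummary` with fields `bp_A`, `bp_B`,
#'   `bp_intersection`, `frac_A_covered`, `frac_B_covered`,
#'   `peaks_A_shared`, `peaks_B_shared`. The intersection is symmetric;
#'   fractions are 0 for an empty set.
#' @examples
#' A <- peak_set(data.frame(contig = "chr1", start = 0, end = 100))
#' B <- peak_set(data.frame(contig = "chr1", start = 50, end = 150))
#' basepair_overlap(A, B)$bp_intersection  # 50
#' @export
basepair_overlap <- function(A, B) {
  stopifnot(inherits(A, "PeakSet"), inherits(B, "PeakSet"))
  ov_A <- overlap_bp_per_peak(A, B)
  ov_B <- overlap_bp_per_peak(B, A)
  bp_A <- total_bp(A)
  bp_B <- total_bp(B)
  bp_int <- sum(ov_A)
  structure(
    list(bp_A = bp_A, bp_B = bp_B, bp_intersection = bp_int,
         frac_A_covered = if (bp_A > 0) bp_int / bp_A else 0,
         frac_B_covered = if (bp_B > 0) bp_int / bp_B else 0,
         peaks_A_shared = sum(ov_A > 0),
         peaks_B_shared = sum(ov_B > 0)),
    class = "OverlapSummary"
  )
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat(sprintf("OverlapSummary: %s bp shared (%.1f%% of A, %.1f%% of B); ",
              format(x$bp_intersection, big.mark = ","),
              100 * x$frac_A_covered, 100 * x$frac_B_covered),
      sprintf("%d A-peaks / %d B-peaks share >= 1 bp\n",
              x$peaks_A_shared, x$peaks_B_shared), sep = "")
  invisible(x)
}

#' Peak sharing by at-least-one-base-pair overlap
#'
#' A peak is shared when it overlaps the other set by one base pair or
#' more; it is counted once no matter how many peaks it touches. Under the
#' half-open convention, bookended peaks do not share.
#'
#' @param A,B [peak_set()] objects.
#' @return Named integer vector `c(peaks_A_shared, peaks_B_shared)`.
#' @export
peak_sharing <- function(A, B) {
  s <- basepair_overlap(A, B)
  c(peaks_A_shared = s$peaks_A_shared, peaks_B_shared = s$peaks_B_shared)
}

# Peak-length bin label: the upper edge of the bin (a 250 bp peak falls in
# bin 300 for 100-bp bins).
.length_bin <- function(len, bin_width) {
  ceiling(len / bin_width) * bin_width
}

#' Peak-size distribution
#'
#' Counts peaks per length bin; a peak of length L falls in the bin
#' labelled `ceiling(L / bin_width) * bin_width` (the bin's upper edge).
#'
#' @param S A [peak_set()].
#' @param bin_width Bin width in bp (default 100).
#' @return A `data.frame` of class `LengthBinTable` with columns
#'   `length_bin`, `peak_count`, `bp_in_bin`; counts sum to `n_peaks(S)`.
#' @export
size_distribution <- function(S, bin_width = 100) {
  stopifnot(inherits(S, "PeakSet"), bin_width > 0)
  len <- peak_lengths(S)
  if (!length(len)) {
    out <- data.frame(length_bin = numeric(), peak_count = integer(),
                      bp_in_bin = numeric())
    class(out) <- c("LengthBinTable", class(out))
    return(out)
  }
  bin <- .length_bin(len, bin_width)
  out <- data.frame(
    length_bin = sort(unique(bin)),
    peak_count = as.integer(table(bin)[as.character(sort(unique(bin)))]),
    bp_in_bin = as.numeric(tapply(len, bin, sum)[
      as.character(sort(unique(bin)))])
  )
  rownames(out) <- NULL
  class(out) <- c("LengthBinTable", class(out))
  out
}

#' Length-stratified overlap with a reference, globally normalized
#'
#' For every peak-length bin of `S`, the percentage of that bin's base
#' pairs covered by the reference set, and the same percentage normalized
#' by the global base-pair overlap:
#' `normalized = 100 * bin_overlap_pct / global_overlap_pct`. Bins with no
#' peaks are reported with `NA` overlap fields (undefined, distinct from
#' zero).
#'
#' @param S A [peak_set()] whose peaks are stratified by length.
#' @param reference The reference [peak_set()].
#' @param bin_width Length-bin width in bp (default 100).
#' @param global_overlap_pct Global percentage of `S`'s base pairs covered
#'   by `reference`; computed from [basepair_overlap()] when `NULL`. Must
#'   lie in (0, 100].
#' @return A `data.frame` of class `LengthBinTable` with one row per
#'   length bin from the smallest to the largest occupied bin: `length_bin`,
#'   `peak_count`, `bp_in_bin`, `bp_overlap`, `overlap_pct`,
#'   `normalized_overlap_pct`.
#' @export
length_stratified_overlap <- function(S, reference, bin_width = 100,
                                      global_overlap_pct = NULL) {
  stopifnot(inherits(S, "PeakSet"), inherits(reference, "PeakSet"),
            bin_width > 0)
  if (is.null(global_overlap_pct)) {
    global_overlap_pct <- 100 * basepair_overlap(S, reference)$frac_A_covered
  }
  if (global_overlap_pct <= 0 || global_overlap_pct > 100) {
    stop("`global_overlap_pct` must lie in (0, 100]", call. = FALSE)
  }
  len <- peak_lengths(S)
  ov <- overlap_bp_per_peak(S, reference)
  if (!length(len)) {
    out <- data.frame(length_bin = numeric(), peak_count = integer(),
                      bp_in_bin = numeric(), bp_overlap = numeric(),
                      overlap_pct = numeric(),
                      normalized_overlap_pct = numeric())
    class(out) <- c("LengthBinTable", class(out))
    return(out)
  }
  bin <- .length_bin(len, bin_width)
  ladder <- seq(min(bin), max(bin), by = bin_width)
  idx <- factor(match(bin, ladder), levels = seq_along(ladder))
  peak_count <- as.integer(table(idx))
  bp_in_bin <- as.numeric(tapply(len, idx, sum))
  bp_overlap <- as.numeric(tapply(ov, idx, sum))
  bp_in_bin[is.na(bp_in_bin)] <- 0
  bp_overlap[is.na(bp_overlap)] <- 0
  overlap_pct <- ifelse(peak_count > 0, 100 * bp_overlap / bp_in_bin,
                        NA_real_)
  out <- data.frame(
    length_bin = ladder,
    peak_count = peak_count,
    bp_in_bin = ifelse(peak_count > 0, bp_in_bin, NA_real_),
    bp_overlap = ifelse(peak_count > 0, bp_overlap, NA_real_),
    overlap_pct = overlap_pct,
    normalized_overlap_pct = 100 * overlap_pct / global_overlap_pct
  )
  attr(out, "global_overlap_pct") <- global_overlap_pct
  class(out) <- c("LengthBinTable", class(out))
  out
}

#' Percentage more peaks per length bin
#'
#' For each peak-length bin, `100 * (count_S - count_other) / count_other`.
#' Bins where the comparison set has no peaks are undefined (`NA`), not
#' infinite.
#'
#' @param S,other [peak_set()] objects.
#' @param bin_width Length-bin width in bp (default 100).
#' @return A `data.frame` with columns `length_bin`, `count_S`,
#'   `count_other`, `pct_more_peaks`.
#' @export
pct_more_peaks <- function(S, other, bin_width = 100) {
  stopifnot(inherits(S, "PeakSet"), inherits(other, "PeakSet"),
            bin_width > 0)
  bin_S <- .length_bin(peak_lengths(S), bin_width)
  bin_O <- .length_bin(peak_lengths(other), bin_width)
  if (!length(bin_S) && !length(bin_O)) {
    return(data.frame(length_bin = numeric(), count_S = integer(),
                      count_other = integer(), pct_more_peaks = numeric()))
  }
  ladder <- seq(min(c(bin_S, bin_O)), max(c(bin_S, bin_O)), by = bin_width)
  nS <- tabulate(match(bin_S, ladder), nbins = length(ladder))
  nO <- tabulate(match(bin_O, ladder), nbins = length(ladder))
  data.frame(
    length_bin = ladder,
    count_S = nS,
    count_other = nO,
    pct_more_peaks = ifelse(nO > 0, 100 * (nS - nO) / nO, NA_real_)
  )
}

#' Three-way peak sharing
#'
#' Classifies every peak of a designated counting set by which of the two
#' other sets it shares at least one base pair with. The four classes
#' (shared with both, with the first other set only, with the second only,
#' with neither) partition the counting set — the counting set's view of a
#' three-set Venn diagram.
#'
#' @param A,B,C [peak_set()] objects.
#' @param counting Which set to classify: `"A"`, `"B"` or `"C"`.
#' @return An object of class `ThreeWaySharing`: the counting set's name,
#'   its peak count, and the class counts (named by the sets involved).
#' @export
threeway_sharing <- function(A, B, C, counting = c("A", "B", "C")) {
  counting <- match.arg(counting)
  sets <- list(A = A, B = B, C = C)
  for (s in sets) stopifnot(inherits(s, "PeakSet"))
  cs <- sets[[counting]]
  others <- setdiff(names(sets), counting)
  in1 <- overlap_bp_per_peak(cs, sets[[others[1]]]) > 0
  in2 <- overlap_bp_per_peak(cs, sets[[others[2]]]) > 0
  counts <- c(sum(in1 & in2), sum(in1 & !in2), sum(!in1 & in2),
              sum(!in1 & !in2))
  names(counts) <- c(
    paste0("shared_all_three"),
    paste0("with_", others[1], "_only"),
    paste0("with_", others[2], "_only"),
    paste0(counting, "_only")
  )
  structure(list(counting = counting, n = n_peaks(cs), counts = counts),
            class = "ThreeWaySharing")
}

#' @export
print.ThreeWaySharing <- function(x, ...) {
  cat(sprintf("ThreeWaySharing over set %s (%d peaks):\n", x$counting, x$n))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Peak distances to transcription start sites
#'
#' Signed distance from each peak midpoint to its nearest TSS on the same
#' contig, negative when the midpoint is upstream of the TSS with respect
#' to the TSS strand, binned over configurable edges (default
#' +/- 5 kb / 50 kb / 500 kb, separating proximal from distal peaks).
#'
#' @param S A [peak_set()].
#' @param tss `data.frame` with columns `contig`, `position` (0-based) and
#'   `strand` (`"+"`/`"-"`); must be non-empty.
#' @param breaks Bin edges for the signed distances.
#' @return A list with `distances` (per-peak `data.frame`: midpoint,
#'   nearest TSS, signed distance; `NA` for peaks on contigs without a
#'   TSS) and `counts` (table of distances over `breaks`, `NA` distances
#'   excluded).
#' @export
tss_distance_distribution <- function(S, tss,
                                      breaks = c(-Inf, -5e5, -5e4, -5e3, 0,
                                                 5e3, 5e4, 5e5, Inf)) {
  stopifnot(inherits(S, "PeakSet"))
  tss <- as.data.frame(tss)
  if (!nrow(tss)) stop("`tss` must be non-empty", call. = FALSE)
  stopifnot(all(c("contig", "position", "strand") %in% names(tss)))
  p <- S$peaks
  mid <- floor((p$start + p$end) / 2)
  dist <- rep(NA_real_, nrow(p))
  nearest <- rep(NA_real_, nrow(p))
  for (cn in unique(p$contig)) {
    ti <- which(tss$contig == cn)
    pi <- which(p$contig == cn)
    if (!length(ti)) next
    tp <- sort(tss$position[ti])
    ts <- tss$strand[ti][order(tss$position[ti])]
    # nearest sorted TSS by absolute distance
    j <- findInterval(mid[pi], tp)
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, length(tp))
    pick <- ifelse(abs(mid[pi] - tp[lo]) <= abs(tp[hi] - mid[pi]), lo, hi)
    nearest[pi] <- tp[pick]
    raw <- mid[pi] - tp[pick]
    dist[pi] <- ifelse(ts[pick] == "-", -raw, raw)
  }
  counts <- table(cut(dist[!is.na(dist)], breaks = breaks,
                      include.lowest = TRUE))
  list(distances = data.frame(contig = p$contig, midpoint = mid,
                              tss_position = nearest, distance = dist),
       counts = counts)
}
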