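# Brute-force oracles and fixture builders shared across tests. All oracles
# are deliberately naive (per-base membership vectors, exhaustive pairwise
# scans) and independent of the package's sweep/prefix-sum implementations.

# Random interval set on one small contig, total span <= span bp.
random_peak_df <- function(n, span = 10000, min_len = 1, max_len = 400,
                           contig = "chr1") {
  start <- sample.int(span - max_len, n, replace = TRUE) - 1L
  len <- sample(min_len:max_len, n, replace = TRUE)
  data.frame(contig = contig, start = start, end = start + len,
             score = seq_len(n))
}

# Per-base membership vector of a peak set over [0, span).
membership_vector <- function(ps, span, contig = "chr1") {
  v <- logical(span)
  p <- ps$peaks[ps$peaks$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    if (p$start[i] < span) {
      v[(p$start[i] + 1):min(p$end[i], span)] <- TRUE
    }
  }
  v
}

# Oracle: intersection bp via per-base membership.
oracle_intersection_bp <- function(A, B, span = 10000) {
  contigs <- union(A$peaks$contig, B$peaks$contig)
  sum(vapply(contigs, function(cn) {
    sum(membership_vector(A, span, cn) & membership_vector(B, span, cn))
  }, numeric(1)))
}

# Oracle: per-peak overlap of each A peak with B, by per-base scan.
oracle_overlap_per_peak <- function(A, B, span = 10000) {
  vapply(seq_len(nrow(A$peaks)), function(i) {
    p <- A$peaks[i, ]
    vb <- membership_vector(B, span, p$contig)
    sum(vb[(p$start + 1):p$end])
  }, numeric(1))
}

# Oracle: per-record peak containment by exhaustive scan over peaks.
oracle_counts_in_peaks <- function(records, ps) {
  p <- ps$peaks
  counts <- integer(nrow(p))
  for (r in seq_len(nrow(records))) {
    for (i in seq_len(nrow(p))) {
      if (records$contig[r] == p$contig[i] &&
          records$position[r] >= p$start[i] &&
          records$position[r] < p$end[i]) {
        counts[i] <- counts[i] + 1L
        break
      }
    }
  }
  counts
}

# Oracle: classify each counting-set peak against two other sets by >=1 bp
# sharing, via the per-base oracle.
oracle_threeway <- function(cs, o1, o2, span = 10000) {
  in1 <- oracle_overlap_per_peak(cs, o1, span) > 0
  in2 <- oracle_overlap_per_peak(cs, o2, span) > 0
  c(sum(in1 & in2), sum(in1 & !in2), sum(!in1 & in2), sum(!in1 & !in2))
}

# Oracle: nearest TSS and signed distance by exhaustive pairwise scan.
oracle_tss_distance <- function(ps, tss) {
  p <- ps$peaks
  mid <- floor((p$start + p$end) / 2)
  vapply(seq_len(nrow(p)), function(i) {
    j <- which(tss$contig == p$contig[i])
    if (!length(j)) return(NA_real_)
    d <- abs(mid[i] - tss$position[j])
    # ties broken towards the lower-coordinate TSS, as in the implementation
    jj <- j[order(d, tss$position[j])][1]
    raw <- mid[i] - tss$position[jj]
    if (tss$strand[jj] == "-") -raw else raw
  }, numeric(1))
}

# Small single-contig genome model for capture tests.
toy_model <- function(len = 100000, regions = NULL) {
  genome_model(data.frame(name = "chr1", length = len), regions)
}

# Hand-built insertion event table (already sorted).
events_df <- function(positions, cell = 1L, molecule = 1L, contig = "chr1",
                      orientation = NULL) {
  n <- length(positions)
  if (is.null(orientation)) orientation <- rep("forward", n)
  data.frame(cell_id = rep(cell, n), molecule_id = rep(molecule, n),
             contig = rep(contig, n), position = as.integer(sort(positions)),
             orientation = orientation)
}
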