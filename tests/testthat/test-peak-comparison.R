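test_that("base-pair overlap handles identity, disjoint and partial cases", {
  A <- peak_set(data.frame(contig = "chr1", start = c(0, 200),
                           end = c(100, 300)))
  expect_equal(basepair_overlap(A, A)$frac_A_covered, 1.0)
  expect_equal(basepair_overlap(A, A)$bp_intersection, total_bp(A))

  D <- peak_set(data.frame(contig = "chr1", start = 1000, end = 1100))
  expect_equal(basepair_overlap(A, D)$bp_intersection, 0)

  B <- peak_set(data.frame(contig = "chr1", start = 50, end = 150))
  s <- basepair_overlap(A, B)
  expect_equal(s$bp_intersection, 50)
  expect_equal(s$frac_A_covered, 50 / 200)
  expect_equal(s$frac_B_covered, 0.5)
})

test_that("peak sharing counts >= 1 bp overlaps under half-open coordinates", {
  A <- peak_set(data.frame(contig = "chr1", start = 0, end = 100))
  B1 <- peak_set(data.frame(contig = "chr1", start = 99, end = 200))
  expect_identical(unname(peak_sharing(A, B1)), c(1L, 1L))
  # bookended: [0,100) vs [100,200) share nothing
  B2 <- peak_set(data.frame(contig = "chr1", start = 100, end = 200))
  expect_identical(unname(peak_sharing(A, B2)), c(0L, 0L))
  # identity: everything shared on both sides
  AB <- peak_set(data.frame(contig = "chr1", start = c(0, 300),
                            end = c(100, 450)))
  expect_identical(unname(peak_sharing(AB, AB)), c(2L, 2L))
})

test_that("sweep overlap matches the per-base oracle on random instances", {
  withr::with_seed(101, {
    for (i in 1:60) {
      A <- peak_set(random_peak_df(sample(1:12, 1)))
      B <- peak_set(random_peak_df(sample(1:12, 1)))
      s <- basepair_overlap(A, B)
      expect_equal(s$bp_intersection, oracle_intersection_bp(A, B))
      expect_equal(overlap_bp_per_peak(A, B), oracle_overlap_per_peak(A, B))
      # symmetry and monotonicity under adding a peak to B
      expect_equal(basepair_overlap(B, A)$bp_intersection, s$bp_intersection)
      extra <- random_peak_df(1)
      B2 <- peak_set(rbind(B$peaks, extra))
      s2 <- basepair_overlap(A, B2)
      expect_gte(s2$bp_intersection, s$bp_intersection)
      expect_gte(s2$peaks_A_shared, s$peaks_A_shared)
    }
  })
})

test_that("sweep overlap agrees with an interval-algebra cross-check", {
  skip_if_not_installed("IRanges")
  withr::with_seed(202, {
    for (i in 1:20) {
      A <- peak_set(random_peak_df(8))
      B <- peak_set(random_peak_df(8))
      ia <- IRanges::IRanges(A$peaks$start + 1, A$peaks$end)
      ib <- IRanges::IRanges(B$peaks$start + 1, B$peaks$end)
      expect_equal(basepair_overlap(A, B)$bp_intersection,
                   sum(IRanges::width(IRanges::intersect(ia, ib))))
    }
  })
})

test_that("size distribution bins by upper edge and conserves counts", {
  S <- peak_set(data.frame(contig = "chr1",
                           start = c(0, 1000, 3000, 10000),
                           end = c(100, 1250, 3250, 13000)))
  tab <- size_distribution(S, 100)
  expect_equal(tab$length_bin, c(100, 300, 3000))
  expect_equal(tab$peak_count, c(1L, 2L, 1L))
  expect_identical(sum(tab$peak_count), n_peaks(S))
  expect_equal(sum(tab$bp_in_bin), total_bp(S))
  # empty set
  expect_identical(nrow(size_distribution(peak_set(data.frame()), 100)), 0L)
  # conservation on random sets vs a naive loop
  withr::with_seed(33, {
    for (i in 1:20) {
      S2 <- peak_set(random_peak_df(sample(1:25, 1), max_len = 900))
      tab2 <- size_distribution(S2, 100)
      expect_identical(sum(tab2$peak_count), n_peaks(S2))
      naive <- table(ceiling(peak_lengths(S2) / 100) * 100)
      expect_equal(tab2$peak_count,
                   as.integer(naive[as.character(tab2$length_bin)]))
    }
  })
})

test_that("length-stratified overlap normalizes by the global percentage", {
  S <- peak_set(data.frame(contig = "chr1", start = c(0, 1000),
                           end = c(200, 1400)))
  # identity: every occupied bin at 100%, normalized 100 given global 100
  tab <- length_stratified_overlap(S, S, 100, global_overlap_pct = 100)
  occ <- tab[tab$peak_count > 0, ]
  expect_equal(occ$overlap_pct, c(100, 100))
  expect_equal(occ$normalized_overlap_pct, c(100, 100))
  # forced arithmetic: 30% bin overlap at 60% global -> normalized 50%
  R <- peak_set(data.frame(contig = "chr1", start = 0, end = 60))
  tab2 <- length_stratified_overlap(S, R, 100, global_overlap_pct = 60)
  bin200 <- tab2[tab2$length_bin == 200, ]
  expect_equal(bin200$overlap_pct, 30)
  expect_equal(bin200$normalized_overlap_pct, 50)
  # empty bins are undefined, not zero
  bin300 <- tab2[tab2$length_bin == 300, ]
  expect_true(is.na(bin300$overlap_pct))
})

test_that("per-bin overlap bp totals match the oracle and conserve", {
  withr::with_seed(44, {
    for (i in 1:30) {
      S <- peak_set(random_peak_df(sample(1:15, 1)))
      R <- peak_set(random_peak_df(sample(1:15, 1)))
      ov <- basepair_overlap(S, R)
      if (ov$frac_A_covered == 0) next
      tab <- length_stratified_overlap(S, R, 100)
      expect_equal(sum(tab$bp_overlap, na.rm = TRUE), ov$bp_intersection)
      expect_equal(sum(tab$bp_in_bin, na.rm = TRUE), total_bp(S))
      oracle <- oracle_overlap_per_peak(S, R)
      bins <- ceiling(peak_lengths(S) / 100) * 100
      for (b in unique(bins)) {
        expect_equal(tab$bp_overlap[tab$length_bin == b],
                     sum(oracle[bins == b]))
      }
    }
  })
})

test_that("percentage more peaks is per-bin arithmetic with NA degenerates", {
  S <- peak_set(data.frame(contig = "chr1",
                           start = (0:159) * 1000,
                           end = (0:159) * 1000 + 100))
  O <- peak_set(data.frame(contig = "chr1",
                           start = (0:99) * 1000 + 500,
                           end = (0:99) * 1000 + 600))
  tab <- pct_more_peaks(S, O, 100)
  expect_equal(tab$pct_more_peaks[tab$length_bin == 100], 60)
  # equal counts -> 0%
  expect_equal(pct_more_peaks(O, O, 100)$pct_more_peaks, 0)
  # comparison set empty in a bin -> NA, not infinity
  S2 <- peak_set(data.frame(contig = "chr1", start = 0, end = 250))
  O2 <- peak_set(data.frame(contig = "chr1", start = 1000, end = 1100))
  t2 <- pct_more_peaks(S2, O2, 100)
  expect_true(is.na(t2$pct_more_peaks[t2$length_bin == 300]))
})

test_that("three-way sharing partitions the counting set", {
  A <- peak_set(data.frame(contig = "chr1", start = c(0, 300, 600),
                           end = c(100, 400, 700)))
  # all three equal: everything in the triple class
  tw <- threeway_sharing(A, A, A, counting = "A")
  expect_identical(unname(tw$counts),
                   c(3L, 0L, 0L, 0L))
  # C disjoint from A = B: everything in the "with B only" class
  C <- peak_set(data.frame(contig = "chr1", start = 5000, end = 5100))
  tw2 <- threeway_sharing(A, A, C, counting = "A")
  expect_identical(unname(tw2$counts), c(0L, 3L, 0L, 0L))
  # random sets vs exhaustive per-peak classification
  withr::with_seed(55, {
    for (i in 1:25) {
      X <- peak_set(random_peak_df(sample(1:10, 1)))
      Y <- peak_set(random_peak_df(sample(1:10, 1)))
      Z <- peak_set(random_peak_df(sample(1:10, 1)))
      tw3 <- threeway_sharing(X, Y, Z, counting = "A")
      expect_identical(sum(tw3$counts), n_peaks(X))
      expect_identical(unname(tw3$counts), as.integer(oracle_threeway(X, Y, Z)))
    }
  })
})

test_that("TSS distances are signed, strand-aware and nearest-site exact", {
  tss <- data.frame(contig = "chr1", position = c(10000, 50000),
                    strand = c("+", "-"))
  # midpoint exactly at a TSS
  S0 <- peak_set(data.frame(contig = "chr1", start = 9950, end = 10050))
  d0 <- tss_distance_distribution(S0, tss)
  expect_equal(d0$distances$distance, 0)
  # midpoint 500 bp 3' of a + strand TSS -> +500
  S1 <- peak_set(data.frame(contig = "chr1", start = 10450, end = 10550))
  expect_equal(tss_distance_distribution(S1, tss)$distances$distance, 500)
  # midpoint 500 bp on the higher-coordinate side of a - strand TSS is
  # upstream -> -500
  S2 <- peak_set(data.frame(contig = "chr1", start = 50450, end = 50550))
  expect_equal(tss_distance_distribution(S2, tss)$distances$distance, -500)
  # empty TSS list is an argument error
  expect_error(tss_distance_distribution(S1, tss[0, ]), "non-empty")
  # random peaks/TSS vs exhaustive pairwise oracle
  withr::with_seed(66, {
    for (i in 1:25) {
      S <- peak_set(random_peak_df(sample(1:12, 1)))
      nt <- sample(1:8, 1)
      tt <- data.frame(contig = "chr1",
                       position = sample.int(10000, nt),
                       strand = sample(c("+", "-"), nt, replace = TRUE))
      got <- tss_distance_distribution(S, tt)$distances$distance
      expect_equal(got, oracle_tss_distance(S, tt))
    }
  })
})
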