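test_that("a molecule with no insertions yields no reads under either model", {
  m <- toy_model()
  ev <- events_df(integer(0))
  expect_identical(nrow(ths_capture(ev, capture_params("THS"), m)), 0L)
  ra <- atac_capture(ev, capture_params("ATAC"), m)
  expect_identical(nrow(ra), 0L)
  expect_identical(unname(attr(ra, "fragment_stats")["candidate_pairs"]), 0L)
})

test_that("THS capture matches exhaustive flank enumeration", {
  # 3 insertions spaced 500 bp apart on a 100 kb molecule, window 400-2000:
  # flanks are 10000|500|500|89000 -> per-cut (left, right) runoffs:
  # cut1: (10000, 500), cut2: (500, 500), cut3: (500, 89000).
  # In-window flanks: cut1 right, cut2 both, cut3 left -> 4 templates.
  m <- toy_model(len = 100000)
  ev <- events_df(c(10000, 10500, 11000))
  p <- capture_params("THS", amp_factor = 1)
  reads <- ths_capture(ev, p, m)
  expect_identical(length(unique(reads$duplicate_group)), 4L)
  expect_setequal(
    paste(reads$position, reads$strand),
    c("10000 +", "10500 -", "10500 +", "11000 -")
  )
})

test_that("one captured template amplifies into amp_factor reads, one group", {
  m <- toy_model(len = 10000)
  # single cut: left flank 1000 (in window), right flank 9000 (out)
  ev <- events_df(1000)
  reads <- ths_capture(ev, capture_params("THS", amp_factor = 1000), m)
  expect_identical(nrow(reads), 1000L)
  expect_identical(length(unique(reads$duplicate_group)), 1L)
})

test_that("transposon orientation never affects THS capture", {
  m <- toy_model(len = 50000)
  cfg <- sim_config(seed = 4, accessible_fraction = 0.05, rate_open = 0.01,
                    rate_closed = 2e-4, n_cells = 3, molecules_per_cell = 2)
  mm <- generate_landscape(cfg, genome_size = 5e4)
  ev <- simulate_insertions(mm, cfg)
  p <- capture_params("THS", amp_factor = 2)
  r1 <- ths_capture(ev, p, mm)
  flipped <- ev
  flipped$orientation <- ifelse(ev$orientation == "forward",
                                "reverse", "forward")
  r2 <- ths_capture(flipped, p, mm)
  expect_identical(r1, r2)
})

test_that("single insertions and out-of-window spacings yield no ATAC fragments", {
  m <- toy_model(len = 10000)
  p <- capture_params("ATAC")  # window 200-800
  # one insertion: no adjacent pair
  expect_identical(nrow(atac_capture(events_df(5000), p, m)), 0L)
  # two insertions 1000 bp apart: spacing filter rejects even heteroadapter
  # pairs (checked across many orientation seeds)
  ev <- events_df(c(4000, 5000))
  for (s in 1:10) {
    expect_identical(nrow(atac_capture(ev, p, m, seed = s)), 0L)
  }
})

test_that("ATAC fragments carry two opposite-strand reads per PCR copy", {
  m <- toy_model(len = 10000)
  p <- capture_params("ATAC", pcr_mean_copies = 1)  # copies rarely > 1
  ev <- events_df(c(4000, 4500))
  # find a seed where the heteroadapter draw succeeds
  for (s in 1:20) {
    reads <- atac_capture(ev, p, m, seed = s)
    if (nrow(reads)) break
  }
  expect_gt(nrow(reads), 0)
  expect_setequal(paste(reads$position, reads$strand),
                  c("4000 +", "4500 -"))
  # each end is its own duplicate group, mapped to one (position, strand)
  key <- paste(reads$contig, reads$position, reads$strand)
  expect_identical(length(unique(reads$duplicate_group)),
                   length(unique(key)))
})

test_that("heteroadapter success rate is one half before size filtering", {
  m <- toy_model(len = 1000000)
  cfg <- sim_config(seed = 17, accessible_fraction = 0,
                    rate_open = 0.01, rate_closed = 0.01,
                    n_cells = 1, molecules_per_cell = 12)
  ev <- simulate_insertions(m, cfg)
  p <- capture_params("ATAC", atac_min_frag = 0, atac_max_frag = Inf,
                      pcr_mean_copies = 1)
  reads <- atac_capture(ev, p, m, seed = 170)
  st <- attr(reads, "fragment_stats")
  n <- st[["candidate_pairs"]]
  expect_gte(n, 100000)
  frac <- st[["amplifiable"]] / n
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("distinct THS templates dominate ATAC fragments on any molecule", {
  # every ATAC fragment end is also a THS flank; with both windows wide
  # open the THS template count must be at least the fragment count
  m <- toy_model(len = 100000)
  withr::with_seed(31, {
    for (rep in 1:20) {
      ev <- events_df(sort(sample.int(99999, sample(2:30, 1))))
      pt <- capture_params("THS", amp_factor = 1, ths_min_template = 1,
                           ths_max_template = Inf)
      pa <- capture_params("ATAC", atac_min_frag = 1, atac_max_frag = Inf,
                           pcr_mean_copies = 1)
      n_ths <- length(unique(ths_capture(ev, pt, m)$duplicate_group))
      ra <- atac_capture(ev, pa, m, seed = rep)
      n_frag <- attr(ra, "fragment_stats")[["amplifiable"]]
      expect_gte(n_ths, n_frag)
    }
  })
})

test_that("ATAC capture probability is non-decreasing in region length", {
  # Monte-Carlo: single region of length L, fixed rates; P(>= 1 amplifiable
  # fragment) must not decrease with L beyond binomial noise
  lengths <- seq(100, 3000, by = 290)
  M <- 600
  p <- capture_params("ATAC", pcr_mean_copies = 1)
  probs <- vapply(seq_along(lengths), function(i) {
    L <- lengths[i]
    m <- genome_model(data.frame(name = "chr1", length = 20000),
                      data.frame(contig = "chr1", start = 5000,
                                 end = 5000 + L, weight = 1))
    cfg <- sim_config(seed = 400 + i, rate_open = 0.004, rate_closed = 0,
                      n_cells = M, molecules_per_cell = 1)
    ev <- simulate_insertions(m, cfg)
    reads <- atac_capture(ev, p, m, seed = 500 + i)
    length(unique(reads$source_cell)) / M
  }, numeric(1))
  se_pair <- sqrt(2 * 0.25 / M)
  expect_true(all(diff(probs) >= -3 * se_pair))
  # and the trend is genuinely increasing overall
  expect_gt(probs[length(probs)], probs[1])
})

test_that("reads convert losslessly to sorted alignment records", {
  m <- toy_model(len = 50000)
  cfg <- sim_config(seed = 9, accessible_fraction = 0.05, rate_open = 0.01,
                    rate_closed = 1e-4, n_cells = 2, molecules_per_cell = 2)
  mm <- generate_landscape(cfg, genome_size = 5e4)
  ev <- simulate_insertions(mm, cfg)
  reads <- ths_capture(ev, capture_params("THS", amp_factor = 2), mm)
  al <- reads_to_alignments(reads)
  expect_identical(nrow(al), nrow(reads))
  expect_false(tagcapture:::is.unsorted_records(al))
  expect_identical(nrow(reads_to_alignments(reads[0, ])), 0L)
})

test_that("SAM and TSV exports round-trip alignment records", {
  m <- toy_model(len = 50000)
  ev <- events_df(c(1000, 1500, 2200, 40000))
  reads <- ths_capture(ev, capture_params("THS", amp_factor = 3), m)
  al <- reads_to_alignments(reads)

  sam <- withr::local_tempfile(fileext = ".sam")
  write_alignments_sam(al, m, sam)
  got <- read_alignments_sam(sam)
  expect_equal(got, al)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_reads_tsv(reads, tsv)
  got2 <- read_reads_tsv(tsv)
  expect_equal(got2$position, reads$position)
  expect_equal(got2$strand, reads$strand)
  expect_equal(got2$duplicate_group, reads$duplicate_group)
  expect_equal(got2$source_cell, reads$source_cell)
})
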