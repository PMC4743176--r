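#' Remove clonal (duplicate) reads
#'
#' Collapses amplification duplicates: exactly one record is retained per
#' distinct (contig, 5' position, strand) key — the single-end clonal key —
#' keeping the first record in sort order. Idempotent.
#'
#' @param records Alignment records sorted by (contig, position, strand);
#'   unsorted input is a contract error.
#' @return The deduplicated records, still sorted.
#' @examples
#' rec <- data.frame(contig = "chr1", position = c(5, 5, 5), strand = "+")
#' nrow(remove_clonal(rec))  # 1
#' @export
remove_clonal <- function(records) {
  rec <- as.data.frame(records)
  if (!nrow(rec)) return(rec)
  if (is.unsorted_records(rec)) {
    stop("`records` must be sorted by (contig, position, strand)",
         call. = FALSE)
  }
  key <- paste(rec$contig, rec$position, rec$strand, sep = "\r")
  out <- rec[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is.unsorted_records <- function(rec) {
  n <- nrow(rec)
  if (n < 2L) return(FALSE)
  a <- rec[-n, c("contig", "position", "strand")]
  b <- rec[-1, c("contig", "position", "strand")]
  bad <- b$contig < a$contig |
    (b$contig == a$contig & (b$position < a$position |
       (b$position == a$position & b$strand < a$strand)))
  any(bad)
}

#' Randomly down-sample alignment records
#'
#' Draws a uniformly random subset of exactly `n` records without
#' replacement, reproducible from `seed`, and returns it re-sorted. Used to
#' equalize unique-alignment depth across libraries before any comparison;
#' depth is only ever reduced to the smallest library, never increased.
#'
#' @param records Alignment records.
#' @param n Number of records to keep; must not exceed `nrow(records)`.
#' @param seed Integer seed.
#' @return `n` records, sorted by (contig, position, strand).
#' @export
downsample_alignments <- function(records, n, seed) {
  rec <- as.data.frame(records)
  n <- as.integer(n)
  if (n > nrow(rec)) {
    stop(sprintf("cannot down-sample %d records to %d: depth can only be ",
                 nrow(rec), n),
         "reduced, never increased", call. = FALSE)
  }
  idx <- withr::with_seed(as.integer(seed),
                          sort(sample.int(nrow(rec), n)))
  out <- rec[idx, , drop = FALSE]
  out <- out[order(out$contig, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library summary
#'
#' Totals, unique alignments under the clonal key, the clonal rate and the
#' fraction of mapped reads on the mitochondrial contig.
#'
#' @param records Alignment records (any order).
#' @param model A [genome_model()]; its `mito_contig` (possibly `NULL`)
#'   designates the mitochondrial contig.
#' @return An object of class `LibrarySummary`: `total_reads`,
#'   `unique_alignments`, `clonal_rate`, `mito_fraction`. Fractions are 0
#'   for empty input or when no mitochondrial contig is declared.
#' @export
summarize_library <- function(records, model) {
  stopifnot(inherits(model, "GenomeModel"))
  rec <- as.data.frame(records)
  total <- nrow(rec)
  if (!total) {
    return(structure(list(total_reads = 0L, unique_alignments = 0L,
                          clonal_rate = 0, mito_fraction = 0),
                     class = "LibrarySummary"))
  }
  key <- paste(rec$contig, rec$position, rec$strand, sep = "\r")
  uniq <- length(unique(key))
  mito <- if (is.null(model$mito_contig)) 0 else {
    sum(rec$contig == model$mito_contig) / total
  }
  structure(list(total_reads = total, unique_alignments = uniq,
                 clonal_rate = 1 - uniq / total, mito_fraction = mito),
            class = "LibrarySummary")
}

#' @export
print.LibrarySummary <- function(x, ...) {
  cat(sprintf(paste0("LibrarySummary: %s reads, %s unique alignments ",
                     "(clonal rate %.1f%%), %.1f%% mitochondrial\n"),
              format(x$total_reads, big.mark = ","),
              format(x$unique_alignments, big.mark = ","),
              100 * x$clonal_rate, 100 * x$mito_fraction))
  invisible(x)
}

#' Bin alignment 5' positions into fixed-width coverage tracks
#'
#' Each record is counted in bin `floor(position / bin_size)` of its
#' contig; every contig of the model gets a track covering its full
#' length, so per-contig counts are conserved.
#'
#' @param records Alignment records.
#' @param bin_size Bin width in bp.
#' @param model A [genome_model()] (supplies contig lengths).
#' @return A list of coverage tracks, one per contig: `contig`,
#'   `bin_size`, `counts`.
#' @export
bin_coverage <- function(records, bin_size, model) {
  stopifnot(inherits(model, "GenomeModel"), bin_size > 0)
  rec <- as.data.frame(records)
  lapply(seq_len(nrow(model$contigs)), function(k) {
    cname <- model$contigs$name[k]
    nbin <- ceiling(model$contigs$length[k] / bin_size)
    pos <- rec$position[rec$contig == cname]
    counts <- tabulate(pos %/% bin_size + 1L, nbins = nbin)
    list(contig = cname, bin_size = as.integer(bin_size), counts = counts)
  })
}
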