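#' Read a BED file as a peak set
#'
#' Accepts 3+ column BED (contig, start, end, optionally name/score...),
#' 0-based half-open. Column 4, when numeric, is taken as the score;
#' when column 5 exists (BED6 style name/score layout) column 5 is used
#' instead. Peaks are sorted and merged on load (see [peak_set()]).
#'
#' @param path BED file path.
#' @param name Label for the resulting set; defaults to the file name.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, name = NULL) {
  if (is.null(name)) name <- basename(path)
  all_lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", all_lines) & nzchar(all_lines)
  lineno <- which(keep)
  lines <- all_lines[keep]
  if (!length(lines)) return(peak_set(data.frame(), name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in '%s': fewer than 3 fields",
                 lineno[bad[1]], path), call. = FALSE)
  }
  contig <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                 lineno[bad[1]], path), call. = FALSE)
  }
  score <- rep(0, length(contig))
  if (all(nf >= 5L)) {
    s5 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    if (!anyNA(s5)) score <- s5
  } else if (all(nf >= 4L)) {
    s4 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
    if (!anyNA(s4)) score <- s4
  }
  peak_set(data.frame(contig = contig, start = start, end = end,
                      score = score),
           name = name)
}

#' Write a peak set as BED
#'
#' Four columns: contig, start, end, score; 0-based half-open; coordinate
#' order. Round-trips through [read_peaks()].
#'
#' @param x A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  stopifnot(inherits(x, "PeakSet"))
  p <- x$peaks
  lines <- if (nrow(p)) {
    sprintf("%s\t%d\t%d\t%g", p$contig, as.integer(p$start),
            as.integer(p$end), p$score)
  } else {
    character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write alignment records as minimal single-end SAM
#'
#' Emits an `@HD`/`@SQ` header from the model's contigs and one record per
#' alignment: generated read name, flag 0 (`+`) or 16 (`-`), 1-based
#' position, MAPQ 60, CIGAR `<read_length>M`, `*` sequence and quality.
#' The internal 0-based convention is converted to SAM's 1-based
#' coordinates at this boundary. The duplicate group, when present, is
#' stored in a `dg:i:` tag so the file round-trips.
#'
#' @param records Alignment records (`contig`, `position`, `strand`,
#'   optional `duplicate_group`).
#' @param model A [genome_model()] supplying contig lengths for the header.
#' @param path Output path.
#' @param read_length Read length used in the CIGAR string.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(records, model, path, read_length = 50L) {
  stopifnot(inherits(model, "GenomeModel"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", model$contigs$name,
                   as.integer(model$contigs$length)))
  n <- nrow(records)
  body <- character(0)
  if (n) {
    dg <- records$duplicate_group
    tag <- if (is.null(dg)) rep("", n) else {
      ifelse(is.na(dg), "", sprintf("\tdg:i:%d", as.integer(dg)))
    }
    body <- sprintf("read%07d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*%s",
                    seq_len(n),
                    ifelse(records$strand == "-", 16L, 0L),
                    records$contig,
                    as.integer(records$position) + 1L,
                    as.integer(read_length),
                    tag)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read minimal single-end SAM into alignment records
#'
#' Parses the dialect written by [write_alignments_sam()] (any SAM with
#' mapped single-end records works: only flag bit 16, RNAME and POS are
#' used). Positions are converted from SAM's 1-based coordinates to the
#' internal 0-based convention; a `dg:i:` tag, when present, restores the
#' duplicate group.
#'
#' @param path SAM file path.
#' @return Alignment records sorted by (contig, position, strand).
#' @export
read_alignments_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(contig = character(), position = integer(),
                      strand = character(), duplicate_group = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad)) {
    stop(sprintf("malformed SAM record on line %d", bad[1]), call. = FALSE)
  }
  flag <- as.integer(vapply(fields, `[`, "", 2L))
  dg <- vapply(fields, function(f) {
    t <- grep("^dg:i:", f[-(1:11)], value = TRUE)
    if (length(t)) as.integer(sub("^dg:i:", "", t[1])) else NA_integer_
  }, integer(1))
  rec <- data.frame(
    contig = vapply(fields, `[`, "", 3L),
    position = as.integer(vapply(fields, `[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    duplicate_group = dg
  )
  rec <- rec[order(rec$contig, rec$position, rec$strand), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write captured reads / alignments as 5-column TSV
#'
#' Documented dialect: `contig`, `start` (0-based), `strand`,
#' `duplicate_group`, `cell` — one header line then one row per read.
#' Missing duplicate groups and cells are written as `NA`.
#'
#' @param reads Captured reads or alignment records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  df <- data.frame(
    contig = reads$contig,
    start = as.integer(reads$position),
    strand = reads$strand,
    duplicate_group = if (is.null(reads$duplicate_group)) NA_integer_
                      else as.integer(reads$duplicate_group),
    cell = if (is.null(reads$source_cell)) NA_integer_
           else as.integer(reads$source_cell)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the 5-column TSV read dialect
#'
#' @param path TSV path written by [write_reads_tsv()].
#' @return A `data.frame` with columns `contig`, `position`, `strand`,
#'   `duplicate_group`, `source_cell`.
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer"))
  data.frame(contig = df$contig, position = df$start, strand = df$strand,
             duplicate_group = df$duplicate_group, source_cell = df$cell)
}

#' Export a coverage track as fixed-step wiggle
#'
#' One `fixedStep` block per contig at the track's bin size, for genome
#' browser inspection.
#'
#' @param tracks A list of coverage tracks from [bin_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       tr$contig, tr$bin_size, tr$bin_size), con)
    writeLines(format(tr$counts, scientific = FALSE, trim = TRUE), con)
  }
  invisible(path)
}
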