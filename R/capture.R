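#' THS-style capture: linear amplification of every insertion end
#'
#' Under in vitro transcription capture, each transposase cut carries a
#' phage promoter on both flanks, so every insertion yields usable ends
#' regardless of transposon orientation. Each cut produces up to two end
#' templates, one per flank, transcribing away from the cut until the
#' neighbouring cut on the same molecule (or the molecule end). A template
#' is captured when its runoff length lies within
#' `[ths_min_template, ths_max_template]`; each captured template is
#' linearly amplified into exactly `amp_factor` duplicate reads sharing one
#' duplicate group. The event's `orientation` field never gates capture.
#'
#' @param events Insertion events from [simulate_insertions()], sorted by
#'   (cell, molecule, contig, position).
#' @param params A [capture_params()] with `assay = "THS"`.
#' @param model The [genome_model()] the events were simulated on (supplies
#'   molecule/contig lengths for end runoff).
#' @param seed Integer seed, used only when `ths_end_efficiency < 1`.
#' @return A `data.frame` of captured reads with columns `contig`,
#'   `position` (0-based 5' end at the cut site), `strand` (`"+"` for the
#'   downstream flank, `"-"` for the upstream flank), `duplicate_group`
#'   (one per captured template) and `source_cell`.
#' @seealso [atac_capture()] for the PCR-constrained counterpart.
#' @export
ths_capture <- function(events, params, model, seed = 1L) {
  stopifnot(inherits(params, "CaptureParams"))
  if (params$assay != "THS") stop("`params$assay` must be \"THS\"",
                                  call. = FALSE)
  fl <- .flank_table(events, model)
  if (!nrow(fl$events)) return(.empty_reads())
  ev <- fl$events
  # upstream flank runs to the previous cut, downstream to the next
  cand <- data.frame(
    contig = rep(ev$contig, 2L),
    position = rep(ev$position, 2L),
    strand = rep(c("-", "+"), each = nrow(ev)),
    runoff = c(fl$left_gap, fl$right_gap),
    source_cell = rep(ev$cell_id, 2L)
  )
  keep <- cand$runoff >= params$ths_min_template &
    cand$runoff <= params$ths_max_template
  if (params$ths_end_efficiency < 1) {
    keep <- keep & withr::with_seed(
      seed, stats::runif(nrow(cand)) < params$ths_end_efficiency)
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(.empty_reads())
  cand$duplicate_group <- seq_len(nrow(cand))
  idx <- rep(seq_len(nrow(cand)), each = params$amp_factor)
  reads <- cand[idx, c("contig", "position", "strand", "duplicate_group",
                       "source_cell")]
  rownames(reads) <- NULL
  reads
}

#' ATAC-style capture: orientation- and spacing-constrained PCR
#'
#' Under PCR capture, only the DNA between two adjacent cuts on the same
#' molecule can become a library fragment, and only when the two inserted
#' adaptors are in the heteroadapter configuration required for
#' amplification — which under independent random transposon orientation
#' happens for half of the fragments — and when the fragment length falls
#' in `[atac_min_frag, atac_max_frag]`. Molecule ends never form fragments
#' (PCR needs an adaptor at both ends). Each amplifiable fragment receives
#' `1 + Geometric` PCR copies with mean `pcr_mean_copies`, and every copy
#' yields one read per fragment end, on opposite strands.
#'
#' The returned frame carries a `fragment_stats` attribute with the counts
#' of candidate adjacent pairs, heteroadapter pairs, and amplifiable
#' (heteroadapter and in-window) fragments.
#'
#' @inheritParams ths_capture
#' @param params A [capture_params()] with `assay = "ATAC"`.
#' @param seed Integer seed for the orientation draw and PCR copy numbers.
#' @return A `data.frame` of captured reads (columns as in
#'   [ths_capture()]); each fragment end is its own duplicate group.
#' @export
atac_capture <- function(events, params, model, seed = 1L) {
  stopifnot(inherits(params, "CaptureParams"))
  if (params$assay != "ATAC") stop("`params$assay` must be \"ATAC\"",
                                   call. = FALSE)
  fl <- .flank_table(events, model)
  ev <- fl$events
  i <- which(!fl$last_in_molecule)         # pair (i, i + 1)
  stats_out <- c(candidate_pairs = length(i), heteroadapter = 0L,
                 amplifiable = 0L)
  if (!length(i)) {
    out <- .empty_reads()
    attr(out, "fragment_stats") <- stats_out
    return(out)
  }
  frag_len <- ev$position[i + 1L] - ev$position[i]
  res <- withr::with_seed(seed, {
    hetero <- stats::rbinom(length(i), 1L, 0.5) == 1L
    ok <- hetero & frag_len >= params$atac_min_frag &
      frag_len <= params$atac_max_frag
    copies <- integer(0)
    if (any(ok)) {
      p <- 1 / params$pcr_mean_copies
      copies <- 1L + stats::rgeom(sum(ok), p)
    }
    list(hetero = hetero, ok = ok, copies = copies)
  })
  stats_out["heteroadapter"] <- sum(res$hetero)
  stats_out["amplifiable"] <- sum(res$ok)
  j <- i[res$ok]
  if (!length(j)) {
    out <- .empty_reads()
    attr(out, "fragment_stats") <- stats_out
    return(out)
  }
  ends <- data.frame(
    contig = rep(ev$contig[j], 2L),
    position = c(ev$position[j], ev$position[j + 1L]),
    strand = rep(c("+", "-"), each = length(j)),
    source_cell = rep(ev$cell_id[j], 2L),
    copies = rep(res$copies, 2L)
  )
  ends$duplicate_group <- seq_len(nrow(ends))
  idx <- rep(seq_len(nrow(ends)), times = ends$copies)
  reads <- ends[idx, c("contig", "position", "strand", "duplicate_group",
                       "source_cell")]
  rownames(reads) <- NULL
  attr(reads, "fragment_stats") <- stats_out
  reads
}

#' Convert captured reads to alignment records
#'
#' Models perfect mapping: contig, 5' position and strand are preserved and
#' the duplicate group is carried along as duplicate evidence. Output is
#' sorted by (contig, position, strand), the key order every downstream
#' processing step expects.
#'
#' @param reads Captured reads from [ths_capture()] or [atac_capture()].
#' @return A `data.frame` of alignment records with columns `contig`,
#'   `position`, `strand`, `duplicate_group`.
#' @export
reads_to_alignments <- function(reads) {
  rec <- data.frame(contig = as.character(reads$contig),
                    position = as.integer(reads$position),
                    strand = as.character(reads$strand),
                    duplicate_group =
                      if (is.null(reads$duplicate_group)) NA_integer_
                      else as.integer(reads$duplicate_group))
  rec <- rec[order(rec$contig, rec$position, rec$strand), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# Per-event flank geometry: distance to the previous / next cut on the same
# molecule, with molecule ends (position 0 and the contig length) closing
# the terminal flanks.
.flank_table <- function(events, model) {
  stopifnot(inherits(model, "GenomeModel"))
  ev <- as.data.frame(events)
  need <- c("cell_id", "molecule_id", "contig", "position")
  stopifnot(all(need %in% names(ev)))
  if (!nrow(ev)) {
    return(list(events = ev, left_gap = numeric(), right_gap = numeric(),
                last_in_molecule = logical()))
  }
  o <- order(ev$cell_id, ev$molecule_id, ev$contig, ev$position)
  if (!identical(o, seq_len(nrow(ev)))) ev <- ev[o, , drop = FALSE]
  clen <- model$contigs$length[match(ev$contig, model$contigs$name)]
  if (anyNA(clen)) stop("event on a contig absent from the model",
                        call. = FALSE)
  n <- nrow(ev)
  new_mol <- c(TRUE, ev$cell_id[-1] != ev$cell_id[-n] |
                 ev$molecule_id[-1] != ev$molecule_id[-n] |
                 ev$contig[-1] != ev$contig[-n])
  last <- c(new_mol[-1], TRUE)
  left_gap <- ev$position - c(0, ev$position[-n])
  left_gap[new_mol] <- ev$position[new_mol]            # runs to molecule start
  right_gap <- c(ev$position[-1], 0) - ev$position
  right_gap[last] <- clen[last] - ev$position[last]    # runs to molecule end
  list(events = ev, left_gap = left_gap, right_gap = right_gap,
       last_in_molecule = last)
}

.empty_reads <- function() {
  data.frame(contig = character(), position = integer(),
             strand = character(), duplicate_group = integer(),
             source_cell = integer())
}
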