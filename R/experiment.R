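#' Run a matched THS-versus-ATAC comparative simulation
#'
#' The package's end-to-end workflow on one synthetic genome: generate an
#' accessible-chromatin landscape, simulate per-molecule Tn5 insertions,
#' capture the events under both library models, collapse clonal reads,
#' down-sample both libraries to the smaller unique-alignment depth, and
#' call peaks on each with the stand-in caller. Everything downstream
#' (overlap statistics, capture metrics) can then be computed on the
#' returned pieces.
#'
#' @param seed Integer master seed; the landscape, insertions, both capture
#'   steps and both down-sampling draws use fixed offsets from it.
#' @param genome_size Nuclear genome size in bp (default 2 Mb).
#' @param mito_size Mitochondrial contig length in bp (`NULL` for none).
#' @param mito_copy_factor Per-cell copy factor of the mitochondrial
#'   contig.
#' @param accessible_fraction Fraction of the nuclear genome that is open.
#' @param rate_open,rate_closed Insertion rates per bp per molecule. The
#'   default open rate 0.004 puts the mean open-chromatin cut spacing at
#'   250 bp, inside the PCR-amplifiable window, so the ATAC mechanism is
#'   exercised rather than starved.
#' @param n_cells,molecules_per_cell Experiment size.
#' @param amp_factor Linear amplification fold used for the THS library in
#'   this simulation (duplicates are collapsed before any metric, so this
#'   only scales the pre-deduplication library).
#' @param bin_size,alpha,min_width Stand-in peak-caller settings.
#' @return A list: `config`, `model`, `params_ths`, `params_atac`,
#'   `summary_ths`, `summary_atac` (pre-down-sampling library summaries),
#'   `depth` (matched unique-alignment depth), `aln_ths`, `aln_atac`
#'   (depth-matched unique alignments), `peaks_ths`, `peaks_atac`, and
#'   `truth` (the accessible regions as a [peak_set()]).
#' @examples
#' \donttest{
#' ex <- run_comparative_experiment(seed = 1, genome_size = 5e5,
#'                                  n_cells = 50)
#' peak_sharing(ex$truth, ex$peaks_ths)
#' }
#' @export
run_comparative_experiment <- function(seed,
                                       genome_size = 2e6,
                                       mito_size = 16500,
                                       mito_copy_factor = 50,
                                       accessible_fraction = 0.01,
                                       rate_open = 0.004,
                                       rate_closed = 4e-5,
                                       n_cells = 100,
                                       molecules_per_cell = 2,
                                       amp_factor = 20,
                                       bin_size = 100,
                                       alpha = 0.01,
                                       min_width = 100) {
  cfg <- sim_config(seed = seed, accessible_fraction = accessible_fraction,
                    rate_open = rate_open, rate_closed = rate_closed,
                    n_cells = n_cells,
                    molecules_per_cell = molecules_per_cell)
  model <- generate_landscape(cfg, genome_size = genome_size,
                              mito_size = mito_size,
                              mito_copy_factor = mito_copy_factor)
  events <- simulate_insertions(model, cfg)

  params_ths <- capture_params("THS", amp_factor = amp_factor)
  params_atac <- capture_params("ATAC")
  reads_ths <- ths_capture(events, params_ths, model)
  reads_atac <- atac_capture(events, params_atac, model,
                             seed = cfg$seed + 2L)

  uniq_ths <- remove_clonal(reads_to_alignments(reads_ths))
  uniq_atac <- remove_clonal(reads_to_alignments(reads_atac))
  summary_ths <- summarize_library(reads_to_alignments(reads_ths), model)
  summary_atac <- summarize_library(reads_to_alignments(reads_atac), model)

  depth <- min(nrow(uniq_ths), nrow(uniq_atac))
  aln_ths <- downsample_alignments(uniq_ths, depth, seed = cfg$seed + 3L)
  aln_atac <- downsample_alignments(uniq_atac, depth, seed = cfg$seed + 4L)

  peaks_ths <- call_peaks_standin(bin_coverage(aln_ths, bin_size, model),
                                  alpha = alpha, min_width = min_width)
  peaks_ths$name <- "THS"
  peaks_atac <- call_peaks_standin(bin_coverage(aln_atac, bin_size, model),
                                   alpha = alpha, min_width = min_width)
  peaks_atac$name <- "ATAC"

  list(config = cfg, model = model,
       params_ths = params_ths, params_atac = params_atac,
       summary_ths = summary_ths, summary_atac = summary_atac,
       depth = depth, aln_ths = aln_ths, aln_atac = aln_atac,
       peaks_ths = peaks_ths, peaks_atac = peaks_atac,
       truth = truth_peaks(model))
}

#' Truth-region recall restricted to a length range
#'
#' Fraction of ground-truth accessible regions in `[min_len, max_len]` bp
#' that share at least one base pair with a called peak set.
#'
#' @param truth Truth regions as a [peak_set()] (see [truth_peaks()]).
#' @param peaks Called [peak_set()].
#' @param min_len,max_len Length range in bp (inclusive).
#' @return A list: `n_regions`, `n_recovered`, `recall` (fraction; `NA`
#'   when no region falls in the range).
#' @export
truth_recall_by_length <- function(truth, peaks, min_len = 0,
                                   max_len = Inf) {
  stopifnot(inherits(truth, "PeakSet"), inherits(peaks, "PeakSet"))
  len <- peak_lengths(truth)
  keep <- len >= min_len & len <= max_len
  sub <- peak_set(truth$peaks[keep, , drop = FALSE], name = truth$name)
  ov <- overlap_bp_per_peak(sub, peaks)
  list(n_regions = sum(keep), n_recovered = sum(ov > 0),
       recall = if (sum(keep)) sum(ov > 0) / sum(keep) else NA_real_)
}
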