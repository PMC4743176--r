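#' Simulation configuration
#'
#' Bundles every knob of the synthetic tagmentation experiment: the RNG
#' seed, the accessible-chromatin landscape (fraction of the genome open,
#' law for region lengths), per-base-pair insertion rates for open and
#' closed chromatin, and the number of cells and genome copies per cell.
#'
#' Rates are expressed as expected insertions per base pair per chromosomal
#' molecule, so the expected number of cuts a region of length L receives in
#' the whole experiment is `rate * L * n_cells * molecules_per_cell`
#' (times the region weight for open chromatin).
#'
#' @param seed Integer seed; all randomness in the simulation derives from
#'   it through fixed offsets (see package help).
#' @param accessible_fraction Target fraction of nuclear genome base pairs
#'   inside accessible regions. Default 0.01: roughly one percent of the
#'   genome is open in a typical cell.
#' @param region_length_range Numeric length-2 vector, bounds in bp of the
#'   log-uniform law used to draw accessible-region lengths. The default
#'   100-3000 bp spans the peak-length range analysed downstream.
#' @param rate_open Insertions per bp per molecule inside accessible
#'   regions (before the per-region `weight` multiplier).
#' @param rate_closed Insertions per bp per molecule in closed chromatin;
#'   must not exceed `rate_open`.
#' @param n_cells Number of cells in the experiment.
#' @param molecules_per_cell Copies of each nuclear contig per cell
#'   (2 for a diploid genome).
#'
#' @return An object of class `SimConfig`.
#' @examples
#' cfg <- sim_config(seed = 1, rate_open = 0.004, rate_closed = 4e-5)
#' cfg
#' @export
sim_config <- function(seed,
                       accessible_fraction = 0.01,
                       region_length_range = c(100, 3000),
                       rate_open = 0.004,
                       rate_closed = 4e-5,
                       n_cells = 100L,
                       molecules_per_cell = 2L) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  if (!is.numeric(accessible_fraction) || accessible_fraction < 0 ||
      accessible_fraction > 1) {
    stop("`accessible_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length(region_length_range) != 2L ||
      region_length_range[1] <= 0 ||
      region_length_range[1] > region_length_range[2]) {
    stop("`region_length_range` must be increasing positive bounds",
         call. = FALSE)
  }
  if (rate_open < 0 || rate_closed < 0 || !is.finite(rate_open) ||
      !is.finite(rate_closed)) {
    stop("insertion rates must be finite and non-negative", call. = FALSE)
  }
  if (rate_closed > rate_open) {
    stop("`rate_closed` must not exceed `rate_open`", call. = FALSE)
  }
  stopifnot(n_cells >= 1, molecules_per_cell >= 1)
  structure(
    list(
      seed = seed,
      accessible_fraction = accessible_fraction,
      region_length_range = as.numeric(region_length_range),
      rate_open = rate_open,
      rate_closed = rate_closed,
      n_cells = as.integer(n_cells),
      molecules_per_cell = as.integer(molecules_per_cell)
    ),
    class = "SimConfig"
  )
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  accessible fraction: %g\n", x$accessible_fraction))
  cat(sprintf("  region lengths: log-uniform [%g, %g] bp\n",
              x$region_length_range[1], x$region_length_range[2]))
  cat(sprintf("  rates (ins/bp/molecule): open %g, closed %g\n",
              x$rate_open, x$rate_closed))
  cat(sprintf("  cells: %d, molecules per cell: %d\n",
              x$n_cells, x$molecules_per_cell))
  invisible(x)
}

#' Capture (library chemistry) parameters
#'
#' Parameters of the two read-capture mechanisms applied to simulated
#' insertion events.
#'
#' For the THS model every insertion end is a candidate template that runs
#' off to the neighbouring cut (or molecule end); templates whose runoff
#' length falls in `[ths_min_template, ths_max_template]` are linearly
#' amplified into exactly `amp_factor` duplicate reads. For the ATAC model
#' each pair of adjacent cuts on a molecule is a candidate fragment;
#' a fragment amplifies only when its two adaptors are in the heteroadapter
#' (PCR-compatible) configuration — probability 1/2 under independent random
#' orientation — and when its length falls in
#' `[atac_min_frag, atac_max_frag]`; PCR copy numbers follow a geometric law.
#'
#' @param assay `"THS"` or `"ATAC"`.
#' @param amp_factor Linear amplification fold for THS templates
#'   (default 1000, the nominal in vitro transcription yield).
#' @param ths_min_template,ths_max_template Template runoff window in bp
#'   for THS capture (default 400-2000, the observed in vitro transcript
#'   size range).
#' @param atac_min_frag,atac_max_frag Amplifiable fragment window in bp for
#'   ATAC capture (default 200-800, the observed PCR fragment size range).
#'   Set to `0` and `Inf` to disable size selection.
#' @param read_length Read length in bp (metadata for SAM export only;
#'   capture decisions use template/fragment lengths).
#' @param pcr_mean_copies Mean number of PCR copies per amplifiable ATAC
#'   fragment; copies are `1 + Geometric`, so the mean must be >= 1.
#' @param ths_end_efficiency Probability that one insertion end forms a
#'   working template (default 1: both flanks always transcribable).
#'
#' @return An object of class `CaptureParams`.
#' @examples
#' capture_params("THS")
#' capture_params("ATAC", atac_min_frag = 0, atac_max_frag = Inf)
#' @export
capture_params <- function(assay = c("THS", "ATAC"),
                           amp_factor = 1000L,
                           ths_min_template = 400,
                           ths_max_template = 2000,
                           atac_min_frag = 200,
                           atac_max_frag = 800,
                           read_length = 50L,
                           pcr_mean_copies = 2,
                           ths_end_efficiency = 1) {
  assay <- match.arg(assay)
  stopifnot(amp_factor >= 1,
            ths_min_template < ths_max_template,
            atac_min_frag < atac_max_frag,
            read_length >= 1,
            pcr_mean_copies >= 1,
            ths_end_efficiency >= 0, ths_end_efficiency <= 1)
  structure(
    list(
      assay = assay,
      amp_factor = as.integer(amp_factor),
      ths_min_template = ths_min_template,
      ths_max_template = ths_max_template,
      atac_min_frag = atac_min_frag,
      atac_max_frag = atac_max_frag,
      read_length = as.integer(read_length),
      pcr_mean_copies = pcr_mean_copies,
      ths_end_efficiency = ths_end_efficiency
    ),
    class = "CaptureParams"
  )
}

#' @export
print.CaptureParams <- function(x, ...) {
  cat(sprintf("CaptureParams <%s>\n", x$assay))
  if (x$assay == "THS") {
    cat(sprintf("  template window: [%g, %g] bp, amplification x%d\n",
                x$ths_min_template, x$ths_max_template, x$amp_factor))
  } else {
    cat(sprintf("  fragment window: [%g, %g] bp, mean PCR copies %g\n",
                x$atac_min_frag, x$atac_max_frag, x$pcr_mean_copies))
  }
  invisible(x)
}
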