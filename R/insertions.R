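#' Simulate Tn5 insertion events
#'
#' Draws transposition events molecule by molecule. Each cell carries
#' `molecules_per_cell` copies of every nuclear contig; the mitochondrial
#' contig (if any) is carried at `molecules_per_cell * mito_copy_factor`
#' copies, modelling its elevated per-cell copy number rather than an
#' elevated per-copy insertion rate. On one molecule the number of cuts in
#' any interval is Poisson with rate `rate_closed * length` outside
#' accessible regions and `rate_open * weight * length` inside; cut
#' positions are uniform within their interval. Each insertion leaves its
#' transposon in a random orientation — an independent fair draw — which
#' matters only to PCR-based capture downstream.
#'
#' @param model A [genome_model()].
#' @param config A [sim_config()]; the insertion stream uses
#'   `config$seed + 1L`.
#' @return A `data.frame` of insertion events with columns `cell_id`,
#'   `molecule_id` (copy index of the contig within the cell), `contig`,
#'   `position` (0-based cut site) and `orientation`
#'   (`"forward"`/`"reverse"`), sorted by (cell, molecule, contig,
#'   position).
#' @examples
#' cfg <- sim_config(seed = 1, n_cells = 2, molecules_per_cell = 2,
#'                   rate_open = 0.01, rate_closed = 1e-4)
#' m <- generate_landscape(cfg, genome_size = 1e5)
#' ev <- simulate_insertions(m, cfg)
#' head(ev)
#' @export
simulate_insertions <- function(model, config) {
  stopifnot(inherits(model, "GenomeModel"), inherits(config, "SimConfig"))
  segs <- .rate_segments(model, config)
  copies <- .contig_copies(model, config)

  withr::with_seed(config$seed + 1L, {
    out <- vector("list", nrow(model$contigs))
    for (k in seq_len(nrow(model$contigs))) {
      cname <- model$contigs$name[k]
      s <- segs[segs$contig == cname, , drop = FALSE]
      s <- s[s$rate > 0 & s$len > 0, , drop = FALSE]
      if (!nrow(s)) next
      nmol <- config$n_cells * copies[[cname]]
      # one Poisson draw per (segment, molecule instance)
      lam <- rep(s$rate * s$len, times = nmol)
      cnt <- stats::rpois(length(lam), lam)
      if (!sum(cnt)) next
      seg_i <- rep(rep(seq_len(nrow(s)), times = nmol), cnt)
      mol_i <- rep(rep(seq_len(nmol), each = nrow(s)), cnt)
      pos <- s$start[seg_i] +
        floor(stats::runif(sum(cnt)) * s$len[seg_i])
      out[[k]] <- data.frame(
        cell_id = (mol_i - 1L) %/% copies[[cname]] + 1L,
        molecule_id = (mol_i - 1L) %% copies[[cname]] + 1L,
        contig = cname,
        position = as.integer(pos),
        stringsAsFactors = FALSE
      )
    }
    ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(ev)) {
      ev <- data.frame(cell_id = integer(), molecule_id = integer(),
                       contig = character(), position = integer(),
                       orientation = character())
    } else {
      ev$orientation <- c("forward", "reverse")[
        stats::rbinom(nrow(ev), 1L, 0.5) + 1L]
      ev <- ev[order(ev$cell_id, ev$molecule_id, ev$contig, ev$position), ,
               drop = FALSE]
      rownames(ev) <- NULL
    }
    ev
  })
}

# Piecewise-constant insertion-rate segments of every contig:
# closed gaps at rate_closed, accessible regions at rate_open * weight.
.rate_segments <- function(model, config) {
  out <- vector("list", nrow(model$contigs))
  for (k in seq_len(nrow(model$contigs))) {
    cname <- model$contigs$name[k]
    clen <- model$contigs$length[k]
    r <- model$regions[model$regions$contig == cname, , drop = FALSE]
    bounds <- c(0, as.vector(rbind(r$start, r$end)), clen)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    open <- rep(c(FALSE, TRUE), length.out = length(starts))
    w <- rep(1, length(starts))
    if (nrow(r)) w[open] <- r$weight
    out[[k]] <- data.frame(
      contig = cname, start = starts, len = ends - starts,
      rate = ifelse(open, config$rate_open * w, config$rate_closed)
    )
  }
  do.call(rbind, out)
}

# Per-cell molecule copies of each contig.
.contig_copies <- function(model, config) {
  copies <- as.list(rep(config$molecules_per_cell, nrow(model$contigs)))
  names(copies) <- model$contigs$name
  if (!is.null(model$mito_contig)) {
    copies[[model$mito_contig]] <-
      max(1L, as.integer(round(config$molecules_per_cell *
                                 model$mito_copy_factor)))
  }
  copies
}
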