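#' Construct a genome model
#'
#' A genome model is the ground truth of a simulated experiment: a set of
#' contigs, the accessible regions on them (0-based half-open intervals
#' with a relative insertion-rate weight), and optionally a mitochondrial
#' contig carried at elevated copy number per cell.
#'
#' @param contigs `data.frame` with columns `name` (character) and `length`
#'   (positive bp).
#' @param regions `data.frame` with columns `contig`, `start`, `end`,
#'   `weight`; may have zero rows. Regions must fall inside their contig
#'   and must not overlap on a contig.
#' @param mito_contig Name of the mitochondrial contig, or `NULL`.
#' @param mito_copy_factor Relative molecule copy number of the
#'   mitochondrial contig per cell (ignored when `mito_contig` is `NULL`).
#'
#' @return An object of class `GenomeModel`.
#' @export
genome_model <- function(contigs, regions = NULL, mito_contig = NULL,
                         mito_copy_factor = 1) {
  contigs <- as.data.frame(contigs)
  stopifnot(all(c("name", "length") %in% names(contigs)))
  contigs$name <- as.character(contigs$name)
  contigs$length <- as.numeric(contigs$length)
  if (anyDuplicated(contigs$name)) {
    stop("contig names must be unique", call. = FALSE)
  }
  if (any(contigs$length <= 0)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  if (is.null(regions)) {
    regions <- data.frame(contig = character(), start = numeric(),
                          end = numeric(), weight = numeric())
  }
  regions <- as.data.frame(regions)
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  if (is.null(regions$weight)) regions$weight <- rep(1, nrow(regions))
  regions$contig <- as.character(regions$contig)
  if (nrow(regions)) {
    clen <- contigs$length[match(regions$contig, contigs$name)]
    if (anyNA(clen)) stop("region on unknown contig", call. = FALSE)
    if (any(regions$start < 0 | regions$start >= regions$end |
            regions$end > clen)) {
      stop("regions must satisfy 0 <= start < end <= contig length",
           call. = FALSE)
    }
    if (any(regions$weight <= 0)) {
      stop("region weights must be positive", call. = FALSE)
    }
    o <- order(regions$contig, regions$start)
    regions <- regions[o, , drop = FALSE]
    same <- regions$contig[-1] == regions$contig[-nrow(regions)]
    if (nrow(regions) > 1 &&
        any(same & regions$start[-1] < regions$end[-nrow(regions)])) {
      stop("accessible regions on a contig must not overlap", call. = FALSE)
    }
    rownames(regions) <- NULL
  }
  if (!is.null(mito_contig)) {
    if (!mito_contig %in% contigs$name) {
      stop("`mito_contig` is not one of the contigs", call. = FALSE)
    }
    stopifnot(mito_copy_factor > 0)
  }
  structure(
    list(contigs = contigs, regions = regions,
         mito_contig = mito_contig,
         mito_copy_factor = if (is.null(mito_contig)) 1 else mito_copy_factor),
    class = "GenomeModel"
  )
}

#' @export
print.GenomeModel <- function(x, ...) {
  gsize <- sum(x$contigs$length)
  abp <- sum(x$regions$end - x$regions$start)
  cat(sprintf("GenomeModel: %d contig(s), %s bp total\n",
              nrow(x$contigs), format(gsize, big.mark = ",")))
  cat(sprintf("  accessible: %d region(s), %s bp (%.3f%% of genome)\n",
              nrow(x$regions), format(abp, big.mark = ","),
              100 * abp / gsize))
  if (!is.null(x$mito_contig)) {
    cat(sprintf("  mitochondrial contig: %s (copy factor %g)\n",
                x$mito_contig, x$mito_copy_factor))
  }
  invisible(x)
}

#' Generate an accessible-chromatin landscape
#'
#' Places non-overlapping accessible regions uniformly at random on the
#' nuclear contigs until their total length reaches the configured fraction
#' of the nuclear genome. Region lengths are drawn log-uniformly from
#' `config$region_length_range`. Placements that would overlap an existing
#' region or run off a contig end are rejected and redrawn, never clipped.
#'
#' @param config A [sim_config()].
#' @param genome_size Total nuclear genome size in bp. Either a single
#'   number (one contig named `"chr1"`) or a named vector of contig
#'   lengths.
#' @param mito_size Length in bp of an added mitochondrial contig
#'   (`"chrM"`), or `NULL` for none. The mitochondrial contig never
#'   receives accessible regions and does not count towards the accessible
#'   fraction.
#' @param mito_copy_factor Relative per-cell copy number of the
#'   mitochondrial contig.
#' @param region_weight Insertion-rate weight given to every placed region.
#'
#' @return A [genome_model()] whose accessible base-pair total is within
#'   20 percent (relative) of `accessible_fraction * genome_size`;
#'   deterministic given `config$seed`.
#' @examples
#' cfg <- sim_config(seed = 7, accessible_fraction = 0.01)
#' m <- generate_landscape(cfg, genome_size = 1e6)
#' m
#' @export
generate_landscape <- function(config, genome_size = 2e6,
                               mito_size = NULL, mito_copy_factor = 50,
                               region_weight = 1) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(names(genome_size))) {
    if (length(genome_size) != 1L) {
      stop("unnamed `genome_size` must be a single total", call. = FALSE)
    }
    contig_len <- c(chr1 = as.numeric(genome_size))
  } else {
    contig_len <- as.numeric(genome_size)
    names(contig_len) <- names(genome_size)
  }
  total <- sum(contig_len)
  target <- config$accessible_fraction * total
  lo <- config$region_length_range[1]
  hi <- config$region_length_range[2]
  if (target > 0 && target < lo) {
    stop("requested accessible fraction is below the minimum region length",
         call. = FALSE)
  }
  if (target > 0.5 * total) {
    stop("requested accessible fraction infeasible for non-overlapping ",
         "placement on this genome", call. = FALSE)
  }

  regions <- withr::with_seed(config$seed, {
    placed <- vector("list", 0L)
    # per-contig occupied intervals, kept sorted
    occ <- lapply(contig_len, function(x) {
      data.frame(start = numeric(), end = numeric())
    })
    acc <- 0
    attempts <- 0L
    max_attempts <- 10000L + 200L * ceiling(target / lo)
    while (acc < target) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not reach the requested accessible fraction; ",
             "configuration infeasible for this genome", call. = FALSE)
      }
      len <- floor(exp(stats::runif(1, log(lo), log(hi))))
      remaining <- target - acc
      if (len > remaining && (len - remaining) > remaining) {
        # overshooting is worse than stopping short: stop if already within
        # tolerance, otherwise redraw a shorter region
        if (remaining / target <= 0.2) break
        next
      }
      ci <- sample.int(length(contig_len), 1L, prob = contig_len)
      cl <- contig_len[ci]
      if (len > cl) next
      start <- floor(stats::runif(1, 0, cl - len))
      end <- start + len
      o <- occ[[ci]]
      if (nrow(o) && any(start < o$end & o$start < end)) next
      occ[[ci]] <- rbind(o, data.frame(start = start, end = end))
      placed[[length(placed) + 1L]] <-
        data.frame(contig = names(contig_len)[ci], start = start, end = end,
                   weight = region_weight)
      acc <- acc + len
    }
    if (length(placed)) do.call(rbind, placed) else NULL
  })

  contigs <- data.frame(name = names(contig_len), length = contig_len,
                        row.names = NULL)
  mito <- NULL
  if (!is.null(mito_size)) {
    contigs <- rbind(contigs,
                     data.frame(name = "chrM", length = as.numeric(mito_size)))
    mito <- "chrM"
  }
  genome_model(contigs, regions,
               mito_contig = mito, mito_copy_factor = mito_copy_factor)
}

#' Accessible base pairs of a genome model
#' @param model A [genome_model()].
#' @return Total accessible bp.
#' @export
accessible_bp <- function(model) {
  stopifnot(inherits(model, "GenomeModel"))
  sum(model$regions$end - model$regions$start)
}

#' Export truth regions as BED
#'
#' Writes the model's accessible regions to a 4-column BED file (contig,
#' start, end, weight as score), 0-based half-open, in coordinate order.
#' The file round-trips losslessly through [read_peaks()].
#'
#' @param model A [genome_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(model, path) {
  stopifnot(inherits(model, "GenomeModel"))
  r <- model$regions
  lines <- if (nrow(r)) {
    sprintf("%s\t%d\t%d\t%g", r$contig, as.integer(r$start),
            as.integer(r$end), r$weight)
  } else {
    character()
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Accessible regions of a model as a peak set
#'
#' Convenience view of the ground-truth landscape in the container used by
#' all overlap statistics, so truth recall can be computed directly with
#' [peak_sharing()] or [basepair_overlap()].
#'
#' @param model A [genome_model()].
#' @return A [peak_set()] named `"truth"`.
#' @export
truth_peaks <- function(model) {
  stopifnot(inherits(model, "GenomeModel"))
  r <- model$regions
  peak_set(data.frame(contig = r$contig, start = r$start, end = r$end,
                      score = r$weight),
           name = "truth")
}
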