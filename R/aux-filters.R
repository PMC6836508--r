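## Optional post-filters on read depth and assembly-gap content. Off by
## default: they are meant for samples distantly related to the reference or
## for gappy assemblies, where true deletions/duplications should show
## clearly lower/higher depth and calls flanked by Ns are suspect.

#' Auxiliary filter configuration
#'
#' All thresholds are configuration, not constants: the underlying evidence
#' is a pair of density plots without printed cutoffs, so defaults sit
#' between the expected depth modes of heterozygous and homozygous events.
#' Removal uses strict inequalities, so boundary values survive.
#'
#' @param del_max_depth_ratio Deletions kept iff normalized depth ratio is at
#'   most this (default 0.75).
#' @param dup_min_depth_ratio Duplications kept iff the ratio is at least
#'   this (default 1.25).
#' @param excessive_depth Any call with raw median depth above this is
#'   removed (default 1000).
#' @param flank_bp Width of the flanking windows for the gap filter
#'   (default 400).
#' @param max_flank_n_fraction Calls whose flank N-fraction exceeds this are
#'   removed (default 0.5).
#' @param enabled Whether the pipeline applies these filters (default FALSE).
#' @return An `aux_filter_config` list.
#' @export
aux_filter_config <- function(del_max_depth_ratio = 0.75,
                              dup_min_depth_ratio = 1.25,
                              excessive_depth = 1000, flank_bp = 400,
                              max_flank_n_fraction = 0.5, enabled = FALSE) {
  stopifnot(del_max_depth_ratio > 0, del_max_depth_ratio < 1,
            dup_min_depth_ratio > 1, flank_bp > 0)
  structure(list(del_max_depth_ratio = del_max_depth_ratio,
                 dup_min_depth_ratio = dup_min_depth_ratio,
                 excessive_depth = excessive_depth, flank_bp = flank_bp,
                 max_flank_n_fraction = max_flank_n_fraction,
                 enabled = enabled),
            class = "aux_filter_config")
}

#' Per-base depth track
#'
#' A provider contract mapping `(chrom, start, end)` to per-base depths.
#' Tests feed synthetic vectors; production feeds a bedgraph-style track
#' computed by standard external tooling (depth computation from alignments
#' is deliberately not re-implemented here).
#'
#' @param depths Named list of non-negative numeric vectors, one per
#'   chromosome, one value per base.
#' @return A `depth_track` with cached per-chromosome median depths.
#' @export
depth_track <- function(depths) {
  stopifnot(is.list(depths), !is.null(names(depths)))
  lapply(depths, function(d) stopifnot(is.numeric(d), all(d >= 0)))
  structure(list(depths = depths,
                 chrom_median = vapply(depths, median, numeric(1))),
            class = "depth_track")
}

#' Read a bedgraph-style interval depth file into a [depth_track()]
#'
#' Four tab-separated columns (chrom, start, end, depth; 0-based half-open),
#' expanded to per-base vectors over `chrom_lengths`.
#'
#' @param path Text file (optionally gzipped).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @export
read_depth_bedgraph <- function(path, chrom_lengths) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "depth"))
  depths <- lapply(names(chrom_lengths), function(cr) {
    v <- numeric(chrom_lengths[[cr]])
    rows <- df[df$chrom == cr, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      v[(rows$start[i] + 1):rows$end[i]] <- rows$depth[i]
    v
  })
  depth_track(stats::setNames(depths, names(chrom_lengths)))
}

call_depth_region <- function(call) {
  if (call$type == "INS") c(call$ins_pos, call$ins_pos + 1)
  else c(call$start, call$end)
}

region_depths <- function(track, chrom, start, end) {
  d <- track$depths[[chrom]]
  if (is.null(d)) stop("chromosome absent from depth track: ", chrom)
  if (start < 0 || end > length(d)) stop("region outside depth track extent")
  d[(start + 1):end]
}

#' Normalized median depth of a call region
#'
#' Median per-base depth over the call region divided by the median depth of
#' its chromosome. A true deletion sits well below 1, a duplication above.
#'
#' @param call One-row call table.
#' @param track A [depth_track()].
#' @return A single ratio.
#' @export
normalized_median_depth <- function(call, track) {
  stopifnot(inherits(track, "depth_track"), nrow(call) == 1L)
  reg <- call_depth_region(call)
  if (!call$chrom %in% names(track$depths))
    stop("chromosome absent from depth track: ", call$chrom)
  cm <- track$chrom_median[[call$chrom]]
  if (is.na(cm) || cm == 0) stop("zero median depth on ", call$chrom)
  median(region_depths(track, call$chrom, reg[1], reg[2])) / cm
}

#' Depth-based call filter
#'
#' Deletions are retained iff their normalized median depth ratio is at most
#' `del_max_depth_ratio`; tandem and dispersed duplications iff it is at
#' least `dup_min_depth_ratio`; insertions are not ratio-tested. Any call
#' whose raw median depth exceeds `excessive_depth` is removed regardless —
#' such pile-ups are collapsed-repeat artifacts. A subset operator:
#' idempotent, never modifies calls; removals are logged in the `"removed"`
#' attribute with a reason.
#'
#' @param calls Call table.
#' @param track A [depth_track()].
#' @param cfg An [aux_filter_config()].
#' @return Filtered calls (order preserved).
#' @export
depth_filter <- function(calls, track, cfg = aux_filter_config()) {
  validate_calls(calls)
  if (is.null(track)) stop("depth filter requires a depth track")
  keep <- rep(TRUE, nrow(calls))
  reason <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, , drop = FALSE]
    reg <- call_depth_region(cl)
    raw <- median(region_depths(track, cl$chrom, reg[1], reg[2]))
    ratio <- raw / track$chrom_median[[cl$chrom]]
    if (raw > cfg$excessive_depth) {
      keep[i] <- FALSE; reason[i] <- "excessive_depth"
    } else if (cl$type == "DEL" && ratio > cfg$del_max_depth_ratio) {
      keep[i] <- FALSE; reason[i] <- "depth_not_deleted"
    } else if (cl$type %in% c("TDUP", "DDUP") &&
               ratio < cfg$dup_min_depth_ratio) {
      keep[i] <- FALSE; reason[i] <- "depth_not_duplicated"
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(id = calls$id[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(toupper(genome)))
  stop("genome must be a named character vector or a DNAStringSet")
}

#' Fraction of assembly-gap (N) bases flanking a call
#'
#' Counts N bases in the `flank_bp`-wide windows immediately upstream of the
#' 5' breakend and downstream of the 3' breakend, clipped at chromosome
#' boundaries (the denominator shrinks accordingly). Flanks only — the call
#' interior is not examined.
#'
#' @param call One-row call table.
#' @param genome Named character vector of sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param cfg An [aux_filter_config()].
#' @return Fraction in `[0, 1]`.
#' @export
flank_gap_fraction <- function(call, genome, cfg = aux_filter_config()) {
  stopifnot(nrow(call) == 1L)
  genome <- as_genome(genome)
  if (!call$chrom %in% names(genome))
    stop("chromosome absent from genome: ", call$chrom)
  seq <- genome[[call$chrom]]
  len <- length(seq)
  reg <- if (call$type == "INS") c(call$ins_pos, call$ins_pos)
         else c(call$start, call$end)
  up <- c(max(0, reg[1] - cfg$flank_bp), min(reg[1], len))
  down <- c(max(0, min(reg[2], len)), min(reg[2] + cfg$flank_bp, len))
  n_bases <- 0; total <- 0
  for (w in list(up, down)) {
    if (w[2] <= w[1]) next
    sub <- Biostrings::subseq(seq, w[1] + 1, w[2])
    n_bases <- n_bases +
      as.numeric(Biostrings::letterFrequency(sub, letters = "N"))
    total <- total + (w[2] - w[1])
  }
  if (total == 0) return(0)
  unname(n_bases / total)
}

#' Flanking-gap call filter
#'
#' Removes calls whose flank N-fraction strictly exceeds
#' `max_flank_n_fraction`; order preserved, idempotent.
#'
#' @inheritParams flank_gap_fraction
#' @param calls Call table.
#' @return Filtered calls with a `"removed"` attribute.
#' @export
gap_filter <- function(calls, genome, cfg = aux_filter_config()) {
  validate_calls(calls)
  frac <- vapply(seq_len(nrow(calls)), function(i)
    flank_gap_fraction(calls[i, , drop = FALSE], genome, cfg), numeric(1))
  keep <- !(frac > cfg$max_flank_n_fraction)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(id = calls$id[!keep],
                                     reason = rep("flank_gap_fraction",
                                                  sum(!keep)),
                                     stringsAsFactors = FALSE)
  out
}
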