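## Ensemble merging: collapse calls from different tools that represent the
## same CNV event.

#' Merge configuration
#'
#' Calls are merged when they are of the same type, their breakpoints lie
#' within `breakpoint_window` bp of each other on both the 5' and 3' end,
#' they share at least `min_reciprocal_overlap` reciprocal overlap (not
#' applied to insertions), and their insertion sites are no more than
#' `insertion_site_window` bp apart (applied to insertions and dispersed
#' duplications only).
#'
#' @param breakpoint_window bp, default 1000.
#' @param min_reciprocal_overlap Fraction in (0, 1], default 0.5.
#' @param insertion_site_window bp, default 10.
#' @return A `merge_config` list.
#' @export
merge_config <- function(breakpoint_window = 1000,
                         min_reciprocal_overlap = 0.5,
                         insertion_site_window = 10) {
  stopifnot(breakpoint_window >= 0, insertion_site_window >= 0,
            min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  structure(list(breakpoint_window = breakpoint_window,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 insertion_site_window = insertion_site_window),
            class = "merge_config")
}

#' Are two calls merge-compatible?
#'
#' All four merge conditions tested pairwise; for dispersed duplications the
#' breakpoint-window and reciprocal-overlap tests apply to the template
#' region and the insertion-site test to the insertion point.
#'
#' @param a,b One-row call tables.
#' @param cfg A [merge_config()].
#' @return `TRUE`/`FALSE`.
#' @export
mergeable <- function(a, b, cfg = merge_config()) {
  if (a$type != b$type || a$chrom != b$chrom) return(FALSE)
  if (abs(a$start - b$start) > cfg$breakpoint_window) return(FALSE)
  if (abs(a$end - b$end) > cfg$breakpoint_window) return(FALSE)
  if (a$type != "INS") {
    ov <- min(a$end, b$end) - max(a$start, b$start)
    la <- a$end - a$start
    lb <- b$end - b$start
    if (ov <= 0 || la <= 0 || lb <= 0) return(FALSE)
    if (ov / la < cfg$min_reciprocal_overlap ||
        ov / lb < cfg$min_reciprocal_overlap) return(FALSE)
  }
  if (a$type %in% c("INS", "DDUP")) {
    if (is.na(a$ins_pos) || is.na(b$ins_pos)) return(FALSE)
    if (!identical(a$ins_chrom, b$ins_chrom)) return(FALSE)
    if (abs(a$ins_pos - b$ins_pos) > cfg$insertion_site_window) return(FALSE)
  }
  TRUE
}

## even-count median = arithmetic mean of the central pair (stats::median)
merge_component <- function(donors, mid) {
  type <- donors$type[1]
  start <- min(donors$start)
  end <- max(donors$end)
  ins_pos <- if (type %in% c("INS", "DDUP")) median(donors$ins_pos)
             else NA_real_
  ins_chrom <- if (type %in% c("INS", "DDUP")) donors$ins_chrom[1]
               else NA_character_
  if (type == "INS") {
    start <- ins_pos
    end <- ins_pos
  }
  seqs <- donors$inserted_seq[!is.na(donors$inserted_seq) &
                                donors$inserted_seq != UNKNOWN_SEQ]
  inserted_seq <- if (type != "INS") NA_character_
                  else if (length(seqs)) seqs[which.max(nchar(seqs))]
                  else UNKNOWN_SEQ
  out <- cnv_calls(
    type = type, chrom = donors$chrom[1], start = start, end = end,
    ins_chrom = ins_chrom, ins_pos = ins_pos, inserted_seq = inserted_seq,
    pe_support = median(donors$pe_support),
    sr_support = median(donors$sr_support),
    source_tools = paste(sort(unique(unlist(
      strsplit(donors$source_tools, ",")))), collapse = ","),
    n_donors = sum(donors$n_donors), id = mid)
  if (type == "INS" && is.na(out$size)) {
    known <- donors$size[!is.na(donors$size)]
    if (length(known)) out$size <- median(known)
  }
  out
}

#' Merge concordant calls across tools
#'
#' Single-linkage connected components under [mergeable()]: each component
#' becomes one merged call whose region is the union (minimal covering
#' interval) of the donor regions, whose PE/SR supports are the medians of
#' the donor supports, and whose tool set is the union of the donor tools.
#' Singletons pass through as one-donor merged calls. Output is
#' deterministic and order-invariant in the input.
#'
#' @param calls Call table (all tools).
#' @param cfg A [merge_config()].
#' @return Merged call table; attribute `"donor_map"` maps merged ids to
#'   donor call ids.
#' @export
merge_calls <- function(calls, cfg = merge_config()) {
  validate_calls(calls)
  if (nrow(calls) == 0L) {
    out <- empty_calls()
    attr(out, "donor_map") <- data.frame(merged_id = character(0),
                                         donor_id = character(0),
                                         stringsAsFactors = FALSE)
    return(out)
  }
  calls <- sort_calls(calls)
  n <- nrow(calls)
  parent <- uf_new(n)
  ## block by (type, chrom) then test pairs within breakpoint-window reach
  blocks <- split(seq_len(n), paste(calls$type, calls$chrom))
  for (ix in blocks) {
    if (length(ix) < 2L) next
    for (p in seq_along(ix)) {
      for (q in seq_along(ix)) {
        if (q <= p) next
        i <- ix[p]; j <- ix[q]
        if (calls$start[j] - calls$start[i] > cfg$breakpoint_window) break
        if (mergeable(calls[i, ], calls[j, ], cfg)) {
          ra <- uf_find(parent, i); rb <- uf_find(parent, j)
          if (ra != rb) {
            root <- min(ra, rb)
            parent[ra] <- root
            parent[rb] <- root
          }
        }
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), comp)
  merged <- vector("list", length(groups))
  donor_map <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    ix <- groups[[k]]
    mid <- sprintf("m%d", k)
    merged[[k]] <- merge_component(calls[ix, , drop = FALSE], mid)
    donor_map[[k]] <- data.frame(merged_id = mid, donor_id = calls$id[ix],
                                 donor_tool = calls$source_tools[ix],
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged)
  dm <- do.call(rbind, donor_map)
  ord <- order(out$chrom, out$start, out$end, match(out$type, CNV_TYPES))
  out <- out[ord, , drop = FALSE]
  ## renumber merged ids in output order so results are order-invariant
  new_id <- stats::setNames(sprintf("m%d", seq_len(nrow(out))), out$id)
  dm$merged_id <- as.character(new_id[dm$merged_id])
  out$id <- as.character(new_id[out$id])
  rownames(out) <- NULL
  dm <- dm[order(dm$merged_id, dm$donor_id), ]
  rownames(dm) <- NULL
  attr(out, "donor_map") <- dm
  out
}
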