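#' @useDynLib cnvpost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm rpois runif
#' @importFrom utils read.delim write.table head
"_PACKAGE"

## Orientation vocabulary -----------------------------------------------------
##
## Every breakend is a junction coordinate in 0-based, half-open space:
## an "R" (right-anchored) breakend at position p means the retained reference
## sequence occupies [.., p) and the sample sequence jumps away after base
## p - 1; an "L" (left-anchored) breakend at p means the retained sequence
## occupies [p, ..) and the jump lands just before base p.  Under this
## convention a deletion of region [s, e) is the single adjacency (s R, e L)
## and a tandem duplication of [s, e) is (s L, e R).
##
## Bijections used throughout the package:
##   * BEDPE strands: R <-> "+", L <-> "-".
##   * VCF breakend (BND) bracket notation: see `bnd_alt()` / `parse_bnd_alt()`.
##   * VCF 1-based POS: an R breakend at junction p is written POS = p (the
##     1-based index of the last retained base); an L breakend is POS = p + 1
##     (first retained base).  Conversion to/from VCF happens once, at I/O.

ORI_RIGHT <- "R"
ORI_LEFT <- "L"

CNV_TYPES <- c("DEL", "INS", "TDUP", "DDUP")
CALLER_TOOLS <- c("DELLY", "GRIDSS", "LUMPY", "MANTA", "SIM")

## Sentinel for an insertion whose sequence (hence size) is unresolved.
## Distinct from NA (= no inserted sequence at all) so that missingness of the
## size feature is explicit and can never leak into arithmetic.
UNKNOWN_SEQ <- "*"

ADJ_COLS <- c(
  id = "character", chrom1 = "character", pos1 = "numeric", ori1 = "character",
  chrom2 = "character", pos2 = "numeric", ori2 = "character",
  inserted_seq = "character", pe = "numeric", sr = "numeric",
  tool = "character"
)

CALL_COLS <- c(
  id = "character", type = "character", chrom = "character",
  start = "numeric", end = "numeric", ins_chrom = "character",
  ins_pos = "numeric", inserted_seq = "character", size = "numeric",
  pe_support = "numeric", sr_support = "numeric", source_tools = "character",
  n_donors = "numeric", score = "numeric"
)

#' Construct a table of novel adjacencies
#'
#' A novel adjacency joins two breakends: a pair of bases that are adjacent in
#' the sample genome but not in the reference. The two breakends of one
#' adjacency ("mates") are always stored together on one row, never as
#' separate records. Rows are canonicalized so that
#' `(chrom1, pos1) <= (chrom2, pos2)` (chromosome-major, then position, ties
#' broken with the right-anchored breakend first).
#'
#' @param chrom1,pos1,ori1 First breakend: chromosome, 0-based junction
#'   coordinate, orientation (`"R"` right-anchored / `"L"` left-anchored).
#' @param chrom2,pos2,ori2 Second breakend.
#' @param inserted_seq Sequence inserted at the junction: `NA` for none,
#'   [unknown_seq()] for present-but-unresolved, otherwise the nucleotides.
#' @param pe,sr Supporting discordant read-pair and split-read counts.
#' @param tool Source caller identifier (e.g. `"DELLY"`, `"SIM"`).
#' @param id Unique adjacency identifiers; autogenerated when `NULL`.
#' @return A `data.frame` with one row per adjacency.
#' @export
#' @examples
#' adjacencies("chr1", 5000, "L", "chr1", 100, "R", tool = "SIM")
adjacencies <- function(chrom1, pos1, ori1, chrom2, pos2, ori2,
                        inserted_seq = NA_character_, pe = 0L, sr = 0L,
                        tool = "SIM", id = NULL) {
  n <- max(length(chrom1), length(pos1))
  df <- data.frame(
    id = if (is.null(id)) sprintf("adj%d", seq_len(n)) else as.character(id),
    chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
    ori1 = as.character(ori1),
    chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
    ori2 = as.character(ori2),
    inserted_seq = as.character(inserted_seq),
    pe = as.numeric(pe), sr = as.numeric(sr),
    tool = as.character(tool),
    stringsAsFactors = FALSE
  )
  canonicalize_adjacency(df)
}

#' Empty adjacency table with the canonical columns
#' @export
empty_adjacencies <- function() {
  df <- lapply(ADJ_COLS, function(cl) vector(cl, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' The sentinel marking an unresolved inserted sequence
#' @export
unknown_seq <- function() UNKNOWN_SEQ

#' Canonicalize adjacency breakend order
#'
#' Ensures `(chrom1, pos1) <= (chrom2, pos2)`; each orientation travels with
#' its breakend. Idempotent and order-insensitive: canonicalizing a swapped
#' pair yields the same row.
#'
#' @param adjs Adjacency table as from [adjacencies()].
#' @return The table with breakends swapped into canonical order.
#' @export
canonicalize_adjacency <- function(adjs) {
  validate_adjacencies(adjs, canonical = FALSE)
  if (nrow(adjs) == 0L) return(adjs)
  swap <- (adjs$chrom1 > adjs$chrom2) |
    (adjs$chrom1 == adjs$chrom2 & adjs$pos1 > adjs$pos2) |
    (adjs$chrom1 == adjs$chrom2 & adjs$pos1 == adjs$pos2 &
       adjs$ori1 == ORI_LEFT & adjs$ori2 == ORI_RIGHT)
  if (any(swap)) {
    tmp <- adjs[swap, c("chrom1", "pos1", "ori1")]
    adjs[swap, c("chrom1", "pos1", "ori1")] <-
      adjs[swap, c("chrom2", "pos2", "ori2")]
    adjs[swap, c("chrom2", "pos2", "ori2")] <- tmp
  }
  adjs
}

validate_adjacencies <- function(adjs, canonical = TRUE) {
  stopifnot(is.data.frame(adjs))
  missing <- setdiff(names(ADJ_COLS), names(adjs))
  if (length(missing))
    stop("adjacency table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(adjs) == 0L) return(invisible(adjs))
  oris <- c(adjs$ori1, adjs$ori2)
  if (!all(oris %in% c(ORI_RIGHT, ORI_LEFT)))
    stop("breakend orientation must be one of 'R', 'L'")
  if (any(adjs$pos1 < 0) || any(adjs$pos2 < 0))
    stop("breakend positions must be >= 0")
  if (any(is.na(adjs$chrom1)) || any(is.na(adjs$chrom2)))
    stop("breakend chromosome must not be NA")
  if (any(adjs$pe < 0, na.rm = TRUE) || any(adjs$sr < 0, na.rm = TRUE))
    stop("support counts must be >= 0")
  if (canonical) {
    bad <- (adjs$chrom1 > adjs$chrom2) |
      (adjs$chrom1 == adjs$chrom2 & adjs$pos1 > adjs$pos2)
    if (any(bad)) stop("adjacencies are not in canonical breakend order")
  }
  invisible(adjs)
}

#' Construct a table of CNV calls
#'
#' A call is a typed copy-number event backed by one novel adjacency
#' (DEL/INS/TDUP) or two (DDUP). `start`/`end` delimit the affected region in
#' 0-based half-open coordinates; for a dispersed duplication this is the
#' duplicated *template*, with the landing site in `ins_chrom`/`ins_pos`; for
#' an insertion `start == end == ins_pos` (a point feature).
#'
#' @param type One of `"DEL"`, `"INS"`, `"TDUP"`, `"DDUP"`.
#' @param chrom,start,end Region (template region for DDUP).
#' @param ins_chrom,ins_pos Insertion point (INS and DDUP only; NA otherwise).
#' @param inserted_seq Inserted nucleotides for INS (NA or [unknown_seq()]).
#' @param pe_support,sr_support Support counts (medians after merging, hence
#'   possibly fractional).
#' @param source_tools Comma-joined sorted set of contributing tools.
#' @param n_donors Number of donor calls collapsed into this call.
#' @param score Classifier posterior probability in `[0, 1]`, or NA.
#' @param id Call identifiers; autogenerated when `NULL`.
#' @return A `data.frame` with one row per call; `size` is derived (region
#'   length, or inserted-sequence length for INS, NA when unknown).
#' @export
cnv_calls <- function(type, chrom, start, end, ins_chrom = NA_character_,
                      ins_pos = NA_real_, inserted_seq = NA_character_,
                      pe_support = 0, sr_support = 0, source_tools = "SIM",
                      n_donors = 1L, score = NA_real_, id = NULL) {
  n <- max(length(type), length(chrom), length(start))
  df <- data.frame(
    id = if (is.null(id)) sprintf("call%d", seq_len(n)) else as.character(id),
    type = as.character(type), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    ins_chrom = as.character(ins_chrom), ins_pos = as.numeric(ins_pos),
    inserted_seq = as.character(inserted_seq),
    size = NA_real_,
    pe_support = as.numeric(pe_support), sr_support = as.numeric(sr_support),
    source_tools = as.character(source_tools),
    n_donors = as.numeric(n_donors), score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  df$size <- compute_size(df)
  validate_calls(df)
}

#' Empty call table with the canonical columns
#' @export
empty_calls <- function() {
  df <- lapply(CALL_COLS, function(cl) vector(cl, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

compute_size <- function(calls) {
  size <- calls$end - calls$start
  ins <- calls$type == "INS"
  known <- ins & !is.na(calls$inserted_seq) & calls$inserted_seq != UNKNOWN_SEQ
  size[ins] <- NA_real_
  size[known] <- nchar(calls$inserted_seq[known])
  size
}

#' Size of each CNV call
#'
#' DEL/TDUP/DDUP calls have size `end - start` (the DDUP template length);
#' insertions have the length of the inserted sequence, or `NA` when the
#' sequence is unresolved — the explicit "unknown size" sentinel, never 0.
#'
#' @param calls A call table from [cnv_calls()].
#' @return Numeric vector of sizes in bp, `NA` for unknown.
#' @export
cnv_size <- function(calls) {
  validate_calls(calls)
  calls$size
}

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing <- setdiff(names(CALL_COLS), names(calls))
  if (length(missing))
    stop("call table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(calls) == 0L) return(invisible(calls))
  if (!all(calls$type %in% CNV_TYPES))
    stop("cnv type must be one of ", paste(CNV_TYPES, collapse = ", "))
  if (any(calls$start < 0) || any(calls$end < calls$start))
    stop("call regions must satisfy 0 <= start <= end")
  need_ins <- calls$type %in% c("INS", "DDUP")
  if (any(need_ins & (is.na(calls$ins_pos) | is.na(calls$ins_chrom))))
    stop("INS and DDUP calls require an insertion point")
  sc <- calls$score[!is.na(calls$score)]
  if (any(sc < 0 | sc > 1)) stop("scores must lie in [0, 1]")
  invisible(calls)
}

## deterministic call ordering used by reclassify/merge outputs
sort_calls <- function(calls) {
  ord <- order(calls$chrom, calls$start, calls$end,
               match(calls$type, CNV_TYPES), calls$id)
  rownames(calls) <- NULL
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

## VCF breakend bracket notation ----------------------------------------------

#' Serialize one breakend of an adjacency to VCF bracket notation
#'
#' The bijection between the orientation vocabulary and the four bracket
#' forms of the variant-call format:
#' `t[p[` (this R, mate L), `t]p]` (R, R), `]p]t` (L, R), `[p[t` (L, L).
#' VCF POS of a breakend is 1-based: junction `p` maps to POS `p` for an
#' R-anchored breakend and POS `p + 1` for an L-anchored one.
#'
#' @param ori,mate_chrom,mate_pos,mate_ori This breakend's orientation and the
#'   mate breakend (0-based junction coordinates).
#' @param ref Anchor base printed in the ALT (default `"N"`).
#' @param inserted_seq Optional junction insertion carried in the ALT.
#' @return The ALT string.
#' @export
bnd_alt <- function(ori, mate_chrom, mate_pos, mate_ori, ref = "N",
                    inserted_seq = NA_character_) {
  mate_pos1 <- ifelse(mate_ori == ORI_RIGHT, mate_pos, mate_pos + 1)
  mate <- sprintf("%s:%d", mate_chrom, as.integer(mate_pos1))
  ins <- ifelse(is.na(inserted_seq) | inserted_seq == UNKNOWN_SEQ,
                "", inserted_seq)
  ifelse(ori == ORI_RIGHT,
         ifelse(mate_ori == ORI_LEFT,
                sprintf("%s%s[%s[", ref, ins, mate),
                sprintf("%s%s]%s]", ref, ins, mate)),
         ifelse(mate_ori == ORI_RIGHT,
                sprintf("]%s]%s%s", mate, ins, ref),
                sprintf("[%s[%s%s", mate, ins, ref)))
}

#' Parse a VCF breakend ALT string
#'
#' Inverse of [bnd_alt()]. Returns the orientation of the record's own
#' breakend, the mate breakend (0-based junction coordinate and orientation),
#' and any inserted sequence embedded in the ALT.
#'
#' @param alt ALT strings in bracket notation.
#' @param ref The record's REF allele (to strip the anchor base).
#' @return `data.frame` with columns `ori`, `mate_chrom`, `mate_pos`,
#'   `mate_ori`, `inserted_seq`.
#' @export
parse_bnd_alt <- function(alt, ref = "N") {
  m <- regmatches(alt, regexec(
    "^([A-Za-z.]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([A-Za-z.]*)$",
    alt, perl = TRUE))
  out <- lapply(seq_along(alt), function(i) {
    g <- m[[i]]
    if (length(g) == 0L) stop("malformed breakend ALT: ", alt[i])
    pre <- g[2]; br <- g[3]; chrom <- g[4]
    pos1 <- as.numeric(g[5]); post <- g[7]
    this_right <- nzchar(pre)
    mate_right <- br == "]"
    seq <- if (this_right) sub(paste0("^", ref[min(i, length(ref))]), "", pre)
           else sub(paste0(ref[min(i, length(ref))], "$"), "", post)
    data.frame(
      ori = if (this_right) ORI_RIGHT else ORI_LEFT,
      mate_chrom = chrom,
      mate_pos = if (mate_right) pos1 else pos1 - 1,
      mate_ori = if (mate_right) ORI_RIGHT else ORI_LEFT,
      inserted_seq = if (nzchar(seq)) seq else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

## strand bijection used by BEDPE
ori_to_strand <- function(ori) ifelse(ori == ORI_RIGHT, "+", "-")
strand_to_ori <- function(strand) ifelse(strand == "+", ORI_RIGHT, ORI_LEFT)

## local, restore-on-exit RNG scope so generators are deterministic under a
## seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
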