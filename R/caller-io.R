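## Caller VCF dialects and BEDPE I/O.
##
## Each supported caller emits CNVs in its own VCF flavour: Delly/LUMPY/Manta
## mix symbolic ALT records (<DEL>/<DUP>/<INS>) with breakend (BND) records,
## while GRIDSS emits breakends only. Dialects are data-driven field maps, not
## code paths, so adding a caller means adding a list entry.

#' Describe one caller's VCF dialect
#'
#' @param tool Tool identifier (upper-cased).
#' @param record_style `"symbolic"`, `"breakend"`, or `"mixed"`.
#' @param pe_field,sr_field Where the discordant-pair / split-read support
#'   counts live: a `list(key =, where =)` with `where` one of `"info"`,
#'   `"format"`. When both site- and sample-level counts exist, point the map
#'   at the sample-level (FORMAT) field.
#' @return A `caller_dialect` list.
#' @export
caller_dialect <- function(tool, record_style = c("mixed", "symbolic",
                                                  "breakend"),
                           pe_field = list(key = "PE", where = "info"),
                           sr_field = list(key = "SR", where = "info")) {
  record_style <- match.arg(record_style)
  structure(list(tool = toupper(tool), record_style = record_style,
                 pe_field = pe_field, sr_field = sr_field),
            class = "caller_dialect")
}

#' Default dialect map for the four supported callers
#'
#' INFO/FORMAT keys are editable defaults (documented against Delly 0.7.8,
#' GRIDSS 1.8.1, LUMPY 0.2.13, Manta 1.4.0 conventions); override by editing
#' the returned list.
#' @return Named list of [caller_dialect()] objects (plus a `sim` dialect used
#'   by the simulator).
#' @export
default_dialects <- function() {
  list(
    delly  = caller_dialect("DELLY", "mixed",
                            pe_field = list(key = "PE", where = "info"),
                            sr_field = list(key = "SR", where = "info")),
    gridss = caller_dialect("GRIDSS", "breakend",
                            pe_field = list(key = "RP", where = "info"),
                            sr_field = list(key = "SR", where = "info")),
    lumpy  = caller_dialect("LUMPY", "mixed",
                            pe_field = list(key = "PE", where = "format"),
                            sr_field = list(key = "SR", where = "format")),
    manta  = caller_dialect("MANTA", "mixed",
                            pe_field = list(key = "PR", where = "format"),
                            sr_field = list(key = "SR", where = "format")),
    sim    = caller_dialect("SIM", "mixed",
                            pe_field = list(key = "PE", where = "info"),
                            sr_field = list(key = "SR", where = "info"))
  )
}

support_values <- function(vcf, field, n) {
  key <- field$key
  vals <- NULL
  if (identical(field$where, "info")) {
    inf <- VariantAnnotation::info(vcf)
    if (key %in% names(inf)) vals <- inf[[key]]
  } else {
    gen <- VariantAnnotation::geno(vcf)
    if (key %in% names(gen)) {
      g <- gen[[key]]
      ## first sample; Manta-style PR is per-allele (Number=R) -> take the
      ## variant-allele (last) entry
      if (is.list(g) || length(dim(g)) == 3L) {
        vals <- vapply(seq_len(nrow(g)), function(i) {
          v <- unlist(g[i, 1])
          if (length(v) == 0L || all(is.na(v))) NA_real_
          else as.numeric(v[length(v)])
        }, numeric(1))
      } else vals <- as.numeric(g[, 1])
    }
  }
  if (is.null(vals)) return(NULL)
  if (is.list(vals))
    vals <- vapply(vals, function(v)
      if (length(v) == 0L) NA_real_ else as.numeric(v[length(v)]),
      numeric(1))
  vals <- as.numeric(vals)
  vals[is.na(vals)] <- 0
  vals
}

#' Read a caller VCF into a table of novel adjacencies
#'
#' Symbolic records are converted via the documented coordinate bijection
#' (VCF `POS` is the 1-based padding base before the event, `END` its last
#' base, so a DEL/DUP of `POS=s, END=e` affects 0-based region `[s, e)`):
#' a DEL becomes the adjacency `(s R, e L)`, a DUP `(s L, e R)`, an INS the
#' point adjacency at `s` carrying the inserted sequence (INFO `SVINSSEQ`, or
#' the unknown-sequence sentinel). BND records are paired via their `MATEID`
#' and consumed exactly once per mate pair; unmatched mates are skipped with
#' a warning. Unknown symbolic ALTs (e.g. `<INV>`) still yield an adjacency
#' with orientations as encoded — exclusion is the reclassifier's job.
#'
#' @param path VCF file (optionally gzipped).
#' @param dialect A [caller_dialect()].
#' @return Adjacency table (see [adjacencies()]); attribute `"skipped"` counts
#'   unmatched breakend records.
#' @export
read_caller_vcf <- function(path, dialect) {
  stopifnot(inherits(dialect, "caller_dialect"))
  if (!file.exists(path)) stop("no such VCF: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  n <- nrow(vcf)
  if (n == 0L) {
    out <- empty_adjacencies()
    attr(out, "skipped") <- 0L
    return(out)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos1b <- BiocGenerics::start(rr)
  ids <- names(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(seq_len(n), function(i) {
    a <- rr$ALT[[i]]
    if (length(a) == 0L) "." else as.character(a[1])
  }, character(1))
  inf <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% names(inf)) as.character(inf$SVTYPE)
            else rep(NA_character_, n)
  symbolic <- grepl("^<.+>$", alt)
  svtype[is.na(svtype) & symbolic] <- gsub("[<>]", "", alt[is.na(svtype) &
                                                             symbolic])
  svtype[is.na(svtype)] <- ifelse(grepl("\\[|\\]", alt[is.na(svtype)]),
                                  "BND", "UNK")
  end1b <- if ("END" %in% names(inf)) as.numeric(inf$END) else
    rep(NA_real_, n)
  mateid <- if ("MATEID" %in% names(inf)) {
    mi <- inf$MATEID
    if (is.list(mi) || methods::is(mi, "List"))
      vapply(mi, function(v) if (length(v)) as.character(v[1])
             else NA_character_, character(1))
    else as.character(mi)
  } else rep(NA_character_, n)
  insseq <- if ("SVINSSEQ" %in% names(inf)) as.character(inf$SVINSSEQ)
            else rep(NA_character_, n)

  pe <- support_values(vcf, dialect$pe_field, n)
  sr <- support_values(vcf, dialect$sr_field, n)
  if (is.null(pe)) {
    warning("dialect ", dialect$tool, ": missing support field '",
            dialect$pe_field$key, "'; PE support set to 0")
    pe <- rep(0, n)
  }
  if (is.null(sr)) {
    warning("dialect ", dialect$tool, ": missing support field '",
            dialect$sr_field$key, "'; SR support set to 0")
    sr <- rep(0, n)
  }

  rows <- vector("list", n)
  skipped <- 0L
  bnd_done <- character(0)
  for (i in seq_len(n)) {
    st <- svtype[i]
    if (st == "DEL" && !is.na(end1b[i])) {
      rows[[i]] <- adjacencies(chrom[i], pos1b[i], ORI_RIGHT,
                               chrom[i], end1b[i], ORI_LEFT,
                               pe = pe[i], sr = sr[i],
                               tool = dialect$tool, id = ids[i])
    } else if (st == "DUP" && !is.na(end1b[i])) {
      rows[[i]] <- adjacencies(chrom[i], pos1b[i], ORI_LEFT,
                               chrom[i], end1b[i], ORI_RIGHT,
                               pe = pe[i], sr = sr[i],
                               tool = dialect$tool, id = ids[i])
    } else if (st == "INS") {
      seq <- if (!is.na(insseq[i]) && nzchar(insseq[i])) insseq[i]
             else UNKNOWN_SEQ
      rows[[i]] <- adjacencies(chrom[i], pos1b[i], ORI_RIGHT,
                               chrom[i], pos1b[i], ORI_LEFT,
                               inserted_seq = seq, pe = pe[i], sr = sr[i],
                               tool = dialect$tool, id = ids[i])
    } else if (st == "INV" && !is.na(end1b[i])) {
      ## inversion-like: same-orientation pair, produced as encoded so the
      ## reclassifier can exclude it with a reason
      rows[[i]] <- adjacencies(chrom[i], pos1b[i], ORI_RIGHT,
                               chrom[i], end1b[i], ORI_RIGHT,
                               pe = pe[i], sr = sr[i],
                               tool = dialect$tool, id = ids[i])
    } else if (st == "BND" || grepl("\\[|\\]", alt[i])) {
      if (is.na(mateid[i]) || !(mateid[i] %in% ids)) {
        warning("unmatched breakend mate for record ", ids[i], "; skipped")
        skipped <- skipped + 1L
        next
      }
      key <- paste(sort(c(ids[i], mateid[i])), collapse = "\r")
      if (key %in% bnd_done) next
      bnd_done <- c(bnd_done, key)
      b <- parse_bnd_alt(alt[i], ref[i])
      this_pos <- if (b$ori == ORI_RIGHT) pos1b[i] else pos1b[i] - 1
      seq <- if (!is.na(insseq[i]) && nzchar(insseq[i])) insseq[i]
             else b$inserted_seq
      rows[[i]] <- adjacencies(chrom[i], this_pos, b$ori,
                               b$mate_chrom, b$mate_pos, b$mate_ori,
                               inserted_seq = seq,
                               pe = pe[i], sr = sr[i],
                               tool = dialect$tool, id = ids[i])
    } else {
      ## unknown record type: skip quietly (non-SV small variant lines)
      next
    }
  }
  out <- do.call(rbind, c(list(empty_adjacencies()), rows[!vapply(rows,
    is.null, logical(1))]))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

vcf_header_lines <- function(dialect, contigs) {
  fmt <- function(field, desc)
    sprintf("##%s=<ID=%s,Number=1,Type=Integer,Description=\"%s\">",
            ifelse(field$where == "info", "INFO", "FORMAT"), field$key, desc)
  c("##fileformat=VCFv4.2",
    sprintf("##source=cnvpost-%s", dialect$tool),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=SVINSSEQ,Number=1,Type=String,Description=\"Inserted seq\">",
    fmt(dialect$pe_field, "Discordant read pair support"),
    fmt(dialect$sr_field, "Split read support"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE"), collapse = "\t"))
}

#' Write adjacencies as a caller-dialect VCF
#'
#' The inverse of [read_caller_vcf()] for the same dialect: intrachromosomal
#' `(R, L)` adjacencies become symbolic `<DEL>` records, `(L, R)` become
#' `<DUP>`, point adjacencies with an insert become `<INS>`; everything else
#' (and *all* records for breakend-only dialects) is written as a `MATEID`-
#' paired pair of BND records. Round-trips 1-based coordinates exactly.
#'
#' @param adjs Adjacency table.
#' @param path Output path.
#' @param dialect Target [caller_dialect()].
#' @param contigs Named vector of chromosome lengths for the header.
#' @export
write_caller_vcf <- function(adjs, path, dialect, contigs = NULL) {
  validate_adjacencies(adjs)
  if (is.null(contigs)) {
    chroms <- sort(unique(c(adjs$chrom1, adjs$chrom2)))
    contigs <- stats::setNames(
      vapply(chroms, function(cr) {
        max(adjs$pos2[adjs$chrom2 == cr], adjs$pos1[adjs$chrom1 == cr]) + 1000
      }, numeric(1)), chroms)
  }
  info_sup <- function(i) {
    parts <- character(0)
    if (dialect$pe_field$where == "info")
      parts <- c(parts, sprintf("%s=%d", dialect$pe_field$key,
                                as.integer(adjs$pe[i])))
    if (dialect$sr_field$where == "info")
      parts <- c(parts, sprintf("%s=%d", dialect$sr_field$key,
                                as.integer(adjs$sr[i])))
    parts
  }
  fmt_cols <- function(i) {
    keys <- "GT"; vals <- "0/1"
    if (dialect$pe_field$where == "format") {
      keys <- c(keys, dialect$pe_field$key)
      vals <- c(vals, as.character(as.integer(adjs$pe[i])))
    }
    if (dialect$sr_field$where == "format") {
      keys <- c(keys, dialect$sr_field$key)
      vals <- c(vals, as.character(as.integer(adjs$sr[i])))
    }
    c(paste(keys, collapse = ":"), paste(vals, collapse = ":"))
  }
  lines <- character(0)
  for (i in seq_len(nrow(adjs))) {
    a <- adjs[i, ]
    intra <- a$chrom1 == a$chrom2
    has_ins <- !is.na(a$inserted_seq)
    symbolic_ok <- dialect$record_style != "breakend" && intra &&
      ((a$ori1 == ORI_RIGHT && a$ori2 == ORI_LEFT) ||
       (a$ori1 == ORI_LEFT && a$ori2 == ORI_RIGHT) ||
       has_ins)
    f <- fmt_cols(i)
    if (symbolic_ok && has_ins && a$pos2 - a$pos1 <= 10) {
      info <- c("SVTYPE=INS",
                if (a$inserted_seq != UNKNOWN_SEQ)
                  sprintf("SVINSSEQ=%s", a$inserted_seq),
                info_sup(i))
      lines <- c(lines, paste(a$chrom1, as.integer(a$pos1), a$id, "N",
                              "<INS>", ".", "PASS",
                              paste(info, collapse = ";"),
                              f[1], f[2], sep = "\t"))
    } else if (symbolic_ok && a$ori1 == ORI_RIGHT && !has_ins) {
      info <- c("SVTYPE=DEL", sprintf("END=%d", as.integer(a$pos2)),
                info_sup(i))
      lines <- c(lines, paste(a$chrom1, as.integer(a$pos1), a$id, "N",
                              "<DEL>", ".", "PASS",
                              paste(info, collapse = ";"),
                              f[1], f[2], sep = "\t"))
    } else if (symbolic_ok && a$ori1 == ORI_LEFT && !has_ins) {
      info <- c("SVTYPE=DUP", sprintf("END=%d", as.integer(a$pos2)),
                info_sup(i))
      lines <- c(lines, paste(a$chrom1, as.integer(a$pos1), a$id, "N",
                              "<DUP>", ".", "PASS",
                              paste(info, collapse = ";"),
                              f[1], f[2], sep = "\t"))
    } else {
      ## mate pair of BND records
      id1 <- paste0(a$id, "_1"); id2 <- paste0(a$id, "_2")
      pos1b_1 <- if (a$ori1 == ORI_RIGHT) a$pos1 else a$pos1 + 1
      pos1b_2 <- if (a$ori2 == ORI_RIGHT) a$pos2 else a$pos2 + 1
      alt1 <- bnd_alt(a$ori1, a$chrom2, a$pos2, a$ori2,
                      inserted_seq = a$inserted_seq)
      alt2 <- bnd_alt(a$ori2, a$chrom1, a$pos1, a$ori1,
                      inserted_seq = a$inserted_seq)
      for (rec in list(list(a$chrom1, pos1b_1, id1, alt1, id2),
                       list(a$chrom2, pos1b_2, id2, alt2, id1))) {
        info <- c("SVTYPE=BND", sprintf("MATEID=%s", rec[[5]]),
                  if (has_ins && a$inserted_seq == UNKNOWN_SEQ)
                    "SVINSSEQ=*",
                  info_sup(i))
        lines <- c(lines, paste(rec[[1]], as.integer(rec[[2]]), rec[[3]],
                                "N", rec[[4]], ".", "PASS",
                                paste(info, collapse = ";"),
                                f[1], f[2], sep = "\t"))
      }
    }
  }
  writeLines(c(vcf_header_lines(dialect, contigs), lines), path)
  invisible(path)
}

## BEDPE ----------------------------------------------------------------------

BEDPE_HEADER <- c("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "name", "score", "strand1", "strand2", "cnv_type", "size",
                  "pe_support", "sr_support", "source_tools", "n_donors",
                  "ins_chrom", "ins_pos", "inserted_seq")

call_breakends <- function(calls) {
  ## per-type primary breakend pair (junction coordinates + orientations)
  b <- data.frame(pos1 = calls$start, ori1 = rep(ORI_RIGHT, nrow(calls)),
                  pos2 = calls$end, ori2 = rep(ORI_LEFT, nrow(calls)),
                  stringsAsFactors = FALSE)
  dup_like <- calls$type %in% c("TDUP", "DDUP")
  b$ori1[dup_like] <- ORI_LEFT
  b$ori2[dup_like] <- ORI_RIGHT
  ins <- calls$type == "INS"
  b$pos1[ins] <- calls$ins_pos[ins]
  b$pos2[ins] <- calls$ins_pos[ins]
  b
}

#' Write CNV calls as BEDPE
#'
#' Standard BEDPE (0-based, half-open): columns 1-6 are the two breakend
#' intervals (a right-anchored breakend at junction `p` occupies `[p-1, p)`,
#' a left-anchored one `[p, p+1)`), column 7 the call id, column 8 the
#' classifier score (`.` when unscored), columns 9-10 the strand encoding of
#' the orientations (`R` = `+`, `L` = `-`). Extra columns carry type, size,
#' support medians, the comma-joined source tools, donor count and the
#' insertion point (INS/DDUP).
#'
#' @param calls Call table.
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  validate_calls(calls)
  b <- call_breakends(calls)
  na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  num <- function(x) ifelse(is.na(x), ".",
                            sub("\\.?0+$", "", sprintf("%.3f", x)))
  df <- data.frame(
    chrom1 = calls$chrom,
    start1 = as.integer(ifelse(b$ori1 == ORI_RIGHT, pmax(b$pos1 - 1, 0),
                               b$pos1)),
    end1 = as.integer(ifelse(b$ori1 == ORI_RIGHT, b$pos1, b$pos1 + 1)),
    chrom2 = calls$chrom,
    start2 = as.integer(ifelse(b$ori2 == ORI_RIGHT, pmax(b$pos2 - 1, 0),
                               b$pos2)),
    end2 = as.integer(ifelse(b$ori2 == ORI_RIGHT, b$pos2, b$pos2 + 1)),
    name = calls$id,
    score = num(calls$score),
    strand1 = ori_to_strand(b$ori1),
    strand2 = ori_to_strand(b$ori2),
    cnv_type = calls$type,
    size = na_dot(calls$size),
    pe_support = num(calls$pe_support),
    sr_support = num(calls$sr_support),
    source_tools = calls$source_tools,
    n_donors = as.integer(calls$n_donors),
    ins_chrom = na_dot(calls$ins_chrom),
    ins_pos = na_dot(calls$ins_pos),
    inserted_seq = na_dot(calls$inserted_seq),
    stringsAsFactors = FALSE
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(BEDPE_HEADER, collapse = "\t"), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#'
#' Exact inverse: `read_bedpe(write_bedpe(x))` reproduces `x` on all fields.
#' Malformed lines raise an error naming the offending line number.
#'
#' @param path BEDPE path.
#' @return Call table.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("no such BEDPE: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(empty_calls())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(BEDPE_HEADER))) {
    bad <- which(nf != length(BEDPE_HEADER))[1]
    lineno <- which(lines == body[bad])[1]
    stop(sprintf("malformed BEDPE line %d: expected %d fields, found %d",
                 lineno, length(BEDPE_HEADER), nf[bad]))
  }
  m <- do.call(rbind, parts)
  dot_na <- function(x) ifelse(x == ".", NA, x)
  type <- m[, 11]
  strand1 <- m[, 9]
  ## recover the junction from the breakend interval: R-anchored -> interval
  ## end, L-anchored -> interval start
  start1 <- as.numeric(m[, 2]); end1 <- as.numeric(m[, 3])
  start2 <- as.numeric(m[, 5]); end2 <- as.numeric(m[, 6])
  j1 <- ifelse(strand1 == "+", end1, start1)
  j2 <- ifelse(m[, 10] == "+", end2, start2)
  region_start <- ifelse(type == "INS", as.numeric(dot_na(m[, 18])),
                         pmin(j1, j2))
  region_end <- ifelse(type == "INS", as.numeric(dot_na(m[, 18])),
                       pmax(j1, j2))
  calls <- cnv_calls(
    type = type, chrom = m[, 1],
    start = region_start, end = region_end,
    ins_chrom = as.character(dot_na(m[, 17])),
    ins_pos = as.numeric(dot_na(m[, 18])),
    inserted_seq = as.character(dot_na(m[, 19])),
    pe_support = as.numeric(dot_na(m[, 13])),
    sr_support = as.numeric(dot_na(m[, 14])),
    source_tools = m[, 15],
    n_donors = as.numeric(m[, 16]),
    score = as.numeric(dot_na(m[, 8])),
    id = m[, 7]
  )
  ## sizes of unknown-length insertions are not recomputable from sequence
  size_file <- suppressWarnings(as.numeric(dot_na(m[, 12])))
  calls$size <- ifelse(is.na(calls$size) & !is.na(size_file), size_file,
                       calls$size)
  calls
}

#' Reconstruct the adjacencies backing each call
#'
#' DEL/INS/TDUP calls are backed by their single primary adjacency; a DDUP is
#' expanded into its two defining adjacencies (template-start-to-insertion and
#' template-end-to-insertion junctions).
#'
#' @param calls Call table.
#' @return Adjacency table with a `call_id` bookkeeping column.
#' @export
call_adjacencies <- function(calls) {
  validate_calls(calls)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    tool <- strsplit(cl$source_tools, ",")[[1]][1]
    if (cl$type == "DDUP") {
      a <- rbind(
        adjacencies(cl$chrom, cl$start, ORI_LEFT, cl$ins_chrom, cl$ins_pos,
                    ORI_RIGHT, pe = cl$pe_support, sr = cl$sr_support,
                    tool = tool, id = paste0(cl$id, ".1")),
        adjacencies(cl$chrom, cl$end, ORI_RIGHT, cl$ins_chrom, cl$ins_pos,
                    ORI_LEFT, pe = cl$pe_support, sr = cl$sr_support,
                    tool = tool, id = paste0(cl$id, ".2")))
    } else {
      b <- call_breakends(cl)
      a <- adjacencies(cl$chrom, b$pos1, b$ori1, cl$chrom, b$pos2, b$ori2,
                       inserted_seq = if (cl$type == "INS") {
                         if (is.na(cl$inserted_seq)) UNKNOWN_SEQ
                         else cl$inserted_seq
                       } else NA_character_,
                       pe = cl$pe_support, sr = cl$sr_support,
                       tool = tool, id = cl$id)
    }
    a$call_id <- cl$id
    a
  })
  out <- do.call(rbind, c(list(cbind(empty_adjacencies(),
                                     call_id = character(0))), rows))
  rownames(out) <- NULL
  out
}
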