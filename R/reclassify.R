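## Reclassification: cluster same-tool adjacencies and convert each cluster to
## DEL / INS / TDUP / DDUP calls, recovering dispersed duplications from their
## two-adjacency signature. Everything unclassifiable is excluded with a
## reason, never silently dropped.

#' Classification configuration
#'
#' @param cluster_window Single-linkage clustering window in bp: same-tool
#'   adjacencies whose breakpoints co-locate within this distance (on either
#'   end) join one cluster. Also the tolerance on the shared breakpoint of a
#'   dispersed-duplication adjacency pair.
#' @param min_size Minimum event size in bp; calls smaller than this are
#'   excluded (CNVs are defined as events of at least 50 bp).
#' @param allow_inverted_ddup Also search for inverted-copy dispersed
#'   duplication signatures (same-orientation adjacency pairs). Off by
#'   default.
#' @param insertion_site_tolerance Maximum breakend separation for an
#'   unknown-sequence breakend pair to be read as an insertion site.
#' @return A `classification_config` list.
#' @export
classification_config <- function(cluster_window = 10, min_size = 50,
                                  allow_inverted_ddup = FALSE,
                                  insertion_site_tolerance = 10) {
  stopifnot(cluster_window >= 0, min_size >= 0)
  structure(list(cluster_window = cluster_window, min_size = min_size,
                 allow_inverted_ddup = allow_inverted_ddup,
                 insertion_site_tolerance = insertion_site_tolerance),
            class = "classification_config")
}

## minimal union-find (no path compression; instance sizes are small)
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster same-tool adjacencies by breakpoint proximity
#'
#' Two adjacencies of the same tool are linked when any breakend of one lies
#' within `cluster_window` bp of any breakend of the other on the same
#' chromosome; clusters are the single-linkage connected components. The
#' implementation sweeps sorted breakend positions, which yields exactly the
#' components of the pairwise-linkage graph.
#'
#' @param adjs Adjacency table (canonical).
#' @param cfg A [classification_config()].
#' @return The table with an integer `cluster` column, rows ordered by
#'   cluster; clusters are numbered by their leftmost breakend.
#' @export
cluster_adjacencies <- function(adjs, cfg = classification_config()) {
  validate_adjacencies(adjs)
  if (nrow(adjs) == 0L) {
    adjs$cluster <- integer(0)
    return(adjs)
  }
  n <- nrow(adjs)
  parent <- uf_new(n)
  pts <- data.frame(
    tool = rep(adjs$tool, 2L),
    chrom = c(adjs$chrom1, adjs$chrom2),
    pos = c(adjs$pos1, adjs$pos2),
    adj = rep(seq_len(n), 2L),
    stringsAsFactors = FALSE
  )
  pts <- pts[order(pts$tool, pts$chrom, pts$pos), ]
  same_block <- pts$tool[-1] == pts$tool[-nrow(pts)] &
    pts$chrom[-1] == pts$chrom[-nrow(pts)]
  close_enough <- (pts$pos[-1] - pts$pos[-nrow(pts)]) <= cfg$cluster_window
  link <- which(same_block & close_enough)
  for (k in link) {
    ra <- uf_find(parent, pts$adj[k])
    rb <- uf_find(parent, pts$adj[k + 1L])
    if (ra != rb) {
      root <- min(ra, rb)
      parent[ra] <- root
      parent[rb] <- root
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  ## number clusters by leftmost breakend (chrom-major)
  left_chrom <- tapply(adjs$chrom1, comp, min)
  left_pos <- vapply(split(seq_len(n), comp), function(ix) {
    min(adjs$pos1[ix][adjs$chrom1[ix] == min(adjs$chrom1[ix])])
  }, numeric(1))
  ord <- order(left_chrom, left_pos, as.numeric(names(left_chrom)))
  relabel <- stats::setNames(seq_along(ord), names(left_chrom)[ord])
  adjs$cluster <- as.integer(relabel[as.character(comp)])
  adjs <- adjs[order(adjs$cluster, adjs$chrom1, adjs$pos1, adjs$pos2,
                     adjs$id), ]
  rownames(adjs) <- NULL
  adjs
}

excluded_record <- function(adj, reason) {
  cbind(adj[, names(ADJ_COLS), drop = FALSE],
        data.frame(reason = reason, stringsAsFactors = FALSE))
}

empty_excluded <- function() {
  cbind(empty_adjacencies(), data.frame(reason = character(0),
                                        stringsAsFactors = FALSE))
}

call_from_adj <- function(adj, type, start, end, ins_chrom = NA_character_,
                          ins_pos = NA_real_, inserted_seq = NA_character_,
                          pe = adj$pe, sr = adj$sr, id = adj$id) {
  cnv_calls(type = type, chrom = adj$chrom1, start = start, end = end,
            ins_chrom = ins_chrom, ins_pos = ins_pos,
            inserted_seq = inserted_seq, pe_support = pe, sr_support = sr,
            source_tools = adj$tool, n_donors = 1L, id = id)
}

#' Classify a single adjacency in isolation
#'
#' Orientation signatures on one chromosome: `(R, L)` with no insert is a
#' deletion of `[pos1, pos2)`; `(L, R)` a tandem duplication of
#' `[pos1, pos2)`; an adjacency carrying an inserted sequence (or an
#' unknown-sequence breakend pair closer than the insertion-site tolerance)
#' is an insertion at `pos1`. Same-orientation pairs (inversion-like),
#' interchromosomal singletons, and events below `min_size` are excluded
#' with a reason code.
#'
#' @param adj One-row adjacency table.
#' @param cfg A [classification_config()].
#' @return `list(calls =, excluded =)`; exactly one of the two has a row.
#' @export
classify_singleton <- function(adj, cfg = classification_config()) {
  stopifnot(nrow(adj) == 1L)
  has_seq <- !is.na(adj$inserted_seq) && adj$inserted_seq != UNKNOWN_SEQ
  has_unknown <- !is.na(adj$inserted_seq) && adj$inserted_seq == UNKNOWN_SEQ
  dist <- adj$pos2 - adj$pos1
  res <- list(calls = empty_calls(), excluded = empty_excluded())
  if (adj$chrom1 == adj$chrom2 &&
      (has_seq || (has_unknown && dist <= cfg$insertion_site_tolerance))) {
    size <- if (has_seq) nchar(adj$inserted_seq) else NA_real_
    if (!is.na(size) && size < cfg$min_size) {
      res$excluded <- excluded_record(adj, "below_min_size")
    } else {
      res$calls <- call_from_adj(adj, "INS", adj$pos1, adj$pos1,
                                 ins_chrom = adj$chrom1, ins_pos = adj$pos1,
                                 inserted_seq = adj$inserted_seq)
    }
    return(res)
  }
  if (adj$chrom1 != adj$chrom2) {
    res$excluded <- excluded_record(adj, "interchromosomal_singleton")
    return(res)
  }
  if (adj$ori1 == adj$ori2) {
    res$excluded <- excluded_record(adj, "inversion_like")
    return(res)
  }
  type <- if (adj$ori1 == ORI_RIGHT) "DEL" else "TDUP"
  if (dist < cfg$min_size) {
    res$excluded <- excluded_record(adj, "below_min_size")
    return(res)
  }
  res$calls <- call_from_adj(adj, type, adj$pos1, adj$pos2)
  res
}

## Enumerate dispersed-duplication candidate pairs within one cluster.
## Direct-orientation signatures (template [s, e) copied to landing site p):
##   downstream copy (p > e): TDUP-like (s L, p R) + DEL-like (e R, p' L),
##     |p - p'| <= window, s < e < min(p, p')
##   upstream copy (p < s): DEL-like (p R, s L) + TDUP-like (p' L, e R),
##     |p - p'| <= window, p < s <= e
##   interchromosomal: two adjacencies over the same chromosome pair whose
##     breakends on the acceptor chromosome co-locate within the window with
##     opposite orientations, and whose donor breakends (opposite
##     orientations) delimit the template.
ddup_candidates <- function(cl, cfg) {
  n <- nrow(cl)
  if (n < 2L) return(NULL)
  w <- cfg$cluster_window
  no_ins <- is.na(cl$inserted_seq)
  intra <- cl$chrom1 == cl$chrom2
  del_like <- which(intra & no_ins & cl$ori1 == ORI_RIGHT &
                      cl$ori2 == ORI_LEFT)
  tdup_like <- which(intra & no_ins & cl$ori1 == ORI_LEFT &
                       cl$ori2 == ORI_RIGHT)
  out <- list()
  for (d in del_like) for (t in tdup_like) {
    if (cl$chrom1[d] != cl$chrom1[t]) next
    d1 <- cl$pos1[d]; d2 <- cl$pos2[d]
    t1 <- cl$pos1[t]; t2 <- cl$pos2[t]
    ## downstream: template [t1, d1), insertion ~ t2
    if (abs(d2 - t2) <= w && t1 < d1 && d1 < min(d2, t2) &&
        d1 - t1 >= cfg$min_size) {
      out[[length(out) + 1L]] <- data.frame(
        a = d, b = t, dist = abs(d2 - t2), chrom = cl$chrom1[t],
        start = t1, end = d1, ins_chrom = cl$chrom1[t], ins_pos = t2,
        stringsAsFactors = FALSE)
    }
    ## upstream: template [d2, t2), insertion ~ d1
    if (abs(d1 - t1) <= w && d1 < d2 && d2 <= t2 &&
        t2 - d2 >= cfg$min_size) {
      out[[length(out) + 1L]] <- data.frame(
        a = d, b = t, dist = abs(d1 - t1), chrom = cl$chrom1[d],
        start = d2, end = t2, ins_chrom = cl$chrom1[d], ins_pos = d1,
        stringsAsFactors = FALSE)
    }
  }
  if (cfg$allow_inverted_ddup) {
    rr <- which(intra & no_ins & cl$ori1 == ORI_RIGHT & cl$ori2 == ORI_RIGHT)
    ll <- which(intra & no_ins & cl$ori1 == ORI_LEFT & cl$ori2 == ORI_LEFT)
    for (i in rr) for (j in ll) {
      if (cl$chrom1[i] != cl$chrom1[j]) next
      ## shared landing site p: one position of the RR pair within window of
      ## one position of the LL pair; remaining LL position = template start,
      ## remaining RR position = template end; p outside the template
      for (pi in c("pos1", "pos2")) for (pj in c("pos1", "pos2")) {
        p_rr <- cl[[pi]][i]; e <- cl[[setdiff(c("pos1", "pos2"), pi)]][i]
        p_ll <- cl[[pj]][j]; s <- cl[[setdiff(c("pos1", "pos2"), pj)]][j]
        if (abs(p_rr - p_ll) <= w && s < e && e - s >= cfg$min_size &&
            (p_rr >= e || p_rr <= s)) {
          out[[length(out) + 1L]] <- data.frame(
            a = i, b = j, dist = abs(p_rr - p_ll), chrom = cl$chrom1[i],
            start = s, end = e, ins_chrom = cl$chrom1[i], ins_pos = p_rr,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  inter <- which(!intra & no_ins)
  if (length(inter) >= 2L) {
    for (ii in seq_along(inter)) for (jj in seq_along(inter)) {
      if (jj <= ii) next
      i <- inter[ii]; j <- inter[jj]
      if (!setequal(c(cl$chrom1[i], cl$chrom2[i]),
                    c(cl$chrom1[j], cl$chrom2[j]))) next
      for (acc in unique(c(cl$chrom1[i], cl$chrom2[i]))) {
        side <- function(k) if (cl$chrom1[k] == acc)
          list(pos = cl$pos1[k], ori = cl$ori1[k], opos = cl$pos2[k],
               oori = cl$ori2[k], ochrom = cl$chrom2[k])
        else
          list(pos = cl$pos2[k], ori = cl$ori2[k], opos = cl$pos1[k],
               oori = cl$ori1[k], ochrom = cl$chrom1[k])
        ai <- side(i); aj <- side(j)
        if (ai$ochrom == acc || aj$ochrom == acc) next
        opposite_ok <- cfg$allow_inverted_ddup ||
          (ai$ori != aj$ori && ai$oori != aj$oori)
        span <- abs(ai$opos - aj$opos)
        if (abs(ai$pos - aj$pos) <= w && opposite_ok &&
            span >= cfg$min_size) {
          out[[length(out) + 1L]] <- data.frame(
            a = i, b = j, dist = abs(ai$pos - aj$pos), chrom = ai$ochrom,
            start = min(ai$opos, aj$opos), end = max(ai$opos, aj$opos),
            ins_chrom = acc, ins_pos = min(ai$pos, aj$pos),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Classify one adjacency cluster into CNV calls
#'
#' Searches the cluster for dispersed-duplication signatures first (each
#' adjacency participates in at most one DDUP; candidate pairs are taken
#' greedily by smallest shared-breakpoint distance, ties broken by leftmost
#' template coordinate), then classifies the remaining members with
#' [classify_singleton()]. A DDUP call's support counts are the per-signal
#' minimum over its two member adjacencies (both junctions must be
#' supported).
#'
#' @param cl Adjacency table forming one cluster (one tool).
#' @param cfg A [classification_config()].
#' @return `list(calls =, excluded =)`.
#' @export
classify_cluster <- function(cl, cfg = classification_config()) {
  validate_adjacencies(cl)
  cand <- ddup_candidates(cl, cfg)
  used <- logical(nrow(cl))
  calls <- list()
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist, cand$chrom, cand$start, cand$ins_pos), ,
                 drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]; b <- cand$b[k]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      calls[[length(calls) + 1L]] <- cnv_calls(
        type = "DDUP", chrom = cand$chrom[k], start = cand$start[k],
        end = cand$end[k], ins_chrom = cand$ins_chrom[k],
        ins_pos = cand$ins_pos[k],
        pe_support = min(cl$pe[a], cl$pe[b]),
        sr_support = min(cl$sr[a], cl$sr[b]),
        source_tools = cl$tool[a], n_donors = 1L,
        id = paste(cl$id[a], cl$id[b], sep = "+"))
    }
  }
  excluded <- list()
  for (i in which(!used)) {
    res <- classify_singleton(cl[i, , drop = FALSE], cfg)
    if (nrow(res$calls)) calls[[length(calls) + 1L]] <- res$calls
    if (nrow(res$excluded)) excluded[[length(excluded) + 1L]] <- res$excluded
  }
  list(calls = do.call(rbind, c(list(empty_calls()), calls)),
       excluded = do.call(rbind, c(list(empty_excluded()), excluded)))
}

#' Reclassify caller adjacencies into typed CNV calls
#'
#' The Stage-2 core: per source tool, cluster adjacencies
#' ([cluster_adjacencies()]) and convert each cluster to calls
#' ([classify_cluster()]). With `correct_ddup = FALSE` every adjacency is
#' classified in isolation — the behaviour of callers that process the two
#' adjacencies of a dispersed duplication independently, yielding the
#' characteristic overlapping false-positive deletion + tandem-duplication
#' pair.
#'
#' @param adjs Adjacency table (any mix of tools).
#' @param cfg A [classification_config()].
#' @param correct_ddup Search clusters for dispersed-duplication signatures
#'   (default) or classify each adjacency alone.
#' @return `list(calls =, excluded =)`: every input adjacency ends up backing
#'   exactly one call or one excluded record. Calls are sorted
#'   deterministically.
#' @export
reclassify <- function(adjs, cfg = classification_config(),
                       correct_ddup = TRUE) {
  validate_adjacencies(adjs)
  if (nrow(adjs) == 0L)
    return(list(calls = empty_calls(), excluded = empty_excluded()))
  clustered <- cluster_adjacencies(adjs, cfg)
  groups <- if (correct_ddup) split(clustered, clustered$cluster)
            else split(clustered, seq_len(nrow(clustered)))
  calls <- list(); excluded <- list()
  for (g in groups) {
    res <- classify_cluster(g[, names(ADJ_COLS), drop = FALSE], cfg)
    if (nrow(res$calls)) calls[[length(calls) + 1L]] <- res$calls
    if (nrow(res$excluded)) excluded[[length(excluded) + 1L]] <- res$excluded
  }
  calls <- do.call(rbind, c(list(empty_calls()), calls))
  excluded <- do.call(rbind, c(list(empty_excluded()), excluded))
  rownames(excluded) <- NULL
  list(calls = sort_calls(calls), excluded = excluded)
}
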