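## Spike-in simulator and evaluator. Events are simulated at the adjacency
## level: the generator places non-overlapping CNVs on a synthetic genome,
## derives the exact novel-adjacency signature of each event, and a caller
## emulator then degrades that truth the way short-read callers do —
## per-adjacency detection scaled by allele dosage, breakpoint jitter,
## Poisson support counts and false positives. Crucially, emulated callers
## with `split_ddup = TRUE` report the two adjacencies of a dispersed
## duplication independently and unlinked, reproducing the overlapping
## deletion + tandem-duplication misrepresentation the reclassifier corrects.

#' Simulate a truth set of spiked-in CNVs
#'
#' Events are placed uniformly at random without overlap (rejection
#' sampling); sizes are drawn log-uniform over `size_range`. Allele dosage
#' defaults to `ploidy` (homozygous spike-ins, as when reads are simulated
#' from a fully rearranged genome); pass a smaller dosage (or a sampler
#' vector) to emulate variants present on few haplotypes.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_per_type Named counts, e.g. `c(DEL = 100, DDUP = 50)`.
#' @param size_range Two-element bp range for log-uniform sizes
#'   (default `c(50, 1e5)`).
#' @param ploidy Sample ploidy (default 2).
#' @param dosage Allele dosage of each event: a single value or a vector to
#'   sample from uniformly; default `ploidy`.
#' @param ddup_inter_fraction Fraction of dispersed duplications whose copy
#'   lands on a different chromosome (default 0.25; forced to 0 with a
#'   single chromosome).
#' @param margin Bp kept free at chromosome ends.
#' @param seed Seed for reproducible truth sets.
#' @return `data.frame` with columns id, type, chrom, start, end, ins_chrom,
#'   ins_pos, inter, size, dosage; attribute `"ploidy"` and
#'   `"chrom_lengths"`.
#' @export
simulate_truth <- function(chrom_lengths, n_per_type,
                           size_range = c(50, 1e5), ploidy = 2,
                           dosage = ploidy, ddup_inter_fraction = 0.25,
                           margin = 1000, seed = NULL) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            all(names(n_per_type) %in% CNV_TYPES),
            size_range[1] >= 50, all(dosage >= 1), all(dosage <= ploidy))
  if (length(chrom_lengths) == 1L) ddup_inter_fraction <- 0
  with_seed(seed, {
    occupied <- lapply(chrom_lengths, function(...)
      data.frame(start = numeric(0), end = numeric(0)))
    place <- function(size) {
      for (try in 1:200) {
        cr <- sample(names(chrom_lengths), 1,
                     prob = as.numeric(chrom_lengths))
        lo <- margin
        hi <- chrom_lengths[[cr]] - margin - size
        if (hi <= lo) next
        s <- floor(runif(1, lo, hi))
        occ <- occupied[[cr]]
        if (nrow(occ) == 0L ||
            all(s + size <= occ$start | s >= occ$end)) {
          occupied[[cr]] <<- rbind(occ, data.frame(start = s,
                                                   end = s + size))
          return(list(chrom = cr, start = s, end = s + size))
        }
      }
      stop("cannot place events without overlap; lower the event density")
    }
    rows <- list()
    k <- 0L
    for (ty in intersect(CNV_TYPES, names(n_per_type))) {
      for (i in seq_len(n_per_type[[ty]])) {
        k <- k + 1L
        size <- round(10^runif(1, log10(size_range[1]),
                               log10(size_range[2])))
        dos <- if (length(dosage) == 1L) dosage else sample(dosage, 1)
        if (ty == "INS") {
          site <- place(1)
          rows[[k]] <- data.frame(
            id = sprintf("t%d", k), type = "INS", chrom = site$chrom,
            start = site$start, end = site$start, ins_chrom = site$chrom,
            ins_pos = site$start, inter = FALSE, size = size, dosage = dos,
            stringsAsFactors = FALSE)
        } else if (ty == "DDUP") {
          tmpl <- place(size)
          inter <- runif(1) < ddup_inter_fraction
          repeat {
            land <- place(1)
            if (inter && land$chrom != tmpl$chrom) break
            if (!inter && land$chrom == tmpl$chrom) break
          }
          rows[[k]] <- data.frame(
            id = sprintf("t%d", k), type = "DDUP", chrom = tmpl$chrom,
            start = tmpl$start, end = tmpl$end, ins_chrom = land$chrom,
            ins_pos = land$start, inter = land$chrom != tmpl$chrom,
            size = size, dosage = dos, stringsAsFactors = FALSE)
        } else {
          reg <- place(size)
          rows[[k]] <- data.frame(
            id = sprintf("t%d", k), type = ty, chrom = reg$chrom,
            start = reg$start, end = reg$end, ins_chrom = NA_character_,
            ins_pos = NA_real_, inter = FALSE, size = size, dosage = dos,
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$chrom, truth$start, truth$id), ]
    rownames(truth) <- NULL
    attr(truth, "ploidy") <- ploidy
    attr(truth, "chrom_lengths") <- chrom_lengths
    truth
  })
}

#' Derive the exact novel-adjacency signature of each truth event
#'
#' Deletions, insertions and tandem duplications each generate one adjacency;
#' a dispersed duplication generates two — for a downstream intrachromosomal
#' copy of template `[s, e)` landing at `p`, the tandem-duplication-like
#' junction `(s L, p R)` plus the deletion-like junction `(e R, p L)`
#' (mirrored for upstream copies; a translocation-style pair for
#' interchromosomal ones). `reclassify(truth_adjacencies(x))` recovers `x`.
#'
#' @param truth Truth set from [simulate_truth()].
#' @return Adjacency table (tool `"SIM"`) with bookkeeping columns
#'   `variant_id`, `variant_type`, `dosage`.
#' @export
truth_adjacencies <- function(truth) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    v <- truth[i, ]
    a <- switch(v$type,
      DEL = adjacencies(v$chrom, v$start, ORI_RIGHT, v$chrom, v$end,
                        ORI_LEFT, tool = "SIM", id = paste0(v$id, ".1")),
      TDUP = adjacencies(v$chrom, v$start, ORI_LEFT, v$chrom, v$end,
                         ORI_RIGHT, tool = "SIM", id = paste0(v$id, ".1")),
      INS = adjacencies(v$chrom, v$ins_pos, ORI_RIGHT, v$chrom, v$ins_pos,
                        ORI_LEFT, inserted_seq = UNKNOWN_SEQ, tool = "SIM",
                        id = paste0(v$id, ".1")),
      DDUP = rbind(
        adjacencies(v$chrom, v$start, ORI_LEFT, v$ins_chrom, v$ins_pos,
                    ORI_RIGHT, tool = "SIM", id = paste0(v$id, ".1")),
        adjacencies(v$chrom, v$end, ORI_RIGHT, v$ins_chrom, v$ins_pos,
                    ORI_LEFT, tool = "SIM", id = paste0(v$id, ".2"))))
    a$variant_id <- v$id
    a$variant_type <- v$type
    a$dosage <- v$dosage
    a
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Behavioural profile of an emulated caller
#'
#' @param tool Tool identifier.
#' @param detection Named per-type detection probability of a variant's
#'   adjacencies (before dosage scaling).
#' @param jitter_sd Breakpoint jitter standard deviation in bp.
#' @param fp_per_mb Named per-type false-positive rate per Mb of genome.
#' @param split_ddup Report the two adjacencies of a dispersed duplication
#'   independently (each retained/dropped on its own) with no linkage —
#'   the misrepresentation mechanism of short-read callers. When FALSE the
#'   variant is detected or missed as a whole.
#' @param dosage_scaling Multiply detection probabilities and support means
#'   by `dosage / ploidy` (effective coverage of the variant allele).
#' @param mean_pe,mean_sr Mean supporting read counts at full dosage.
#' @return A `caller_profile` list.
#' @export
caller_profile <- function(tool,
                           detection = c(DEL = 0.9, INS = 0.7, TDUP = 0.9,
                                         DDUP = 0.9),
                           jitter_sd = 2,
                           fp_per_mb = c(DEL = 0.5, INS = 0.2, TDUP = 0.3,
                                         DDUP = 0),
                           split_ddup = TRUE, dosage_scaling = TRUE,
                           mean_pe = 10, mean_sr = 8) {
  stopifnot(all(detection >= 0), all(detection <= 1), jitter_sd >= 0,
            all(fp_per_mb >= 0))
  det <- c(DEL = 0.9, INS = 0.7, TDUP = 0.9, DDUP = 0.9)
  det[names(detection)] <- detection
  fp <- c(DEL = 0.5, INS = 0.2, TDUP = 0.3, DDUP = 0)
  fp[names(fp_per_mb)] <- fp_per_mb
  structure(list(tool = toupper(tool), detection = det,
                 jitter_sd = jitter_sd, fp_per_mb = fp,
                 split_ddup = split_ddup, dosage_scaling = dosage_scaling,
                 mean_pe = mean_pe, mean_sr = mean_sr),
            class = "caller_profile")
}

jitter_pos <- function(pos, sd) {
  if (sd == 0) return(pos)
  pmax(0, pos + round(rnorm(length(pos), 0, sd)))
}

#' Emulate one caller's output over a truth adjacency set
#'
#' Each true adjacency is retained with the type-specific (and, for
#' dosage-scaled profiles, dosage-scaled) detection probability; retained
#' breakpoints get integer Gaussian jitter; supports are Poisson draws with
#' dosage-scaled means; false-positive adjacencies are sprinkled at the
#' profile's per-Mb rates. With `detection = 1`, `jitter_sd = 0` and zero
#' false-positive rates the output equals the truth adjacencies.
#'
#' @param truth_adjs Output of [truth_adjacencies()].
#' @param profile A [caller_profile()].
#' @param chrom_lengths Named chromosome lengths (for false-positive
#'   placement); defaults to the truth attribute when present.
#' @param ploidy Sample ploidy; defaults to the truth attribute.
#' @param seed Seed.
#' @return Adjacency table with `tool = profile$tool`.
#' @export
emulate_caller <- function(truth_adjs, profile, chrom_lengths, ploidy = 2,
                           seed = NULL) {
  stopifnot(inherits(profile, "caller_profile"))
  with_seed(seed, {
    scale <- if (profile$dosage_scaling) truth_adjs$dosage / ploidy else 1
    p_det <- unname(profile$detection[truth_adjs$variant_type]) * scale
    keep <- if (profile$split_ddup) runif(nrow(truth_adjs)) < p_det
    else {
      ## variant-level coin: all adjacencies of one variant live or die
      ## together
      u <- stats::setNames(runif(length(unique(truth_adjs$variant_id))),
                           unique(truth_adjs$variant_id))
      u[truth_adjs$variant_id] < p_det
    }
    out <- truth_adjs[keep, names(ADJ_COLS), drop = FALSE]
    if (nrow(out)) {
      out$pos1 <- jitter_pos(out$pos1, profile$jitter_sd)
      out$pos2 <- jitter_pos(out$pos2, profile$jitter_sd)
      sup_scale <- if (profile$dosage_scaling)
        truth_adjs$dosage[keep] / ploidy else 1
      out$pe <- rpois(nrow(out), profile$mean_pe * sup_scale)
      out$sr <- rpois(nrow(out), profile$mean_sr * sup_scale)
      out$tool <- profile$tool
      out$id <- sprintf("%s_%s", tolower(profile$tool), out$id)
      out <- canonicalize_adjacency(out)
    }
    ## false positives
    genome_mb <- sum(as.numeric(chrom_lengths)) / 1e6
    fp_rows <- list()
    for (ty in names(profile$fp_per_mb)) {
      n_fp <- rpois(1, profile$fp_per_mb[[ty]] * genome_mb)
      for (i in seq_len(n_fp)) {
        cr <- sample(names(chrom_lengths), 1,
                     prob = as.numeric(chrom_lengths))
        size <- round(10^runif(1, log10(50), log10(1e5)))
        s <- floor(runif(1, 0, max(1, chrom_lengths[[cr]] - size - 1)))
        fp_rows[[length(fp_rows) + 1L]] <- switch(ty,
          DEL = adjacencies(cr, s, ORI_RIGHT, cr, s + size, ORI_LEFT,
                            pe = rpois(1, profile$mean_pe / 4),
                            sr = rpois(1, profile$mean_sr / 4),
                            tool = profile$tool,
                            id = sprintf("%s_fp%s%d", tolower(profile$tool),
                                         tolower(ty), length(fp_rows) + 1L)),
          TDUP = adjacencies(cr, s, ORI_LEFT, cr, s + size, ORI_RIGHT,
                             pe = rpois(1, profile$mean_pe / 4),
                             sr = rpois(1, profile$mean_sr / 4),
                             tool = profile$tool,
                             id = sprintf("%s_fp%s%d",
                                          tolower(profile$tool),
                                          tolower(ty),
                                          length(fp_rows) + 1L)),
          INS = adjacencies(cr, s, ORI_RIGHT, cr, s, ORI_LEFT,
                            inserted_seq = UNKNOWN_SEQ,
                            pe = rpois(1, profile$mean_pe / 4),
                            sr = rpois(1, profile$mean_sr / 4),
                            tool = profile$tool,
                            id = sprintf("%s_fp%s%d", tolower(profile$tool),
                                         tolower(ty), length(fp_rows) + 1L)),
          NULL)
      }
    }
    out <- do.call(rbind, c(list(out), fp_rows))
    rownames(out) <- NULL
    out
  })
}

greedy_match <- function(pred, truth, type, insertion_window,
                         min_reciprocal_overlap) {
  p_ix <- which(pred$type == type)
  t_ix <- which(truth$type == type)
  if (length(p_ix) == 0L || length(t_ix) == 0L)
    return(data.frame(pred = integer(0), truth = integer(0)))
  cand <- list()
  for (i in p_ix) for (j in t_ix) {
    if (type == "INS") {
      if (pred$chrom[i] != truth$chrom[j]) next
      d <- abs(pred$ins_pos[i] - truth$ins_pos[j])
      if (d > insertion_window) next
      score <- -d
    } else {
      if (pred$chrom[i] != truth$chrom[j]) next
      ov <- min(pred$end[i], truth$end[j]) - max(pred$start[i],
                                                 truth$start[j])
      lp <- pred$end[i] - pred$start[i]
      lt <- truth$end[j] - truth$start[j]
      if (ov <= 0 || ov / lp < min_reciprocal_overlap ||
          ov / lt < min_reciprocal_overlap) next
      if (type == "DDUP") {
        if (!identical(pred$ins_chrom[i], truth$ins_chrom[j])) next
        if (abs(pred$ins_pos[i] - truth$ins_pos[j]) > insertion_window) next
      }
      score <- min(ov / lp, ov / lt)
    }
    cand[[length(cand) + 1L]] <- data.frame(pred = i, truth = j,
                                            score = score)
  }
  if (length(cand) == 0L)
    return(data.frame(pred = integer(0), truth = integer(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, pred$start[cand$pred],
                     truth$start[cand$truth]), , drop = FALSE]
  used_p <- logical(nrow(pred)); used_t <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_p[cand$pred[k]] && !used_t[cand$truth[k]]) {
      keep[k] <- TRUE
      used_p[cand$pred[k]] <- TRUE
      used_t[cand$truth[k]] <- TRUE
    }
  }
  cand[keep, c("pred", "truth"), drop = FALSE]
}

#' Score predicted calls against a truth set
#'
#' Greedy one-to-one matching, same type required: region types match at
#' `min_reciprocal_overlap` reciprocal overlap (dispersed duplications
#' additionally need insertion points within `insertion_window`); insertions
#' match on insertion-point distance alone. Candidates are taken
#' best-overlap-first with deterministic leftmost tie-breaking.
#'
#' @param pred Predicted call table.
#' @param truth Truth set from [simulate_truth()] (or any call-like table
#'   with type/chrom/start/end/ins columns).
#' @param insertion_window Matching tolerance on insertion points (bp,
#'   default 100).
#' @param min_reciprocal_overlap Default 0.5.
#' @return `data.frame` with one row per type plus `"overall"`: tp, fp, fn,
#'   recall, precision (NA where undefined, e.g. precision with no
#'   predictions).
#' @export
evaluate_calls <- function(pred, truth, insertion_window = 100,
                           min_reciprocal_overlap = 0.5) {
  rows <- lapply(CNV_TYPES, function(ty) {
    m <- greedy_match(pred, truth, ty, insertion_window,
                      min_reciprocal_overlap)
    tp <- nrow(m)
    fp <- sum(pred$type == ty) - tp
    fn <- sum(truth$type == ty) - tp
    data.frame(type = ty, tp = tp, fp = fp, fn = fn,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  rbind(per, data.frame(
    type = "overall", tp = tp, fp = fp, fn = fn,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    stringsAsFactors = FALSE))
}
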