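## Stage chaining: VCFs -> reclassified per-tool calls -> merged BEDPE
## (post-processing), labeled BEDPE -> trained model (training), BEDPE +
## model -> scored, filtered BEDPE (filtering). Every run returns a
## machine-readable manifest with the configuration and per-stage counts;
## identical manifests imply identical outputs.

run_manifest <- function(stage, config, counts, seed = NULL) {
  list(tool = "cnvpost",
       version = as.character(utils::packageVersion("cnvpost")),
       stage = stage, seed = seed, config = config, counts = counts)
}

#' Write a run manifest as JSON
#' @param manifest Manifest list from a `run_*` function's `$manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Post-process caller VCFs into a merged call set
#'
#' Reads each caller VCF with its dialect, reclassifies adjacencies per tool
#' (dispersed-duplication correction included), merges concordant calls
#' across tools, and optionally writes the merged BEDPE. An input set that
#' yields no classifiable calls produces an empty output with a warning, not
#' an error.
#'
#' @param vcfs Named character vector of VCF paths; names select the dialect
#'   (e.g. `c(delly = "delly.vcf", manta = "manta.vcf")`).
#' @param out_bedpe Optional output BEDPE path.
#' @param class_cfg A [classification_config()].
#' @param merge_cfg A [merge_config()].
#' @param dialects Dialect map, as [default_dialects()].
#' @return `list(calls, excluded, donor_map, manifest)`.
#' @export
run_postprocess <- function(vcfs, out_bedpe = NULL,
                            class_cfg = classification_config(),
                            merge_cfg = merge_config(),
                            dialects = default_dialects()) {
  stopifnot(length(vcfs) >= 1, !is.null(names(vcfs)))
  adjs <- list()
  n_read <- integer(0)
  for (nm in names(vcfs)) {
    dialect <- dialects[[tolower(nm)]]
    if (is.null(dialect)) stop("unknown caller dialect: ", nm)
    a <- read_caller_vcf(vcfs[[nm]], dialect)
    n_read[nm] <- nrow(a)
    adjs[[nm]] <- a
  }
  adjs <- do.call(rbind, c(list(empty_adjacencies()), adjs))
  rec <- reclassify(adjs, class_cfg)
  merged <- merge_calls(rec$calls, merge_cfg)
  if (nrow(merged) == 0L)
    warning("no classifiable CNV calls in input; writing empty call set")
  counts <- list(
    adjacencies_read = as.list(n_read),
    classified = nrow(rec$calls),
    excluded_by_reason = as.list(table(rec$excluded$reason)),
    merged = nrow(merged))
  if (!is.null(out_bedpe)) write_bedpe(merged, out_bedpe)
  list(calls = merged, excluded = rec$excluded,
       donor_map = attr(merged, "donor_map"),
       manifest = run_manifest("postprocess",
                               list(class_cfg = unclass(class_cfg),
                                    merge_cfg = unclass(merge_cfg)),
                               counts))
}

per_type_pr <- function(calls, labels, scores, cutoff = 0.5) {
  pred_pos <- scores >= cutoff
  do.call(rbind, lapply(CNV_TYPES, function(ty) {
    ix <- calls$type == ty
    tp <- sum(ix & pred_pos & labels == 1)
    fp <- sum(ix & pred_pos & labels == 0)
    fn <- sum(ix & !pred_pos & labels == 1)
    data.frame(type = ty, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Train the call classifier on a labeled call set
#'
#' Splits by hold-out chromosome, grid-searches the forest with stratified
#' cross-validation on the training partition, refits, and reports held-out
#' accuracy and per-type precision/recall at the 0.5 cutoff.
#'
#' @param calls Labeled call table (merged calls).
#' @param labels 0/1 vector (1 = true positive), aligned with `calls`.
#' @param holdout_chroms Chromosomes reserved for the held-out report.
#' @param grid,folds,seed Passed to [train_rf()].
#' @param model_path Optional path to persist the model as JSON.
#' @return `list(model, report, manifest)`.
#' @export
run_train <- function(calls, labels, holdout_chroms, grid = default_rf_grid(),
                      folds = 10, seed = 1, model_path = NULL) {
  sp <- split_by_chromosome(calls, labels, holdout_chroms)
  model <- train_rf(extract_features(sp$train$calls), sp$train$labels,
                    grid = grid, folds = folds, seed = seed)
  test_scores <- predict_rf(model, extract_features(sp$test$calls))
  report <- list(
    chosen = model$chosen,
    cv_report = model$cv_report,
    holdout_chroms = holdout_chroms,
    holdout_accuracy = mean((test_scores >= 0.5) == (sp$test$labels == 1)),
    holdout_per_type = per_type_pr(sp$test$calls, sp$test$labels,
                                   test_scores))
  if (!is.null(model_path)) save_rf_model(model, model_path)
  counts <- list(train = nrow(sp$train$calls), test = nrow(sp$test$calls))
  list(model = model, report = report,
       manifest = run_manifest("train",
                               list(grid = grid, folds = folds,
                                    holdout = holdout_chroms),
                               counts, seed = seed))
}

#' Score and filter a merged call set
#'
#' Featurizes, scores with the model, drops calls below the cutoff, and —
#' only when `aux_cfg$enabled` — applies the depth and flanking-gap filters.
#' With the auxiliary filters disabled (the default) the output is identical
#' whether or not a depth track / genome is supplied.
#'
#' @param calls Call table (or BEDPE path).
#' @param model `rf_model` (or model JSON path).
#' @param cutoff Probability cutoff in `[0, 1]` (default 0.5).
#' @param depth Optional [depth_track()].
#' @param genome Optional genome (named character / `DNAStringSet`).
#' @param aux_cfg An [aux_filter_config()].
#' @param out_bedpe Optional output path.
#' @return `list(calls, manifest)`; `calls` carry their scores.
#' @export
run_filter <- function(calls, model, cutoff = 0.5, depth = NULL,
                       genome = NULL, aux_cfg = aux_filter_config(),
                       out_bedpe = NULL) {
  if (is.character(calls)) calls <- read_bedpe(calls)
  if (is.character(model)) model <- load_rf_model(model)
  scored <- score_calls(model, calls)
  kept <- filter_by_score(scored, cutoff)
  counts <- list(input = nrow(calls), above_cutoff = nrow(kept))
  if (isTRUE(aux_cfg$enabled)) {
    if (!is.null(depth)) {
      kept <- depth_filter(kept, depth, aux_cfg)
      counts$after_depth_filter <- nrow(kept)
    }
    if (!is.null(genome)) {
      kept <- gap_filter(kept, genome, aux_cfg)
      counts$after_gap_filter <- nrow(kept)
    }
  }
  if (!is.null(out_bedpe)) write_bedpe(kept, out_bedpe)
  list(calls = kept,
       manifest = run_manifest("filter",
                               list(cutoff = cutoff,
                                    aux_cfg = unclass(aux_cfg)),
                               counts))
}
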