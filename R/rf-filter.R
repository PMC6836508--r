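## Random-forest call filter: feature extraction, chromosome hold-out split,
## grid-searched cross-validated training, probabilistic scoring, cutoff
## filtering.

FEATURE_NAMES <- c("type_DEL", "type_INS", "type_TDUP", "type_DDUP",
                   "size_log10", "size_known", "n_tools",
                   "tool_DELLY", "tool_GRIDSS", "tool_LUMPY", "tool_MANTA",
                   "pe_support", "sr_support", "total_support")

#' Build the per-call feature matrix
#'
#' One row per merged call: type one-hot indicators; `log10(size)` with an
#' explicit `size_known` missingness flag (0/0 for unknown-size insertions,
#' so the sentinel never enters arithmetic); the number of concordant tools
#' and per-tool indicator flags; and the merged median PE, SR and total
#' support. Deterministic: identical calls map to identical rows.
#'
#' @param calls Call table.
#' @return Numeric matrix with `rownames = calls$id`.
#' @export
extract_features <- function(calls) {
  validate_calls(calls)
  n <- nrow(calls)
  m <- matrix(0, nrow = n, ncol = length(FEATURE_NAMES),
              dimnames = list(calls$id, FEATURE_NAMES))
  if (n == 0L) return(m)
  for (ty in CNV_TYPES)
    m[, paste0("type_", ty)] <- as.numeric(calls$type == ty)
  known <- !is.na(calls$size)
  m[known, "size_log10"] <- log10(pmax(calls$size[known], 1))
  m[, "size_known"] <- as.numeric(known)
  tools <- strsplit(calls$source_tools, ",")
  m[, "n_tools"] <- lengths(tools)
  for (tl in c("DELLY", "GRIDSS", "LUMPY", "MANTA"))
    m[, paste0("tool_", tl)] <- vapply(tools, function(x) tl %in% x,
                                       logical(1))
  m[, "pe_support"] <- calls$pe_support
  m[, "sr_support"] <- calls$sr_support
  m[, "total_support"] <- calls$pe_support + calls$sr_support
  storage.mode(m) <- "double"
  m
}

#' Write / read a feature matrix as TSV
#' @param features Matrix from [extract_features()].
#' @param path File path.
#' @return The matrix (reader) or `path` (writer), invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(call_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Split a labeled call set by chromosome
#'
#' Calls on the hold-out chromosomes form the test partition; everything else
#' trains the model. Mirrors hold-out evaluation on chromosomes unseen during
#' training rather than a random split, which would leak locus-level
#' structure.
#'
#' @param calls Call table.
#' @param labels 0/1 vector aligned with `calls` rows.
#' @param holdout Character vector of chromosome names to hold out.
#' @return `list(train = list(calls, labels), test = list(calls, labels))`.
#' @export
split_by_chromosome <- function(calls, labels, holdout) {
  validate_calls(calls)
  stopifnot(length(labels) == nrow(calls), all(labels %in% c(0, 1)))
  missing <- setdiff(holdout, unique(calls$chrom))
  if (length(missing))
    stop("holdout chromosomes absent from call set: ",
         paste(missing, collapse = ", "))
  test_ix <- calls$chrom %in% holdout
  if (!any(test_ix)) stop("empty test partition")
  if (all(test_ix)) stop("empty training partition")
  list(train = list(calls = calls[!test_ix, , drop = FALSE],
                    labels = labels[!test_ix]),
       test = list(calls = calls[test_ix, , drop = FALSE],
                   labels = labels[test_ix]))
}

#' Default hyperparameter grid
#'
#' Searched dimensions are the ensemble size, maximum tree depth (0 =
#' unbounded) and features tried per split.
#' @return `data.frame` grid.
#' @export
default_rf_grid <- function() {
  expand.grid(n_trees = c(100L, 250L, 500L), max_depth = c(0L, 5L, 10L),
              mtry = c("sqrt", "all"), stringsAsFactors = FALSE)
}

resolve_mtry <- function(mtry, p) {
  if (identical(mtry, "sqrt")) max(1L, floor(sqrt(p)))
  else if (identical(mtry, "all")) p
  else as.integer(mtry)
}

fit_forest <- function(features, labels, n_trees, max_depth, mtry, seed) {
  forest <- .rf_grow_cpp(features, as.integer(labels), as.integer(n_trees),
                         as.integer(max_depth),
                         resolve_mtry(mtry, ncol(features)),
                         as.integer(seed))
  structure(list(forest = forest, feature_names = colnames(features),
                 n_trees = n_trees, max_depth = max_depth, mtry = mtry,
                 seed = seed),
            class = "rf_model")
}

## stratified fold assignment: within each class, deterministic shuffled
## round-robin, so every example lands in exactly one validation fold and
## folds are class-balanced
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      ix <- which(labels == cls)
      fold[ix[sample.int(length(ix))]] <- rep_len(seq_len(folds), length(ix))
    }
  })
  fold
}

#' Train the random-forest call classifier
#'
#' Grid search with stratified k-fold cross-validation: for every grid point
#' the mean validation accuracy over the folds is computed; the best point
#' (ties broken towards the smallest ensemble, then the shallowest bounded
#' depth) is refit on the full training set. The seed fixes the fold
#' assignment and all tree randomness, so identical inputs give identical
#' models and reports.
#'
#' @param features Feature matrix from [extract_features()].
#' @param labels 0/1 vector (1 = true positive).
#' @param grid Hyperparameter grid, as [default_rf_grid()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed.
#' @return An `rf_model` with the fitted forest, chosen hyperparameters and a
#'   `cv_report` data frame of per-point mean validation accuracies.
#' @export
train_rf <- function(features, labels, grid = default_rf_grid(), folds = 10,
                     seed = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  if (min(table(labels)) < folds)
    stop("need at least ", folds, " labeled examples per class")
  fold <- stratified_folds(labels, folds, seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- fit_forest(features[tr, , drop = FALSE], labels[tr],
                          grid$n_trees[g], grid$max_depth[g], grid$mtry[g],
                          seed + g * 1000L + f)
      p <- predict_rf(model, features[!tr, , drop = FALSE])
      correct <- correct + sum((p >= 0.5) == (labels[!tr] == 1L))
    }
    acc[g] <- correct / length(labels)
  }
  depth_key <- ifelse(grid$max_depth == 0L, Inf, grid$max_depth)
  best <- order(-acc, grid$n_trees, depth_key)[1]
  model <- fit_forest(features, labels, grid$n_trees[best],
                      grid$max_depth[best], grid$mtry[best], seed)
  model$cv_report <- cbind(grid, mean_cv_accuracy = acc)
  model$cv_folds <- folds
  model$chosen <- grid[best, , drop = FALSE]
  model
}

#' Predict positive-class probabilities
#'
#' The score of a call is the mean over trees of the per-leaf positive-class
#' fraction — a posterior probability estimate in `[0, 1]` of the call being
#' a true positive.
#'
#' @param model An `rf_model`.
#' @param features Feature matrix with the model's columns.
#' @return Numeric vector of scores.
#' @export
predict_rf <- function(model, features) {
  stopifnot(inherits(model, "rf_model"))
  if (!identical(colnames(features), model$feature_names))
    stop("feature schema mismatch; model expects columns: ",
         paste(setdiff(model$feature_names, colnames(features)),
               collapse = ", "))
  .rf_predict_cpp(model$forest, features)
}

#' Annotate calls with classifier scores
#'
#' @param model An `rf_model` from [train_rf()].
#' @param calls Call table.
#' @return `calls` with the `score` column filled.
#' @export
score_calls <- function(model, calls) {
  validate_calls(calls)
  calls$score <- if (nrow(calls)) predict_rf(model, extract_features(calls))
                 else numeric(0)
  calls
}

#' Drop calls below a probability cutoff
#'
#' @param calls Scored call table.
#' @param cutoff Threshold in `[0, 1]`; calls with `score >= cutoff` are
#'   retained, order preserved.
#' @return Filtered call table.
#' @export
filter_by_score <- function(calls, cutoff = 0.5) {
  validate_calls(calls)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1)
    stop("cutoff must be a single number in [0, 1]")
  if (nrow(calls) && anyNA(calls$score))
    stop("calls must be scored before filtering")
  out <- calls[calls$score >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persist / restore a trained model
#'
#' The model is stored as versioned JSON with embedded metadata (seed, grid,
#' CV report, chosen point) so a scoring run can verify the feature schema.
#'
#' @param model An `rf_model`.
#' @param path File path (`.json`).
#' @return `path` (writer) / the model (reader).
#' @export
save_rf_model <- function(model, path) {
  stopifnot(inherits(model, "rf_model"))
  payload <- list(
    format = "cnvpost-rf-1",
    feature_names = model$feature_names,
    n_trees = model$n_trees, max_depth = model$max_depth, mtry = model$mtry,
    seed = model$seed, cv_folds = model$cv_folds,
    chosen = model$chosen, cv_report = model$cv_report,
    forest = lapply(model$forest, function(m) unclass(m))
  )
  ## digits = I(17): decimal significands that reconstruct IEEE doubles
  ## exactly, so a reloaded model scores identically
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_rf_model
#' @export
load_rf_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "cnvpost-rf-1"))
    stop("not a cnvpost random-forest model file: ", path)
  forest <- lapply(payload$forest, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  structure(list(forest = forest, feature_names = payload$feature_names,
                 n_trees = payload$n_trees, max_depth = payload$max_depth,
                 mtry = payload$mtry, seed = payload$seed,
                 cv_folds = payload$cv_folds, chosen = payload$chosen,
                 cv_report = payload$cv_report),
            class = "rf_model")
}
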