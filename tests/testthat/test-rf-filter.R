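small_grid <- data.frame(n_trees = c(60L, 120L), max_depth = c(5L, 0L),
                         mtry = "sqrt", stringsAsFactors = FALSE)

test_that("feature extraction encodes type, size, concordance and support", {
  del <- cnv_calls("DEL", "chr1", 0, 1000, pe_support = 4, sr_support = 6,
                   source_tools = "DELLY,LUMPY,MANTA", id = "x")
  f <- extract_features(del)
  expect_equal(unname(f[1, c("type_DEL", "type_INS", "type_TDUP",
                             "type_DDUP")]), c(1, 0, 0, 0))
  expect_equal(unname(f[1, "size_log10"]), 3)
  expect_equal(unname(f[1, "size_known"]), 1)
  expect_equal(unname(f[1, "n_tools"]), 3)
  expect_equal(unname(f[1, "tool_GRIDSS"]), 0)
  expect_equal(unname(f[1, "total_support"]), 10)

  ins <- cnv_calls("INS", "chr1", 5, 5, ins_chrom = "chr1", ins_pos = 5,
                   inserted_seq = unknown_seq())
  fi <- extract_features(ins)
  expect_equal(unname(fi[1, "size_known"]), 0)
  expect_equal(unname(fi[1, "size_log10"]), 0)

  ## purity: identical calls, identical rows
  expect_equal(extract_features(rbind(del, del))[1, ],
               extract_features(rbind(del, del))[2, ])
})

test_that("chromosome hold-out split is disjoint and exhaustive", {
  set <- planted_call_set(200, seed = 3)
  sp <- split_by_chromosome(set$calls, set$labels, c("chr2", "chr4"))
  expect_setequal(unique(sp$test$calls$chrom), c("chr2", "chr4"))
  expect_false(any(sp$train$calls$chrom %in% c("chr2", "chr4")))
  expect_equal(nrow(sp$train$calls) + nrow(sp$test$calls), 200L)
  expect_error(split_by_chromosome(set$calls, set$labels, character(0)),
               "empty test")
  expect_error(split_by_chromosome(set$calls, set$labels, "chrZ"), "absent")
})

test_that("the forest recovers a noise-free planted concordance rule", {
  set <- planted_call_set(400, noise = 0, seed = 11)
  set$labels <- as.integer(extract_features(set$calls)[, "n_tools"] >= 3)
  sp <- split_by_chromosome(set$calls, set$labels, "chr5")
  model <- train_rf(extract_features(sp$train$calls), sp$train$labels,
                    grid = small_grid, folds = 10, seed = 4)
  p <- predict_rf(model, extract_features(sp$test$calls))
  acc <- mean((p >= 0.5) == (sp$test$labels == 1))
  expect_gte(acc, 0.95)
  ## planted separability: positives score higher on average
  expect_gt(mean(p[sp$test$labels == 1]), mean(p[sp$test$labels == 0]))
})

test_that("training is deterministic and validates its inputs", {
  set <- planted_call_set(120, noise = 0.1, seed = 9)
  X <- extract_features(set$calls)
  m1 <- train_rf(X, set$labels, grid = small_grid, folds = 5, seed = 2)
  m2 <- train_rf(X, set$labels, grid = small_grid, folds = 5, seed = 2)
  expect_identical(m1$cv_report, m2$cv_report)
  expect_identical(m1$chosen, m2$chosen)
  expect_identical(predict_rf(m1, X), predict_rf(m2, X))

  ## degenerate one-point grid is simply chosen
  g1 <- small_grid[1, , drop = FALSE]
  m3 <- train_rf(X, set$labels, grid = g1, folds = 5, seed = 2)
  expect_equal(m3$chosen$n_trees, g1$n_trees)

  expect_error(train_rf(X, rep(1L, nrow(X)), grid = g1, folds = 5),
               "single class")
  expect_error(train_rf(X[1:12, ], set$labels[1:12], grid = g1, folds = 10),
               "per class")
})

test_that("scores are probabilities and pure functions of the features", {
  set <- planted_call_set(150, noise = 0.1, seed = 13)
  model <- train_rf(extract_features(set$calls), set$labels,
                    grid = small_grid[1, , drop = FALSE], folds = 5,
                    seed = 1)
  scored <- score_calls(model, set$calls)
  expect_true(all(scored$score >= 0 & scored$score <= 1))
  dup <- score_calls(model, rbind(set$calls[1, ], set$calls[1, ]))
  expect_equal(dup$score[1], dup$score[2])

  ## schema mismatch is a clear error
  X <- extract_features(set$calls)[, -1]
  expect_error(predict_rf(model, X), "schema")
})

test_that("cutoff filtering is validated, boundary-correct and monotone", {
  set <- planted_call_set(100, seed = 17)
  model <- train_rf(extract_features(set$calls), set$labels,
                    grid = small_grid[1, , drop = FALSE], folds = 5,
                    seed = 1)
  scored <- score_calls(model, set$calls)
  expect_equal(nrow(filter_by_score(scored, 0)), nrow(scored))
  expect_error(filter_by_score(scored, 1.2), "\\[0, 1\\]")
  expect_error(filter_by_score(scored, -0.1), "\\[0, 1\\]")
  kept <- vapply(seq(0, 1, by = 0.1),
                 function(ct) nrow(filter_by_score(scored, ct)), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("a persisted model reloads to identical predictions", {
  set <- planted_call_set(80, seed = 23)
  X <- extract_features(set$calls)
  model <- train_rf(X, set$labels, grid = small_grid[1, , drop = FALSE],
                    folds = 5, seed = 6)
  path <- tempfile(fileext = ".json")
  save_rf_model(model, path)
  back <- load_rf_model(path)
  expect_identical(predict_rf(back, X), predict_rf(model, X))
  expect_equal(back$chosen, model$chosen)
})
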