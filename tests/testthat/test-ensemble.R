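test_that("grid search enumerates the exponent grid and finds separators", {
  d <- separable_xy()
  gs <- grid_search_svm(d$x, d$y, exponents = -2:2, folds = 3L, seed = 1L)
  expect_identical(gs$n_evaluated, 25L)
  expect_identical(nrow(gs$table), 25L)
  expect_equal(gs$cv_acc, 1)
  expect_true(gs$cost %in% 2^(-2:2) && gs$gamma %in% 2^(-2:2))

  # singleton grid returns exactly that pair
  one <- grid_search_svm(d$x, d$y, exponents = 3L, folds = 3L, seed = 1L)
  expect_identical(one$n_evaluated, 1L)
  expect_equal(one$cost, 8)
  expect_equal(one$gamma, 8)

  expect_error(grid_search_svm(d$x, rep("virion", nrow(d$x))),
               "both classes")
})

test_that("member scores are calibrated to [0, 1] and ensembles average them", {
  fx <- tiny_model_fixture()
  model <- fx$model
  expect_length(model$baselines, 5L)
  for (b in model$baselines) expect_length(b$members, 5L)

  test <- generate_dataset(synth_spec(n_pos = 5L, n_neg = 5L,
                                      length_range = c(30L, 50L), delta = 6,
                                      seed = 881L, id_prefix = "t_"))
  pred <- predict(model, test)
  score_cols <- paste0("score_", EVOLUTIONARY_ENCODERS)
  expect_true(all(as.matrix(pred[score_cols]) >= 0 &
                    as.matrix(pred[score_cols]) <= 1))
  # the final score is the unweighted mean of the per-feature scores
  expect_equal(pred$score_final,
               rowMeans(as.matrix(pred[score_cols])), tolerance = 1e-12)
  # and each per-feature score is the mean of its five member scores
  x <- encode_feature_matrix(test$records, test$profiles, "AAC_PSSM")
  member_scores <- sapply(model$baselines$AAC_PSSM$members,
                          virionpred:::.member_score, x = x)
  expect_equal(pred$score_AAC_PSSM, unname(rowMeans(member_scores)),
               tolerance = 1e-12)
  # calls follow the threshold with >= at the boundary
  expect_identical(pred$call,
                   ifelse(pred$score_final >= model$threshold, "virion",
                          "nonvirion"))
  at_boundary <- predict(model, test, threshold = pred$score_final[1L])
  expect_identical(at_boundary$call[1L], "virion")
})

test_that("prediction continues past proteins lacking a profile", {
  fx <- tiny_model_fixture()
  test <- generate_dataset(synth_spec(n_pos = 3L, n_neg = 3L,
                                      length_range = c(30L, 50L), delta = 6,
                                      seed = 882L, id_prefix = "u_"))
  profiles <- test$profiles[-2L]
  pred <- predict(fx$model, test$records, profiles = profiles)
  expect_identical(pred$error[2L], "missing PSSM profile")
  expect_true(is.na(pred$score_final[2L]))
  expect_false(anyNA(pred$score_final[-2L]))
})

test_that("training is deterministic in the seed and persists losslessly", {
  fx <- tiny_model_fixture()
  test <- generate_dataset(synth_spec(n_pos = 4L, n_neg = 4L,
                                      length_range = c(30L, 50L), delta = 6,
                                      seed = 883L, id_prefix = "v_"))
  retrained <- train_virion_ensemble(fx$ds, seed = 302L, exponents = c(-10L, 0L, 10L),
                           folds = 3L)
  expect_identical(predict(fx$model, test), predict(retrained, test))

  other_seed <- train_virion_ensemble(fx$ds, seed = 999L, exponents = c(-10L, 0L, 10L),
                            folds = 3L)
  p <- predict(other_seed, test)
  expect_true(all(p$score_final >= 0 & p$score_final <= 1))

  path <- withr::local_tempfile(fileext = ".rds")
  save_virion_ensemble(fx$model, path)
  expect_identical(predict(load_virion_ensemble(path), test), predict(fx$model, test))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other-format/9", model = NULL), bad)
  expect_error(load_virion_ensemble(bad), "refusing to load")
})

test_that("training demands a profile for every record", {
  fx <- tiny_model_fixture()
  ds <- fx$ds
  ds$profiles[["pos_001"]] <- NULL
  expect_error(train_virion_ensemble(ds, seed = 1L), "missing: pos_001")
})

test_that("averaging the feature ensembles never falls below the weakest one", {
  # moderate signal so individual feature ensembles vary in quality
  n_seeds <- 20L
  wins <- 0L
  for (s in seq_len(n_seeds)) {
    ds <- generate_dataset(synth_spec(n_pos = 10L, n_neg = 24L,
                                      length_range = c(20L, 35L),
                                      delta = 1.5, seed = 5000L + s))
    model <- train_virion_ensemble(ds, seed = 6000L + s, exponents = c(-10L, 0L), folds = 3L)
    test <- generate_dataset(synth_spec(n_pos = 12L, n_neg = 12L,
                                        length_range = c(20L, 35L),
                                        delta = 1.5, seed = 7000L + s,
                                        id_prefix = "t_"))
    pred <- predict(model, test)
    truth <- vapply(test$records, `[[`, character(1), "label")
    mcc_of <- function(score) {
      calls <- ifelse(score >= 0.5, "virion", "nonvirion")
      compute_metrics(confusion_counts(truth, calls))$MCC
    }
    final_mcc <- mcc_of(pred$score_final)
    member_mcc <- vapply(paste0("score_", EVOLUTIONARY_ENCODERS),
                         function(cn) mcc_of(pred[[cn]]), numeric(1))
    if (final_mcc >= min(member_mcc) - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
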