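test_that("fold plans partition indices with a 10% validation hold-out", {
  plan <- make_fold_plan(100, folds = 10, seed = 3)
  expect_equal(nrow(plan), 10)
  all_test <- sort(unlist(plan$test))
  expect_equal(all_test, 1:100)           # test folds partition the data
  for (f in 1:10) {
    expect_length(plan$test[[f]], 10)
    expect_length(plan$validation[[f]], 9)   # 10% of the 90 remaining
    expect_length(plan$train[[f]], 81)
    expect_equal(sort(c(plan$train[[f]], plan$validation[[f]],
                        plan$test[[f]])), 1:100)
  }
  expect_identical(plan, make_fold_plan(100, folds = 10, seed = 3))
  expect_false(identical(plan, make_fold_plan(100, folds = 10, seed = 4)))
  expect_error(make_fold_plan(5, folds = 10), "cannot split")
})

test_that("training validates inputs and records one history row per epoch", {
  ds <- simulate_dataset(simulation_config(n = 12, seed = 6))
  ls <- attr(ds, "label_space")
  bad <- ds
  bad$labels[[1]] <- character(0)
  expect_error(train_model(bad, k = 3, label_space = ls), "label")
  fit <- train_model(ds, arch = "cnn", k = 3, epochs = 1,
                     learning_rate = 0.01, label_space = ls,
                     validation_fraction = 0, seed = 1)
  expect_equal(nrow(fit$history), 1)
  fit3 <- train_model(ds, arch = "cnn", k = 3, epochs = 3,
                      learning_rate = 0.01, label_space = ls,
                      validation_fraction = 0.2, seed = 1)
  expect_equal(fit3$history$epoch, 1:3)
  expect_true(all(is.finite(fit3$history$val_loss)))
  expect_s3_class(tidy(fit3), "tbl_df")
  expect_equal(glance(fit3)$epochs, 3)
})

test_that("training is deterministic given a seed", {
  ds <- simulate_dataset(simulation_config(n = 15, seed = 8))
  ls <- attr(ds, "label_space")
  f1 <- train_model(ds, arch = "cnn", k = 3, epochs = 3, seed = 11,
                    learning_rate = 0.01, label_space = ls)
  f2 <- train_model(ds, arch = "cnn", k = 3, epochs = 3, seed = 11,
                    learning_rate = 0.01, label_space = ls)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("vocabulary and length statistics never leak from test records", {
  ds <- simulate_dataset(simulation_config(n = 20, seed = 9))
  ls <- attr(ds, "label_space")
  # poison a held-out record with a k-mer absent from every training record:
  # training sequences never contain the literal run "GGGGGG"
  train <- ds[1:15, ]
  train$sequence <- vapply(train$sequence, function(s) {
    while (grepl("GGG", s, fixed = TRUE)) s <- sub("GGG", "GCG", s,
                                                   fixed = TRUE)
    s
  }, character(1), USE.NAMES = FALSE)
  fit <- train_model(train, arch = "cnn", k = 3, epochs = 1,
                     learning_rate = 0.01, label_space = ls,
                     validation_fraction = 0, seed = 1)
  expect_false("GGG" %in% names(fit$vocab$ids))
  poisoned <- tibble::tibble(id = "p", sequence = "ACGUAGGGGGGACGUAACGUA")
  enc <- encode_sequences(poisoned, fit$vocab, fit$max_len)
  toks <- generate_kmers(poisoned$sequence, 3)
  expect_equal(unname(enc$ids[1, which(toks == "GGG")]),
               rep(fit$vocab$unk_id, sum(toks == "GGG")))
  # max_len comes from the training corpus, not the prediction input
  long <- tibble::tibble(id = "L", sequence = strrep("ACGU", 20))
  expect_equal(ncol(encode_sequences(long, fit$vocab, fit$max_len)$ids),
               fit$max_len)
})

test_that("cross-validation honors the protocol and serializes bit-stably", {
  ds <- simulate_dataset(simulation_config(n = 30, seed = 13))
  ls <- attr(ds, "label_space")
  run <- function() {
    cross_validate(ds, folds = 2, arch = "cnn", scheme = "kmerPR2vec",
                   k = 3, epochs = 2, learning_rate = 0.01, batch_size = 10,
                   label_space = ls, seed = 17)
  }
  cv1 <- run()
  expect_equal(nrow(cv1$fold_metrics), 2)
  expect_equal(sort(unlist(cv1$plan$test)), 1:30)
  # aggregate is the arithmetic mean of the fold reports
  expect_equal(cv1$mean_metrics$f1, mean(cv1$fold_metrics$f1))
  expect_equal(cv1$mean_metrics$hamming_loss,
               mean(cv1$fold_metrics$hamming_loss))
  # fixed seed -> byte-identical serialized run result
  cv2 <- run()
  expect_identical(as.character(export_run_result(cv1)),
                   as.character(export_run_result(cv2)))
  f <- withr::local_tempfile(fileext = ".json")
  export_run_result(cv1, f)
  expect_true(jsonlite::validate(readLines(f)))
  expect_s3_class(tidy(cv1), "tbl_df")
  expect_equal(nrow(glance(cv1)), 1)
})

test_that("independent-test evaluation reports per-cardinality exact hits", {
  ds <- simulate_dataset(simulation_config(n = 40, seed = 14))
  ls <- attr(ds, "label_space")
  fit <- train_model(ds[1:30, ], arch = "cnn", k = 3, epochs = 1,
                     learning_rate = 0.01, label_space = ls,
                     validation_fraction = 0, seed = 1)
  ev <- evaluate_on_test(fit, ds[31:40, ])
  expect_s3_class(ev$metrics, "mirloc_metrics")
  expect_equal(sum(ev$by_cardinality$n), 10)
  expect_true(all(ev$by_cardinality$n_exact <= ev$by_cardinality$n))
  expect_error(evaluate_on_test(fit, ds[0, ]), "empty test set")
  unlabeled <- ds[31:32, ]
  unlabeled$labels <- list(character(0), character(0))
  expect_error(evaluate_on_test(fit, unlabeled), "labeled")
})

test_that("a trained model memorizes a tiny separable set", {
  ds <- simulate_dataset(simulation_config(n = 20, seed = 5))
  fit <- train_model(ds, arch = "cnn", scheme = "kmerPR2vec", k = 3,
                     label_space = attr(ds, "label_space"), epochs = 80,
                     learning_rate = 0.01, validation_fraction = 0, seed = 2)
  pred <- predict(fit, ds, type = "labels")$predicted
  expect_gte(example_accuracy(ds$labels, pred), 0.95)
})
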