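ls6 <- mirna_label_space()

test_that("example-based metrics reproduce hand-computed set arithmetic", {
  B <- list(c("exosome", "nucleus")); P <- list(c("exosome", "cytoplasm"))
  expect_equal(example_accuracy(B, P), 1 / 3)
  expect_equal(example_f1(B, P), 0.5)
  expect_equal(hamming_loss(B, P, ls6), 2 / 6)

  B <- list(c("exosome", "nucleus")); P <- list("exosome")
  expect_equal(example_precision(B, P), 1)
  expect_equal(example_recall(B, P), 0.5)

  # identity, disjoint and superset boundary cases
  B <- list(c("exosome", "nucleus", "cytoplasm"))
  expect_equal(example_accuracy(B, B), 1)
  expect_equal(example_f1(B, B), 1)
  expect_equal(hamming_loss(B, B, ls6), 0)
  expect_equal(example_recall(B, list(ls6)), 1)
  D <- list(c("circulating", "microvesicle"))
  expect_equal(example_accuracy(B, D), 0)
  expect_equal(example_f1(B, D), 0)
  expect_equal(hamming_loss(list(ls6[1:3]), list(ls6[4:6]), ls6), 1)
})

test_that("empty-set conventions are honored", {
  expect_equal(example_precision(list("exosome"), list(character(0))), 0)
  expect_equal(example_precision(list(character(0)), list(character(0))), 1)
  expect_equal(example_recall(list(character(0)), list("exosome")), 1)
  expect_equal(example_accuracy(list(character(0)), list(character(0))), 1)
  expect_equal(example_f1(list(character(0)), list(character(0))), 1)
  expect_error(example_accuracy(list(), list()), "empty corpus")
})

test_that("micro and macro F1 follow pooled and per-label contingencies", {
  B <- list("exosome"); P <- list(c("exosome", "cytoplasm"))
  expect_equal(micro_f1(B, P), 2 * (0.5 * 1) / 1.5)
  expect_equal(micro_f1(B, B), 1)
  # a label never true and never predicted contributes 0 to the macro mean
  B <- list("exosome", "cytoplasm"); P <- list("exosome", "cytoplasm")
  expect_equal(macro_f1(B, P, ls6), 2 / 6)
  # identical per-label contingencies make micro and macro agree exactly
  B <- rep(list("exosome", "cytoplasm"), 10)
  P <- rep(list(c("exosome", "cytoplasm")), 20)
  expect_equal(micro_f1(B, P), macro_f1(B, P, ls6[1:2]))
})

test_that("average precision matches rank-prefix evaluation", {
  s <- rbind(c(0.9, 0.5, 0.4, 0.3, 0.2, 0.1))
  colnames(s) <- ls6
  expect_equal(average_precision(list("exosome"), s), 1)
  # relevant labels at ranks 1 and 3 -> (1/1 + 2/3) / 2
  expect_equal(as.numeric(
    average_precision(list(c("exosome", "mitochondrion")), s)),
    (1 + 2 / 3) / 2)
  # all labels relevant -> 1 regardless of scores
  expect_equal(as.numeric(average_precision(list(ls6), s)), 1)
  # empty-truth instances are skipped and counted
  ap <- average_precision(list("exosome", character(0)), rbind(s, s))
  expect_equal(as.numeric(ap), 1)
  expect_equal(attr(ap, "n_skipped"), 1)
  expect_error(average_precision(list(character(0)), s), "empty label set")
})

test_that("AUROC handles separation, ties and one-class labels", {
  y <- matrix(c(1, 1, 0, 0), ncol = 1, dimnames = list(NULL, "exosome"))
  perfect <- matrix(c(.9, .8, .2, .1), ncol = 1,
                    dimnames = list(NULL, "exosome"))
  expect_equal(auroc(y, perfect, "exosome")$macro, 1)
  ties <- matrix(rep(.5, 4), ncol = 1, dimnames = list(NULL, "exosome"))
  expect_equal(auroc(y, ties, "exosome")$macro, 0.5)
  inverted <- matrix(c(.1, .2, .8, .9), ncol = 1,
                     dimnames = list(NULL, "exosome"))
  expect_equal(auroc(y, inverted, "exosome")$macro, 0)
  # a label with no positives is excluded from the macro mean, with a note
  y2 <- cbind(y, cytoplasm = c(0, 0, 0, 0))
  s2 <- cbind(perfect, cytoplasm = runif(4))
  expect_message(r <- auroc(y2, s2, c("exosome", "cytoplasm")), "excluded")
  expect_equal(r$macro, 1)
  expect_true(is.na(r$per_label$auroc[2]))
})

test_that("all nine metrics agree with independent naive oracles", {
  set.seed(101)
  tr <- random_triples(300)
  ex <- oracle_example_metrics(tr$B, tr$P)
  expect_equal(example_accuracy(tr$B, tr$P), ex$accuracy, tolerance = 1e-12)
  expect_equal(example_precision(tr$B, tr$P), ex$precision, tolerance = 1e-12)
  expect_equal(example_recall(tr$B, tr$P), ex$recall, tolerance = 1e-12)
  expect_equal(example_f1(tr$B, tr$P), ex$f1, tolerance = 1e-12)
  expect_equal(micro_f1(tr$B, tr$P), oracle_micro_f1(tr$B, tr$P),
               tolerance = 1e-12)
  expect_equal(macro_f1(tr$B, tr$P, ls6), oracle_macro_f1(tr$B, tr$P, ls6),
               tolerance = 1e-12)
  expect_equal(hamming_loss(tr$B, tr$P, ls6), oracle_hamming(tr$B, tr$P, 6),
               tolerance = 1e-12)
  expect_equal(as.numeric(average_precision(tr$B, tr$S)),
               oracle_average_precision(tr$B, tr$S, ls6), tolerance = 1e-12)
  expect_equal(auroc(tr$B, tr$S)$macro,
               oracle_macro_auroc(tr$B, tr$S, ls6), tolerance = 1e-12)
})

test_that("threshold-sweep AUROC matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(77)
  y <- rbinom(80, 1, 0.4)
  s <- runif(80) + 0.3 * y
  s[1:10] <- 0.5  # force ties
  ours <- mirloc:::auc_one_label(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the combined report matches its component metrics", {
  set.seed(5)
  tr <- random_triples(60)
  rep_all <- evaluate_all(tr$B, tr$P, tr$S)
  expect_s3_class(rep_all, "mirloc_metrics")
  expect_equal(rep_all$accuracy, example_accuracy(tr$B, tr$P))
  expect_equal(rep_all$f1_macro, macro_f1(tr$B, tr$P, ls6))
  expect_equal(rep_all$auroc, auroc(tr$B, tr$S)$macro)
  vals <- unlist(rep_all[mirloc:::metric_names()])
  expect_true(all(vals >= 0 & vals <= 1))
  # perfect prediction: ones across the board, hamming 0
  perfect <- evaluate_all(tr$B[1:10], tr$B[1:10],
                          labels_to_matrix(tr$B[1:10], ls6))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_micro, 1)
  expect_equal(perfect$hamming_loss, 0)
  expect_equal(perfect$average_precision, 1)
})

test_that("hamming loss complements exact bitwise agreement", {
  set.seed(9)
  tr <- random_triples(120)
  Bm <- labels_to_matrix(tr$B, ls6); Pm <- labels_to_matrix(tr$P, ls6)
  expect_equal(hamming_loss(tr$B, tr$P, ls6), 1 - mean(Bm == Pm),
               tolerance = 1e-12)
  # Jaccard accuracy is dominated by precision and recall per instance
  expect_lte(example_accuracy(tr$B, tr$P), example_precision(tr$B, tr$P))
  expect_lte(example_accuracy(tr$B, tr$P), example_recall(tr$B, tr$P))
})
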