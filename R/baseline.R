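#' Position-free bag-of-k-mers logistic baseline
#'
#' A deliberately position-blind reference classifier: each sequence is
#' reduced to its k-mer count vector and a ridge-penalized logistic
#' regression is fitted per binary task. On data where only motif POSITION
#' separates the classes (see [positional_pair_benchmark()]) this baseline
#' can do no better than chance, which is the control the positional
#' representation is measured against.
#'
#' @param records Labeled records; every label set must contain exactly one
#'   of two class labels.
#' @param k k-mer size for the count features.
#' @param folds Number of cross-validation folds used to estimate balanced
#'   accuracy.
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @param seed RNG seed for the fold assignment.
#' @return A list with `balanced_accuracy` (CV estimate), `per_fold` tibble,
#'   and the two class labels.
#' @export
bag_of_kmers_baseline <- function(records, k = 5L, folds = 5L,
                                  lambda = 0.01, seed = 1L) {
  classes <- sort(unique(unlist(records$labels)))
  if (length(classes) != 2 || any(lengths(records$labels) != 1)) {
    abort("baseline expects single-label records over exactly two classes")
  }
  y <- vapply(records$labels, `[[`, character(1), 1) == classes[2]
  X <- kmer_count_matrix(records$sequence, k)
  withr::with_seed(seed, {
    fold_of <- sample(rep(seq_len(folds), length.out = nrow(records)))
  })
  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- fold_of != f
    fitted <- glmnet::glmnet(X[tr, , drop = FALSE], factor(y[tr]),
                             family = "binomial", alpha = 0, lambda = lambda,
                             standardize = TRUE)
    p <- as.vector(predict(fitted, X[!tr, , drop = FALSE], type = "response"))
    pred <- p >= 0.5
    truth <- y[!tr]
    sens <- if (any(truth)) mean(pred[truth]) else NA_real_
    spec <- if (any(!truth)) mean(!pred[!truth]) else NA_real_
    tibble(fold = f, balanced_accuracy = mean(c(sens, spec), na.rm = TRUE))
  })
  list(balanced_accuracy = mean(per_fold$balanced_accuracy),
       per_fold = per_fold, classes = classes)
}

# Sequences -> matrix of k-mer counts over the union of observed k-mers.
kmer_count_matrix <- function(sequences, k) {
  toks <- lapply(sequences, generate_kmers, k = k, stride = 1L)
  universe <- sort(unique(unlist(toks)))
  X <- matrix(0, nrow = length(sequences), ncol = length(universe),
              dimnames = list(NULL, universe))
  for (i in seq_along(toks)) {
    tb <- table(toks[[i]])
    X[i, names(tb)] <- as.numeric(tb)
  }
  X
}
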