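#' Build a cross-validation fold plan
#'
#' Shuffles the indices `1..n_records` into `folds` test folds of near-equal
#' size; within each fold, 10% (by default) of the remaining training
#' indices — at least one — are held out for validation. Test folds
#' partition the dataset and, within a fold, train, validation and test are
#' pairwise disjoint.
#'
#' @param n_records Number of records.
#' @param folds Number of folds (default 10).
#' @param validation_fraction Fraction of the training indices held out for
#'   validation, rounded down but at least 1 (0 disables validation).
#' @param seed RNG seed.
#' @return A tibble of class `mirloc_fold_plan` with list-columns `train`,
#'   `validation`, `test`.
#' @export
make_fold_plan <- function(n_records, folds = 10L, validation_fraction = 0.1,
                           seed = 1L) {
  if (n_records < folds) {
    abort(paste0("cannot split ", n_records, " records into ", folds,
                 " folds"))
  }
  if (validation_fraction < 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must lie in [0, 1)")
  }
  withr::with_seed(seed, {
    shuffled <- sample(n_records)
    fold_of <- rep(seq_len(folds), length.out = n_records)
    plan <- purrr::map_dfr(seq_len(folds), function(f) {
      test <- sort(shuffled[fold_of == f])
      rest <- shuffled[fold_of != f]          # keep shuffled order
      n_val <- if (validation_fraction > 0) {
        max(1L, floor(validation_fraction * length(rest)))
      } else 0L
      validation <- sort(head(rest, n_val))
      train <- sort(tail(rest, length(rest) - n_val))
      tibble(fold = f, train = list(train), validation = list(validation),
             test = list(test))
    })
  })
  structure(plan, class = c("mirloc_fold_plan", class(plan)))
}

#' Cross-validate a classifier under the 10-fold protocol
#'
#' For each fold the vocabulary, maximum length and embeddings are fitted on
#' the training indices only (validation and test k-mers unseen in training
#' map to the unknown token), the model is trained, the held-out fold is
#' scored, and the full nine-metric report is computed. Fold metrics are
#' aggregated two ways: `mean_metrics` (arithmetic mean of fold reports, the
#' primary summary) and `pooled_metrics` (one report over the pooled
#' predictions of all folds).
#'
#' @param records Labeled records (`id`, `sequence`, `labels`).
#' @param folds Number of folds.
#' @param threshold Score threshold for set predictions.
#' @param seed Seed governing the fold plan and (offset per fold) each
#'   training run.
#' @param ... Passed to [train_model()] (architecture, scheme, k, epochs,
#'   learning rate, ...). `validation_fraction` here controls the per-fold
#'   validation split of the plan.
#' @param validation_fraction See [make_fold_plan()].
#' @return An object of class `mirloc_cv`: list with `fold_metrics` (tibble,
#'   one row per fold), `mean_metrics`, `pooled_metrics`, `plan`, `history`
#'   (per-fold loss curves) and `config`.
#' @export
cross_validate <- function(records, folds = 10L, threshold = 0.5,
                           validation_fraction = 0.1, seed = 1L, ...) {
  records <- as_tibble(records)
  if (any(lengths(records$labels) == 0)) {
    abort("all records must be labeled for cross-validation")
  }
  dots <- list(...)
  label_space <- dots$label_space %||% mirna_label_space()
  plan <- make_fold_plan(nrow(records), folds = folds,
                         validation_fraction = validation_fraction,
                         seed = seed)
  fold_rows <- list(); histories <- list()
  pooled <- list(truth = list(), pred = list(), scores = list())
  for (f in seq_len(folds)) {
    tr <- records[plan$train[[f]], ]
    va <- if (length(plan$validation[[f]])) records[plan$validation[[f]], ] else NULL
    te <- records[plan$test[[f]], ]
    args <- c(list(records = tr, val_records = va,
                   seed = seed + f), dots)
    args$validation_fraction <- 0
    fit <- do.call(train_model, args)
    scores <- predict(fit, te, type = "matrix")
    pred <- predict_labels(scores, threshold, label_space)
    rep_f <- evaluate_all(te$labels, pred, scores, label_space)
    fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = f), rep_f)
    histories[[f]] <- dplyr::bind_cols(tibble(fold = f), fit$history)
    pooled$truth <- c(pooled$truth, te$labels)
    pooled$pred <- c(pooled$pred, pred)
    pooled$scores <- c(pooled$scores, list(scores))
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  mean_metrics <- dplyr::summarise(fold_metrics[setdiff(names(fold_metrics), "fold")],
                                   dplyr::across(dplyr::everything(),
                                                 ~ mean(.x, na.rm = TRUE)))
  pooled_metrics <- evaluate_all(pooled$truth, pooled$pred,
                                 do.call(rbind, pooled$scores), label_space)
  structure(
    list(fold_metrics = fold_metrics,
         mean_metrics = as_tibble(mean_metrics),
         pooled_metrics = pooled_metrics,
         plan = plan,
         history = dplyr::bind_rows(histories),
         config = c(list(folds = as.integer(folds), threshold = threshold,
                         validation_fraction = validation_fraction,
                         seed = as.integer(seed)),
                    dots[!vapply(dots, is.object, logical(1))])),
    class = "mirloc_cv"
  )
}

#' @export
#' @method print mirloc_cv
print.mirloc_cv <- function(x, ...) {
  cat("<mirloc_cv> ", nrow(x$fold_metrics), " folds\n", sep = "")
  print(x$mean_metrics)
  invisible(x)
}

#' @export
tidy.mirloc_cv <- function(x, ...) {
  tidyr::pivot_longer(x$fold_metrics, -"fold",
                      names_to = "metric", values_to = "value")
}

#' @export
glance.mirloc_cv <- function(x, ...) x$mean_metrics

#' Serialize a cross-validation result to JSON
#'
#' Writes (or returns) a canonical JSON rendering of the per-fold metrics,
#' both aggregates, the fold plan and the run configuration; two runs with
#' the same records, configuration and seed serialize byte-identically.
#'
#' @param cv A `mirloc_cv`.
#' @param path Optional output path.
#' @return The JSON string, invisibly when `path` is given.
#' @export
export_run_result <- function(cv, path = NULL) {
  stopifnot(inherits(cv, "mirloc_cv"))
  obj <- list(
    fold_metrics = as.data.frame(cv$fold_metrics),
    mean_metrics = as.data.frame(cv$mean_metrics),
    pooled_metrics = as.data.frame(strip_metrics(cv$pooled_metrics)),
    plan = lapply(seq_len(nrow(cv$plan)), function(f) {
      list(train = cv$plan$train[[f]], validation = cv$plan$validation[[f]],
           test = cv$plan$test[[f]])
    }),
    config = cv$config
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

strip_metrics <- function(m) {
  attr(m, "per_label_auroc") <- NULL
  class(m) <- setdiff(class(m), "mirloc_metrics")
  m
}

#' Evaluate a fitted model on an independent labeled test set
#'
#' Computes the full nine-metric report plus a per-cardinality breakdown:
#' for each true-label-set size, how many sequences had their predicted set
#' exactly equal to the true set.
#'
#' @param fit A `mirloc_fit`.
#' @param test_records Labeled records.
#' @param threshold Score threshold for set predictions.
#' @return A list of class `mirloc_eval` with `metrics` (one-row tibble) and
#'   `by_cardinality` (tibble: cardinality, n, n_exact).
#' @export
evaluate_on_test <- function(fit, test_records, threshold = 0.5) {
  stopifnot(inherits(fit, "mirloc_fit"))
  if (nrow(test_records) == 0) abort("empty test set")
  if (any(lengths(test_records$labels) == 0)) {
    abort("test records must be labeled")
  }
  scores <- predict(fit, test_records, type = "matrix")
  pred <- predict_labels(scores, threshold, fit$label_space)
  truth <- test_records$labels
  exact <- purrr::map2_lgl(truth, pred, setequal)
  by_card <- tibble(cardinality = lengths(truth), exact = exact) |>
    dplyr::group_by(.data$cardinality) |>
    dplyr::summarise(n = dplyr::n(), n_exact = sum(.data$exact),
                     .groups = "drop")
  structure(
    list(metrics = evaluate_all(truth, pred, scores, fit$label_space),
         by_cardinality = by_card),
    class = "mirloc_eval"
  )
}

#' @export
#' @method print mirloc_eval
print.mirloc_eval <- function(x, ...) {
  cat("<mirloc_eval>\n")
  print(x$metrics)
  print(x$by_cardinality)
  invisible(x)
}
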