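# The nine multi-label evaluation measures: example-based accuracy /
# precision / recall / F1 (per-instance set overlaps averaged over the
# corpus), pooled micro-F1, per-label macro-F1, label-ranking average
# precision, Hamming loss, and one-vs-rest AUROC.
#
# Empty-set conventions (undefined in the usual printed formulas) are fixed
# here and tested: a per-instance term is 1 when both the true and predicted
# sets are empty; precision is 0 when only the prediction is empty; recall is
# 1 when the true set is empty; average precision skips instances with no
# relevant label (their denominator is undefined) and reports how many were
# skipped.

metric_corpus_check <- function(truth, estimate) {
  if (length(truth) == 0) abort("empty corpus")
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length")
  }
}

#' Example-based (Jaccard) accuracy
#'
#' Mean over instances of `|B ∩ P| / |B ∪ P|`, where `B` is the true and `P`
#' the predicted label set; an instance with both sets empty counts 1.
#'
#' @param truth,estimate Lists of label sets (character vectors) or 0/1
#'   indicator matrices with label column names.
#' @return A single number in `[0, 1]`.
#' @export
example_accuracy <- function(truth, estimate) {
  B <- as_label_sets(truth); P <- as_label_sets(estimate)
  metric_corpus_check(B, P)
  mean(purrr::map2_dbl(B, P, function(b, p) {
    u <- length(union(b, p))
    if (u == 0) 1 else length(intersect(b, p)) / u
  }))
}

#' Example-based precision
#'
#' Mean over instances of `|B ∩ P| / |P|`; 0 when only `P` is empty, 1 when
#' both sets are empty.
#'
#' @inheritParams example_accuracy
#' @return A single number in `[0, 1]`.
#' @export
example_precision <- function(truth, estimate) {
  B <- as_label_sets(truth); P <- as_label_sets(estimate)
  metric_corpus_check(B, P)
  mean(purrr::map2_dbl(B, P, function(b, p) {
    if (length(p) == 0) return(if (length(b) == 0) 1 else 0)
    length(intersect(b, p)) / length(p)
  }))
}

#' Example-based recall
#'
#' Mean over instances of `|B ∩ P| / |B|`; 1 when the true set is empty.
#'
#' @inheritParams example_accuracy
#' @return A single number in `[0, 1]`.
#' @export
example_recall <- function(truth, estimate) {
  B <- as_label_sets(truth); P <- as_label_sets(estimate)
  metric_corpus_check(B, P)
  mean(purrr::map2_dbl(B, P, function(b, p) {
    if (length(b) == 0) return(1)
    length(intersect(b, p)) / length(b)
  }))
}

#' Example-based F1
#'
#' Mean over instances of `2 |B ∩ P| / (|B| + |P|)`; 1 when both sets are
#' empty.
#'
#' @inheritParams example_accuracy
#' @return A single number in `[0, 1]`.
#' @export
example_f1 <- function(truth, estimate) {
  B <- as_label_sets(truth); P <- as_label_sets(estimate)
  metric_corpus_check(B, P)
  mean(purrr::map2_dbl(B, P, function(b, p) {
    s <- length(b) + length(p)
    if (s == 0) 1 else 2 * length(intersect(b, p)) / s
  }))
}

#' Micro-averaged F1
#'
#' Pools true/false positives and false negatives over every label and
#' instance, then takes the harmonic mean of the pooled precision and recall
#' (0 when their sum is 0).
#'
#' @inheritParams example_accuracy
#' @return A single number in `[0, 1]`.
#' @export
micro_f1 <- function(truth, estimate) {
  B <- as_label_sets(truth); P <- as_label_sets(estimate)
  metric_corpus_check(B, P)
  tp <- sum(purrr::map2_int(B, P, ~ length(intersect(.x, .y))))
  fp <- sum(purrr::map2_int(B, P, ~ length(setdiff(.y, .x))))
  fn <- sum(purrr::map2_int(B, P, ~ length(setdiff(.x, .y))))
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

per_label_counts <- function(B, P, label_space) {
  Bm <- labels_to_matrix(B, label_space)
  Pm <- labels_to_matrix(P, label_space)
  tibble(
    label = label_space,
    tp = colSums(Bm == 1 & Pm == 1),
    fp = colSums(Bm == 0 & Pm == 1),
    fn = colSums(Bm == 1 & Pm == 0),
    tn = colSums(Bm == 0 & Pm == 0)
  )
}

#' Macro-averaged F1
#'
#' Per-label precision/recall from each label's one-vs-rest contingency
#' counts (0 when a denominator is 0), per-label F1 as their harmonic mean
#' (0 when `p + r = 0`), averaged over all `Q` labels — a label that never
#' occurs and is never predicted contributes 0.
#'
#' @inheritParams example_accuracy
#' @param label_space Ordered label names defining `Q`.
#' @return A single number in `[0, 1]`.
#' @export
macro_f1 <- function(truth, estimate, label_space = mirna_label_space()) {
  B <- as_label_sets(truth); P <- as_label_sets(estimate)
  metric_corpus_check(B, P)
  ct <- per_label_counts(B, P, check_label_space(label_space))
  p <- ifelse(ct$tp + ct$fp == 0, 0, ct$tp / (ct$tp + ct$fp))
  r <- ifelse(ct$tp + ct$fn == 0, 0, ct$tp / (ct$tp + ct$fn))
  f1 <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  mean(f1)
}

# Descending-score ranks with stable (first-occurrence) tie breaking, as used
# for label-ranking average precision.
score_ranks <- function(scores) {
  ord <- order(-scores)
  rk <- integer(length(scores)); rk[ord] <- seq_along(scores)
  rk
}

#' Label-ranking average precision
#'
#' For each instance and each relevant label, the fraction of labels ranked
#' at or above it (by descending score) that are themselves relevant,
#' averaged over the relevant labels and then over instances. Instances with
#' no relevant label are skipped (undefined denominator); their count is
#' attached as attribute `n_skipped`.
#'
#' @param truth List of true label sets or a 0/1 indicator matrix.
#' @param scores Numeric matrix of prediction scores, one column per label
#'   (column names give the label space).
#' @param label_space Ordered label names; defaults to `colnames(scores)`.
#' @return A single number in `[0, 1]`.
#' @export
average_precision <- function(truth, scores, label_space = colnames(scores)) {
  check_label_space(label_space)
  scores <- as.matrix(scores)
  B <- as_label_sets(truth, label_space)
  metric_corpus_check(B, rep(list(NULL), nrow(scores)))
  if (length(B) != nrow(scores)) abort("truth/scores length mismatch")
  if (any(!is.finite(scores))) abort("scores must be finite")
  ap <- vapply(seq_along(B), function(i) {
    rel <- match(B[[i]], label_space)
    if (length(rel) == 0) return(NA_real_)
    rk <- score_ranks(scores[i, ])
    mean(vapply(rel, function(b) {
      sum(rk[rel] <= rk[b]) / rk[b]
    }, numeric(1)))
  }, numeric(1))
  n_skipped <- sum(is.na(ap))
  if (n_skipped == length(ap)) abort("every instance has an empty label set")
  out <- mean(ap, na.rm = TRUE)
  if (n_skipped > 0) attr(out, "n_skipped") <- n_skipped
  out
}

#' Hamming loss
#'
#' Mean over instances of the symmetric-difference size between true and
#' predicted sets, divided by the number of labels `Q`. Zero means every
#' label slot of every instance is predicted correctly.
#'
#' @inheritParams macro_f1
#' @return A single number in `[0, 1]`.
#' @export
hamming_loss <- function(truth, estimate, label_space = mirna_label_space()) {
  B <- as_label_sets(truth); P <- as_label_sets(estimate)
  metric_corpus_check(B, P)
  Q <- length(check_label_space(label_space))
  mean(purrr::map2_dbl(B, P, function(b, p) {
    (length(setdiff(b, p)) + length(setdiff(p, b))) / Q
  }))
}

# Trapezoid AUC for one label from a threshold sweep over the unique scores;
# tied thresholds enter as single ROC points so ties contribute half.
auc_one_label <- function(y, s) {
  ths <- sort(unique(s), decreasing = TRUE)
  P <- sum(y == 1); N <- sum(y == 0)
  tpr <- c(0, vapply(ths, function(t) sum(s >= t & y == 1), numeric(1)) / P)
  fpr <- c(0, vapply(ths, function(t) sum(s >= t & y == 0), numeric(1)) / N)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' One-vs-rest AUROC per label, with macro average
#'
#' For each label, the area under the ROC curve (true-positive rate against
#' false-positive rate `FP / (FP + TN)`) obtained by sweeping a threshold
#' over the unique scores, with trapezoidal integration so score ties
#' contribute one half. Labels with no positive or no negative instance are
#' undefined: they are reported as `NA` and excluded from the macro mean.
#'
#' @inheritParams average_precision
#' @return A list with `macro` (mean over defined labels) and `per_label`
#'   (tibble: label, auroc, n_pos, n_neg).
#' @export
auroc <- function(truth, scores, label_space = colnames(scores)) {
  check_label_space(label_space)
  scores <- as.matrix(scores)
  Bm <- if (is.matrix(truth)) truth else labels_to_matrix(truth, label_space)
  if (nrow(Bm) != nrow(scores)) abort("truth/scores length mismatch")
  per <- purrr::map_dfr(seq_along(label_space), function(j) {
    y <- Bm[, j]
    n_pos <- sum(y == 1); n_neg <- sum(y == 0)
    a <- if (n_pos == 0 || n_neg == 0) NA_real_ else auc_one_label(y, scores[, j])
    tibble(label = label_space[j], auroc = a, n_pos = n_pos, n_neg = n_neg)
  })
  defined <- !is.na(per$auroc)
  if (!any(defined)) {
    abort("no label has both positive and negative instances")
  }
  if (any(!defined)) {
    inform(paste0(sum(!defined), " label(s) without both classes excluded ",
                  "from the macro AUROC"))
  }
  list(macro = mean(per$auroc[defined]), per_label = per)
}

#' Compute the full nine-metric report
#'
#' @param truth List of true label sets or 0/1 matrix.
#' @param predicted List of predicted label sets or 0/1 matrix.
#' @param scores Numeric score matrix (for average precision and AUROC); may
#'   be `NULL`, in which case those two fields are `NA`.
#' @param label_space Ordered label names.
#' @return A one-row tibble of class `mirloc_metrics` with columns accuracy,
#'   precision, recall, f1, f1_micro, f1_macro, average_precision,
#'   hamming_loss, auroc; the per-label AUROC table is attached as attribute
#'   `per_label_auroc`.
#' @export
evaluate_all <- function(truth, predicted, scores = NULL,
                         label_space = mirna_label_space()) {
  check_label_space(label_space)
  out <- tibble(
    accuracy = example_accuracy(truth, predicted),
    precision = example_precision(truth, predicted),
    recall = example_recall(truth, predicted),
    f1 = example_f1(truth, predicted),
    f1_micro = micro_f1(truth, predicted),
    f1_macro = macro_f1(truth, predicted, label_space),
    average_precision = NA_real_,
    hamming_loss = hamming_loss(truth, predicted, label_space),
    auroc = NA_real_
  )
  if (!is.null(scores)) {
    out$average_precision <-
      as.numeric(average_precision(truth, scores, label_space))
    roc <- withCallingHandlers(
      auroc(truth, scores, label_space),
      message = function(m) invokeRestart("muffleMessage"))
    out$auroc <- roc$macro
    attr(out, "per_label_auroc") <- roc$per_label
  }
  class(out) <- c("mirloc_metrics", class(out))
  out
}

metric_names <- function() {
  c("accuracy", "precision", "recall", "f1", "f1_micro", "f1_macro",
    "average_precision", "hamming_loss", "auroc")
}
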