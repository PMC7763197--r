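# Shared fixtures and independent oracles for the test suite. The oracles
# are deliberately naive (explicit loops, set arithmetic, pairwise rank
# statistics) and never call the package's metric implementations.

tiny_records <- function() {
  tibble::tibble(
    id = c("m1", "m2", "m3"),
    sequence = c("ACGUACGUCGU", "UUUGGGCCCAAA", "ACGUACGUACGUACGUACGU"),
    labels = list(c("exosome", "nucleus"), "cytoplasm",
                  c("exosome", "circulating", "mitochondrion"))
  )
}

random_rna <- function(n, len_range = c(11, 40)) {
  vapply(seq_len(n), function(i) {
    L <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(len_range[1]:len_range[2], 1)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Random multi-label corpus: list of true sets, predicted sets, score matrix.
random_triples <- function(n, label_space = mirna_label_space(), p = 0.4) {
  Q <- length(label_space)
  B <- lapply(seq_len(n), function(i) label_space[runif(Q) < p])
  P <- lapply(seq_len(n), function(i) label_space[runif(Q) < p])
  S <- matrix(runif(n * Q), n, Q, dimnames = list(NULL, label_space))
  list(B = B, P = P, S = S)
}

write_embedding_fixture <- function(path, tokens, d, header = FALSE,
                                    seed = 1) {
  set.seed(seed)
  lines <- vapply(tokens, function(tk) {
    paste(c(tk, format(round(runif(d, -1, 1), 6), trim = TRUE)),
          collapse = " ")
  }, character(1))
  if (header) lines <- c(paste(length(tokens), d), lines)
  writeLines(lines, path)
  path
}

# --- naive metric oracles ---------------------------------------------------

oracle_example_metrics <- function(B, P) {
  n <- length(B)
  acc <- pre <- rec <- f1 <- numeric(n)
  for (i in seq_len(n)) {
    b <- B[[i]]; p <- P[[i]]
    inter <- length(intersect(b, p))
    acc[i] <- if (length(union(b, p)) == 0) 1 else inter / length(union(b, p))
    pre[i] <- if (length(p) == 0) (if (length(b) == 0) 1 else 0) else inter / length(p)
    rec[i] <- if (length(b) == 0) 1 else inter / length(b)
    f1[i] <- if (length(b) + length(p) == 0) 1 else
      2 * inter / (length(b) + length(p))
  }
  list(accuracy = mean(acc), precision = mean(pre), recall = mean(rec),
       f1 = mean(f1))
}

oracle_micro_f1 <- function(B, P) {
  tp <- fp <- fn <- 0
  for (i in seq_along(B)) {
    tp <- tp + length(intersect(B[[i]], P[[i]]))
    fp <- fp + length(setdiff(P[[i]], B[[i]]))
    fn <- fn + length(setdiff(B[[i]], P[[i]]))
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

oracle_macro_f1 <- function(B, P, label_space) {
  f1s <- vapply(label_space, function(l) {
    tp <- sum(vapply(seq_along(B), function(i)
      l %in% B[[i]] && l %in% P[[i]], logical(1)))
    fp <- sum(vapply(seq_along(B), function(i)
      !(l %in% B[[i]]) && l %in% P[[i]], logical(1)))
    fn <- sum(vapply(seq_along(B), function(i)
      l %in% B[[i]] && !(l %in% P[[i]]), logical(1)))
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f1s)
}

oracle_hamming <- function(B, P, Q) {
  mean(vapply(seq_along(B), function(i) {
    length(setdiff(B[[i]], P[[i]])) + length(setdiff(P[[i]], B[[i]]))
  }, numeric(1))) / Q
}

oracle_average_precision <- function(B, S, label_space) {
  vals <- c()
  for (i in seq_along(B)) {
    rel <- B[[i]]
    if (length(rel) == 0) next
    s <- S[i, ]
    ord <- order(-s)                 # stable: ties by column order
    rank_of <- function(l) which(label_space[ord] == l)
    terms <- vapply(rel, function(b) {
      rb <- rank_of(b)
      sum(vapply(rel, function(b2) rank_of(b2) <= rb, logical(1))) / rb
    }, numeric(1))
    vals <- c(vals, mean(terms))
  }
  mean(vals)
}

# Mann-Whitney rank-statistic AUC: P(score_pos > score_neg) + 0.5 ties.
oracle_auc <- function(y, s) {
  sp <- s[y == 1]; sn <- s[y == 0]
  if (!length(sp) || !length(sn)) return(NA_real_)
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}

oracle_macro_auroc <- function(B, S, label_space) {
  Bm <- labels_to_matrix(B, label_space)
  aucs <- vapply(seq_along(label_space), function(j) {
    oracle_auc(Bm[, j], S[, j])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}
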