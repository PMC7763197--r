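#' Train a localization classifier on labeled sequence records
#'
#' Fits the tokenizer vocabulary and maximum token length on the training
#' records only, builds the requested representation scheme, and minimizes
#' the mean per-label binary cross-entropy of the sigmoid outputs with ADAM.
#' One train-loss (and, when a validation set exists, one validation-loss)
#' entry is recorded per epoch and the returned parameters are those of the
#' epoch with the lowest validation loss (the final epoch when there is no
#' validation set). The run is fully reproducible from `seed`.
#'
#' The default learning rate 0.08 follows the published training protocol for
#' the real benchmark; for small synthetic datasets 0.001–0.01 is the
#' recommended range (ADAM at 0.08 is aggressive and can oscillate).
#'
#' @param records A data frame with `id`, `sequence` and `labels` columns;
#'   every record must be labeled.
#' @param arch `"cnn"` (convolutional head) or `"rnn"` (two-layer
#'   bidirectional LSTM head).
#' @param scheme Representation scheme name; see [representation_spec()].
#' @param k,stride Tokenizer window and step; see [generate_kmers()].
#' @param max_len Fixed token-sequence length, or `"auto"` (the training
#'   maximum).
#' @param trim Trimming side for over-long sequences.
#' @param label_space Ordered label names.
#' @param pretrained A `kmer_embedding_file` (required by `pre-*` schemes).
#' @param emb_dim Embedding dimension for random-based schemes (default 120)
#'   and for the pure positional scheme.
#' @param trainable_embeddings Override the scheme's default trainability.
#' @param n_filters,hidden CNN head sizes (convolution filters, first dense
#'   layer width).
#' @param rnn_hidden LSTM hidden size per direction.
#' @param out_activation `"sigmoid"` (independent per-label scores, default)
#'   or `"softmax"` (compatibility inference mode; training always uses the
#'   per-label binary cross-entropy on sigmoid outputs).
#' @param epochs,learning_rate,batch_size ADAM loop controls (defaults 10,
#'   0.08, 50).
#' @param validation_fraction Fraction of `records` held out for epoch
#'   selection when `val_records` is `NULL`; 0 disables validation.
#' @param val_records Optional explicit validation records.
#' @param seed RNG seed governing initialization, the validation split and
#'   batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return A fitted model of class `mirloc_fit`, containing the learned
#'   parameters, vocabulary, positional matrix, label space and the
#'   per-epoch loss history.
#' @export
train_model <- function(records,
                        arch = c("cnn", "rnn"),
                        scheme = "kmerPR2vec",
                        k = 3L, stride = 1L, max_len = "auto",
                        trim = "prefix",
                        label_space = mirna_label_space(),
                        pretrained = NULL,
                        emb_dim = NULL,
                        trainable_embeddings = NULL,
                        n_filters = 64L, hidden = 128L, rnn_hidden = 64L,
                        out_activation = c("sigmoid", "softmax"),
                        epochs = 10L, learning_rate = 0.08,
                        batch_size = 50L,
                        validation_fraction = 0.1,
                        val_records = NULL,
                        seed = 1L, verbose = FALSE) {
  arch <- match.arg(arch)
  out_activation <- match.arg(out_activation)
  check_label_space(label_space)
  check_training_args(epochs, learning_rate, batch_size, validation_fraction)
  if (!all(c("id", "sequence", "labels") %in% names(records))) {
    abort("`records` needs columns id, sequence, labels")
  }
  if (any(lengths(records$labels) == 0)) {
    abort("all training records must carry at least one label")
  }
  records <- as_tibble(records)

  withr::with_seed(seed, {
    # validation split (from the training data unless given explicitly)
    if (is.null(val_records) && validation_fraction > 0) {
      n_val <- max(1L, floor(validation_fraction * nrow(records)))
      if (n_val >= nrow(records)) abort("validation split leaves no training data")
      val_idx <- sample(nrow(records), n_val)
      val_records <- records[val_idx, ]
      records <- records[-val_idx, ]
    }

    spec <- representation_spec(scheme, emb_dim = emb_dim,
                                trainable = trainable_embeddings)
    vocab <- build_vocabulary(records, k = k, stride = stride)
    if (identical(max_len, "auto")) {
      max_len <- infer_max_len(records, k = k, stride = stride)
    }
    fit <- build_fit(arch, spec, vocab, max_len, trim, label_space,
                     pretrained, n_filters, hidden, rnn_hidden,
                     out_activation, seed)

    toks <- encode_sequences(records, vocab, max_len, trim = trim)
    Y <- labels_to_matrix(records$labels, label_space)
    val <- NULL
    if (!is.null(val_records)) {
      vt <- encode_sequences(val_records, vocab, max_len, trim = trim)
      val <- list(toks = vt,
                  Y = labels_to_matrix(val_records$labels, label_space))
    }
    fit <- run_adam_loop(fit, toks, Y, val, epochs, learning_rate,
                         batch_size, verbose)
  })
  fit$config <- list(scheme = spec_of(fit)$scheme, k = as.integer(k),
                     stride = as.integer(stride), epochs = as.integer(epochs),
                     learning_rate = learning_rate,
                     batch_size = as.integer(batch_size),
                     validation_fraction = validation_fraction,
                     seed = as.integer(seed))
  fit
}

spec_of <- function(fit) fit$spec

check_training_args <- function(epochs, lr, batch_size, val_frac) {
  if (epochs < 1) abort("`epochs` must be >= 1")
  if (lr <= 0) abort("`learning_rate` must be positive")
  if (batch_size < 1) abort("`batch_size` must be >= 1")
  if (val_frac < 0 || val_frac >= 1) {
    abort("`validation_fraction` must lie in [0, 1)")
  }
  invisible(TRUE)
}

build_fit <- function(arch, spec, vocab, max_len, trim, label_space,
                      pretrained, n_filters, hidden, rnn_hidden,
                      out_activation, seed) {
  Q <- length(label_space)
  if (spec$use_pretrained) {
    if (is.null(pretrained)) {
      abort(paste0("scheme '", spec$scheme,
                   "' requires pretrained embeddings (`pretrained`)"))
    }
    emb <- assemble_pretrained_table(pretrained, vocab, seed = seed)
    spec$emb_dim <- ncol(emb)
  } else if (spec$use_embedding) {
    emb <- init_random_embeddings(vocab_size(vocab), d = spec$emb_dim,
                                  seed = seed)
  } else {
    emb <- NULL
  }
  d <- spec$emb_dim
  pe <- if (spec$use_positional) positional_matrix(max_len + 1L, d) else NULL
  params <- if (arch == "cnn") {
    cnn_init_params(d, n_filters, hidden, Q)
  } else {
    rnn_init_params(d, rnn_hidden, Q)
  }
  if (!is.null(emb)) params$emb <- emb
  structure(
    list(arch = arch, spec = spec, params = params, pe = pe, vocab = vocab,
         max_len = as.integer(max_len), trim = trim,
         label_space = label_space, d = d,
         hyper = list(n_filters = as.integer(n_filters),
                      hidden = as.integer(hidden),
                      rnn_hidden = as.integer(rnn_hidden),
                      conv_width = 3L),
         out_activation = out_activation,
         history = NULL, version = "mirloc-0.1.0"),
    class = "mirloc_fit"
  )
}

forward_pass <- function(fit, ids, n_tokens, keep_cache = FALSE) {
  if (fit$arch == "cnn") {
    cnn_forward_pass(fit, ids, n_tokens, keep_cache)
  } else {
    rnn_forward_pass(fit, ids, n_tokens, keep_cache)
  }
}

backward_pass <- function(fit, cache, dlogits) {
  if (fit$arch == "cnn") {
    cnn_backward_pass(fit, cache, dlogits)
  } else {
    rnn_backward_pass(fit, cache, dlogits)
  }
}

frozen_params <- function(fit) {
  if (!is.null(fit$params$emb) && !fit$spec$trainable) "emb" else character(0)
}

run_adam_loop <- function(fit, toks, Y, val, epochs, lr, batch_size,
                          verbose) {
  n <- nrow(toks$ids)
  state <- adam_init(fit$params)
  skip <- frozen_params(fit)
  history <- tibble(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best <- list(loss = Inf, params = fit$params)
  for (e in seq_len(epochs)) {
    ord <- sample(n)
    starts <- seq(1L, n, by = batch_size)
    epoch_loss <- 0
    for (s in starts) {
      b <- ord[s:min(s + batch_size - 1L, n)]
      fw <- forward_pass(fit, toks$ids[b, , drop = FALSE], toks$n_tokens[b],
                         keep_cache = TRUE)
      yb <- Y[b, , drop = FALSE]
      loss <- bce_from_logits(fw$logits, yb)
      if (!is.finite(loss)) {
        abort(paste0("non-finite training loss at epoch ", e,
                     "; lower the learning rate"))
      }
      epoch_loss <- epoch_loss + loss * length(b)
      grads <- backward_pass(fit, fw$cache, bce_grad(fw$logits, yb))
      upd <- adam_step(fit$params, grads, state, lr, skip = skip)
      fit$params <- upd$params
      state <- upd$state
    }
    train_loss <- epoch_loss / n
    val_loss <- NA_real_
    if (!is.null(val)) {
      vw <- forward_pass(fit, val$toks$ids, val$toks$n_tokens)
      val_loss <- bce_from_logits(vw$logits, val$Y)
      if (val_loss < best$loss) best <- list(loss = val_loss,
                                             params = fit$params)
    }
    history <- dplyr::bind_rows(history,
      tibble(epoch = e, train_loss = train_loss, val_loss = val_loss))
    if (verbose) {
      cat(sprintf("epoch %3d  train %.5f  val %s\n", e, train_loss,
                  ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
    }
  }
  if (!is.null(val) && is.finite(best$loss)) fit$params <- best$params
  fit$history <- history
  fit
}

#' @export
#' @method print mirloc_fit
print.mirloc_fit <- function(x, ...) {
  cat("<mirloc_fit> ", toupper(x$arch), " / ", x$spec$scheme,
      "  (k = ", x$vocab$k, ", max_len = ", x$max_len,
      ", d = ", x$d, ", Q = ", length(x$label_space), ")\n", sep = "")
  cat("  parameters: ", n_parameters(x), "; epochs trained: ",
      nrow(x$history %||% tibble()), "\n", sep = "")
  invisible(x)
}

#' Number of learnable parameters in a fitted model
#'
#' @param fit A `mirloc_fit`.
#' @param include_embeddings Count the embedding table rows (the padding row
#'   is excluded either way).
#' @return Integer parameter count.
#' @export
n_parameters <- function(fit, include_embeddings = TRUE) {
  stopifnot(inherits(fit, "mirloc_fit"))
  tot <- 0L
  for (nm in names(fit$params)) {
    if (nm == "emb") {
      if (include_embeddings) {
        tot <- tot + (nrow(fit$params$emb) - 1L) * ncol(fit$params$emb)
      }
    } else {
      tot <- tot + length(fit$params[[nm]])
    }
  }
  as.integer(tot)
}

#' Score new sequences with a fitted model
#'
#' Sequences are tokenized with the model's vocabulary (unseen k-mers map to
#' the unknown token) and encoded to the model's fixed length; scores are the
#' element-wise sigmoid of the output logits (or a softmax across labels when
#' the model was built with `out_activation = "softmax"`).
#'
#' @param object A `mirloc_fit`.
#' @param new_data A data frame with `id` and `sequence` columns.
#' @param type `"scores"` for a tibble of per-label scores, `"labels"` for a
#'   tibble with a `predicted` list-column (threshold rule), `"matrix"` for
#'   the bare score matrix.
#' @param threshold Score threshold for `type = "labels"` (inclusive).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.mirloc_fit <- function(object, new_data,
                               type = c("scores", "labels", "matrix"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  toks <- encode_sequences(new_data, object$vocab, object$max_len,
                           trim = object$trim)
  fw <- forward_pass(object, toks$ids, toks$n_tokens)
  scores <- if (object$out_activation == "softmax") {
    ex <- exp(fw$logits - apply(fw$logits, 1, max))
    ex / rowSums(ex)
  } else {
    sigmoid(fw$logits)
  }
  colnames(scores) <- object$label_space
  rownames(scores) <- new_data$id
  if (type == "matrix") return(scores)
  out <- dplyr::bind_cols(tibble(id = new_data$id),
                          as_tibble(as.data.frame(scores)))
  if (type == "labels") {
    out <- tibble(id = new_data$id,
                  predicted = predict_labels(scores, threshold,
                                             object$label_space))
  }
  out
}

#' Threshold a score matrix into predicted label sets
#'
#' A label enters the predicted set when its score is greater than or equal
#' to the threshold; the empty set is allowed.
#'
#' @param scores Numeric matrix, one column per label.
#' @param threshold Inclusion threshold in `(0, 1)`.
#' @param label_space Label names; defaults to `colnames(scores)`.
#' @return A list of character vectors.
#' @export
predict_labels <- function(scores, threshold = 0.5,
                           label_space = colnames(scores)) {
  check_label_space(label_space)
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == length(label_space))
  lapply(seq_len(nrow(scores)), function(i) {
    label_space[scores[i, ] >= threshold]
  })
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single-file archive holding the parameters,
#' vocabulary, positional matrix, configuration and version stamp; a reloaded
#' model reproduces scores exactly.
#'
#' @param fit A `mirloc_fit`.
#' @param path Checkpoint path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `mirloc_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "mirloc_fit"))
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version)) abort("not a mirloc checkpoint")
  structure(obj, class = "mirloc_fit")
}

#' @export
tidy.mirloc_fit <- function(x, ...) {
  x$history %||% tibble(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
}

#' @export
glance.mirloc_fit <- function(x, ...) {
  h <- x$history
  tibble(
    arch = x$arch, scheme = x$spec$scheme, k = x$vocab$k,
    max_len = x$max_len, d = x$d,
    n_parameters = n_parameters(x),
    epochs = nrow(h %||% tibble()),
    final_train_loss = if (!is.null(h) && nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    best_val_loss = if (!is.null(h) && any(is.finite(h$val_loss))) {
      min(h$val_loss, na.rm = TRUE)
    } else NA_real_
  )
}
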