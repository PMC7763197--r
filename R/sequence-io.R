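#' Read mature miRNA sequences from a FASTA file
#'
#' Sequences are upper-cased and DNA-style `T` is normalized to `U`, so both
#' miRBase RNA downloads and DNA-alphabet exports are accepted. Any character
#' outside `A`, `C`, `G`, `U` (after normalization) is an error naming the
#' offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` (RNA alphabet), one row
#'   per FASTA entry, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- unname(normalize_rna(as.character(set), ids))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(id = ids, sequence = seqs)
}

normalize_rna <- function(seqs, ids) {
  seqs <- chartr("t", "T", toupper(seqs))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs) | !nzchar(seqs)
  if (any(bad)) {
    abort(paste0("sequence(s) with characters outside {A,C,G,U} (or empty): ",
                 paste(ids[bad], collapse = ", ")))
  }
  seqs
}

#' Write sequence records to FASTA
#'
#' @param records A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Read a label table (TSV: id, comma-joined label names)
#'
#' The second column holds the label set as comma-separated names; an empty
#' field is tolerated (with a warning) so prediction-only inputs can be read.
#' A header row `id<TAB>labels` is detected and skipped.
#'
#' @param path Path to the TSV file.
#' @param label_space Ordered label names every entry is validated against.
#' @return A tibble with columns `id` and `labels` (list of character vectors).
#' @export
read_label_table <- function(path, label_space = mirna_label_space()) {
  check_label_space(label_space)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) abort("label table needs at least two columns")
  # wide prediction files carry score columns between id and the label set;
  # the set is always the last column
  df <- tibble(id = df[[1]], labels = df[[ncol(df)]])
  if (nrow(df) && identical(tolower(df$id[1]), "id")) df <- df[-1, ]
  labels <- strsplit(ifelse(is.na(df$labels), "", df$labels), ",", fixed = TRUE)
  labels <- lapply(labels, function(x) trimws(x[nzchar(trimws(x))]))
  for (i in seq_along(labels)) {
    bad <- setdiff(labels[[i]], label_space)
    if (length(bad)) {
      abort(paste0("unknown label '", bad[1], "' for id '", df$id[i],
                   "' (row ", i, ")"))
    }
  }
  n_empty <- sum(lengths(labels) == 0)
  if (n_empty > 0) {
    warn(paste0(n_empty, " record(s) with an empty label set"))
  }
  tibble(id = df$id, labels = labels)
}

#' Read a one-hot label table (id plus one 0/1 column per label)
#'
#' Alternative label-table dialect: a delimited file whose header names the
#' labels and whose cells are 0/1 indicators.
#'
#' @inheritParams read_label_table
#' @return A tibble with columns `id` and `labels` (list-column).
#' @export
read_label_onehot <- function(path, label_space = mirna_label_space()) {
  check_label_space(label_space)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  lab_cols <- setdiff(names(df), "id")
  bad <- setdiff(lab_cols, label_space)
  if (length(bad)) abort(paste0("unknown label column(s): ",
                                paste(bad, collapse = ", ")))
  m <- as.matrix(df[lab_cols])
  storage.mode(m) <- "integer"
  tibble(id = as.character(df$id),
         labels = matrix_to_labels(m, lab_cols))
}

#' Write a label table readable by [read_label_table()]
#'
#' @param records A data frame with columns `id` and `labels` (list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(records, path) {
  stopifnot(all(c("id", "labels") %in% names(records)))
  lines <- paste0(records$id, "\t",
                  vapply(records$labels, paste, character(1), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Load pretrained k-mer embeddings from a text file
#'
#' One line per k-mer: the token followed by its vector, whitespace-separated.
#' A word2vec-style `N d` count header line is auto-detected and skipped.
#' The k-mer length `k` and the embedding dimension `d` are inferred and all
#' lines are checked for consistency.
#'
#' @param path Path to the embedding text file.
#' @return An object of class `kmer_embedding_file`: a list with `vectors`
#'   (numeric matrix, rownames = k-mers), `k`, and `d`.
#' @export
load_pretrained_embeddings <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty embedding file")
  parts <- strsplit(trimws(lines), "\\s+")
  # word2vec header: two integers, no token
  first <- parts[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.integer(first)))) {
    parts <- parts[-1]
    if (!length(parts)) abort("embedding file has a header but no vectors")
  }
  tokens <- toupper(vapply(parts, `[`, character(1), 1))
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L) {
    abort(paste0("ragged embedding vectors: dimensions ",
                 paste(sort(unique(dims)), collapse = ", ")))
  }
  d <- dims[1]
  if (d < 1) abort("embedding vectors must have at least one dimension")
  ks <- nchar(tokens)
  if (length(unique(ks)) != 1L) {
    abort("k-mer tokens of mixed lengths in embedding file")
  }
  if (anyDuplicated(tokens)) {
    abort(paste0("duplicate token in embedding file: ",
                 tokens[duplicated(tokens)][1]))
  }
  vecs <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(parts, `[`, -1)))),
    nrow = length(tokens), ncol = d, byrow = TRUE,
    dimnames = list(tokens, NULL)
  )
  if (anyNA(vecs)) abort("non-numeric entries in embedding file")
  structure(list(vectors = vecs, k = ks[1], d = d),
            class = "kmer_embedding_file")
}

#' @export
#' @method print kmer_embedding_file
print.kmer_embedding_file <- function(x, ...) {
  cat("<kmer_embedding_file> ", nrow(x$vectors), " ", x$k, "-mers, d = ",
      x$d, "\n", sep = "")
  invisible(x)
}

#' Write prediction scores and thresholded label sets
#'
#' Emits a TSV with one row per sequence: id, one score column per label, and
#' a final comma-joined predicted label set (score >= `threshold`). The id and
#' predicted-set columns round-trip through [read_label_table()].
#'
#' @param path Output path.
#' @param ids Character vector of sequence ids.
#' @param scores Numeric matrix in `[0, 1]`, one row per id, one column per label.
#' @param threshold Inclusion threshold for the predicted set.
#' @param label_space Ordered label names.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(path, ids, scores, threshold = 0.5,
                              label_space = mirna_label_space()) {
  check_label_space(label_space)
  scores <- as.matrix(scores)
  if (length(ids) != nrow(scores)) {
    abort(paste0("length mismatch: ", length(ids), " ids vs ",
                 nrow(scores), " score rows"))
  }
  if (ncol(scores) != length(label_space)) {
    abort("`scores` must have one column per label")
  }
  if (any(scores < 0 | scores > 1)) abort("scores must lie in [0, 1]")
  sets <- predict_labels(scores, threshold = threshold,
                         label_space = label_space)
  header <- paste(c("id", label_space, "predicted"), collapse = "\t")
  rows <- paste(
    ids,
    apply(scores, 1, function(r) paste(format(r, digits = 10, trim = TRUE),
                                       collapse = "\t")),
    vapply(sets, paste, character(1), collapse = ","),
    sep = "\t"
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a prediction file written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @param label_space Ordered label names.
#' @return A tibble with `id`, one numeric score column per label, and a
#'   `predicted` list-column of label sets.
#' @export
read_predictions <- function(path, label_space = mirna_label_space()) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("id", label_space, "predicted") %in% names(df)))
  pred <- strsplit(ifelse(is.na(df$predicted), "", df$predicted), ",",
                   fixed = TRUE)
  pred <- lapply(pred, function(x) x[nzchar(x)])
  out <- tibble(id = as.character(df$id))
  for (l in label_space) out[[l]] <- as.numeric(df[[l]])
  out$predicted <- pred
  out
}
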