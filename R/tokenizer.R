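#' Generate overlapping k-mers from one RNA sequence
#'
#' Slides a window of width `k` over the sequence with the given stride. At
#' stride 1 this yields `L - k + 1` overlapping tokens that preserve the
#' positional distribution of the four nucleotides.
#'
#' @param sequence A single RNA string.
#' @param k Window size. Sizes outside 3..10 are allowed with a warning.
#' @param stride Step size, `1 <= stride <= k`. Default 1 (overlapping).
#' @return Character vector of k-mers in left-to-right order.
#' @export
#' @examples
#' generate_kmers("ACGUACGUCGU", k = 3)
generate_kmers <- function(sequence, k, stride = 1L) {
  check_tokenizer_args(k, stride)
  L <- nchar(sequence)
  if (L < k) {
    abort(paste0("sequence shorter than window: length ", L, " < k = ", k))
  }
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(sequence, starts, starts + k - 1L)
}

check_tokenizer_args <- function(k, stride) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("`k` must be a single positive integer")
  }
  if (k < 3 || k > 10) {
    warn(paste0("window size k = ", k, " is outside the usual 3..10 range"))
  }
  if (!is.numeric(stride) || length(stride) != 1 || stride < 1 ||
      stride > k || stride != round(stride)) {
    abort("`stride` must satisfy 1 <= stride <= k")
  }
  invisible(TRUE)
}

n_tokens_for <- function(lengths, k, stride = 1L) {
  ifelse(lengths < k, NA_integer_,
         as.integer((lengths - k) %/% stride + 1L))
}

#' Build a k-mer vocabulary from a training corpus
#'
#' IDs start at 1 and are assigned in order of first appearance in the corpus
#' (deterministic given record order); ID 0 is reserved for padding and an
#' `<unk>` ID, absorbing k-mers unseen at training time, is appended last.
#' With `all_kmers = TRUE` the vocabulary instead enumerates all `4^k` strings
#' in lexicographic order.
#'
#' @param records A data frame with a `sequence` column (the training corpus).
#' @param k,stride Tokenizer settings; see [generate_kmers()].
#' @param all_kmers Enumerate the full `4^k` token universe instead of the
#'   observed k-mers.
#' @return An object of class `kmer_vocab`.
#' @export
build_vocabulary <- function(records, k, stride = 1L, all_kmers = FALSE) {
  check_tokenizer_args(k, stride)
  if (all_kmers) {
    toks <- do.call(paste0, rev(expand.grid(
      rep(list(c("A", "C", "G", "U")), k), stringsAsFactors = FALSE)))
    toks <- sort(toks)
  } else {
    if (is.null(records) || nrow(records) == 0) {
      abort("empty corpus: cannot build a vocabulary")
    }
    toks <- unique(unlist(lapply(records$sequence, generate_kmers,
                                 k = k, stride = stride)))
  }
  ids <- setNames(seq_along(toks), toks)
  structure(
    list(ids = ids, unk_id = length(toks) + 1L, k = as.integer(k),
         stride = as.integer(stride)),
    class = "kmer_vocab"
  )
}

#' @export
#' @method print kmer_vocab
print.kmer_vocab <- function(x, ...) {
  cat("<kmer_vocab> k = ", x$k, ", stride = ", x$stride, ", ",
      length(x$ids), " tokens + <unk> (pad = 0)\n", sep = "")
  invisible(x)
}

#' Vocabulary size (tokens plus the unknown-token slot, excluding padding)
#' @param vocab A `kmer_vocab`.
#' @return Integer.
#' @export
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  vocab$unk_id
}

#' Serialize a vocabulary as TSV (token, id)
#'
#' The unknown-token slot is written as the literal token `<unk>`; ordering is
#' by ID so runs are reproducible byte-for-byte.
#'
#' @param vocab A `kmer_vocab`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  lines <- c(paste0("#k=", vocab$k, "\tstride=", vocab$stride),
             paste(names(vocab$ids), vocab$ids, sep = "\t"),
             paste("<unk>", vocab$unk_id, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#' @param path Path to the TSV.
#' @return A `kmer_vocab`.
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^#k=", "", lines[1]), "\tstride=")[[1]]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  toks <- vapply(parts, `[`, character(1), 1)
  ids <- as.integer(vapply(parts, `[`, character(1), 2))
  unk <- ids[toks == "<unk>"]
  keep <- toks != "<unk>"
  structure(
    list(ids = setNames(ids[keep], toks[keep]), unk_id = unk,
         k = as.integer(meta[1]), stride = as.integer(meta[2])),
    class = "kmer_vocab"
  )
}

#' Longest token sequence in a corpus
#'
#' The fixed encoding length is taken as the maximum number of k-mer tokens
#' over the (training) records: `floor((L - k) / stride) + 1` for the longest
#' sequence.
#'
#' @inheritParams build_vocabulary
#' @return Integer.
#' @export
infer_max_len <- function(records, k, stride = 1L) {
  check_tokenizer_args(k, stride)
  if (is.null(records) || nrow(records) == 0) abort("empty corpus")
  L <- nchar(records$sequence)
  if (any(L < k)) {
    abort("corpus contains sequence(s) shorter than the window size")
  }
  max(n_tokens_for(L, k, stride))
}

#' Encode records as fixed-length k-mer ID vectors
#'
#' Tokens are looked up in the vocabulary (unseen k-mers map to the `<unk>`
#' ID, never an error); sequences with more than `max_len` tokens are trimmed
#' and shorter ones right-padded with the reserved ID 0. Trimming keeps the
#' sequence prefix by default.
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param vocab A `kmer_vocab` built on the training corpus.
#' @param max_len Fixed token-sequence length.
#' @param trim One of "prefix", "suffix", "center": which `max_len`-token
#'   piece to keep when a sequence is longer than `max_len`.
#' @return An object of class `mirloc_tokens`: list with `ids` (integer
#'   matrix, one row per record, `max_len` columns, rownames = record ids)
#'   and `n_tokens` (real, un-padded token counts after trimming).
#' @export
encode_sequences <- function(records, vocab, max_len,
                             trim = c("prefix", "suffix", "center")) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  trim <- match.arg(trim)
  if (!is.numeric(max_len) || max_len < 1) abort("`max_len` must be >= 1")
  max_len <- as.integer(max_len)
  n <- nrow(records)
  ids <- matrix(0L, nrow = n, ncol = max_len,
                dimnames = list(records$id, NULL))
  n_tokens <- integer(n)
  for (i in seq_len(n)) {
    toks <- generate_kmers(records$sequence[i], vocab$k, vocab$stride)
    v <- unname(vocab$ids[toks])
    v[is.na(v)] <- vocab$unk_id
    if (length(v) > max_len) {
      v <- switch(trim,
        prefix = v[seq_len(max_len)],
        suffix = v[seq.int(length(v) - max_len + 1L, length(v))],
        center = {
          off <- (length(v) - max_len) %/% 2L
          v[seq.int(off + 1L, off + max_len)]
        })
    }
    n_tokens[i] <- length(v)
    ids[i, seq_along(v)] <- v
  }
  structure(list(ids = ids, n_tokens = n_tokens, max_len = max_len,
                 k = vocab$k, stride = vocab$stride, trim = trim),
            class = "mirloc_tokens")
}

#' @export
#' @method print mirloc_tokens
print.mirloc_tokens <- function(x, ...) {
  cat("<mirloc_tokens> ", nrow(x$ids), " sequences x ", x$max_len,
      " token slots (k = ", x$k, ")\n", sep = "")
  invisible(x)
}
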