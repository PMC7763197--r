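#' Sinusoidal positional-encoding matrix
#'
#' Builds the `n_pos x emb_dim` table of position vectors used to fuse k-mer
#' order into embeddings. Row `p + 1` encodes position `p`: even (0-based)
#' dimensions hold `sin(p / 10000^(2i/emb_dim))` and odd dimensions the
#' matching cosine, so every entry lies in `[-1, 1]`, rows are pairwise
#' distinct, and the dot product between rows a fixed offset apart is constant
#' (the "symmetric neighbor distance" property). Row 1 (position 0) is
#' overwritten with zeros and reserved for padded slots, so padding
#' contributes nothing after fusion.
#'
#' @param n_pos Number of rows, i.e. `max_len + 1` (position 0 = padding).
#' @param emb_dim Dimension of the paired embeddings. An odd `emb_dim` gets a
#'   final sine-only dimension.
#' @return A numeric `n_pos x emb_dim` matrix.
#' @export
#' @examples
#' pe <- positional_matrix(4, 4)
#' pe[2, ] # sin(1), cos(1), sin(0.01), cos(0.01)
positional_matrix <- function(n_pos, emb_dim) {
  if (!is.numeric(n_pos) || n_pos < 2) abort("`n_pos` must be >= 2")
  if (!is.numeric(emb_dim) || emb_dim < 1) abort("`emb_dim` must be >= 1")
  n_pos <- as.integer(n_pos); emb_dim <- as.integer(emb_dim)
  j <- 0:(emb_dim - 1L)                   # 0-based dimension index
  rates <- 1 / 10000^(2 * (j %/% 2) / emb_dim)
  ang <- outer(0:(n_pos - 1L), rates)
  even <- j %% 2 == 0
  pe <- ang
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, !even] <- cos(ang[, !even, drop = FALSE])
  pe[1, ] <- 0
  pe
}

#' Randomly initialized k-mer embedding table
#'
#' Entries are i.i.d. uniform on `[-1/sqrt(d), 1/sqrt(d)]` (scale-matched to
#' the unit-bounded positional encoding) and fully reproducible from `seed`.
#' Row 1 is the all-zero padding row (token ID 0); the last row belongs to the
#' unknown-token ID.
#'
#' @param vocab_size Number of token IDs including the unknown slot, as
#'   returned by [vocab_size()].
#' @param d Embedding dimension (default 120, the dimension used with the
#'   random scheme).
#' @param seed RNG seed.
#' @return A numeric `(vocab_size + 1) x d` matrix; row `i + 1` holds ID `i`.
#' @export
init_random_embeddings <- function(vocab_size, d = 120L, seed = 1L) {
  if (!is.numeric(d) || d < 1) abort("`d` must be >= 1")
  if (!is.numeric(vocab_size) || vocab_size < 1) {
    abort("`vocab_size` must be >= 1")
  }
  n <- as.integer(vocab_size) + 1L
  tab <- withr::with_seed(seed,
    matrix(runif(n * d, -1 / sqrt(d), 1 / sqrt(d)), nrow = n, ncol = d))
  tab[1, ] <- 0
  tab
}

#' Assemble an embedding table from a pretrained file
#'
#' Rows are copied from the file by token; vocabulary tokens absent from the
#' file (including the unknown slot) receive seeded random rows and their
#' count is reported.
#'
#' @param embedding_file A `kmer_embedding_file` from
#'   [load_pretrained_embeddings()].
#' @param vocab A `kmer_vocab`; its `k` must match the file's.
#' @param seed Seed for the random fallback rows.
#' @return A numeric `(vocab_size(vocab) + 1) x d` matrix with a zero padding
#'   row first; attribute `n_fallback` counts the randomly filled tokens.
#' @export
assemble_pretrained_table <- function(embedding_file, vocab, seed = 1L) {
  stopifnot(inherits(embedding_file, "kmer_embedding_file"),
            inherits(vocab, "kmer_vocab"))
  if (embedding_file$k != vocab$k) {
    abort(paste0("k mismatch: embeddings are ", embedding_file$k,
                 "-mers but vocabulary uses k = ", vocab$k))
  }
  d <- embedding_file$d
  tab <- init_random_embeddings(vocab_size(vocab), d = d, seed = seed)
  hit <- names(vocab$ids)[names(vocab$ids) %in% rownames(embedding_file$vectors)]
  tab[vocab$ids[hit] + 1L, ] <- embedding_file$vectors[hit, , drop = FALSE]
  n_fallback <- (length(vocab$ids) - length(hit)) + 1L  # + <unk>
  if (n_fallback > 0) {
    inform(paste0(n_fallback, " token(s) missing from the pretrained file; ",
                  "seeded random rows used"))
  }
  attr(tab, "n_fallback") <- n_fallback
  tab
}

#' Fuse an embedded sequence with positional vectors
#'
#' Element-wise sum per token slot: slot `j` (occupied by the token at
#' sequence position `j`) receives positional row `j`, padded slots receive
#' the all-zero row 0, so they stay exactly zero.
#'
#' @param embedded A `max_len x d` matrix of per-slot embedding vectors.
#' @param pe A positional matrix from [positional_matrix()] with
#'   `emb_dim == d` and at least `max_len + 1` rows.
#' @param positions Integer vector of length `max_len`: the 1-based sequence
#'   position of each slot, 0 for padded slots. Defaults to
#'   `1..n_real` followed by zeros when `n_real` is given via `n_tokens`.
#' @param n_tokens Convenience alternative to `positions`: the number of real
#'   (non-pad) leading slots.
#' @return A `max_len x d` matrix.
#' @export
fuse_positional <- function(embedded, pe, positions = NULL, n_tokens = NULL) {
  embedded <- as.matrix(embedded)
  if (ncol(embedded) != ncol(pe)) {
    abort(paste0("dimension mismatch: embedding d = ", ncol(embedded),
                 " but positional emb_dim = ", ncol(pe)))
  }
  T_ <- nrow(embedded)
  if (is.null(positions)) {
    if (is.null(n_tokens)) abort("give either `positions` or `n_tokens`")
    positions <- c(seq_len(min(n_tokens, T_)),
                   integer(max(0L, T_ - n_tokens)))
  }
  if (length(positions) != T_) abort("`positions` must match nrow(embedded)")
  if (max(positions) + 1L > nrow(pe)) abort("positional matrix too short")
  embedded + pe[positions + 1L, , drop = FALSE]
}

#' Representation scheme specification
#'
#' The five statistical representation schemes compared in this package:
#' `"pre-embedding"` (pretrained lookup), `"rand-embedding"` (random lookup),
#' `"pos-encoding"` (position vectors only, no token identity),
#' `"pre-embedding+pos-encoding"`, and `"kmerPR2vec"` (random lookup fused
#' with positional vectors — the headline scheme).
#'
#' @param scheme Scheme name (the alias `"pre+pos"` is accepted).
#' @param emb_dim Embedding dimension; default 120 for random-based schemes
#'   and the file's `d` for pretrained ones.
#' @param trainable Whether embedding rows update during training. Defaults to
#'   `TRUE` for random tables and `FALSE` for pretrained ones.
#' @return An object of class `representation_spec`.
#' @export
representation_spec <- function(scheme = c("kmerPR2vec", "rand-embedding",
                                           "pre-embedding", "pos-encoding",
                                           "pre-embedding+pos-encoding",
                                           "pre+pos"),
                                emb_dim = NULL, trainable = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "pre+pos") scheme <- "pre-embedding+pos-encoding"
  use_pre <- scheme %in% c("pre-embedding", "pre-embedding+pos-encoding")
  use_emb <- scheme != "pos-encoding"
  use_pe <- scheme %in% c("pos-encoding", "pre-embedding+pos-encoding",
                          "kmerPR2vec")
  if (is.null(trainable)) trainable <- use_emb && !use_pre
  if (is.null(emb_dim) && !use_pre) emb_dim <- 120L
  structure(list(scheme = scheme, emb_dim = emb_dim,
                 use_embedding = use_emb, use_pretrained = use_pre,
                 use_positional = use_pe, trainable = trainable),
            class = "representation_spec")
}

#' @export
#' @method print representation_spec
print.representation_spec <- function(x, ...) {
  cat("<representation_spec> ", x$scheme, " (d = ", x$emb_dim %||% "?",
      ", trainable = ", x$trainable, ")\n", sep = "")
  invisible(x)
}

#' Build per-sequence representation matrices
#'
#' Dispatches on the representation scheme: embedding lookup, positional rows,
#' or their element-wise fusion. Mainly a user-facing inspection tool; model
#' training uses the same arithmetic on whole batches internally.
#'
#' @param tokens A `mirloc_tokens` object from [encode_sequences()].
#' @param spec A `representation_spec`.
#' @param embeddings Embedding table (required unless scheme is
#'   `"pos-encoding"`): from [init_random_embeddings()] or
#'   [assemble_pretrained_table()].
#' @param pe Positional matrix; built automatically when the scheme needs one.
#' @return A list of `max_len x emb_dim` matrices, named by record id.
#' @export
represent <- function(tokens, spec, embeddings = NULL, pe = NULL) {
  stopifnot(inherits(tokens, "mirloc_tokens"),
            inherits(spec, "representation_spec"))
  d <- spec$emb_dim
  if (spec$use_embedding) {
    if (is.null(embeddings)) {
      abort(paste0("scheme '", spec$scheme, "' requires an embedding table"))
    }
    d <- ncol(embeddings)
    if (!is.null(spec$emb_dim) && spec$emb_dim != d) {
      abort("embedding table dimension does not match the spec's emb_dim")
    }
  }
  if (spec$use_positional && is.null(pe)) {
    pe <- positional_matrix(tokens$max_len + 1L, d)
  }
  if (spec$use_positional && ncol(pe) != d) {
    abort("positional emb_dim must equal the embedding dimension")
  }
  flat <- represent_batch(tokens$ids, tokens$n_tokens,
                          embeddings = embeddings, pe = pe,
                          use_embedding = spec$use_embedding,
                          use_positional = spec$use_positional, d = d)
  T_ <- tokens$max_len
  out <- lapply(seq_len(nrow(tokens$ids)), function(b) {
    flat[((b - 1L) * T_ + 1L):(b * T_), , drop = FALSE]
  })
  names(out) <- rownames(tokens$ids)
  out
}

# Batch representation: returns a (B*T) x d matrix, token slots ordered
# t = 1..T within each sequence. Pad slots are exactly zero.
represent_batch <- function(ids, n_tokens, embeddings, pe,
                            use_embedding, use_positional, d) {
  B <- nrow(ids); T_ <- ncol(ids)
  idx <- as.vector(t(ids))                       # slot-major within sequence
  X <- matrix(0, nrow = B * T_, ncol = d)
  if (use_embedding) X <- embeddings[idx + 1L, , drop = FALSE]
  if (use_positional) {
    pos <- rep(seq_len(T_), times = B)
    pos[idx == 0L] <- 0L
    X <- X + pe[pos + 1L, , drop = FALSE]
  }
  X
}
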