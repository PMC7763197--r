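# Motif-planting generator for miRNA-like multi-label datasets. Each label
# owns a short motif; a sequence carries a label exactly when that label's
# motif occurs in the sequence (within the label's start window, when one is
# set). Labels are therefore a deterministic, purely sequence-measurable
# function — the stored label sets are always recomputed from the final
# sequence, so chance occurrences that survive generation still grant the
# label.

default_motifs <- function() {
  c(exosome = "ACGUG", cytoplasm = "CAUCC", mitochondrion = "GGAUA",
    microvesicle = "UCCGU", circulating = "AGGAC", nucleus = "UUGCA")
}

#' Cardinality profile of the benchmark corpus
#'
#' The proportions of uni- through hexa-label miRNAs in the 1047-sequence
#' public benchmark (424, 233, 128, 78, 64, 120), used as the generator's
#' default label-cardinality profile.
#'
#' @return A numeric vector of length 6 summing to 1.
#' @export
benchmark_cardinality_profile <- function() {
  c(424, 233, 128, 78, 64, 120) / 1047
}

#' Configuration for the synthetic dataset generator
#'
#' @param n Number of sequences.
#' @param length_range Sequence length range in nucleotides (default 20–30,
#'   the mature-miRNA range the classifier targets).
#' @param motifs Named character vector: one planted motif per label (names
#'   define the label space). All motifs must share one length and fit within
#'   the shortest sequence.
#' @param windows Optional named list of `c(lo, hi)` allowed start positions
#'   per label; `NULL` (default) allows a motif anywhere it fits.
#' @param cardinality_profile Target proportions of 1..Q-label sequences.
#' @param background Nucleotide sampling probabilities for A, C, G, U.
#' @param scrub_chance_hits Redraw background nucleotides that create
#'   unplanned motif occurrences (bounded retries), keeping the realized
#'   cardinality profile close to the target.
#' @param seed RNG seed.
#' @return A list of class `mirloc_sim_config`.
#' @export
simulation_config <- function(n,
                              length_range = c(20L, 30L),
                              motifs = default_motifs(),
                              windows = NULL,
                              cardinality_profile = benchmark_cardinality_profile(),
                              background = c(A = 0.25, C = 0.25,
                                             G = 0.25, U = 0.25),
                              scrub_chance_hits = TRUE,
                              seed = 1L) {
  if (n < 1) abort("`n` must be >= 1")
  if (length(length_range) != 2 || length_range[1] > length_range[2]) {
    abort("`length_range` must be c(min, max)")
  }
  if (is.null(names(motifs)) || anyDuplicated(names(motifs))) {
    abort("`motifs` must be uniquely named by label")
  }
  ml <- unique(nchar(motifs))
  if (length(ml) != 1) abort("all motifs must share one length")
  if (ml > length_range[1]) {
    abort("motifs longer than the minimum sequence length")
  }
  if (grepl("[^ACGU]", paste(motifs, collapse = ""))) {
    abort("motifs must use the RNA alphabet A/C/G/U")
  }
  Q <- length(motifs)
  if (length(cardinality_profile) != Q) {
    abort("`cardinality_profile` must have one entry per label")
  }
  if (any(cardinality_profile < 0) ||
      abs(sum(cardinality_profile) - 1) > 1e-8) {
    abort("`cardinality_profile` must be non-negative and sum to 1")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-8) {
    abort("`background` must be 4 probabilities summing to 1")
  }
  structure(
    list(n = as.integer(n), length_range = as.integer(length_range),
         motifs = motifs, windows = windows,
         cardinality_profile = cardinality_profile,
         background = background,
         scrub_chance_hits = isTRUE(scrub_chance_hits),
         seed = as.integer(seed)),
    class = "mirloc_sim_config"
  )
}

motif_starts <- function(sequence, motif, window = NULL) {
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (!is.null(window)) hits <- hits[hits >= window[1] & hits <= window[2]]
  hits
}

#' Recompute label sets from sequences with the motif rule
#'
#' The generator's labeling function: a sequence carries a label exactly when
#' that label's motif occurs in it (with its start inside the label's window,
#' when windows are set). Exposed so the label rule can be audited
#' independently of the generator.
#'
#' @param sequences Character vector of RNA sequences.
#' @param motifs Named motif vector (names = labels).
#' @param windows Optional named list of start windows per label.
#' @return A list of character label sets.
#' @export
motif_labels <- function(sequences, motifs, windows = NULL) {
  lapply(sequences, function(s) {
    names(motifs)[vapply(names(motifs), function(l) {
      length(motif_starts(s, motifs[[l]], windows[[l]])) > 0
    }, logical(1))]
  })
}

sample_background <- function(L, background) {
  paste(sample(names(background), L, replace = TRUE, prob = background),
        collapse = "")
}

plant_at <- function(sequence, motif, start) {
  paste0(substr(sequence, 1, start - 1), motif,
         substr(sequence, start + nchar(motif), nchar(sequence)))
}

# Redraw background nucleotides that create motif occurrences outside the
# planted intervals. `protected` is an integer vector of 1-based positions
# that must not change.
scrub_sequence <- function(sequence, motifs, windows, protected,
                           keep_starts, background, max_iter = 20L) {
  alphabet <- c("A", "C", "G", "U")
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (l in names(motifs)) {
      hits <- motif_starts(sequence, motifs[[l]], windows[[l]])
      hits <- setdiff(hits, keep_starts[[l]])
      for (s in hits) {
        span <- s:(s + nchar(motifs[[l]]) - 1L)
        free <- setdiff(span, protected)
        if (!length(free)) next  # occurrence lies inside planted material
        pos <- free[sample.int(length(free), 1)]
        cur <- substr(sequence, pos, pos)
        repl <- sample(setdiff(alphabet, cur), 1)
        substr(sequence, pos, pos) <- repl
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  sequence
}

#' Simulate a motif-labeled multi-label sequence dataset
#'
#' Draws each sequence from the background composition, samples a target
#' label cardinality from the configured profile, plants the chosen labels'
#' motifs at non-overlapping uniform positions (inside their windows when
#' windows are set), optionally scrubs chance occurrences of any motif from
#' the background, and finally recomputes the stored label set from the
#' finished sequence with [motif_labels()] — the labels are exactly what the
#' motif rule implies. The sequence length is drawn uniformly from the part
#' of `length_range` that can host all planted motifs.
#'
#' @param config A `mirloc_sim_config` from [simulation_config()].
#' @return A tibble (`id`, `sequence`, `labels`) with attributes `config`,
#'   `label_space` and `placements` (per-sequence tibble of planted label /
#'   start).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "mirloc_sim_config"))
  motifs <- config$motifs
  m <- nchar(motifs[[1]])
  Q <- length(motifs)
  lab_names <- names(motifs)
  withr::with_seed(config$seed, {
    rows <- vector("list", config$n)
    placements <- vector("list", config$n)
    for (i in seq_len(config$n)) {
      ci <- sample.int(Q, 1, prob = config$cardinality_profile)
      labs <- sample(lab_names, ci)
      L_lo <- max(config$length_range[1], ci * m)
      if (L_lo > config$length_range[2]) {
        abort("length range cannot host the sampled number of motifs")
      }
      L <- if (L_lo == config$length_range[2]) L_lo else
        sample(L_lo:config$length_range[2], 1)
      s <- sample_background(L, config$background)
      if (is.null(config$windows)) {
        slack <- L - ci * m
        cuts <- sort(sample.int(slack + 1L, ci, replace = TRUE) - 1L)
        starts <- cuts + (seq_len(ci) - 1L) * m + 1L
      } else {
        starts <- vapply(labs, function(l) {
          w <- config$windows[[l]] %||% c(1L, L - m + 1L)
          hi <- min(w[2], L - m + 1L)
          if (hi < w[1]) abort("window does not fit the sequence length")
          if (hi == w[1]) w[1] else sample(w[1]:hi, 1)
        }, integer(1))
      }
      for (j in seq_len(ci)) s <- plant_at(s, motifs[[labs[j]]], starts[j])
      protected <- unique(unlist(lapply(starts, function(st) st:(st + m - 1L))))
      keep <- split(as.integer(starts), labs)
      if (config$scrub_chance_hits) {
        s <- scrub_sequence(s, motifs, config$windows, protected, keep,
                            config$background)
      }
      rows[[i]] <- s
      placements[[i]] <- tibble(label = labs, start = as.integer(starts))
    }
    sequences <- unlist(rows)
    out <- tibble(
      id = sprintf("syn%06d", seq_len(config$n)),
      sequence = sequences,
      labels = motif_labels(sequences, motifs, config$windows)
    )
  })
  attr(out, "config") <- config
  attr(out, "label_space") <- lab_names
  attr(out, "placements") <- placements
  out
}

#' Two-label benchmark where only motif POSITION is informative
#'
#' Every sequence contains exactly one occurrence of the same motif inside
#' the union of two disjoint start windows: label `pos_early` when it starts
#' inside `window_a`, `pos_late` for `window_b` (`n/2` sequences each,
#' alternating). Because both classes share one motif and one background
#' composition, their k-mer count distributions coincide and a position-free
#' (bag-of-k-mers) classifier cannot beat chance; only a representation that
#' retains token position can separate them.
#'
#' The default windows sit at least `nchar(motif) - 1` nucleotides inside
#' both sequence ends. This matters: a window touching a sequence edge
#' truncates the motif/background junction k-mers on that side, which makes
#' the classes' k-mer COUNT distributions differ and leaks position into
#' bag-of-k-mers features. With full junction context on both sides the two
#' classes are exchangeable up to motif position, which is the property the
#' benchmark exists to isolate; a warning is raised for edge-adjacent custom
#' windows.
#'
#' @param n Number of sequences (even).
#' @param motif The shared planted motif.
#' @param window_a,window_b Disjoint `c(lo, hi)` start windows; the motif
#'   must fit `window_b` (and `window_a`) within the shortest sequence.
#' @param length_range Sequence length range.
#' @param labels Length-2 label names for the early/late classes.
#' @param seed RNG seed.
#' @return A tibble as in [simulate_dataset()], with `label_space` attribute
#'   equal to `labels`.
#' @export
positional_pair_benchmark <- function(n = 600L, motif = "ACGUA",
                                      window_a = c(5L, 6L),
                                      window_b = c(11L, 12L),
                                      length_range = c(20L, 30L),
                                      labels = c("pos_early", "pos_late"),
                                      seed = 1L) {
  if (n %% 2 != 0) abort("`n` must be even for a balanced benchmark")
  m <- nchar(motif)
  if (window_a[2] >= window_b[1] && window_b[2] >= window_a[1]) {
    abort("start windows must be disjoint")
  }
  if (max(window_a[2], window_b[2]) + m - 1L > length_range[1]) {
    abort("motif does not fit both windows within the shortest sequence")
  }
  if (min(window_a[1], window_b[1]) < m ||
      max(window_a[2], window_b[2]) > length_range[1] - 2L * m + 2L) {
    warn(paste0("window within ", m - 1L, " nt of a sequence edge: ",
                "truncated junction k-mers leak position into ",
                "bag-of-k-mers features"))
  }
  wins <- setNames(list(as.integer(window_a), as.integer(window_b)), labels)
  motifs <- setNames(c(motif, motif), labels)
  withr::with_seed(seed, {
    cls <- rep(labels, length.out = n)
    sequences <- character(n)
    starts <- integer(n)
    union_lo <- min(window_a[1], window_b[1])
    union_hi <- max(window_a[2], window_b[2])
    for (i in seq_len(n)) {
      L <- if (length_range[1] == length_range[2]) length_range[1] else
        sample(length_range[1]:length_range[2], 1)
      w <- wins[[cls[i]]]
      st <- if (w[1] == w[2]) w[1] else sample(w[1]:w[2], 1)
      s <- plant_at(sample_background(L, c(A = .25, C = .25, G = .25, U = .25)),
                    motif, st)
      # exactly one occurrence inside the window union
      s <- scrub_sequence(
        s, setNames(motif, "m"),
        windows = list(m = c(union_lo, union_hi)),
        protected = st:(st + m - 1L),
        keep_starts = list(m = st),
        background = c(A = .25, C = .25, G = .25, U = .25))
      sequences[i] <- s
      starts[i] <- st
    }
    out <- tibble(
      id = sprintf("pos%06d", seq_len(n)),
      sequence = sequences,
      labels = motif_labels(sequences, motifs, wins)
    )
  })
  attr(out, "label_space") <- labels
  attr(out, "placements") <- purrr::map2(cls, starts,
                                         ~ tibble(label = .x, start = .y))
  attr(out, "config") <- list(n = n, motif = motif, windows = wins,
                              length_range = length_range, seed = seed)
  out
}

#' Export a synthetic dataset as FASTA plus label TSV
#'
#' @param dataset A record tibble (e.g. from [simulate_dataset()]).
#' @param fasta_path,labels_path Output paths.
#' @return Invisibly, `c(fasta_path, labels_path)`.
#' @export
export_dataset <- function(dataset, fasta_path, labels_path) {
  if (nrow(dataset) == 0) abort("empty dataset")
  write_fasta(dataset, fasta_path)
  write_label_table(dataset, labels_path)
  invisible(c(fasta_path, labels_path))
}
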