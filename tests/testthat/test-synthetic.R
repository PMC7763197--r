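test_that("simulated datasets respect alphabet, lengths and determinism", {
  cfg <- simulation_config(n = 100, seed = 42)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds), 100)
  expect_true(all(nchar(ds$sequence) >= 20 & nchar(ds$sequence) <= 30))
  expect_false(any(grepl("[^ACGU]", ds$sequence)))
  expect_equal(ds$id[1], "syn000001")
  expect_equal(ds, simulate_dataset(cfg), ignore_attr = TRUE)
  expect_false(identical(ds$sequence,
                         simulate_dataset(simulation_config(100, seed = 43))$sequence))
})

test_that("stored labels equal the motif rule recomputed from sequences", {
  ds <- simulate_dataset(simulation_config(n = 200, seed = 7))
  cfg <- attr(ds, "config")
  recomputed <- motif_labels(ds$sequence, cfg$motifs, cfg$windows)
  expect_identical(ds$labels, recomputed)
  # every planted motif is present at its recorded position
  pl <- attr(ds, "placements")
  for (i in sample(200, 25)) {
    for (j in seq_len(nrow(pl[[i]]))) {
      mot <- cfg$motifs[[pl[[i]]$label[j]]]
      expect_equal(substr(ds$sequence[i], pl[[i]]$start[j],
                          pl[[i]]$start[j] + nchar(mot) - 1), mot)
    }
  }
})

test_that("realized label-cardinality proportions track the profile", {
  ds <- simulate_dataset(simulation_config(n = 2000, seed = 19))
  card <- table(factor(lengths(ds$labels), levels = 1:6)) / nrow(ds)
  expect_true(all(abs(as.numeric(card) - benchmark_cardinality_profile())
                  <= 0.05))
})

test_that("a degenerate cardinality profile is honored exactly", {
  cfg <- simulation_config(n = 50, seed = 3,
                           cardinality_profile = c(1, 0, 0, 0, 0, 0))
  ds <- simulate_dataset(cfg)
  expect_true(all(lengths(ds$labels) == 1))
  expect_identical(ds$labels,
                   motif_labels(ds$sequence, cfg$motifs, cfg$windows))
})

test_that("the positional pair benchmark isolates position as the signal", {
  ds <- positional_pair_benchmark(n = 600, seed = 11)
  expect_equal(unname(table(unlist(ds$labels))), c(300L, 300L),
               ignore_attr = TRUE)
  expect_true(all(lengths(ds$labels) == 1))
  cfg <- attr(ds, "config")
  # exactly one motif occurrence inside the union of the two windows
  union_w <- c(min(cfg$windows[[1]][1], cfg$windows[[2]][1]),
               max(cfg$windows[[1]][2], cfg$windows[[2]][2]))
  n_occ <- vapply(ds$sequence, function(s) {
    length(mirloc:::motif_starts(s, cfg$motif, union_w))
  }, numeric(1))
  expect_true(all(n_occ == 1))
  # per-class k-mer count distributions are indistinguishable (chi-square)
  k <- nchar(cfg$motif)
  cls <- vapply(ds$labels, `[[`, character(1), 1)
  counts <- lapply(split(ds$sequence, cls), function(ss) {
    table(unlist(lapply(ss, generate_kmers, k = k)))
  })
  all_kmers <- union(names(counts[[1]]), names(counts[[2]]))
  m <- rbind(as.numeric(counts[[1]][all_kmers]),
             as.numeric(counts[[2]][all_kmers]))
  m[is.na(m)] <- 0
  m <- m[, colSums(m) >= 10]
  p <- suppressWarnings(stats::chisq.test(m)$p.value)
  expect_gt(p, 0.01)
  expect_error(positional_pair_benchmark(window_a = c(5, 8),
                                         window_b = c(7, 9)),
               "disjoint")
})

test_that("datasets export to FASTA + TSV and read back identically", {
  ds <- simulate_dataset(simulation_config(n = 25, seed = 23))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_dataset(ds, fa, tsv)
  seqs <- read_fasta(fa)
  labs <- read_label_table(tsv, attr(ds, "label_space"))
  expect_equal(seqs$id, ds$id)
  expect_equal(seqs$sequence, ds$sequence)
  expect_true(all(purrr::map2_lgl(labs$labels, ds$labels, setequal)))
  # byte-identical on re-export of the same configuration
  ds2 <- simulate_dataset(simulation_config(n = 25, seed = 23))
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  export_dataset(ds2, fa2, tsv2)
  expect_identical(readLines(fa), readLines(fa2))
  expect_identical(readLines(tsv), readLines(tsv2))
  expect_error(export_dataset(ds[0, ], fa, tsv), "empty")
})

test_that("the bag-of-k-mers control sits at chance on positional data", {
  ds <- positional_pair_benchmark(n = 300, seed = 29)
  bl <- bag_of_kmers_baseline(ds, k = 5, seed = 1)
  expect_gt(bl$balanced_accuracy, 0.38)
  expect_lt(bl$balanced_accuracy, 0.62)
  expect_error(bag_of_kmers_baseline(tiny_records()), "two classes")
})
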