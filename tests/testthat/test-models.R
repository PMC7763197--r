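make_tiny_fit <- function(arch, scheme = "kmerPR2vec", d = 5, seed = 1,
                          recs = NULL, max_len = 8) {
  if (is.null(recs)) {
    set.seed(20)
    recs <- tibble::tibble(id = paste0("r", 1:10),
                           sequence = random_rna(10, c(15, 20)))
  }
  v <- build_vocabulary(recs, k = 3)
  fit <- mirloc:::build_fit(arch, representation_spec(scheme, emb_dim = d),
                            v, max_len = max_len, trim = "prefix",
                            label_space = mirna_label_space(),
                            pretrained = NULL, n_filters = 4, hidden = 6,
                            rnn_hidden = 3, out_activation = "sigmoid",
                            seed = seed)
  list(fit = fit, toks = encode_sequences(recs, v, max_len), recs = recs)
}

test_that("the convolution rectifies and counts positions correctly", {
  # all-zero input with all-ones filter stays at zero
  w <- matrix(1, 3 * 2, 1)
  expect_equal(conv_feature(matrix(0, 12, 2), w), matrix(0, 10, 1))
  # negative pre-activation clips to zero
  xs <- matrix(1, 4, 2)
  expect_equal(conv_feature(xs, -w, bias = 1), matrix(0, 2, 1))
  expect_equal(conv_feature(xs, w, bias = -1), matrix(5, 2, 1))
  # max_len = 12 gives 12 - 3 + 1 = 10 positions per filter
  expect_equal(nrow(conv_feature(matrix(rnorm(12 * 2), 12, 2), w)), 10)
  expect_error(conv_feature(matrix(0, 2, 2), w), "shorter")
})

test_that("forward passes emit per-label scores in (0,1) of the right shape", {
  for (arch in c("cnn", "rnn")) {
    m <- make_tiny_fit(arch)
    fw <- mirloc:::forward_pass(m$fit, m$toks$ids, m$toks$n_tokens)
    scores <- plogis(fw$logits)
    expect_equal(dim(scores), c(10, 6))
    expect_true(all(scores > 0 & scores < 1))
    # duplicated input rows produce identical score rows
    ids2 <- m$toks$ids[c(1, 1), , drop = FALSE]
    fw2 <- mirloc:::forward_pass(m$fit, ids2, m$toks$n_tokens[c(1, 1)])
    expect_equal(fw2$logits[1, ], fw2$logits[2, ])
  }
})

test_that("analytic gradients match finite differences for both heads", {
  set.seed(31)
  for (arch in c("cnn", "rnn")) {
    m <- make_tiny_fit(arch, d = 4, max_len = 6)
    ids <- m$toks$ids[1:4, , drop = FALSE]
    nt <- m$toks$n_tokens[1:4]
    y <- matrix(rbinom(24, 1, 0.4), 4, 6)
    lossfn <- function(f) {
      mirloc:::bce_from_logits(mirloc:::forward_pass(f, ids, nt)$logits, y)
    }
    fw <- mirloc:::forward_pass(m$fit, ids, nt, keep_cache = TRUE)
    gr <- mirloc:::backward_pass(m$fit, fw$cache,
                                 mirloc:::bce_grad(fw$logits, y))
    eps <- 1e-5
    for (nm in names(m$fit$params)) {
      p <- m$fit$params[[nm]]
      for (ii in sample(length(p), min(6, length(p)))) {
        f2 <- m$fit
        f2$params[[nm]][ii] <- p[ii] + eps; lp <- lossfn(f2)
        f2$params[[nm]][ii] <- p[ii] - eps; lm <- lossfn(f2)
        expect_equal(gr[[nm]][ii], (lp - lm) / (2 * eps), tolerance = 1e-4,
                     label = paste(arch, nm))
      }
    }
  }
})

test_that("parameter counts match the closed-form architecture formulas", {
  m <- make_tiny_fit("cnn", d = 5)
  V <- vocab_size(m$fit$vocab)
  d <- 5; Fn <- 4; H <- 6; Q <- 6
  expect_equal(n_parameters(m$fit),
               V * d +                       # embeddings (pad row excluded)
                 (3 * d * Fn + Fn) +         # conv filters + bias
                 ((Fn + d) * H + H) +        # dense 1
                 (H * Q + Q))                # dense 2
  r <- make_tiny_fit("rnn", d = 5)
  h <- 3
  lstm1 <- d * 4 * h + h * 4 * h + 4 * h
  lstm2 <- (2 * h) * 4 * h + h * 4 * h + 4 * h
  expect_equal(n_parameters(r$fit),
               V * d + 2 * lstm1 + 2 * lstm2 + (4 * h * Q + Q))
})

test_that("max pooling is motif-position-blind without positional fusion", {
  # two sequences identical up to the location of one motif in a homogeneous
  # background; windows never overlap other informative windows
  s1 <- paste0(strrep("A", 4), "CGUCG", strrep("A", 15))
  s2 <- paste0(strrep("A", 12), "CGUCG", strrep("A", 7))
  recs <- tibble::tibble(id = c("a", "b"), sequence = c(s1, s2))
  for (case in list(list("rand-embedding", TRUE),
                    list("kmerPR2vec", FALSE))) {
    m <- make_tiny_fit("cnn", scheme = case[[1]], recs = recs,
                       max_len = 22, d = 6)
    fw <- mirloc:::forward_pass(m$fit, m$toks$ids, m$toks$n_tokens)
    if (case[[2]]) {
      expect_equal(fw$logits[1, ], fw$logits[2, ], tolerance = 1e-12)
    } else {
      expect_gt(max(abs(fw$logits[1, ] - fw$logits[2, ])), 1e-4)
    }
  }
})

test_that("softmax inference mode normalizes rows; sigmoid does not", {
  set.seed(40)
  ds <- simulate_dataset(simulation_config(n = 12, seed = 2))
  fit <- train_model(ds, arch = "rnn", k = 3, epochs = 1,
                     learning_rate = 0.01, label_space = attr(ds, "label_space"),
                     validation_fraction = 0, out_activation = "softmax",
                     seed = 1)
  sm <- predict(fit, ds, type = "matrix")
  expect_equal(unname(rowSums(sm)), rep(1, nrow(ds)))
  fit$out_activation <- "sigmoid"
  sg <- predict(fit, ds, type = "matrix")
  expect_false(isTRUE(all.equal(rowSums(sg), rep(1, nrow(ds)))))
})

test_that("checkpoints reload byte-stably and reproduce scores", {
  set.seed(50)
  ds <- simulate_dataset(simulation_config(n = 15, seed = 4))
  fit <- train_model(ds, arch = "cnn", k = 3, epochs = 2,
                     learning_rate = 0.01,
                     label_space = attr(ds, "label_space"),
                     validation_fraction = 0, seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, f)
  fit2 <- load_model(f)
  expect_identical(fit2$params, fit$params)
  s1 <- predict(fit, ds, type = "matrix")
  s2 <- predict(fit2, ds, type = "matrix")
  expect_equal(s1, s2, tolerance = 1e-6)
  # unseen k-mers at prediction time go through <unk>, not an error
  novel <- tibble::tibble(id = "x", sequence = strrep("ACGU", 6))
  expect_silent(predict(fit, novel, type = "scores"))
})

test_that("thresholding uses the inclusive >= rule", {
  s <- rbind(c(0.9, 0.6, 0.1, 0.1, 0.1, 0.5))
  colnames(s) <- mirna_label_space()
  expect_equal(predict_labels(s, 0.5),
               list(c("exosome", "cytoplasm", "nucleus")))
  expect_equal(predict_labels(s * 0, 0.5), list(character(0)))
})
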