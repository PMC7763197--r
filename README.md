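# mirloc

Multi-label prediction of miRNA subcellular localization from positional
k-mer representations.

## The problem

Mature microRNAs (~22 nt) act in specific cellular compartments — exosomes,
cytoplasm, mitochondria, microvesicles, the circulation, the nucleus — and a
single miRNA commonly occupies several at once, so the task is multi-label:
map a 20–30-nt RNA sequence to a subset of six compartments. Because the
sequences are so short, *where* a nucleotide pattern sits carries as much
information as whether it occurs. `mirloc` is for computational biologists
who want a self-contained, CPU-only, fully reproducible implementation of a
position-aware sequence classifier together with the complete multi-label
evaluation suite and a synthetic benchmark generator that makes every stage
testable without downloading anything.

## The method

1. **Overlapping k-mer tokenization.** A sequence of length *L* becomes the
   ordered tokens *s[i..i+k−1]*, *i = 1..L−k+1* (window k = 3..10,
   stride 1); token IDs are fitted on training data with `<unk>` for unseen
   k-mers and ID 0 for padding.
2. **kmerPR2vec representation.** Each token's trainable random embedding
   (d = 120) is fused by element-wise addition with a sinusoidal positional
   encoding,

   PE(p)₂ᵢ = sin(p / 10000^(2i/d)),  PE(p)₂ᵢ₊₁ = cos(p / 10000^(2i/d)),

   with PE(0) ≡ 0 reserved for padding. Four reference schemes
   (`pre-embedding`, `rand-embedding`, `pos-encoding`,
   `pre-embedding+pos-encoding`) share the same interface.
3. **Classifiers.** A 1-D CNN (width-3 valid convolution, ReLU, global max
   pooling, conv features concatenated with mean-pooled embedding features,
   two dense layers, per-label sigmoid) and a two-layer bidirectional LSTM
   baseline whose per-layer final features are concatenated before the
   dense output. Both are trained with ADAM on mean per-label binary
   cross-entropy; forward and backward passes are hand-written vectorized
   linear algebra, verified against finite differences in the tests.
4. **Evaluation.** Nine measures: example-based accuracy (Jaccard),
   precision, recall, F1; micro- and macro-F1; label-ranking average
   precision; Hamming loss; one-vs-rest AUROC — each checked against an
   independent naive oracle to 1e−12.
5. **Protocol.** 10-fold cross-validation with a 10% validation split of
   the training folds, per-fold vocabulary fitting (no leakage), seeded
   end-to-end determinism, and an independent-test evaluator with a
   per-cardinality exact-match breakdown.

The key design point: global max pooling destroys position, so a CNN on
plain embeddings cannot tell *where* a motif sits — fusing the sinusoid in
restores that information. The package ships a generator
(`positional_pair_benchmark()`) in which position is, by construction, the
*only* signal, plus a bag-of-k-mers logistic control that provably sits at
chance on it.

## Worked example

```r
library(mirloc)

ds <- simulate_dataset(simulation_config(n = 300, seed = 1))
head(ds, 3)
#> # A tibble: 3 × 3
#>   id        sequence                    labels
#>   <chr>     <chr>                       <list>
#> 1 syn000001 AUCCGUCCCUGAGUAGAACUCGGCGA  <chr [1]>
#> 2 syn000002 ACUGAUUGCACGACGUGCCC        <chr [2]>
#> 3 syn000003 UGGGGAUAGGGCAUCCAGGACCUCCCC <chr [3]>

set.seed(2); idx <- sample(300, 60)
fit <- train_model(ds[-idx, ], arch = "cnn", scheme = "kmerPR2vec", k = 3,
                   label_space = attr(ds, "label_space"),
                   epochs = 20, learning_rate = 0.01, seed = 1)
fit
#> <mirloc_fit> CNN / kmerPR2vec  (k = 3, max_len = 28, d = 120, Q = 6)
#>   parameters: 55358; epochs trained: 20

evaluate_on_test(fit, ds[idx, ])
#> <mirloc_eval>
#> # A tibble: 1 × 9
#>   accuracy precision recall    f1 f1_micro f1_macro average_precision
#>      <dbl>     <dbl>  <dbl> <dbl>    <dbl>    <dbl>             <dbl>
#> 1    0.871     0.896  0.904 0.894    0.949    0.950             0.977
#> # ℹ 2 more variables: hamming_loss <dbl>, auroc <dbl>
#> # A tibble: 6 × 3
#>   cardinality     n n_exact
#>         <int> <int>   <int>
#> 1           1    20      14
#> 2           2    15      14
#> 3           3     9       4
#> 4           4     4       3
#> 5           5     6       5
#> 6           6     6       6
```

The metrics row reads: on the 60 held-out synthetic sequences the predicted
compartment sets overlap the true sets with mean Jaccard accuracy 0.87 and
example-F1 0.89; the pooled micro-F1 (0.95) and per-label macro-F1 (0.95)
say performance is not carried by one frequent label; average precision
0.98 means true labels are ranked near the top almost always. The
cardinality table counts exactly-correct label sets by true set size —
e.g. all 6 of the six-compartment sequences were predicted exactly.

Per-sequence scores are tibbles, ready for thresholding or ranking:

```r
predict(fit, ds[idx[1:2], ])
#> # A tibble: 2 × 7
#>   id         exosome cytoplasm mitochondrion microvesicle circulating nucleus
#>   <chr>        <dbl>     <dbl>         <dbl>        <dbl>       <dbl>   <dbl>
#> 1 syn000198 0.0165       0.999        0.998         0.847    0.998      0.998
#> 2 syn000262 0.000601     0.962        0.0449        0.263    0.000341   0.937
```

`cross_validate()` runs the full 10-fold protocol and returns per-fold and
mean metric tables with `tidy()`/`glance()`/`autoplot()` methods; real data
enter through `read_fasta()` + `read_label_table()` (or a one-hot table),
and `inst/cli/mirloc.R` exposes `simulate`, `train`, `cv`, `grid`,
`predict` and `evaluate` subcommands for shell use.

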