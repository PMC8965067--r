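# gltm

Classify 40-residue transmembrane (TM) helix fragments as dimerizing or
non-dimerizing, and localize the candidate dimerization motif — without
alignments or motif databases.

Single-pass membrane proteins dimerize through short TM sequence motifs:
the glycine zipper **GxxxG**, **polar residues** capable of interhelical
hydrogen bonds, and **leucine-zipper heptad repeats**. `gltm` implements an
attention-based global-local bidirectional LSTM: each fragment is cut into
`n` randomly placed windows of length `k`, every window is encoded as a
`(k+2) × 22` matrix (20-channel one-hot plus overlap flags and two
overlap-state rows), a shared local Bi-LSTM summarizes each window, a global
Bi-LSTM reads the window summaries, and a self-attention layer

```
A(x) = softmax(Ws2 · tanh(Ws1 · H(x)ᵀ)),   H(x) ∈ ℝ^{n×2u}
```

scores the windows. The dimer probability is `sigmoid(w · (A H) + b)`.
Training minimizes summed squared error plus `α · P(x)`, where the penalty
`P(x)` is the **self-focus** term `‖A Aᵀ − I‖²` (concentrates attention on
one window) for unannotated fragments, and the **position** term `‖S − A‖²`
for fragments with a known motif, with `S` the softmax of negative distances
between window centers and the motif center. Motifs are called by voting:
20 repeated predictions on fresh random segmentations, one vote per residue
covered by the top-attention window of each dimer-classified run, tiered
blue (≥1 vote) / orange (>5) / red (>10).

Because no machine-readable benchmark is deposited for the original model,
the package ships a synthetic planted-motif generator (524 positives /
1,413 negatives by default, hydrophobic TM-like background, exact-pattern
rejection for negatives) so the whole pipeline is trainable and testable
from code alone.

## Worked example

```r
library(gltm)

# a small planted-motif benchmark: 150 dimer / 400 non-dimer fragments
d <- simulate_dataset(sim_config(n_positive = 150, n_negative = 400, seed = 1))
set.seed(2)
test_ids  <- sample(nrow(d), 110)
test_set  <- d[test_ids, ]
rest      <- d[-test_ids, ]
set.seed(3)
val_ids   <- sample(nrow(rest), 80)   # early-stopping slice

cfg <- model_config(k = 5, n = 12, u = 32, d_a = 16, alpha = 0.5, seed = 3)
m <- train(rest[-val_ids, ], cfg,
           train_config(epochs = 100, lr = 5e-3, weight_decay = 1e-4, seed = 4),
           validation = rest[val_ids, ], keep_best = TRUE)

set.seed(5)
res <- locate_all(m, test_set, runs = 20)
cls <- evaluate_classification(
  vapply(res, `[[`, character(1), "predicted_label"), test_set$label)
unlist(cls[c("accuracy", "precision", "recall")])
#>  accuracy precision    recall
#> 0.8090909 0.6666667 0.3200000

loc <- evaluate_localization(res, test_set)
round(loc$recovery, 3)
#>    red orange   blue
#>  0.250  0.750  0.875

# localization of one true positive (R/O/B = red/orange/blue tier, . = none)
i <- which(!is.na(test_set$motif_start))[2]
test_set[i, c("sequence", "motif_start", "motif_end")]
#>                                    sequence motif_start motif_end
#> 45 MAAITKAISTFIGLVVNGIITGFGVSSGICGLALLQDNWL          23        28
print(res[[i]])
#> <gltm_localization> pos_0045: dimer (16/20 dimer votes)
#> .............BBOOOOROOOBB...............
```

The orange tier (votes > 5 of 20) reaches into the planted `GxxxG` motif at
`[23, 28)`; the recovery table shows how often each tier's region intersects
the true interval across all annotated test positives.
`evaluate_localization()` also reports the mean located-center offset and
the located-position histograms used to diagnose positional shortcut
learning. At this small training scale (360 fragments) localization is
noisy; `tests/testthat/test-acceptance.R` runs the full-scale benchmark
(524/1,413 fragments, 120 epochs with early stopping, roughly 9 minutes on
one CPU), where majority-vote accuracy reaches 0.80 and red-tier recovery
0.63. The methods vignette explains why per-view motif visibility —
especially for the 15-residue leucine heptad, which never fits inside a
length-5 window — bounds what this benchmark can reach.

## Files and formats

* FASTA for fragment sequences; tab-separated annotation tables
  (`fragment_id  label  motif_start  motif_end`, 0-based half-open).
* Localization output: TSV with one row per residue
  (`fragment_id  predicted_label  true_times  residue_index  votes  tier`).
* YAML config files (`read_config`/`write_config`); JSON checkpoints
  (`save_model`/`load_model`).
* CLI: `exec/gltm` with subcommands `simulate`, `train`, `locate`,
  `evaluate` (see `?gltm_cli`).

## Tests and acceptance report

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "gltm", load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The acceptance script recomputes the model's structural constants from
scratch — the 22-channel width of the improved one-hot encoding and the
attention vector's unit sum — and writes them as JSON.
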