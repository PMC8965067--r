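---
title: "Methods: the global-local attention model and its synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the global-local attention model and its synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-pass membrane proteins dimerize through short sequence motifs in their
transmembrane (TM) helix — the glycine zipper (GxxxG), polar residues capable
of interhelical hydrogen bonds, and leucine-zipper heptad repeats. Given a
fixed-length (40-residue) TM fragment, `gltm` answers two questions at once:
does the fragment dimerize, and which subsequence is the likely motif? The
localization comes for free from the classifier's attention weights rather
than from motif enumeration or homology search, so it can propose motifs that
are not over-represented in any database.

## Model

A fragment view is built in three steps.

1. **Random-step segmentation.** `n` windows of length `k` are placed on the
   fragment: the first at position 0, the last ending at `L`, and the `n - 2`
   interior starts drawn uniformly without replacement and sorted. Each call
   yields a different view of the same fragment, which serves simultaneously
   as data augmentation, class rebalancing (minority fragments contribute
   more views per epoch), and the randomness that the voting localizer
   averages over.

2. **Overlap-aware one-hot encoding.** Each window becomes a `(k + 2) x 22`
   matrix: `k` residue rows carrying a 20-channel one-hot plus two overlap
   flags (channel 20: position shared with the previous window, channel 21:
   with the next), and two window-state rows carrying the normalized overlap
   counts `|overlap| / k`. Because consecutive windows usually overlap, the
   overlap channels give the network a chain of relative-offset information
   linking neighbouring windows.

3. **Hierarchy + attention.** A shared bidirectional LSTM (u units per
   direction) reads each window's rows — by default the overlap-state row
   first in each direction, so repeated-residue information is consumed
   before the residues — and emits a `2u` summary. A second bidirectional
   LSTM reads the `n` summaries in order, producing the hidden-state matrix
   `H` (`n x 2u`). The annotation vector is

   `A = softmax(Ws2 tanh(Ws1 H^T))`,

   a probability distribution over windows. The context vector `A H` is
   mapped by a learned linear head to a scalar logit and a sigmoid
   probability of the dimer class (threshold 0.5). The original GLTM formulation writes
   the classifier as `sigmoid(A H)` without an output projection; since the
   label is a scalar and `A H` is a `2u` vector, a learned linear map with
   bias is the minimal completion, and that is what this package implements.

## Training objective and penalties

Training minimizes summed squared error — kept as squared error rather than
cross-entropy for fidelity to the original GLTM objective — plus a penalty on
the attention vector weighted by `alpha`:

* **Self-focus** (no motif annotation): `||A A^T - I||_F^2`, which for a
  `1 x n` vector is `(sum(A_i^2) - 1)^2`; minimized exactly when `A` is
  one-hot. It forces the model to commit to a single window.
* **Position** (annotated motif): `||S - A||^2`, where `S` is the softmax of
  negative distances between window centers and the motif center
  (`s_i ∝ exp(c - |cen_i - l|)`). The constant `c` cancels algebraically
  between numerator and denominator; it defaults to 0 and is exposed only
  because the original formula names it.

The routing is decided by the presence of the annotation, not by the class
label: a positive fragment lacking a motif annotation is penalized with the
self-focus term.

Window centers are `start + (k - 1)/2`, so even `k` gives half-integral
centers; the motif center is the interval midpoint `(start + end)/2`.
Distances are never rounded. Ties in the nearest window produce equal scores,
which the softmax handles naturally; argmax ties in the localizer are broken
toward the lowest window index for determinism.

## Optimization choices

The original GLTM description fixes the objective but not the optimizer. This
package uses Adam (rate 5e-3 in the worked examples, 1e-3 as the
conservative default), minibatches of 32, gradients averaged within a batch,
and decoupled weight decay (AdamW). Weight decay matters here: each training
fragment is seen under many random segmentations, and without regularization
the network memorizes fragment identities instead of motif patterns (train
loss keeps falling while held-out accuracy degrades). Every epoch re-segments
every fragment afresh. All gradients are analytic (verified against central
finite differences to better than 1e-4 relative error); training aborts with
a diagnostic if the loss becomes non-finite.

Early stopping is available in its simplest form: when a validation set is
supplied, `train(..., keep_best = TRUE)` returns the parameters of the epoch
with the highest validation accuracy. On the synthetic benchmark the
held-out accuracy peaks well before the loss stops falling, so the
full-scale experiments carve a 15% validation slice out of the training
fragments and keep the best epoch.

The penalty weight `alpha` is not fixed by the original GLTM description.
The package default is a conservative 0.1; the full-scale acceptance
experiment uses `alpha = 0.5`, chosen during development because stronger
attention supervision pays off twice — the position penalty teaches the
network where the decisive pattern is, which improves both the features the
classifier sees and the red-tier recovery rate. The acceptance test prints
the accuracy and recovery it measures at this setting.

Parameter initialization is Glorot-scaled normal with LSTM forget-gate
biases at 1. The local layer's sweep order ("state rows first") is a config
option (`sweep`), since the original description of how repeat-residue
information is "preferentially accepted" admits more than one reading.

## Voting localization

A trained model predicts a fragment 20 times (configurable `runs`), each time
on a fresh random segmentation. In every run classified as dimer, the
residues covered by the highest-attention window each gain one vote. Votes
are accumulated per residue — not per window identity — because the residue
index is the only coordinate system stable across random segmentations.
Tiers follow the GLTM thresholds out of 20 total runs: blue for at least
one vote, orange for more than five, red for more than ten. The fragment's
label is the majority vote; `true_times` counts runs matching the known
label.

## The synthetic benchmark

No machine-readable benchmark accompanies the original GLTM model, so the
package generates one. The generator's world is fixed once:

* 524 positives and 1,413 negatives of length 40, matching the reference
  benchmark's class ratio.
* Background residues drawn i.i.d. from a hydrophobic-biased distribution
  (L 0.15, V 0.12, I 0.115, A 0.10, F 0.08, G 0.08 — together 0.645 —
  with the rest of the mass spread over the remaining 14 residues), a
  deliberate idealization of TM-helix composition.
* Each positive carries exactly one planted motif — template drawn uniformly
  from `GxxxG`, `NxxxN` (polar pair one helix turn apart) and
  `LxxxxxxLxxxxxxL` (leucine heptad) — at a uniform admissible position,
  with wildcards refilled from the background.
* Negatives are rejection-sampled until they contain no template's exact
  pattern. Rejection is exact-pattern only: near-motifs (GxxxA, lone
  asparagines, two spaced leucines) remain, keeping the task non-trivial.

What a green test on this benchmark establishes: the architecture, the
penalties and the voting procedure can learn and localize planted patterns
of the three motif families from hydrophobic background at the original
class ratio. What it does not establish: performance on real Membranome
fragments, where negatives are real TM helices with correlated composition,
orthologous redundancy and no guarantee of motif absence; nor any claim of
biological dimerization.

Two features of the benchmark are worth flagging when reading results. A
`k = 5` window fully contains a GxxxG occurrence only when a window start
coincides with the motif start (probability about 1/3 per view), so much of
the usable evidence is split across overlapping windows; and the heptad
motif (15 residues) never fits in one window at all, so its detection rests
entirely on the global layer integrating across windows. Both make the
synthetic task intrinsically harder per view than a fixed-frame motif scan,
and they bound what majority voting can deliver.

## Numerical choices and degenerate inputs

* Softmaxes are computed with max-shift stabilization.
* `position_scores` refuses unannotated fragments (the annotation-empty
  branch of the penalty is the self-focus term, not a zero position term).
* Precision with zero predicted positives is reported as 0 with a warning;
  empty evaluation input is an error.
* Segmentation requires `L - k >= n - 1`; infeasible combinations error with
  the constraint spelled out.
* The uniformity diagnostic for positional shortcut learning (chi-square of
  located positions of non-dimer fragments) is computed over interior-window
  picks only: the first and last windows are pinned by design, so their pick
  rates reflect the sampling scheme, not the model. Under a positionally
  unbiased model the interior argmax start is exactly uniform.
* Checkpoints are JSON (all weights plus the full configuration) so they are
  portable and diffable; no binary formats.

## Known limitations

* The squared-error objective saturates more easily than cross-entropy;
  learning is slower than a modern classifier head would be, by design.
* Window spacing between non-overlapping windows is invisible to the model
  (only overlaps are encoded), limiting recovery of long-range spacing
  patterns such as the heptad.
* The chi-square uniformity check is extremely powerful at the default
  sample size (hundreds of counts per bin); small but real positional
  preferences of a trained network are detectable and will fail it even when
  the located-position histogram looks visually flat.
* Training at the benchmark scale takes minutes on one CPU; the package is
  not built for GPU-scale corpora.
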