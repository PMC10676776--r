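---
title: "Predicting and designing replication origins with oriforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and designing replication origins with oriforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriforge)
```

## The problem

Origins of replication (ORIs) are the genomic loci where DNA replication
initiates. Experimentally mapped human ORIs vary widely in length (hundreds
to thousands of base pairs), which is awkward for most sequence classifiers:
truncating to a fixed window can destroy the very elements that make an
origin fire. `oriforge` addresses this with a *length-invariant* encoding:
whatever the sequence length, it is summarized into a fixed-dimension vector
of Z-curve composition parameters, which a neural classifier then scores.
The trained classifier in turn serves as the fitness function of a genetic
algorithm (GA) that evolves artificial origin-like sequences from scratch.

## The Z-curve encoding

The Z-curve represents a DNA sequence through three base-class contrasts:

* `x = (A + G) - (C + T)` — purine vs pyrimidine,
* `y = (A + C) - (G + T)` — amino vs keto,
* `z = (A + T) - (G + C)` — weak vs strong hydrogen bonding,

where the letters are occurrence counts. Phase structure is captured by
splitting the sequence into three subsequences (bases at positions 1, 4,
7, ...; 2, 5, 8, ...; 3, 6, 9, ...) and computing the same contrasts per
phase, giving 3 phase-free + 9 phase-specific = 12 mononucleotide
parameters. Replacing single bases with di- and trinucleotides (the
contrasts applied to the final base of every k-mer within each preceding
context) contributes 48 and 192 further parameters. The seven admissible
family combinations therefore span Z-spaces of dimension 12, 48, 60, 192,
204, 240 and 252; the full 252-dimensional space is the package default.

Two conventions are fixed here and documented because the encoding order is
otherwise arbitrary:

* **Normalization** (default on): every count difference is divided by the
  number of counted windows of its (subsequence, k) pair, so components lie
  in \[-1, 1\] and sequences of different lengths are directly comparable.
  Raw counts remain available (`normalize = FALSE`); they are what the
  brute-force oracle tests check exactly.
* **Component order**: families mono → di → tri; within a family the
  phase-free block then phases 1–3; within a block, contexts in
  lexicographic order with axes x, y, z. Column names such as `tri.s2.GC.y`
  make the layout explicit.

Sequences must be pure A/C/G/T — ambiguity codes have no defined Z
coordinates and are rejected (the CLI can drop such records with a logged
warning). The shortest encodable sequence for a family with word length k is
3k bases, so that every phase subsequence admits at least one window; with
the full configuration that means 9 bp. Shorter input is an error, not a
silent zero-pad. Phase-specific k-mers for k ≥ 2 are counted *within* each
phase subsequence (i.e. between bases three positions apart in the original
sequence), the reading most consistent with the mononucleotide definition;
this is one of the genuinely open conventions and is frozen here.

## The classifier

The model stacks three *structure blocks* — self-attention →
1-D convolution → ELU → average pooling → nearest-neighbour up-sampling —
followed by an MLP head ending in a sigmoid. Attention is single-head
scaled dot-product, `softmax(QK^T / sqrt(d_k)) V`, with
`d_k = d_v = conv_channels`. The up-sampling factor equals the pooling
width, so each block preserves the token-sequence length and blocks can be
stacked freely.

How a flat feature vector enters a token-based pipeline is not dictated by
the architecture itself, so the package picks the grouping that respects the
encoding's structure: each (family, phase, context) triple becomes one
token whose three channels are the x/y/z axes. Every admissible dimension D
is divisible by 3, giving L = D/3 tokens (84 for the full space). Besides
being the natural grouping, it keeps the attention maps (L × L) small
enough to train briskly on one CPU; treating each scalar component as its
own token would make them nine times larger for no representational gain.

Defaults, all exposed in `classifier_config()`:

| parameter | default | note |
|---|---|---|
| `n_blocks` | 3 | the published block count |
| `conv_channels` | 8 | channel width; also attention `d_k`, `d_v` |
| `conv_kernel` | 3 | same-padding 1-D convolution |
| `pool_size` | 2 | up-sampling factor is tied to it |
| `elu_alpha` | 1.0 | the standard ELU scale |
| `mlp_hidden` | 64, 16 | small dense head |
| `attention` | TRUE | FALSE gives the ablation variant |

Training (`train_config()`) uses Adam at learning rate 0.0002 with batch
size 64 — the published optimization hyperparameters — minimizing binary
cross-entropy with predictions clamped to \[1e-7, 1 - 1e-7\]. Early
stopping keeps the parameters of the best validation epoch (patience 10).
Forward, backward and the optimizer are implemented directly in R matrix
code; the backward pass is verified against finite differences in the test
suite, and all randomness (initialization, shuffling, splits) derives from
the configured seed, so runs are bit-reproducible.

**Problem sizes.** The package's benchmark-scale runs (tests and the
acceptance script) train on 2000 sequences with 500 held out, capping
`max_epochs` at 30: on this synthetic task the validation loss plateaus
after roughly 15–25 epochs (held-out AUC is stable from the first epochs),
so longer schedules buy nothing but wall-clock time. Smaller illustrative
fits in the unit tests use reduced blocks/channels and a faster learning
rate.

## Evaluation

ACC and MCC are computed at threshold 0.5 (the sigmoid-symmetric default;
MCC returns 0 whenever a denominator factor vanishes) and AUC by the
Mann–Whitney formulation with half-credit ties. `cross_validate()` runs
stratified k-fold CV (default k = 10): per fold, the model trains on the
remaining parts with an inner stratified 90/10 split for early stopping.
Folds are stratified so that small fixture datasets cannot produce
single-class folds. `cross_cell_line_experiment()` compares per-dataset
models against a model trained on the pooled union, and
`cell_line_discrimination()` is the negative control: it relabels the
positive sequences of two datasets by their dataset of origin and tries to
tell them apart — for identically distributed pseudo-cell-lines this sits
at chance, mirroring the finding that origins from different cell lines are
not separable after Z-curve encoding. (With more than two lines the
pairwise binary version of this control is used; the model's head is
binary by design.)

## The genetic algorithm

`evolve()` starts from `pop_size` homopolymers (1000 bp of A or of G),
applies four mutation modes — single-base substitution, single-base
insertion, single-base deletion, and segment reversal as the
length/composition-preserving realization of "structural variation" — and
selects by truncation (top half), with the whole survivor set passing
unmutated, which implies elitism: the best individual is never lost and the
maximum fitness is monotone. Offspring apply each mode independently with
its configured per-offspring rate; insertions/deletions that would cross
the hard length bounds are skipped rather than failed, so the population
cannot collapse. The run terminates when the *minimum* population fitness
exceeds the threshold (default 0.5) or the generation budget runs out.
There is no crossover — only the four mutation modes are specified — and
ties in selection break by original index, which keeps constant-fitness
populations stable and runs reproducible.

One dose parameter deserves explanation: `point_events` (default 10), the
number of single-base substitutions applied when the point mode fires. With
literally one substitution per offspring, a 1000-bp all-A population needs
~450 *selected* GC-raising substitutions to reach the GC levels where an
origin classifier responds, which cannot happen within any reasonable
generation budget; ten substitutions per offspring (1% of the initial
sequence) keeps single generations local while letting composition evolve
in ~100 generations.

### What termination implies for the final population

Because the run stops the moment the worst individual clears the fitness
threshold, the final population sits *at* the threshold contour of the
fitness landscape, not at its optimum. A truncation-selected population is
cohesive (individuals are within a mutation dose or two of each other), so
its mean trails the contour by only ~0.01 in GC terms. Two consequences,
both visible in the shipped analyses and worth knowing before comparing to
the 50–60% GC band reported for evolved origins:

* Under the toy objective `1 - |GC - 0.55| * 4` the fitness-0.5 contour is
  at GC 0.425, so evolution from all-A reliably stops with mean GC ≈ 0.43 —
  just *below* a 0.45–0.65 window around the optimum. Reaching the optimum
  would require either a stricter threshold or termination on the mean
  rather than the minimum; the package keeps the minimum-fitness rule.
* With the trained classifier as fitness, the 0.5-probability contour for
  motif-free candidates sits at GC ≈ 0.495 under the default synthetic
  conditions — the statistically correct boundary, since genome-like
  negatives reach up to ≈ 0.52 and positive support starts at 0.50 — so
  evolved populations stop with mean GC ≈ 0.49, at the lower edge of the
  positives' band rather than inside it. Where the boundary lies is a
  property of the training data, not of the GA.

## Synthetic fixtures

The generator emulates the compositional structure of the real benchmark so
that everything above is testable without downloads:

* **ORI-like positives**: per-sequence GC target uniform in 0.50–0.60, hit
  exactly up to rounding (the planted motifs' composition is accounted
  for), with 3 non-overlapping copies of the GC-rich 9-mer `GGGCGGGGC` —
  evocative of the GC-box/zinc-finger motifs enriched in real origins, with
  no claim of biological fidelity.
* **Genome-like negatives** (default): per-sequence GC from a beta
  distribution with mean 0.40 and concentration 80 (SD ≈ 0.055, so ~±0.10
  spread), bases i.i.d. given that GC — mimicking AT-biased genomic
  background without shipping a genome.
* **Uniform-random negatives** (option): i.i.d. uniform bases, GC
  concentrated near 0.50.

Lengths are uniform in 300–3000 bp and classes are balanced by default.
What the fixtures deliberately do *not* model: positional motif grammar,
epigenetic context, repeat structure, chromosome-scale composition waves.
Passing tests on fixtures therefore demonstrate that the pipeline learns
and exploits compositional signal end to end — not that it would reach any
particular AUC on real benchmark data.

## Numerical choices and limitations

* Attention softmax subtracts row maxima before exponentiation; ELU and
  BCE use the exact closed forms with clamping only inside the loss.
* MCC's zero-denominator convention is 0; AUC errors on single-class input.
* GC histogram bins are right-closed deciles, `(0.1(i-1), 0.1 i]`, with
  GC = 0 assigned to the first bin.
* "Cosine distance" in the origin-analysis literature is used with
  similarity orientation (1 = alike); the package names it
  `cosine_similarity()` accordingly, and set-level similarity averages all
  cross pairs (centroid comparison is available as an option).
* 2-D embeddings (LLE, t-SNE) are visualization wrappers delegating to
  scikit-learn through the `python` on the PATH; the manifold algorithms
  are intentionally not reimplemented.
* Training is CPU-bound pure R; it is sized for thousands of sequences and
  the 252-dimensional space, not for genome-scale scans. The model predicts
  for whole presented sequences; sliding-window genome scanning is out of
  scope.
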