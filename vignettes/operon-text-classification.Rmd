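---
title: "Operon prediction from textual gene-pair descriptions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operon prediction from textual gene-pair descriptions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operotext)
```

## The model

`operotext` treats operon prediction as binary classification of adjacent
gene pairs: for two neighbouring genes on one contig, decide whether they are
transcribed as part of the same operon. Instead of a fixed feature vector,
each pair is rendered as a deterministic natural-language paragraph and the
paragraph is classified. The serialization template is fixed:

> Gene A is {length_A} bp long, annotated as '{function_A}', and is part of
> the {family_A} family. It is followed by Gene B, {length_B} bp long,
> annotated as '{function_B}', and is part of the {family_B} family. The
> intergenic distance is {distance} base pairs. The GC content difference is
> {gc_diff}%. They are on the {strand_orientation} strand. They are adjacent
> in {adjacency_percent}% of representative genomes.

Numerical values are inserted directly, without discretization. A
`feature_mask()` removes whole clauses or sentences: the functional
annotation clauses, the protein-family clauses, the conservation sentence,
and the optional appended STRING sentence ("STRING reports a combined
interaction score of {score} between these genes."). The four baseline
features — lengths, intergenic distance, GC difference, strand orientation —
can never be masked. An empty annotation string drops its clause exactly as a
mask would, rather than fabricating a placeholder annotation.

The underlying biological assumptions are the classical ones: genes of one
operon lie on one strand, are separated by short (often negative,
i.e. overlapping) intergenic gaps, share compositional properties such as GC
content, and their protein families tend to be adjacent across many genomes
because the gene order of operons is evolutionarily conserved.

## Features

All coordinates are 1-based inclusive throughout (the convention of GFF3 and
the BV-BRC features.tab dialect), so no internal conversion can introduce
off-by-one errors in distances.

* **Gene length**: `end − start + 1` bp.
* **Intergenic distance**: `start_B − end_A − 1` bp, signed; 0 for abutting
  genes and negative for overlaps, which are common inside operons and are
  serialized as negative integers.
* **Strand orientation**: `"same"` / `"opposite"`. The template sentence is
  filled with the bare adjective so it reads grammatically.
* **GC difference**: GC% is computed on each annotated gene span of the
  forward contig sequence (G+C is strand-symmetric) counting only unambiguous
  A/C/G/T; the feature is the absolute difference, rounded to 2 decimals. The
  absolute value is used because the template prints a single non-negative
  number.
* **Adjacency conservation**: an `adjacency_index` built over a genome panel
  records, for every unordered pair of protein families with non-empty
  identifiers, the set of genomes in which the pair occurs adjacently at
  least once. The feature is `100 × |presence| / panel_size`, rounded to 1
  decimal. The denominator is the full panel size by default, matching the
  sentence "adjacent in X% of representative genomes"; a `"shared"`
  denominator (genomes containing both families) is available as an option.
* **STRING score**: consumed from a user-supplied table keyed on ordered gene
  id pairs with fallback to the reversed key; absent scores simply omit the
  sentence.

Fixed rounding (2 decimals for GC, 1 for conservation, trailing-zero-free
formatting for all numbers) makes serialization byte-deterministic, which the
test suite relies on.

## Dataset construction

Positives are the consecutive gene pairs inside each multi-gene annotated
operon (an operon of *k* genes yields *k − 1* positives). Negatives pair the
terminal gene of **each** annotated operon — including single-gene operons —
with its immediately adjacent downstream genomic neighbour outside the
operon. "Downstream" follows transcription: for a forward-strand terminal
gene the neighbour with the next-higher start, for a reverse-strand gene the
next-lower. This yields genomically adjacent negatives with realistic context
rather than trivially distant ones. A pair labeled by both rules (shared
operon boundaries) is kept once with the operonic label. No class balancing
is performed; curated operon-pair collections are already near-balanced, and
the synthetic generator's default mean operon size of 2 reproduces that
balance (expected positives per operon `k − 1 ≈ 1`, negatives `≈ 1`).

Benchmark-style test sets can be formed with `intersect_operons()`, which
keeps operons whose gene sets are confirmed in two independent annotation
sources.

## Training protocol

`train_classifier()` implements one fixed protocol regardless of backbone:
binary cross-entropy minimized with AdamW (decoupled weight decay 0.01),
mini-batches of 32 over a seeded shuffle, an optional linear-decay schedule,
at most 10 epochs with evaluation and checkpointing at every epoch end, and
post-hoc selection of the checkpoint with minimum validation loss (earliest
epoch on ties — validation loss is used because it is the quantity the
optimizer targets and is threshold-free). Early stopping is deliberately not
used: the epoch budget is fixed and selection happens after the fact. All
randomness flows from `classifier_config(seed=)`, so a fixed seed gives
bit-identical training runs.

The shipped backbone, `bow-linear`, scores a paragraph by a linear function
of its token counts. The tokenizer splits words and signed numbers and, by
default, decomposes each numeral into magnitude subtokens (sign, digit count,
leading digit × order of magnitude). This mirrors what byte-pair subword
tokenization gives an encoder model: an unseen value such as a 327 bp gap
still activates "3-digit, leading 3" features seen in training, so numeric
magnitude generalizes beyond exact token matches. Out-of-vocabulary tokens
at prediction time are ignored.

Two learning-rate regimes matter. The config default (3e-5) is the standard
fine-tuning step size for a large pretrained encoder and is kept as the
package default for fidelity to that protocol. A linear model trained from
zero initialization needs a larger step to reach a useful margin within the
10-epoch budget; all evaluation examples, tests and the acceptance script
therefore pass `learning_rate = 0.1`, chosen once as a standard Adam step
size for shallow models and not revisited. `max_tokens` defaults to 512;
`tokenize_audit()` reports the maximum tokenized length and how many inputs
would truncate (none do for the shipped template, whose paragraphs stay
around 60–100 tokens).

The decision threshold on the operonic probability is fixed at 0.5 for all
reported metrics; it is a config field but is never tuned.

## Evaluation regimes

* **LOSO** (`run_loso`): each genome in turn is held out entirely; the
  remaining pairs are split 90/10 into train/validation by a seeded,
  genome-stratified draw (stratification keeps every training genome
  represented in validation; the validation count equals
  `round(0.1 × n)` exactly via largest-remainder quotas). Held-out pairs
  never influence training or model selection.
* **Mixed split** (`random_split` + `run_ablation`): all pairs pooled and cut
  80/10/10 after a seeded shuffle — a conventional baseline without
  genome-level separation.
* **Ablation** (`run_ablation`): six masks from baseline to
  baseline+function+conservation+family+STRING, every mask trained and
  evaluated on the same seeded split so differences reflect features, not
  partitioning.
* **Resilience** (`run_resilience`): one model trained on the full
  non-STRING configuration scores the test set re-serialized under
  progressively reduced masks (none / −family / −function,family /
  −function,family,conservation). No retraining occurs; the protocol rejects
  STRING-trained models, whose decision boundary depends on a signal that
  vanishes under removal.
* **Metrics** (`binary_metrics`): sensitivity, specificity, precision, F1,
  accuracy, and PR-AUC as step-function average precision of the operonic
  class with tie grouping and no interpolation (the estimator is specified
  here because interpolated variants are not comparable).

`chain_operons()` assembles operon calls by taking maximal runs of
consecutive positive pair predictions on one contig, additionally breaking
runs at strand changes — a pairwise classifier can emit a positive for an
opposite-strand pair, but an operon is a single-strand structure, so such
pairs terminate a call. Singleton genes are never reported as operons.

## The synthetic panel generator

`generate_panel()` emulates exactly the statistical structure the features
exploit, and nothing else. A shared pool of operon *archetypes* (family
sequence, functions, GC level, size drawn as 1 + Geometric with mean 2) is
instantiated per genome with probability `p_conserved_adjacency` (default
0.75), in shuffled order, so operonic family pairs recur adjacently across
genomes while boundary pairs do not — this plants the conservation signal.
Within an operon, genes share a strand and a GC level (per-gene noise sd 3
percentage points) and are separated by gaps drawn uniformly from
[−10, 80] bp; operon boundaries carry gaps from [100, 400] bp and flip strand
with probability 0.5. Gene lengths are uniform on [200, 1500] bp. Contig
sequences are a neutral random backbone overwritten by GC-controlled gene
spans. Emulated STRING scores draw from [700, 999] for operonic and [0, 299]
for non-operonic pairs.

With `null_signal = TRUE` every class-conditional rule is removed: one shared
gap distribution for both classes, per-gene random families, functions and
GC, fully overlapping score ranges, and constant strands. Strands are held
constant rather than randomized for a non-obvious reason: the boundary
negative rule is strand-aware, and with random strands a terminal gene whose
strand points back into its own operon emits no negative, which skews the
class prior to roughly 60/40 and lets a classifier score above 50% by prior
alone. With constant strands the control is genuinely null — balanced prior,
no informative feature — and trained models sit at chance.

What the generator does **not** emulate: realistic sequence evolution, codon
usage, promoter/terminator motifs, annotation errors, fragmented assemblies,
or operons interleaved with non-coding features. Tests passing on synthetic
panels therefore demonstrate that the pipeline recovers the feature signals
it models, under its own assumptions — not that real-genome accuracy will
match; real evaluations require curated operon annotations.

## Numerical and degenerate-input choices

* Sorting ties (identical starts) break by `(start, end, gene_id)`, so pair
  order is deterministic; fully nested genes still participate in adjacency.
* Genes with empty family identifiers never enter the adjacency index and
  query to 0% conservation; an empty panel, a single-class training set, a
  held-out genome absent from the data, and a one-class metrics input all
  raise typed errors rather than returning degenerate numbers.
* `gc_percent` on a sequence with no unambiguous bases is an error, not 0.
* Probabilities are clipped at 1e-12 inside the cross-entropy only.
* Splitting uses `round()` for the validation count and contiguous slicing,
  so partition sizes are exact and reproducible.

## Scale of the shipped analyses

The test suite and `scripts/acceptance.R` run on 3-genome panels of ~240
genes each (about 650 labeled pairs, vocabularies of ~1300 tokens), chosen so
a full LOSO + ablation + resilience pass completes in well under a minute on
one CPU while leaving every class-conditional signal measurable. Larger
panels only sharpen the same estimates.

## Known limitations

* The transformer backbone named in `classifier_config()` is a protocol
  specification here; this package ships and tests the `bow-linear` backbone
  and raises an informative error for encoder backbones, which require a
  deep-learning runtime. The training loop, checkpoint selection, masks,
  splits and metrics are backbone-independent.
* A linear bag-of-tokens model degrades gracefully when a strong feature is
  removed at inference (its remaining weights still carry signal); it does
  not reproduce the catastrophic collapse a fine-tuned encoder can show under
  feature-distribution shift. The STRING-removal comparison in the acceptance
  suite reports the measured drop for both training regimes.
* Operon structure is treated as static and binary; condition-specific
  transcriptional units are out of scope, as are circular-contig wraparound
  pairs and cross-database gene-identifier resolution.
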