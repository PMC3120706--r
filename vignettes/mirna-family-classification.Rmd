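---
title: "Alignment-free miRNA family classification: model, protocols and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free miRNA family classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgram)
```

## The model

`mirgram` assigns miRNA precursor or mature sequences to families using
only primary sequence. The underlying assumption is biological: members of
a curated miRNA family descend from a common ancestor and therefore share
short-word (n-gram) usage, even where an alignment would struggle — across
length differences, small indels, or scattered substitutions.

### Feature space

For each selected type $n$, a window of size $n$ slides 5'→3' along the
sequence and the occurrence count $t_j$ of every encountered $n$-gram is
recorded; $T_i$ denotes the total count of type-$i$ windows. With the four
RNA bases there are $4^n$ unique grams of type $n$; the default types
$\{1,2,3,4\}$ give a $4+16+64+256 = 340$-dimensional space. Each type is
weighted by its *concentration*
$$C_i = \frac{4^i}{\sum_k 4^k},$$
the fraction of the vocabulary contributed by type $i$ (the sum runs over
the selected types, so restricted runs are self-normalizing; e.g.
$C_3 = 64/340 \approx 0.188$ under the default, $64/84$ for types 1–3).
The feature value of gram $j$ of type $i$ is
$$x_{ij} = C_i \, \frac{t_j}{T_i},$$
so each type block sums to $C_i$ and the full vector sums to 1 whenever
every selected type has at least one countable window. Blocks are laid out
longest type first, lexicographically (A < C < G < U) within a type.

The rationale for the weighting is that longer words are more informative
(a trigram is a codon-sized unit; a tetragram more specific still).
Empirically the weighting shifts cross-family center variance into the
long-gram blocks — `weighting_variance_shares()` computes this directly,
and the test suite asserts that on families built from disjoint trigram
pools the trigram share of center variance strictly increases under
weighting while the unigram share shrinks.

### Classifier

One-vs-all linear max-margin classification: for $M$ families, $M$ binary
soft-margin linear SVMs are fitted (family $i$ as positives, the rest as
negatives) and reduced to explicit affine decision functions
$F_i(x) = w_i \cdot x + b_i$. A query is assigned to
$\arg\max_i F_i(x)$; exact ties go to the lexicographically smallest
label, so predictions are reproducible across platforms. The binary fits
are delegated to libsvm (via `e1071`) with a linear kernel and
`scale = FALSE`: the concentration weighting *is* the intended feature
scaling, and per-feature standardization would silently undo it.

A joint multiclass max-margin formulation would be a reasonable
alternative; on these low-dimensional, nearly separable feature vectors
the two coincide in practice, and the one-vs-all scheme has the simpler,
more transparent contract (each $F_i$ is independently interpretable).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `types` | `1:4` | n-gram sizes; 340 dimensions. Types 1–3 (84 dims) suffice for well-separated problems and train faster. |
| `cost` (c) | 1.0 | SVM trade-off between training error and margin. Defaults to 1; on separable synthetic data results are insensitive to it over several orders of magnitude. |
| `k` | 5 | cross-validation folds. |
| `seed` | 42 | governs every random operation (fold assignment, generators); recorded in reports and logs. |

Noise handling: letters outside A/C/G/U are retained at I/O time (so
records with ambiguity codes are classifiable), and any window containing
such a letter is skipped entirely — it contributes to neither $t_j$ nor
$T_i$. This choice preserves the sum-to-1 property and makes a handful of
noise bases perturb the vector only marginally: a single base change in a
length-100 sequence alters at most $2n$ window counts per type, bounding
the L1 change of the vector by
$\sum_i C_i \cdot 2n_i / T_i \approx 0.08$ under the default types.
A type whose $T_i$ is zero (sequence shorter than $n$, or all windows
noisy) contributes an all-zero block rather than an error, so degenerate
inputs do not crash batch runs; matures (~22 nt) always have $T_4 > 0$.

## Evaluation protocols

* **Metrics** (percent scale): $SE = 100\,TP/(TP+FN)$,
  $SP = 100\,TN/(TN+FP)$, $Acc = 100\,(TP+TN)/\text{all}$. A zero
  denominator raises a typed condition instead of returning 0 — silent
  zeros corrupt averages.
* **Stratified k-fold CV**: folds are disjoint, cover the dataset, differ
  in size by at most 1, and each family's per-fold counts differ by at
  most 1. Stratification is per family (proportional allocation), the
  natural generalization of positive/negative ratio preservation to
  multi-family data. Each family's surplus members go to the currently
  smallest folds, processed in sorted family order, so a seed fully
  determines the partition. A leakage guard asserts on every run that the
  union of test folds is the dataset exactly once. The reported mean
  accuracy is the example-weighted mean of fold accuracies, i.e. the
  pooled accuracy.
* **Small-family split**: families with at least $k$ members contribute a
  stratified $1/k$ fraction to the test side; smaller families (down to 2
  members) contribute exactly one randomly chosen member. Single-member
  families are rejected — they cannot appear on both sides.
* **Training-size sweep**: the data is cut into ten stratified parts;
  round $f$ trains on the first $10f$ parts (cumulative, so training sets
  are nested) and tests on the rest, for $f \in \{0.1,\dots,0.5\}$.
  Cumulative rather than re-drawn partitions isolate the effect of
  training-set *size* from partition noise.

## Synthetic data

The generators produce every benchmark input in code, as pure functions
of an integer seed (byte-identical FASTA across repeated calls):

* `reverse_sequences()` — plain 5'→3' string reversal, **without**
  complementation. Reversal preserves length and composition exactly, so
  the reversed set is a composition-identical negative that differs only
  in word order; `complement = TRUE` is exposed for users who want the
  reverse complement instead.
* `random_matched_composition()` — i.i.d. sequences drawn from the
  reference's pooled mononucleotide frequencies, lengths uniform over the
  reference's length range. Matching is order-0 by design;
  `shuffle_dinucleotide()` provides the stricter order-1 null (an
  Eulerian-walk shuffle preserving exact dinucleotide counts).
* `generate_families()` — one random ancestor per family; members are
  i.i.d. mutated copies (substitution to a uniformly chosen different
  base with rate $s$; deletion or single-base insertion with rate $r/2$
  each). Defaults — 10 families × 20 members, 80 nt ancestors,
  $s = 0.10$, $r = 0.02$ — give within-family identity around 90%,
  comparable to a mid-sized curated family collection, and are the
  conditions under which the end-to-end recovery tests run.
* `trigram_pool_families()` — ancestors concatenated from disjoint
  per-family trigram pools; the controlled setting for the weighting
  analysis.

What the generators emulate is the *shared-ancestor* structure of real
families and the standard negative-control designs. What they do not
emulate: hairpin secondary structure and its constraint on base
composition along the stem, phylogenetic (tree-structured) relatedness
within families, between-family homology, and the sequence statistics of
hard real negatives such as snoRNAs. Passing the synthetic benchmarks
therefore demonstrates that the feature space and classifier recover
common-descent signal at realistic divergence levels — not that any
particular accuracy will be attained on a specific curated database.

## Numerical choices and problem sizes

* Vector normalization is checked to 1e-9 (at most 340 double additions);
  vocabulary concentration sums to 1 within 1e-12.
* Fold/test sizes in the shipped tests: recovery tests use 10 families ×
  20 members over 5 seeds; binary discrimination uses 100 + 100 sequences
  at 5% substitution; the permutation null uses 2 × 50 sequences and a
  binomial 95% band at that n; the sweep compares 10% vs 50% training
  fractions over 10 seeds. These sizes give stable Monte-Carlo behavior
  while keeping a full test run in the low minutes on one CPU.
* Model files are versioned JSON with a magic header; the vocabulary
  signature (types + dimension) is stored and verified at load and
  predict time, turning silent dimension mismatches into typed
  compatibility errors.

## Known limitations

* Strand-directional features: no reverse-complement folding of k-mers —
  the windows run 5'→3' on the given strand, which is the correct
  convention for RNA but means DNA input on the wrong strand will not
  match.
* The one-vs-all scheme trains $M$ binary models; for thousands of
  families training cost grows linearly in $M$ (prediction is a single
  matrix product).
* Families are assumed internally cohesive in n-gram space; a family
  whose members share only structure (not sequence) will not be captured
  by any primary-sequence method, this one included.
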