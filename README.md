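# mirgram

Alignment-free assignment of microRNA sequences to families.

## The problem

Curated miRNA family systems group precursor (~70 nt hairpin) and mature
(~22 nt) sequences that descend from a common ancestor. Assigning a newly
discovered miRNA to its family is traditionally done by BLAST-seeded
clustering plus manual multiple-sequence-alignment curation — slow, and
sensitive to alignment parameters. `mirgram` instead treats family
assignment as supervised classification on primary sequence alone: it
needs no alignment, no secondary-structure prediction, and no assumption
about sequence length, and it tolerates noise bases (SNPs, sequencing
errors, IUPAC ambiguity codes) gracefully.

## The method

**Features.** A window of size *n* slides 5'→3' along the sequence for each
selected type *n* (by default unigrams through tetragrams). With the four
RNA bases there are 4^*n* unique *n*-grams of type *n*, so the default
feature space has 4 + 16 + 64 + 256 = **340 dimensions**, laid out from
tetragrams down to unigrams and lexicographically (A &lt; C &lt; G &lt; U)
within a type. Each type is weighted by its *concentration*

C_i = 4^i / Σ_k 4^k  (sum over the selected types),

e.g. C_tri = 64/340 ≈ 0.188, and the feature value of gram *j* of type *i*
is

x_ij = C_i · t_j / T_i,

where t_j is the window count of gram *j* and T_i the total count of
type-*i* windows. The entries of a feature vector sum to 1. The
concentration factor makes the longer, more informative grams dominate the
vector, which visibly increases the between-family variance of the
long-gram blocks (see `weighting_variance_shares()`).

**Classifier.** One-vs-all linear max-margin classification: for M
families, M binary soft-margin linear SVMs F_i are fitted (family *i*
positive, all others negative; trade-off parameter *c*, default 1.0), and
a query *x* is assigned to argmax_i F_i(x), ties going to the
lexicographically smallest label.

**Evaluation.** Sensitivity, specificity and accuracy on the percent
scale (SE = 100·TP/(TP+FN), SP = 100·TN/(TN+FP),
Acc = 100·(TP+TN)/all); stratified k-fold cross-validation (default
k = 5); a small-family protocol that holds out exactly one member of each
family with fewer than k members; and a cumulative training-size sweep
(10%…50% of the data for training).

**Synthetic controls.** Everything needed to benchmark the pipeline is
generated in code: 5'→3' reversed positives, random sequences with matched
base composition (plus a stricter dinucleotide-preserving shuffle), and
mutation-derived families descending from random ancestors.

## Worked example

```r
library(mirgram)

# three synthetic families, 20 members each, 5% substitution rate
ds <- generate_families(n_families = 3, members_per_family = 20,
                        substitution_rate = 0.05, seed = 7)
ds
#> <mir_seqs> 60 sequence(s), 3 families, lengths 78-82 nt

v <- build_vocabulary(1:4)
v
#> <ngram_vocab> types {1,2,3,4}, 340 dimensions
#> concentrations: C_4 = 256/340, C_3 = 64/340, C_2 = 16/340, C_1 = 4/340

x <- featurize(ds$bases[1], v)
sum(x)
#> [1] 1

cross_validate(ds, vocab = v, k = 5, seed = 7)
#> <cv_report> 5 fold(s), mean accuracy 100.00%
#>   fold n_test accuracy
#> 1    1     12      100
#> 2    2     12      100
#> 3    3     12      100
#> 4    4     12      100
#> 5    5     12      100
```

Each of the five folds holds out 12 sequences (4 per family); every
held-out sequence is assigned back to the family whose mutated ancestor it
descends from, so the pooled mean accuracy is 100%. At higher mutation
rates, or with the concentration weighting disabled
(`featurize_dataset(..., weighted = FALSE)`), accuracy degrades — the test
suite quantifies both effects.

The same workflows are scriptable from a shell through the installed CLI
wrapper (`system.file("cli", "mirgram", package = "mirgram")`), which
exposes five verbs: `featurize`, `train`, `predict`, `cv`, `synth`.

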