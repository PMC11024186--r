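---
title: "Semi-supervised topic modelling of microbiome profiles with randomized feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised topic modelling of microbiome profiles with randomized feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfslda)
```

## The model

`rfslda` classifies subjects into health-status groups from a subjects ×
taxa table of 16S read counts. The central assumption is the LDA
mixed-membership model: a small number `T` of latent *sub-communities*
(topics) exist, each a probability distribution `β_t` over taxa, and each
subject's gut is a personal mixture `θ_d` of them. Generatively, for
subject *d*: a total read count `N_d ~ Poisson(λ)`, topic proportions
`θ_d ~ Dirichlet(α)` (symmetric), and for each read a topic
`z ~ Mult(θ_d)` followed by a taxon `w ~ Mult(β_z)`. Because the counts
are observed, `N_d` is ancillary to `θ` and `β` and plays no role in
estimation; the Poisson law lives only in the simulator.

Health-status labels are deliberately kept out of the fit. They are fuzzy
(self-reported), so they are used only *after* clustering, to choose the
interpretation of the topics: every bijection between the `T` topics and
the `C = T` levels is enumerated and scored by the weighted accuracy
`A_w = Σ_t w_t · TPR_t`, and the best-scoring bijection wins. Prior
knowledge ("topic 1 cannot be healthy") enters as per-topic admissible
sets that shrink the enumeration. A confusion-matrix convention is fixed
package-wide: **columns index true classes, rows predicted classes**, so
`TPR_t` is the diagonal over the column sum. Weighted precision, which the
evaluation layer also reports, is defined symmetrically over row sums with
`0/0 → 0`; it is the only self-consistent analogue of the recall-based
metric.

## Estimation

The model is estimated by collapsed Gibbs sampling written for this
package (C++ via Rcpp): the topic indicator of every read is resampled
from its collapsed conditional, and `θ`, `β` are reported as posterior
means averaged over post-burn-in sweeps, with symmetric Dirichlet
smoothing (`α` on `θ`, `η = 0.1` on `β`) so no probability is ever zero
and perplexity stays finite. The sampler owns a private `mt19937_64`
stream, so a seed reproduces a fit bit-for-bit regardless of R's RNG
state. The per-sweep joint log-likelihood is recorded; it climbs from the
random initialisation and is stationary after burn-in (asserted in the
tests). Defaults are 300 sweeps with 150 burn-in; the feature-search
scorer uses 150/75, where topic *identification* (not tight posterior
means) is what the score needs.

Two standard variational conventions are kept even though the estimator is
a sampler: `α` defaults to `50/T`, and `α` is treated as fixed rather than
estimated — hyperparameter estimation inside a collapsed sampler is a
different algorithm, and every downstream layer consumes only `θ` and
`β`.

Held-out subjects are *folded in*: `β` is frozen and only `θ` is
estimated, by per-subject EM on the multinomial mixture with the same
Dirichlet posterior-mean smoothing. This is deterministic and matches the
training-side estimates to within a few percent total variation on refits
(tested). Perplexity is `exp(−log L / N)` with `log L` summed over reads
under each subject's mixture; it selects `T` when the user has no a
priori `C` to match.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `T` | 3 | latent sub-communities; matched 1:1 to label levels |
| `K` | 50 | taxa kept by the concordance filter (rest → "Others") |
| `ω` | 0.001 | detection threshold (relative abundance) for prevalence |
| `w` | (0.6, 0.15, 0.25) | class weights of `A_w`, in level order |
| `λ` (similarity) | 0.7 | "Predominantly" threshold on the top topic proportion |
| `α` | `50/T` | Dirichlet concentration of `θ` |
| `η` | 0.1 | Dirichlet smoothing of `β` |
| `c, p, t0, u, R` | 1, `⌈n/2⌉`, 1e-4, 0.5, 50 | feature-search move size, start size, improvement tolerance, stay probability, restarts |

`ω` is a conventional microbiome detection threshold (0.1% relative
abundance) and is exposed because reasonable studies differ on it. The
stay probability `u` of the search is a genuinely open choice; 0.5 is the
least-informative coin and is configurable. `p = n/2` is rounded *up* for
odd feature spaces (with `n = 51` the convention must be fixed one way;
up keeps the start closer to the full model).

## Taxon pre-filtering

Taxa are summarised by abundance `𝒜_ℓ` (column sums of the row-proportion
matrix, so `Σ 𝒜_ℓ = M`) and prevalence `𝒫_ℓ` (subjects at or above `ω`).
The filter keeps the `K` taxa whose abundance and prevalence rankings
agree best: taxa are ordered by descending rank-sum, then
backward-eliminated from the tail — at each step dropping the tail-most
taxon whose removal raises the within-set Kendall tau (the plain tail
taxon when none does) — until `K` remain. This surrogate is deterministic
(rank ties break by taxon name) and is verified against exhaustive
subset search on small fixtures. Concordance-based tau-path procedures in
the literature differ in detail; the function is a plug-in point, and a
per-class variant (filter within each class, union the picks) is exposed
as a config flag. Aggregation of the dropped taxa into "Others" conserves
per-subject totals exactly (integer equality, tested).

## The feature search

The search walks over subsets of the `B₀ = K + 1` post-filter features.
Each move flips an unbiased three-sided coin: swap `c` features (size
preserved), remove `c`, or add `c`; sides whose result would leave
`[1, n]` are redrawn among the feasible sides. A strictly better `A_w`
always moves; otherwise the walk stays with probability `u`. A run stops
when the best score has not improved by more than `t0` for 100 consecutive
moves (hard cap 2000), and `R` restarts guard against initialisation
sensitivity — the winner is the highest-scoring restart, ties to the
lowest index. Scores are cached by subset: the scorer is deterministic
(the LDA refit seed is held fixed across subsets, so subsets are compared
on equal footing), and the refit dominates cost. Subsets that silence all
reads of some subject are unfittable and score `-Inf` rather than
aborting the walk. Dropped features are excluded outright, not
re-aggregated into "Others": the search operates downstream of the
aggregation step, on the already-reduced feature space.

## Class balancing

For a balanced re-analysis the SCUT hybrid is provided: minority classes
are SMOTE-oversampled (each synthetic row lies on the segment between a
class row and one of its `k = 5` nearest same-class neighbours, `δ ~
U(0,1)`, rounded to non-negative integers for count semantics; `k` clamps
to `size − 1` for tiny classes), and majority classes are undersampled by
seeded k-means into `target` sub-clusters keeping the rows nearest each
centre — at least one per sub-cluster, so the class's spread survives.
The default per-class target `round(M/C)` turns (66, 6, 17) into
30 + 30 + 30 = 90. SMOTE operates on raw counts by default; a
`proportions` mode interpolates compositions instead and rescales by the
class's median depth, for users who consider depth a nuisance. Balancing
sits after taxon filtering (the balanced table keeps the `B₀` columns),
and every synthetic row records its seed row, neighbour and `δ`.

## Evaluation protocol

Train/test discipline: LDA fitting, matching, and feature selection see
training subjects only; test subjects are folded in against the frozen
`β`, hard-assigned, and pushed through the *trained* matching. The
stratified split uses per-class floor rounding — `floor(0.8 · n_c)` per
class — which is the unique convention sending an 89-subject cohort with
classes (66, 6, 17) to a 69/20 split; k-fold assignment deals shuffled
classes round-robin, giving 18-subject folds on 90 subjects at `k = 5`. A
class absent from a training fold leaves its recall undefined and is an
error rather than a silent skip.

## The simulator and what passing tests mean

`generate_corpus()` draws exactly from the generative process above, plus
three real-data features: class imbalance (subjects are rejection-sampled
until the dominant-topic layout matches a prescribed class-size vector),
label noise (each label flips to a uniformly random other level with
probability `ρ`), and zero-inflation (cells are zeroed independently with
probability `π₀` after generation — the fitted model is *not*
zero-inflated, so this stresses robustness; a row never loses its last
read). The study-shaped preset is `M = 89`, `B = 109`, `T = 3`, class
sizes (66, 6, 17), depth `λ = 5000`, `π₀ = 0.3`. Topic separation uses a
block structure with 70% own-block mass (pairwise total variation ≥ 0.7
between topics); the generated data has no phylogenetic correlation among
taxa, no overdispersion beyond the mixture itself, and its label noise is
uniform rather than structured — so passing tests demonstrate the
machinery is correct under the model's own assumptions, not that real
fuzzy labels behave this well.

The feature-search benchmark plants 5 informative taxa and 10 distractors
whose mass is identical under every topic. It uses `T = 5` topics with
one signature taxon each, so that *every* informative taxon is
individually necessary for full accuracy; with fewer topics than
informative taxa a subset of them can already saturate the score and
"recovering all informative taxa" would not be a well-posed target. The
recovery tests demand ≥ 4 of 5 planted taxa in ≥ 16 of 20 seeded runs.

## Numerical choices and degenerate inputs

Hard topic assignment breaks ties toward the lowest topic index — also
for the second-highest topic in similarity labels, and exactly at the
`λ` threshold the "Predominantly" branch wins (`≥`, not `>`). Zero-total
subjects are rejected by name everywhere (proportions, fitting, fold-in).
`β` renormalisation after averaging guards floating drift; row sums are
asserted to 1e-8. All stochastic stages derive child seeds from one
master seed via a small multiplicative hash (kept below 2^31), so the
pipeline report is byte-identical across reruns and stages can be
re-executed in isolation. Test problem sizes are chosen to exercise each
property at the smallest scale where it is informative: recovery suites
use `M = 200` subjects at depth 500, search benchmarks `M = 50` at depth
150 with 150/75 and 100/50 Gibbs sweeps respectively.

## Known limitations

- The matching layer requires `T = C`; unequal topic/level counts would
  need injective (not bijective) matchings and are out of scope.
- `α` is fixed, not estimated; users with strong prior beliefs about
  mixing sharpness should set it.
- The concordance filter is a documented surrogate for tau-path ranking;
  its selections may differ from other published concordance procedures.
- Weighted accuracies from tiny classes (the 6-subject infection class)
  rest on very few subjects per cell; the class weights, not the package,
  decide how much that matters.
- SMOTE on raw counts ignores compositionality; the `proportions` mode is
  provided but neither mode models sequencing depth explicitly.
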