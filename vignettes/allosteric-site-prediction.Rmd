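---
title: "Predicting allosteric pockets from FPocket descriptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting allosteric pockets from FPocket descriptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopocket)
```

## The problem

Allosteric modulators bind proteins at sites distinct from the active site
and regulate activity through conformational or dynamical change. Finding
candidate allosteric sites on a structure is a ranking problem over its
surface pockets: a geometry-based detector (FPocket) enumerates pockets
and scores their general small-molecule binding capacity, and the question
is which of those pockets — often 20 or more per protein, almost all of
them negative — is the allosteric one.

`allopocket` treats this as supervised tabular classification. Each pocket
is described by FPocket's 19 per-pocket descriptors (pocket score,
druggability score, SASA terms, volume, hydrophobicity and polarity
scores, alpha-sphere geometry, flexibility, ...). A model maps the
descriptor vector to a probability that the pocket is allosteric; pockets
are then both *classified* (probability above a threshold) and *ranked*
(per protein, by descending probability).

## Reference predictor

Pocket scores already carry signal: in curated allosteric benchmarks the
top-scored pocket is the allosteric one for roughly 70% of proteins. The
package therefore ships a baseline — predict the rank-1 pocket positive
and every other pocket negative (`baseline_predict()`). Any trained model
must beat this baseline either in classifying power or in ranking power
to be worth deploying; on the reference confusion matrix of 144/60/107/4844
(TP/FP/FN/TN) the baseline scores accuracy 0.968, precision 0.706, recall
0.574, F1 0.633.

## Labeling schemes

Ground-truth labels come from the bound modulator in the structure, under
two schemes mirroring how curated databases annotate sites:

* **Contact** (`label_by_contact()`): a pocket is positive iff it contains
  at least one residue with a heavy atom within a cutoff of any modulator
  heavy atom. Several pockets may be positive. The default cutoff is
  4.5 Å — the conventional heavy-atom ligand-contact threshold; it is a
  user-facing parameter because annotation conventions differ.
* **Closest centroid** (`label_by_centroid()`): exactly one pocket is
  positive — the one whose centroid is nearest the modulator's heavy-atom
  centroid. The pocket centroid is the mean of its alpha-sphere vertex
  centers, because the vertices trace the cavity interior; when vertices
  are unavailable the mean of the pocket's residue atoms is used instead
  (logged). Exact distance ties break toward the better FPocket rank and
  are warned about.

Which HETATM groups count as modulators is operationalized as "every
HETATM residue group not on an exclusion list" (waters, common ions,
cryoprotectants); the list is an argument of `extract_modulators()`, and
an explicit residue list can be passed when a database's own annotations
should be reproduced exactly.

## Class imbalance and the rank cutoff

About 1 pocket in 20 is positive, which starves most learners of
minority examples. Over-sampling synthesizes pockets that are not
biologically meaningful, so the package under-samples instead, exploiting
the score-rank structure of the data: positives concentrate at good
FPocket ranks, so keeping only each *training* protein's top-k pockets
(`apply_cutoff()`, default k = 6) raises the positive rate seen by the
learner several-fold while discarding mostly easy negatives. Two details
matter:

* the cutoff applies only to training proteins — validation and test
  proteins are always evaluated on *all* their pockets;
* the cutoff is applied after labeling, so a positive ranked worse than k
  is genuinely dropped from training; the count of such drops is recorded
  on the returned object.

Splitting (`split_proteins()`) is uniform at the protein level — pockets
of one protein never straddle splits.

## The ensemble

`train_ensemble()` fits a portfolio of heterogeneous tabular classifiers —
gradient-boosted trees, random forest, extremely randomized trees,
elastic-net logistic regression, k-nearest neighbours, and a shallow
feed-forward network — each with k-fold bagging (default k = 5,
stratified): k models per learner, each trained on k−1 folds, with
out-of-fold probabilities collected on the held-out fold. Predictions of
a bagged learner are the mean over its k fold models.

The learners are combined by greedy forward selection with replacement:
starting from the single best learner, repeatedly add the learner whose
inclusion in the running average most improves out-of-fold F1 at the
decision threshold, stopping when no addition helps. Selection counts
become the ensemble weights (non-negative, summing to 1). Because the
first pick is the best single learner and additions are kept only on
improvement, the ensemble's out-of-fold F1 is never below the best
single learner's — a property the test suite asserts.

F1 is the selection objective because it is the quantity the cutoff
position itself is tuned against, balancing precision and recall on data
that remain imbalanced even after under-sampling. The decision threshold
defaults to 0.5 and is strict: a probability of exactly 0.5 is negative.
Class weighting is deliberately not used — imbalance is handled by the
cutoff mechanism alone, so the two mechanisms are never confounded.

Everything is deterministic under the config seed: fold assignment,
each learner's internal randomness (single-threaded tree learners,
seeded initializations), and hence every probability. `cmd_train()` run
twice with the same inputs and seed produces byte-identical evaluation
reports.

## Evaluation

Classifying power pools all pockets into one confusion matrix
(`confusion()`, `metrics()`): accuracy, precision = TP/(TP+FP), recall =
TP/(TP+FN), F1 = harmonic mean. Zero denominators yield 0 with a
`degenerate` flag rather than an error, so aggregation over independent
runs (`aggregate_runs()`, sample mean and n−1 SD) never aborts on a
pathological run.

Ranking power (`ranking_power()`) asks, per protein, whether any truly
positive pocket sits within the top k when pockets are sorted by
descending predicted probability; ties break by the better FPocket rank
(deterministic, and it favors the geometrically stronger pocket).
Proteins in which no positive pocket exists are excluded from the
denominator and counted separately. Top-k probabilities are reported for
k = 1, 2, 3.

## The synthetic benchmark

Real curated structures cannot ship with the package, so
`generate_feature_dataset()` builds datasets with the statistical
structure the pipeline assumes, with every planted truth recorded in a
manifest. Defaults describe the benchmark conditions the package is
designed around:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 204 | proteins per dataset |
| `pocket_min/max/mean` | 4 / 91 / 25 | truncated negative binomial (size 2) fitted so the truncated mean is 25 |
| `positive_rate` | 0.0487 | expected overall fraction of positive pockets |
| `top1_enrichment` | 0.706 | probability the primary positive has score rank 1 |
| `signal_strength` | 0.35 | class-conditional descriptor separation, in [0, 1] |

Each protein gets one guaranteed positive pocket; extra positives are
added with the per-pocket probability that makes the expected overall
rate hit `positive_rate`. The primary positive sits at score rank 1 with
probability `top1_enrichment`, otherwise uniformly among the remaining
ranks. Descriptors are class-conditional Gaussians with shared
(diagonal) covariance and a mean shift on six descriptors scaled so the
total Mahalanobis separation is 12·`signal_strength`: at 1 the classes
are separable for practical purposes (Bayes error ≪ 10⁻⁶), at 0 the
labels are independent of the descriptors. The default 0.35 (separation
≈ 4.2, Bayes error ≈ 2%) yields imperfect separability, so that default
datasets exercise the interesting regime where the model must trade
precision against recall rather than memorize a separable rule.

Two deliberate design points:

* **Null datasets.** "No signal" must mean *no* feature is informative.
  Because the score column is a descriptor too, `top1_enrichment = NA`
  (uniform positive rank) accompanies `signal_strength = 0` in null
  configurations; otherwise the score-rank association alone would give a
  model real, not hallucinated, skill and a no-skill check would be
  meaningless.
* **Substreams.** All randomness flows from one master seed through a
  per-protein substream, so protein i is identical whether the dataset
  has 10 proteins or 10,000 — single proteins are reproducible in
  isolation.

`generate_geometric_protein()` adds a geometric fidelity: toy structures
with spatially separated residue clusters (18 Å apart), alpha-sphere
vertices at each cluster, and a HETATM modulator placed within 3.5 Å of
one designated cluster and more than 8 Å from all others, emitted as a
PDB file plus an FPocket-style output directory. By construction the
contact and centroid schemes agree on exactly the designated pocket,
which gives an end-to-end cross-scheme consistency check through the real
parsers.

What the synthetic data do **not** model: correlations among real FPocket
descriptors (columns are independent given the class), physically
realistic protein geometry, multiple modulators per structure, and
proteins whose allosteric pocket FPocket fails to detect. Passing tests
therefore demonstrate that the machinery is correct under the stated
statistical structure, not that the trained toy models transfer to real
structures — training on real FPocket output is what `cmd_train()` is for.

## Numerical and procedural choices

* Score ties in FPocket ranking break by ascending pocket index
  (FPocket's own output order); ranking-power values depend on this, so
  it is fixed and tested.
* Missing descriptors are imputed with per-column training medians,
  persisted inside the model bundle and reused at prediction time.
* Altloc records resolve to the highest-occupancy conformer, ties to
  altloc 'A'; chain filtering keeps HETATMs of all chains unless a strict
  flag is set, because modulators frequently sit on their own chain.
* Probabilities in the JSON prediction API are percentages rounded
  half-even to 2 decimals.
* The bagging fold count is capped at the minority-class count; training
  refuses single-class labels outright.

## Problem sizes used by the shipped tests

The test suite exercises the full protocol at desk scale: 20-seed
benchmark repetitions on 204-protein datasets for the strong-signal
property (out-of-fold F1 and top-1 ranking against the 0.706 baseline,
pooled one-sided binomial test at α = 0.01), 10 seeds of 40-protein null
datasets for the no-skill property, 200 geometric proteins for
cross-scheme agreement, and 1,000 random profiles for the ranking-power
oracle. These sizes give the binomial tests comfortable power while the
whole suite runs in a few minutes on one CPU.

## Known limitations

* FPocket is consumed, never run or re-implemented; structures whose
  allosteric site FPocket misses are invisible to the whole pipeline.
* The 19-descriptor schema is configurable but fixed per model; mixing
  FPocket versions with renamed fields relies on the built-in synonym map.
* mmCIF input, structure repair, and resolution/sequence-identity
  filtering of input sets are out of scope.
* The centroid scheme generalizes to several modulators by OR-ing one
  positive per modulator; curated single-site annotations should use the
  contact scheme with an explicit residue list when exact reproduction is
  required.
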