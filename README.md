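# allopocket

Allosteric site prediction from FPocket pocket descriptors, for
structural bioinformaticians and allosteric-drug-discovery groups who
need to triage which of a protein's surface pockets is likely to bind an
allosteric modulator.

## What it does

An allosteric modulator binds a protein away from the active site and
regulates its activity. Geometry-based pocket detectors (FPocket)
enumerate a structure's surface pockets — typically dozens per protein,
of which at most a couple are allosteric — and score each pocket's
general small-molecule binding capacity. `allopocket` turns this into a
supervised prediction problem:

1. **Parse** PDB structures (`read_structure`) and FPocket output
   directories (`parse_fpocket_dir`) into pocket records carrying the 19
   FPocket descriptors, residues, and alpha-sphere centers.
2. **Label** pockets against the bound modulator, either by residue
   contact (positive iff a pocket residue has a heavy atom within 4.5 Å
   of a modulator heavy atom; several positives allowed) or by closest
   centroid (exactly one positive: the pocket whose centroid is nearest
   the modulator centroid).
3. **Under-sample** the heavily imbalanced training data (~1 positive in
   20 pockets) by keeping only each training protein's top-k pockets by
   pocket score (default k = 6) — validation/test proteins keep all
   pockets.
4. **Train** a bagged, greedily weighted ensemble of tabular classifiers
   (gradient-boosted trees, random forest, extra trees, elastic-net
   logistic regression, k-NN, shallow MLP) with 5-fold bagging; ensemble
   weights maximize out-of-fold F1 at the 0.5 decision threshold.
5. **Evaluate** classifying power — accuracy, precision = TP/(TP+FP),
   recall = TP/(TP+FN), F1 = 2PR/(P+R), pooled over pockets — and
   ranking power: the fraction of proteins whose true allosteric pocket
   appears in the top k (k = 1, 2, 3) by predicted probability.

The reference baseline predicts each protein's top-scored pocket
positive and everything else negative; on the reference benchmark
confusion matrix (TP 144, FP 60, FN 107, TN 4844) it scores accuracy
0.968, precision 0.706, recall 0.574, F1 0.633. A useful trained model
must beat it in classifying or ranking power.

A synthetic-benchmark generator (`generate_feature_dataset`,
`generate_geometric_protein`) reproduces the statistical structure of
curated allosteric benchmarks — 204 proteins, 4–91 pockets each (mean
25), 4.87% positives, top-1 score enrichment 70.6% — with full planted
ground truth, at both feature-table and geometric (PDB + FPocket-style
files) fidelity.

## Worked example

Simulate a 60-protein benchmark, train with 3 independent runs, and
query one toy protein through the JSON prediction API:

```r
library(allopocket)

bundle <- cmd_simulate("demo_bundle", generator_config(n_proteins = 60, seed = 7),
                       n_geometric = 1)
tab <- read_feature_table(bundle$features_csv)
sprintf("pockets: %d  positives: %d (%.2f%%)", nrow(tab), sum(tab$label),
        100 * mean(tab$label))
#> "pockets: 1572  positives: 75 (4.77%)"

base <- baseline_evaluate(table_to_sets(tab))
sprintf("baseline top-1: %.3f  F1: %.3f", base$top1_rate, base$metrics$f1)
#> "baseline top-1: 0.683  F1: 0.607"

cmd_train(bundle$features_csv, "demo_model.rds", "demo_report.json",
          seed = 1, runs = 3, cutoff = 6)
rep <- jsonlite::read_json("demo_report.json", simplifyVector = TRUE)
sprintf("ensemble F1 (validation, mean +/- sd over 3 runs): %.3f +/- %.3f",
        rep$aggregate$mean$f1, rep$aggregate$sd$f1)
#> "ensemble F1 (validation, mean +/- sd over 3 runs): 0.912 +/- 0.024"
sprintf("ranking power top-1/2/3: %.2f / %.2f / %.2f",
        rep$ranking$mean$top1, rep$ranking$mean$top2, rep$ranking$mean$top3)
#> "ranking power top-1/2/3: 1.00 / 1.00 / 1.00"

g <- bundle$geometric[[1]]
cmd_predict(g$pdb_path, g$fpocket_dir, "demo_model.rds", top = 3)
```

```json
{
  "protein": "GEO001",
  "chain": "",
  "model": "ensemble",
  "pockets": [
    {
      "pocket": 3,
      "probability": 4.76,
      "residues": ["A9 ALA", "A10 ALA", "A11 ALA", "A12 ALA"]
    },
    {
      "pocket": 1,
      "probability": 1.93,
      "residues": ["A1 ALA", "A2 ALA", "A3 ALA", "A4 ALA"]
    },
    {
      "pocket": 5,
      "probability": 1.22,
      "residues": ["A17 ALA", "A18 ALA", "A19 ALA", "A20 ALA"]
    }
  ]
}
```

The 1572 pockets and 4.77% positive rate realize the configured
benchmark statistics; the baseline's 68.3% top-1 rate recovers the
planted 70.6% enrichment within binomial noise. The ensemble lifts
validation F1 from the baseline's 0.607 to 0.912 ± 0.024 and ranks the
true pocket first for every validation protein at this (default) signal
strength. In the JSON response, probabilities are percentages (2
decimals) and pockets are sorted by descending probability — the model
tags pocket 3, the cluster the modulator was planted next to, as the top
candidate. (The percentages are small because a toy geometric protein's
descriptors are drawn class-blind; the ordering, not the calibration, is
the point of this fixture.)

A thin shell dispatcher over the same functions is installed at
`inst/cli/allopocket.R`
(`Rscript inst/cli/allopocket.R predict <pdb> <fpocket_dir> <model>`).

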