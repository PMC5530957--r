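# bpac

Supervised prediction of **bound transcription factor (TF) binding
sites** from chromatin accessibility data (DNase-Seq / ATAC-Seq), and
assessment of how well such models **transfer** across TFs and cell
types.

A PWM scan of a genome yields many candidate motif matches; only a
fraction are occupied in any given cell type. `bpac` scans a genome with
a log-odds PWM at an exact p-value cutoff (default `1e-4`, computed from
the exact discretized null score distribution), describes every
candidate site with 11 features, and trains a random forest (100 trees,
`round(sqrt(k))` features per split) against ChIP-Seq peak overlap as
the bound/unbound label:

- **static features** — PWM score, mean phastCons conservation,
  distance to the nearest TSS;
- **dynamic features** — per-base read- and cut-profile means at the
  site and its two site-length flanks, and the footprint score
  `fp = (upstream + downstream + pseudocount) / (at_site + pseudocount)`
  for both profiles (`fp > 1`: classic footprint; `fp < 1`: inverse).

Evaluation is by ROC AUC and precision–recall AUPR, implemented from
first principles (tie-collapsed thresholds; trapezoidal AUC equal to the
Mann–Whitney statistic; average-precision AUPR). A scenario layer runs
**self** (2/3–1/3 split), **cross-TF**, **multi-TF**, **cross-cell** and
**mixed** predictions with a strict train/test leakage guard, plus a
sweep over the number of training TFs.

Everything is testable without downloads: a synthetic-data module
generates a genome with planted motif instances, decoy matches,
peak calls, a conservation track, TSS annotation and accessibility reads
exhibiting the observed footprint morphologies (footprint / flat /
inverse / mixed) with known ground truth.

## Worked example

```r
library(bpac)

cfg <- simulation_config(genome_length = 5e5, n_sites = 150,
                         n_decoys = 150, seed = 7,
                         tf = "TF1", cell = "cellA")
sim <- simulate_dataset(cfg)       # simulate + scan + features + labels
sim$dataset
#> labeled_dataset TF1 @ cellA: 324 sites, 69 bound (prevalence 0.213)

parts <- split_self(sim$dataset, seed = 1)       # 2/3 train, 1/3 test
model <- train_model(parts$train, model_config(seed = 1))
evaluate_scores(predict_scores(model, parts$test), parts$test$labels,
                scenario = "self")
#> eval_result [self]: AUC 1.0000, AUPR 1.0000 (27 pos / 81 neg)

static <- train_model(parts$train,
                      model_config(features = static_features(), seed = 1))
evaluate_scores(predict_scores(static, parts$test), parts$test$labels,
                scenario = "self")
#> eval_result [self]: AUC 0.7106, AUPR 0.5088 (27 pos / 81 neg)
```

The 324 candidate sites are every genomic window passing the `1e-4` PWM
cutoff (planted instances, decoys and a few chance matches); 69 overlap
an emitted peak and are therefore bound. The held-out AUC of 1 says the
forest fully recovers the planted accessibility-to-binding rule at this
depth; the static-only model is much weaker (AUC 0.71), mirroring the
qualitative ordering seen on real data.

The same pipeline is scriptable from a shell via the bundled entry
point (`exec/bpac`): `simulate`, `scan`, `features`, `train`, `predict`,
`evaluate`, `scenarios` subcommands, each writing a run manifest with
input digests and seeds.

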