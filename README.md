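# snapqsar

Image-based QSAR modeling from multi-angle 3D molecular snapshots.

## What it does, and for whom

`snapqsar` is for computational toxicologists and cheminformaticians who
want to model agonist/antagonist bioassay activity (e.g. nuclear-receptor
screens of the Tox21 kind) *without* molecular descriptors: each compound
is turned into a single 3D ball-and-stick conformer, photographed from a
deterministic grid of rotations, and the snapshot images are classified
by a convolutional network. The whole chain — activity normalization,
labeling, splitting, 3D embedding, rendering, training, evaluation — runs
sequentially from one config file as one unit.

The core quantities:

- **Percent activity** `= 100 · (V_compound − V_dmso) / (V_pos − V_dmso)`,
  banded into inactive (0), inconclusive ((0,40)) and active ([40,100]);
  the binary label is `score ≥ 40`.
- **Viewpoint grid**: per axis `{k·θ : k ≥ 0, k·θ < 360}`, so the number
  of snapshots per molecule is `∏ ceiling(360/θ)` — 8 images at
  θ = 195°, 27 at 176°, 64 at 95°.
- **Evaluation**: Youden-cutoff confusion table and
  sensitivity, specificity, BAC = (sens+spec)/2, Acc, precision, F,
  MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
  ROC AUC (Mann–Whitney) and PR AUC (average precision), averaged over
  N = 3 seeded replicates; early stopping keeps the epoch with minimum
  validation loss within a 30-epoch budget.

A seedable toy-assay generator provides offline test data in which the
active class carries a dibromoaryl marker — a structural signal that is
visible in the rendered image — so the entire pipeline is testable
without any external download.

## Requirements and installation

R (≥ 4.3) with `png`, `yaml`, `jsonlite`, plus a system `python` with
RDKit on the PATH (used only for SMILES parsing/canonicalization and
ETKDG 3D embedding; everything else is native R).

```sh
R CMD INSTALL .
# test suite
Rscript -e 'testthat::test_dir("tests/testthat", package = "snapqsar", load_package = "installed")'
```

## Worked example

```r
library(snapqsar)
options(snapqsar.quiet = TRUE)

cfg <- list(
  data   = list(toy = list(n = 30, prevalence = 0.25, seed = 0),
                ratios = c(1, 1, 1), seed = 1),
  render = list(theta = c(195, 195, 195), image_size = 256,
                background = "white"),
  train  = list(learning_rate = 1e-3, batch_size = 8, max_epochs = 30,
                seed = 0, replicate_count = 1, input_size = 32),
  output = list(dir = "run")
)
rec <- run_all(cfg)
print(rec)
```

```
<run_record 8badbac6 >
  prepare    run     0.01s
  conformers run     1.02s
  snapshots  run    13.80s
  train      run    41.20s
  valid    ROC_AUC 1.000  BAC 1.000  MCC 1.000
  test     ROC_AUC 0.750  BAC 0.750  MCC 0.408
```

30 toy molecules (8 active) were normalized, split 1:1:1 (10/10/10,
stratified: 2–3 actives per split), embedded, rendered at 8 viewpoints
each (240 PNGs), and a small CNN was trained with 30-epoch early
stopping. The report lines are molecule-level metrics on the validation
and test splits at the Youden cutoff: the model ranks the validation
actives perfectly and generalizes imperfectly to the 10-molecule test
split (ROC AUC 0.750 — 3 actives, so every misranking costs a third of a
point) after about a minute of CPU work. This is a wiring check, not a
toxicology claim; see the methods vignette for what the toy signal does
and does not establish. Rerunning the same config reuses every cached
stage and reproduces identical metrics.

Individual stages are exported too — `percent_activity()`,
`classify_activity()`, `split_dataset()`, `smiles_to_conformer()`,
`write_sdf()`/`read_sdf()`, `enumerate_viewpoints()`,
`render_snapshot()`, `generate_snapshots()`, `train_model()`,
`evaluate_split()`, `metric_report()`, `run_sweep()` — and a CLI lives at
`inst/cli/snapqsar` (`snapqsar run-all --config cfg.yaml --seed 1`).

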