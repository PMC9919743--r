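# wristfall

Fall detection from wrist-worn tri-axial accelerometers, for researchers
building or evaluating smartwatch-based fall alerting: a small LSTM
classifier over sliding windows of the acceleration stream, a
layer-freezing transfer-learning protocol that adapts a model trained on
one device's large dataset to another device's small dataset, and
dual-wrist ensemble fusion. Because labeled fall recordings are scarce and
hard to share, the package includes a synthetic signal generator that
emulates the structure of such datasets (per-subject fall and
activity-of-daily-living trials on profiled devices at 32 or 50 Hz), so
every part of the pipeline is testable and reproducible with no data
downloads.

## The method

The stream is cut into *data blocks* of `Window_Size` consecutive samples
× 3 axes (one second of samples by default), advancing by `Step_Size = 1`.
Each block gets a fall probability from an LSTM classifier

```
LSTM(U) → Dense(U, relu) → BatchNorm → Dense(U, relu) → BatchNorm → Dense(1, sigmoid)
```

with `U` = samples per second (16,351 parameters at U = 50; the older
baseline without the second Dense/BatchNorm pair has 13,601). The emitted
fall probability is the **median of the last `Smooth_Window` block
probabilities** (two seconds of blocks), and a fall is declared when it
strictly exceeds `Fall_Threshold = 0.4`. Training minimizes binary
cross-entropy with Adam (default settings), bit-reproducibly per seed;
the network core is implemented in C++ (RcppArmadillo) with
finite-difference-verified gradients.

Transfer learning (for a new device or user with little data): train on
the source corpus, **freeze the recurrent layer**, fine-tune the dense
head on the target training blocks, and compare against the same
architecture trained from scratch on exactly the same target data. When
source and target sampling rates differ, target blocks are linearly
resampled onto the source model's native window length so the frozen
gates keep their per-step time scale. Synchronized left- and right-wrist
models are fused by averaging their smoothed probabilities under a single
threshold.

## Worked example

Simulate an 8-subject dataset (50 Hz meta-sensor profile, 8 falls and 6
ADL trials each, including jacket-donning confounders), hold out one
subject, train, and evaluate the streaming pipeline (~1 minute on one
CPU):

```r
library(wristfall)
prof <- device_profile("metasensor")
hp <- prof$default_hparams            # W=50, S=1, K=100, threshold 0.4

cfg <- synthetic_config(n_subjects = 8, falls_per_type = 2,
                        adl_menu = c(walking = 1, waving = 1, drinking = 1,
                                     jacket = 1, sitting = 1, picking = 1),
                        seed = 55)
ds <- simulate_dataset(cfg)
#> <fall_dataset: 112 recordings (64 with falls), 8 subjects [s01, s02, s03, s04, s05, s06, s07, s08]>

subj  <- vapply(ds$recordings, attr, "", "subject_id")
train <- fall_dataset(ds$recordings[subj != "s08"])
test  <- fall_dataset(ds$recordings[subj == "s08"])

model <- train_model(build_model(model_spec(50), seed = 1),
                     blocks_from_dataset(train, hp), epochs = 8, seed = 1)
#> <fall_model: improved U=50, 16351 params, trained 8 epochs>

evaluate_stream(model, test, hp)
#> <eval_report: F1 0.767, precision 0.704, recall 0.843, PR-AUC 0.855,
#>   2909 blocks, events predicted/true: 10/8>
```

The block-level F1 of 0.767 counts every window decision against the
majority label of that window; the two extra predicted events are false
alarms on jacket-donning confounder trials. At the trial level the same
model alarms on 8 of 8 held-out falls and stays quiet on 4 of 6 ADLs
(trial-level F1 0.889). Parameter counts are exact:

```r
count_params(model_spec(50, "improved"))  # 16351
count_params(model_spec(50, "baseline"))  # 13601
```

## Command line

Every step is also a CLI subcommand (deterministic per `--seed`):

```sh
CLI="$(Rscript -e 'cat(system.file("cli", "wristfall", package = "wristfall"))')"
Rscript "$CLI" simulate --out data --subjects 4 --seed 1
Rscript "$CLI" train    --data data --out model --epochs 10 --seed 1
Rscript "$CLI" evaluate --model model --data data --out report.json
Rscript "$CLI" transfer --base model --data newdata --out tuned
Rscript "$CLI" protocol --source src_data --target tgt_data \
               --source-device msband --split lopo --out protocol.json
```

Flags can live in a YAML file (`--config run.yaml`); explicit flags win.

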