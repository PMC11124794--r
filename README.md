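# poseclass

Real-time exercise classification from 3-D pose landmarks, for people
building tele-rehabilitation, home-workout or movement-analysis tools: given
a time series of body keypoints (the MediaPipe Pose convention — 33
landmarks per frame, of which the 22 non-facial ones are used), poseclass
decides *which* of ten exercises is being performed — arm raise, bicycle
crunch, bird dog, curl, fly, leg raise, overhead press, push-up, squat,
superman — quickly enough to drive live feedback.

## Method

Three stages, each a module of the package:

1. **Feature engineering.** Every frame becomes 78 attributes: the 66 raw
   coordinates (22 landmarks × *x, y, z*) plus 12 joint angles in degrees.
   An angle at vertex `p2` between segments `p1–p2` and `p2–p3` is computed
   by the law of cosines from the pairwise Euclidean distances
   *a* = |p1p2|, *b* = |p2p3|, *c* = |p3p1|:

   ∠p1p2p3 = (180/π)·arccos((a² + b² − c²) / 2ab)

   The default set covers elbow, shoulder, hip, knee, ankle and wrist on
   both sides.

2. **Per-frame 1-D CNN.** A convolutional stack
   (conv 32 → pool → conv 64 → pool → conv 128 → pool → conv 256 → pool →
   flatten 768 → dense 512 → softmax 10; valid convolutions with kernel 3,
   floor max-pooling with size 2, so the signal shrinks
   78 → 76 → 38 → 36 → 18 → 16 → 8 → 6 → 3) emits one probability vector
   over the ten classes per frame. The network is implemented in the
   package itself on base matrix algebra (im2col + BLAS) and trained with
   Adam on the categorical cross-entropy.

3. **Soft-voting ensemble.** Per-frame probabilities of each block of
   K = 30 consecutive frames (one second at 30 fps) are summed and the
   argmax is the window's verdict — single corrupted frames (pose-estimator
   glitches) get outvoted. Ties break toward the lowest class index;
   summing and averaging pick the same class.

A forward-kinematics motion simulator (`simulate_sequence()`,
`simulate_dataset()`) generates labelled landmark sequences with
class-specific periodic joint-angle signatures, Gaussian coordinate noise
and occasional outlier frames, so the whole pipeline can be trained,
evaluated (stratified k-fold cross-validation, confusion matrices,
accuracy-versus-window curves) and tested with no external data. See the
methods vignette (`vignettes/poseclass-methods.Rmd`) for the model,
simulator and design notes.

## Worked example

```r
library(poseclass)

# 1. simulate a small labelled dataset (8 training + 2 test sequences per class)
ds <- simulate_dataset(sequences_per_class = 10, n_frames = 120, seed = 42)
test_ids  <- ds$manifest$sequence_id[ave(seq_len(100), ds$manifest$label, FUN = seq_along) <= 2]
train_seqs <- ds$sequences[setdiff(names(ds$sequences), test_ids)]
test_seqs  <- ds$sequences[test_ids]

# 2. per-frame features: 66 coordinates + 12 joint angles
feats <- extract_dataset_features(train_seqs)
dim(feats)
#> [1] 9600   81

# 3. train the per-frame CNN
model <- train_cnn(feats, cnn_config(epochs = 8, seed = 43))
glance(model)
#> # A tibble: 1 × 6
#>   n_parameters input_length n_classes epochs   loss accuracy
#>          <int>        <int>     <int>  <int>  <dbl>    <dbl>
#> 1       528458           78        10      8 0.0447    0.986

# 4. classify a held-out squat video window by window (30-frame soft votes)
classify_stream(model, test_seqs[["squat_001"]], ensemble_config(window = 30))[, 1:5]
#> # A tibble: 4 × 5
#>   sequence_id window_start window_end predicted      score_0
#>   <chr>              <int>      <int> <chr>            <dbl>
#> 1 squat_001              0         30 squat     0.0000115
#> 2 squat_001             30         60 squat     0.00000520
#> 3 squat_001             60         90 squat     0.00000703
#> 4 squat_001             90        120 squat     0.0000000300
classify_sequence(model, test_seqs[["squat_001"]])
#> [1] "squat"

# 5. how much do 30-frame windows buy over single frames?
accuracy_vs_frames(model, test_seqs, frame_counts = c(1, 10, 30))
#> # A tibble: 3 × 3
#>       K accuracy n_windows
#>   <int>    <dbl>     <int>
#> 1     1    0.991      2400
#> 2    10    1           240
#> 3    30    1            80
```

Reading the output: the trained network labels 99.1% of individual held-out
frames correctly (the errors are mostly the injected outlier frames), and
pooling 30 frames into one soft vote lifts window-level accuracy to 1.0 on
this synthetic task — the ensemble absorbing exactly the noise it was
designed for. `classify_stream()` emits one row per 30-frame window with
the aggregated score for every class (`score_0` … `score_9`, in class-index
order); `classify_sequence()` is the majority verdict over windows.

Fitted models save/load as checkpoints (`save_model()` / `load_model()`:
a directory with `config.json` and `weights.rds`), evaluation reports have
`tidy()`/`glance()`/`autoplot()` methods, and `inst/cli/poseclass.R` wraps
the pipeline for the shell:

```sh
Rscript inst/cli/poseclass.R simulate --out data --seed 1
Rscript inst/cli/poseclass.R train    --manifest data/manifest.csv --out run
Rscript inst/cli/poseclass.R predict  --checkpoint run/checkpoint --input data/squat_001.csv --out pred
```

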