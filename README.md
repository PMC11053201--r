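# fallfusion

Multimodal fall detection for a single person in a small indoor space, from
two signals captured by one non-intrusive device: **video**, reduced to
per-frame tracks of 17 skeletal keypoints, and **audio**. Each 3-second clip
is labelled *fall* or *not-fall*. The two modalities fail differently —
video misses falls in the dark, off-screen or behind furniture; audio
confuses soft falls with stomps — so the package classifies each modality
separately and merges the clip-level probabilities at the decision level,
where the complementary errors cancel.

## What is inside

**Video branch.** A two-stream spatio-temporal graph convolutional network
(ST-GCN) over the COCO 17-joint skeleton graph. Within each frame, a graph
convolution aggregates a joint's 1-hop neighborhood, split by a partition
strategy (uni-label, distance, or spatial configuration) with
neighborhood-size normalization:

    f_out(v_ti) = Σ_{v_tj ∈ B(v_ti)}  f_in(v_tj) · w(l(v_tj)) / Z_ti(v_tj)

Across frames, temporal convolutions (kernel Γ = 9) act on corresponding
joints. Nine such layers per stream (temporal strides 2 at layers 4 and 7,
dropout 0.5), one stream fed joint coordinates and the other their frame
differences, merge in a fully connected sigmoid head trained with binary
cross-entropy (Adam, lr 1e-3). Frame-level scores from sliding windows are
aggregated to a video decision by the **15-consecutive-frame rule**: a clip
is a fall iff ≥ 15 consecutive frames are individually fall-positive, with
confidence the maximum mean probability over qualifying runs.

**Audio branch.** Log-scaled mel spectrograms (FFT 1024, hop 512, 64 mel
bands) classified by MobileNetV2 — inverted residual bottlenecks of
depthwise-separable convolutions with linear projections — with energy-gate
silence trimming, five label-preserving augmentations (white noise, time
stretch ×1.2 / ×0.8, gain ±6 dB; 260 clips → 1560), and stratified 5-fold
cross-validation utilities.

**Decision fusion.** Linear weighting `c = α·a + (1−α)·b` with video weight
α ∈ [0.6, 0.9], and Dempster–Shafer evidence combination on
Θ = {fall, not-fall}: classifier probabilities become mass functions
(optionally discounted toward ignorance), combined by Dempster's rule

    m₁₂(A) = 1/(1−K) · Σ_{B∩C=A} m₁(B)·m₂(C),   K = Σ_{B∩C=∅} m₁(B)·m₂(C)

with belief/plausibility intervals and pignistic decisions.

**Evaluation.** Sensitivity, specificity, accuracy, precision and F1 from
TP/FP/TN/FN with fall as the positive class.

**Synthetic data.** A generator producing paired, labelled skeleton + audio
corpora (fall kinematics with a time-locked impact transient vs. walking,
sitting and squatting over ambient noise), so the whole pipeline trains and
tests with no external recordings.

## Worked example

```r
library(fallfusion)

# a small paired corpus: 40 fall + 40 non-fall clips, 3 s @ 25 fps / 16 kHz
cfg <- sim_config(n_per_class = 40, seed = 42)
ds  <- gen_dataset(cfg)
sp  <- fallfusion:::split_indices(ds$manifest$label, 0.8, seed = 42)  # 8:2

# video branch: normalize, train the two-stream ST-GCN, aggregate frames
nseqs <- lapply(ds$skeletons, normalize_sequence)
vmod  <- train_video_model(nseqs[sp$train], video_benchmark_config(seed = 1))
aggregate_frames(predict_frames(vmod, nseqs[[16]]))   # held-out fall clip
#> Video decision 'clip0016': fall (confidence 0.906, fall prob 0.906), run 29..75
aggregate_frames(predict_frames(vmod, nseqs[[51]]))   # held-out daily activity
#> Video decision 'clip0051': notfall (confidence 0.824, fall prob 0.176)

# audio branch: log-mel spectrograms + MobileNetV2
mels <- lapply(ds$audio, logmel)
amod <- train_audio_model(mels[sp$train], ds$manifest$label[sp$train],
                          mobilenet_benchmark_config(seed = 2))
audio_prob <- predict_audio(amod, mels[sp$test])

# decision fusion (Dempster-Shafer), per held-out clip
video_scores <- aggregate_clips(lapply(nseqs[sp$test], predict_frames, model = vmod))
fused <- fuse_scores(data.frame(clip_id = video_scores$clip_id, prob = video_scores$prob),
                     data.frame(clip_id = video_scores$clip_id, prob = audio_prob),
                     method = "dempster")
head(fused[, c("clip_id", "video_prob", "audio_prob", "fused", "label")], 3)
#>    clip_id video_prob audio_prob     fused label
#> 1 clip0016  0.9064843  0.2012283 0.7094695  fall
#> 2 clip0019  0.7994274  0.9999992 0.9999998  fall
#> 3 clip0022  0.8184669  0.9999926 0.9999984  fall

# metrics exactly as printed tables compute them
metrics(confusion_counts(tp = 98, fp = 0, tn = 120, fn = 22))
#> Sensitivity  81.67%
#> Specificity  100.00%
#> Accuracy     90.83%
#> Precision    100.00%
#> F1-score     89.91%
```

Every number above is from an actual run (about five minutes on one CPU).
On this run the held-out accuracies were video 100%, audio 87.5%, fused
93.75%: with only 64 training clips the video branch saturates while the
audio branch still errs, so fusion cannot improve on video here. The regime
where fusion pays off — confident-but-complementary errors in both branches
— is generated directly by `gen_modality_scores()` and measured by
`fusion_benefit()`, where both fusion rules beat the better single modality
by 2–4 accuracy points. `run_pipeline(run_config(seed = 1))` chains the
whole thing — corpus, both branches, aggregation, an α-sweep of linear
fusion and Dempster fusion — and writes CSV/JSON reports. A thin
command-line front end lives at `inst/cli/fallfusion.R`
(`simulate | run | fuse | evaluate`).

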