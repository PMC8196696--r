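# pillcam

Recognition of medication-taking behavior from wrist-camera video, as a
two-stage pipeline over short (~15–20 s) episodes:

1. **Model 1 — object detection.** A region-based detector finds nine
   medication-related object categories per frame (*bottle, cap, cup,
   face, hand, mouth, open_bottle, open_mouth, pill*), structured as the
   four classic R-CNN modules: category-agnostic region proposal,
   fixed-size warp/crop feature extraction, per-category linear SVM
   classification, and bounding-box regression, followed by per-category
   non-maximum suppression. Detection quality is scored as AP@0.5 IoU
   per category and mean AP.
2. **Model 2 — action recognition.** Per-frame detections become a
   *sequence of takes*: a T×20 feature matrix (per-category confidences
   and box-area fractions, a pill-to-open-mouth proximity, and a
   pill-in-hand flag). An LSTM — implemented directly from the gate
   recurrences
   f_t = σ(W_xf·x_t + W_hf·h_{t−1} + b_f), i_t, o_t likewise,
   g_t = tanh(·), c_t = f_t ⊙ c_{t−1} + i_t ⊙ g_t, h_t = o_t ⊙ tanh(c_t) —
   classifies the episode as medication / non-medication, alongside a
   rule-based recognizer (pill confirmed inside an open mouth for k
   consecutive shots) and four classical baselines (logistic regression,
   boosted trees, SVM, random forest). Episode-level results are
   reported as a confusion matrix with accuracy, precision and recall.

The package is aimed at researchers building or evaluating camera-based
medication-adherence monitors. Since wrist-camera study data are not
publicly available, a first-class synthetic generator (step grammar →
rendered frames and ground-truth boxes → detector-noise corruption)
reproduces the study geometry — 250-frame episodes, 50/50 class balance,
270 episodes split 160 train / 110 test — so every stage is testable end
to end.

## Worked example

```r
library(pillcam)

cfg <- system.file("extdata", "quickstart.yaml", package = "pillcam")
res <- runPipeline(cfg, output_dir = "quickstart_run")
res$report
```

On the quickstart configuration (60 synthetic episodes, 40/20 split,
oracle-noise detection with dropout 0.1, clutter 0.5 boxes/frame,
2 px jitter) this printed:

```
                  method accuracy precision recall
1                   lstm     0.95     0.909    1.0
2    logistic_regression     0.65     0.615    0.8
3  boosted_decision_tree     1.00     1.000    1.0
4 support_vector_machine     0.95     0.909    1.0
5        decision_forest     0.95     0.909    1.0
6             rule_based     1.00     1.000    1.0
```

Each row is one classifier evaluated on the same 20 test episodes:
`accuracy` is the fraction of episodes labeled correctly, `precision`
the fraction of predicted medication events that were real, and
`recall` the fraction of real medication events recovered. The LSTM here
misses nothing (recall 1.0) and raises one false alarm; the rule-based
recognizer is exact because moderate noise rarely fakes a
pill-inside-open-mouth configuration over three consecutive frames. The
run directory additionally holds the dataset manifest, serialized
models (JSON), per-episode predictions, the LSTM's 2×2 confusion
matrix, a stage log, and `summary.json` with the seed and config hash;
rerunning the same config reproduces identical summary values.

Individual stages are plain functions (`sampleEpisode()`,
`renderFrame()`, `corruptDetections()`, `trainDetector()`,
`detectFrame()`, `averagePrecision()`, `detectionsToSequence()`,
`trainActionClassifier()`, `ruleBasedClassify()`, `confusion()`, …), and
a thin CLI with the same stages as subcommands lives at
`inst/cli/pillcam.R`. The methods vignette
(`vignettes/medication-behavior-recognition.Rmd`) documents the model,
the generator's assumptions, and all numerical choices.

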