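# sadirt — State-Aware Deep Item Response Theory

`sadirt` models binary test responses with a one-parameter logistic (Rasch)
law whose difficulty side carries a **per-trial latent state**:

P(y<sub>ij</sub> = 1) = σ(θ<sub>j</sub> − (β<sub>i</sub> + φ<sub>ij</sub>))

θ<sub>j</sub> is student *j*'s ability and β<sub>i</sub> item *i*'s
difficulty, both produced by small index-input neural networks (Deep-IRT);
φ<sub>ij</sub> is a *relative subjective difficulty* regressed, by a causal
dilated temporal convolutional network, from a time series of behavioural
features recorded while the student worked on the item — for instance
clip-level facial-video embeddings. A standardize-and-weight output stage
pins φ's distribution at mean zero with a learnable SD |w|, so the state
is interpretable on the same logit scale as θ and β and the model
collapses exactly onto Deep-IRT when w = 0. All components are trained
jointly by cross-entropy minimization with Adam.

The package is for quantitative researchers in psychometrics, affective
computing and learning analytics who want to (a) test whether in-trial
behavioural signals explain response variance beyond static ability and
difficulty, and (b) validate such estimators by simulation with known
ground truth. It ships:

* the state-aware model plus its baseline family (Deep-IRT with/without
  batch normalization, scalar-parameter Base IRT, a summary-statistics
  feature baseline);
* the full evaluation protocol: stratified k-fold cross-validation with
  accuracy/F1, Wilcoxon signed-rank fold comparisons, early prediction at
  response-time quantile cutoffs, parameter-similarity (RMSE / Pearson /
  Kendall τ-b) and prediction-agreement reports, per-student AR(1) state
  analysis, and a leave-one-student-out robustness driver;
* a seeded synthetic-data generator with ground-truth θ, β, φ and
  surrogate feature sequences carrying a tunable, optionally time-ramped
  state signal;
* CSV readers/writers for response logs and feature stores, YAML/JSON run
  configs, and a thin command-line wrapper (`inst/cli/sadirt`).

## Worked example

```r
library(sadirt)

gen <- generateDataset(generatorConfig(nStudents = 10L, nItems = 30L,
                                       seed = 42L))
gen$data
#> ResponseData: 300 trials, 10 students x 30 items
#>   correct-response rate: 0.570
#>   response time [s]: 2.14-59.92 (mean 25.32)

cfg <- trainConfig(variant = "sad_irt", epochs = 40L, seed = 42L)
model <- trainModel(gen$data, gen$features, cfg)
model
#> SadModel (variant 'sad_irt'), 10 students x 30 items
#>   trained 40 epochs, final mean loss 0.3902
#>   variance weight w = 0.8203

report <- runCV(gen$data, gen$features, cfg, k = 5L)
report
#> CVReport: variant 'sad_irt', 5-fold stratified CV
#>   trainAccuracy  0.845 +/- 0.011
#>   trainF1        0.865 +/- 0.010
#>   testAccuracy   0.610 +/- 0.059
#>   testF1         0.662 +/- 0.061

est <- averagedEntityEstimates(report)
cor(unname(est$theta), gen$truth$theta)
#> [1] 0.938
```

Reading the numbers: the fitted variance weight (w ≈ 0.82) is the model's
estimate of the state SD on the logit scale (the generator used 0.75).
Training accuracy 0.85 against test accuracy 0.61 reflects the small,
noisy design — individual Bernoulli responses at these parameter scales
are far from deterministic — while the per-entity averaged ability
estimates still correlate 0.94 with the generating abilities. Pooled
test-fold state estimates correlate ≈ 0.53 (Spearman) with the true
per-trial states at the generator's default signal-to-noise of 2.

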