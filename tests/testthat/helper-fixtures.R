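# Shared fixtures: all generated in code at test time.

# A small synthetic dataset + features for fast structural tests.
smallDataset <- function(seed = 1L, nStudents = 5L, nItems = 8L, ...) {
  generateDataset(generatorConfig(nStudents = nStudents, nItems = nItems,
                                  seed = seed, ...))
}

# A fast training configuration (tiny TCN, few epochs).
fastConfig <- function(variant = "sad_irt", epochs = 3L, seed = 5L,
                       batchSize = 8L, ...) {
  trainConfig(variant = variant, epochs = epochs, seed = seed,
              batchSize = batchSize,
              tcn = tcnConfig(channels = c(6L, 6L), dilations = c(1L, 16L)),
              ...)
}

# Brute-force cross-entropy: per-sample loop, no vectorization.
bruteForceCE <- function(y, p) {
  eps <- 1e-7
  total <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    total <- total - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  total
}

# Brute-force confusion-matrix metrics.
bruteForceMetrics <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0; correct <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == truth[i]) correct <- correct + 1
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  prec <- if (tp + fp == 0) NA else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0 else
    2 * prec * rec / (prec + rec)
  c(accuracy = correct / length(pred), f1 = f1)
}
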