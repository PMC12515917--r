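# shared fixture builders (all generated in code, nothing stored on disk)

quiet_params <- function(baseline = 140, duration_s = 1200, seed = 1, ...) {
  sim_params(baseline_bpm = baseline, variability_amp = 0,
             contraction_rate = 0, duration_s = duration_s, seed = seed, ...)
}

# a record with contractions but a noiseless FHR channel, so injected
# decelerations have exactly their constructed geometry
contraction_record <- function(seed = 4, duration_s = 1200, rate = 3) {
  simulate_record(sim_params(baseline_bpm = 140, variability_amp = 0,
                             contraction_rate = rate,
                             duration_s = duration_s, seed = seed))
}

# brute-force confusion recount used as the metrics oracle
brute_metrics <- function(labels, predictions) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(labels)) {
    if (labels[i] == "normal") {
      if (predictions[i] == "normal") tp <- tp + 1 else fn <- fn + 1
    } else {
      if (predictions[i] == "normal") fp <- fp + 1 else tn <- tn + 1
    }
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       accuracy = (tp + tn) / length(labels),
       precision_normal = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       precision_abnormal = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       recall_normal = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       recall_abnormal = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# O(n^2) pairwise-comparison AUC oracle (ties count 1/2)
pairwise_auc <- function(labels, scores, positive = "normal") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

smoke_layout_hw <- function() c(48, 72)
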