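# Build a one-infant long-format trace from signal vectors.
# Samples are `interval` seconds apart starting at t0.
make_trace <- function(spo2, hr = rep(160, length(spo2)),
                       fio2 = rep(0.21, length(spo2)),
                       valid = rep(1L, length(spo2)),
                       interval = 60, t0 = 0, infant_id = "T001") {
  n <- length(spo2)
  data.frame(infant_id = infant_id,
             t_seconds = t0 + (seq_len(n) - 1) * interval,
             spo2 = spo2, hr = hr, fio2 = fio2, valid = valid,
             stringsAsFactors = FALSE)
}

# independent moment-based skewness oracle (biased moments, b1 form)
skew_oracle <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  (m3 / m2^1.5) * ((n - 1) / n)^1.5
}

# crafted prediction_set from probability/truth vectors
make_predictions <- function(prob, truth) {
  structure(data.frame(infant_id = sprintf("I%03d", seq_along(prob)),
                       truth = as.integer(truth), prob = prob,
                       pred = as.integer(prob >= 0.5),
                       fold = seq_along(prob), stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

# small synthetic cohort used across classification tests
small_sim <- function(n = 30, npos = 6, seed = 42, interval = 1800,
                      effects = default_effect_windows()) {
  generate_cohort(generator_config(
    n_infants = n, n_positive = npos, sampling_interval = interval,
    effect_windows = effects, seed = seed))
}
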