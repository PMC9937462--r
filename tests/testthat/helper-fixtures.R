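# Shared fixtures: built in code at test time (no stored data files).

# A deterministic run configuration used across the simulation tests.
det_cfg <- function(seed = 1L) run_config(deterministic = TRUE, seed = seed)

# Random articulatory state inside the box.
random_state <- function(fit = default_forward_fit()) {
  c(runif(fit$n_shape, -1, 1), runif(3, 0, 1))
}

# Random but valid forward fit (ordered, non-overlapping output ranges).
random_fit <- function() {
  aw <- rbind(rep(0, 10), matrix(runif(30, -1.5, 1.5), 3, 10))
  sw <- matrix(runif(60, -1, 1), 6, 10)
  forward_fit(aud_weights = aw, aud_bias = runif(4, -0.5, 0.5),
              aud_lo = c(70, 240, 940, 2840),
              aud_hi = c(230, 920, 2820, 4250),
              som_weights = sw, som_bias = runif(6, -0.5, 0.5))
}

# Short reachable target for fast closed-loop tests (600 ms).
quick_target <- function(name = "fixture", duration_ms = 600) {
  make_reachable_target(name, shape = c(0.6, -0.4, 0.5, 0.3, -0.2, 0.4,
                                        0, 0, 0, 0),
                        f0_ctrl = 0.45, duration_ms = duration_ms)
}

# Target whose region is the entire sensory space: errors are zero
# everywhere, so no feedback is ever generated.
unconstrained_target <- function(duration_ms = 300) {
  speech_target("open", list(target_segment(0, duration_ms)),
                control_dt = 5, interp = "linear")
}

# Published group summaries (mean, SD over 10 paired samples) for the five
# speech-quality metrics used by the enhancement comparison, with the
# reported pooled-variance effect sizes.
metric_group_summary <- function() {
  data.frame(
    metric = c("PESQ", "CSIG", "CBAK", "COVL", "SEGSNR"),
    m1 = c(1.06, -5.543, -0.372, -2.974, -4.347),
    sd1 = c(0.053, 1.319, 0.379, 0.712, 3.471),
    m2 = c(1.622, 2.841, 1.566, 2.111, -5.573),
    sd2 = c(0.61, 1.497, 0.778, 1.139, 3.147),
    d_reported = c(-1.296, -5.942, -3.168, -5.351, 0.370))
}

# Constant-frame sensory matrices for audio tests.
constant_frames <- function(n, aud = c(140, 300, 2300, 3000),
                            pressure = 0.9, voicing = 1) {
  list(aud = matrix(rep(aud, each = n), n, 4),
       som = matrix(rep(c(rep(0.5, 6), pressure, voicing), each = n), n, 8))
}
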