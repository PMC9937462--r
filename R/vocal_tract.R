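#' Articulatory state helpers
#'
#' The articulatory (motor) state is a length-13 numeric vector: 10 unitless
#' vocal-tract shape parameters in \[-1, 1\] followed by three source
#' controls in \[0, 1\]: `f0_ctrl` (pitch), `pressure_ctrl` (subglottal
#' drive) and `voicing_ctrl` (periodic vs. noise excitation mix).
#' `initial_state()` is the rest posture used at the start of every
#' production: neutral shape, mid pitch, pressure and voicing off (they are
#' driven up by the controller; a short onset envelope in [synth_audio()]
#' avoids clicks).
#'
#' @param fit a [forward_fit()] (supplies the shape dimension).
#' @return `initial_state()` returns a length-13 numeric state;
#'   `state_box()` returns a list with `lo` and `hi` clamping bounds.
#' @export
initial_state <- function(fit = default_forward_fit()) {
  c(rep(0, fit$n_shape), 0.5, 0, 0)
}

#' @rdname initial_state
#' @export
state_box <- function(fit = default_forward_fit()) {
  list(lo = c(rep(-1, fit$n_shape), 0, 0, 0),
       hi = c(rep(1, fit$n_shape), 1, 1, 1))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

.check_state <- function(x, fit) {
  if (length(x) != fit$n_shape + 3)
    stop(sprintf("articulatory state must have length %d, got %d",
                 fit$n_shape + 3, length(x)), call. = FALSE)
  if (any(!is.finite(x)))
    stop("articulatory state contains non-finite values", call. = FALSE)
}

#' Sensory consequence of a motor state
#'
#' Deterministic forward map of the vocal tract: for formants k = F1..F3,
#' `aud[k] = aud_lo[k] + (aud_hi[k] - aud_lo[k]) * sigmoid(w_k . shape + b_k)`;
#' `F0 = f0_lo + (f0_hi - f0_lo) * f0_ctrl`. Place coordinates are
#' `sigmoid(som_weights %*% shape + som_bias)`; pressure and voicing pass
#' through from their controls. All outputs lie inside their declared ranges
#' for every state in the box.
#'
#' @param x length-13 articulatory state (see [initial_state()]).
#' @param fit a [forward_fit()].
#' @return list with `aud` (named length-4, Hz) and `som` (named length-8:
#'   six place dims, pressure, voicing).
#' @export
synth_sample <- function(x, fit = default_forward_fit()) {
  .check_state(x, fit)
  ns <- fit$n_shape
  shape <- x[seq_len(ns)]
  aud <- fit$aud_lo + (fit$aud_hi - fit$aud_lo) *
    sigmoid(drop(fit$aud_weights %*% shape) + fit$aud_bias)
  aud[1] <- fit$aud_lo[1] + (fit$aud_hi[1] - fit$aud_lo[1]) * x[ns + 1]
  place <- sigmoid(drop(fit$som_weights %*% shape) + fit$som_bias)
  som <- c(place, x[ns + 2], x[ns + 3])
  names(aud) <- c("F0", "F1", "F2", "F3")
  names(som) <- c(paste0("place", seq_len(fit$n_place)), "pressure", "voicing")
  list(aud = aud, som = som)
}

#' Jacobian of the forward map
#'
#' Closed-form derivative of [synth_sample()] with respect to the 13 motor
#' dimensions. Rows 1-4 are the auditory outputs (F0-F3), rows 5-12 the
#' somatosensory outputs (place 1-6, pressure, voicing). The sigmoid
#' derivative is `p * (1 - p)` evaluated at the current state, so the
#' Jacobian agrees with central finite differences everywhere in the box.
#'
#' @inheritParams synth_sample
#' @return a 12 x 13 numeric matrix.
#' @export
vt_jacobian <- function(x, fit = default_forward_fit()) {
  .check_state(x, fit)
  ns <- fit$n_shape; np <- fit$n_place
  shape <- x[seq_len(ns)]
  J <- matrix(0, 4 + np + 2, ns + 3)
  p_aud <- sigmoid(drop(fit$aud_weights %*% shape) + fit$aud_bias)
  for (k in 2:4)
    J[k, seq_len(ns)] <- (fit$aud_hi[k] - fit$aud_lo[k]) *
      p_aud[k] * (1 - p_aud[k]) * fit$aud_weights[k, ]
  J[1, ns + 1] <- fit$aud_hi[1] - fit$aud_lo[1]
  p_som <- sigmoid(drop(fit$som_weights %*% shape) + fit$som_bias)
  for (i in seq_len(np))
    J[4 + i, seq_len(ns)] <- p_som[i] * (1 - p_som[i]) * fit$som_weights[i, ]
  J[4 + np + 1, ns + 2] <- 1   # pressure pass-through
  J[4 + np + 2, ns + 3] <- 1   # voicing pass-through
  J
}

# ---------------------------------------------------------------------------
# Audio synthesis (source-filter)
# ---------------------------------------------------------------------------

#' Audio synthesis configuration
#'
#' @param sample_rate output rate in Hz; must exceed twice the highest
#'   formant range bound (default 11025).
#' @param bandwidths length-3 resonator bandwidths for F1-F3 in Hz.
#' @param jitter_sigma relative standard deviation of the per-frame F0
#'   perturbation (0 disables pitch jitter).
#' @param noise_floor aspiration noise amplitude added to the excitation.
#' @param seed integer seed for the jitter and noise streams.
#' @param format WAV sample format, `"pcm16"` or `"float32"`.
#' @return an object of class `audio_config`.
#' @export
audio_config <- function(sample_rate = 11025, bandwidths = c(80, 100, 120),
                         jitter_sigma = 0.01, noise_floor = 0.02,
                         seed = 1L, format = c("pcm16", "float32")) {
  if (any(bandwidths <= 0)) stop("bandwidths must be positive", call. = FALSE)
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0", call. = FALSE)
  structure(list(sample_rate = as.numeric(sample_rate),
                 bandwidths = as.numeric(bandwidths),
                 jitter_sigma = as.numeric(jitter_sigma),
                 noise_floor = as.numeric(noise_floor),
                 seed = as.integer(seed), format = match.arg(format)),
            class = "audio_config")
}

#' Seeded relative pitch perturbation
#'
#' Multiplies each frame's F0 by `1 + eps`, `eps ~ Normal(0, sigma)`, drawn
#' from a dedicated seeded stream: the same seed always reproduces the same
#' perturbation (the precondition for deterministic cross-run comparison),
#' and `sigma = 0` is the identity.
#'
#' @param f0_track numeric F0 sequence in Hz.
#' @param sigma relative standard deviation, `>= 0`.
#' @param seed integer seed for the perturbation stream.
#' @return perturbed F0 sequence of the same length.
#' @export
perturb_f0 <- function(f0_track, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(f0_track)
  eps <- with_seed(seed, rnorm(length(f0_track), 0, sigma))
  f0_track * (1 + eps)
}

#' Band-limited glottal pulse train
#'
#' Harmonic source with 1/k amplitude rolloff (a band-limited sawtooth-like
#' glottal waveform): the fundamental is the strongest spectral component, so
#' the magnitude-spectrum peak of a voiced source sits at F0. Phase is
#' accumulated sample by sample, so the pulse train stays continuous when F0
#' varies.
#'
#' @param f0 F0 in Hz: a scalar or a per-sample sequence of length
#'   `n_samples`.
#' @param sample_rate sampling rate in Hz.
#' @param n_samples number of samples to generate.
#' @return numeric waveform (unnormalized).
#' @export
glottal_pulse_train <- function(f0, sample_rate, n_samples) {
  if (length(f0) == 1) f0 <- rep(f0, n_samples)
  stopifnot(length(f0) == n_samples, all(f0 > 0))
  phase <- cumsum(2 * pi * f0 / sample_rate)
  n_harm <- max(1L, floor((sample_rate / 2 - 50) / max(f0)))
  k <- seq_len(n_harm)
  drop(sin(outer(phase, k)) %*% (1 / k))
}

# Cascade of three two-pole resonators with per-frame center frequencies and
# state carried across frame boundaries. `chunks` is the per-sample frame
# index (non-decreasing). Uses the recursive filter kernel of stats::filter
# per chunk with explicit initial conditions.
resonator_cascade <- function(src, formants, chunks, bandwidths,
                              sample_rate) {
  n_frames <- nrow(formants)
  idx_list <- split(seq_along(src), factor(chunks, levels = seq_len(n_frames)))
  y <- src
  for (j in 1:3) {
    r <- exp(-pi * bandwidths[j] / sample_rate)
    state <- c(0, 0)  # (y[n-1], y[n-2])
    out <- numeric(length(y))
    for (f in seq_len(n_frames)) {
      idx <- idx_list[[f]]
      if (length(idx) == 0) next
      th <- 2 * pi * formants[f, j] / sample_rate
      B <- 2 * r * cos(th); C <- -r^2
      A <- 1 - B - C  # unity gain at DC
      seg <- stats::filter(A * y[idx], c(B, C), method = "recursive",
                           init = state)
      seg <- as.numeric(seg)
      out[idx] <- seg
      ns <- length(seg)
      state <- if (ns >= 2) c(seg[ns], seg[ns - 1]) else c(seg[ns], state[1])
    }
    y <- out
  }
  y
}

#' Synthesize the audio waveform of a production
#'
#' Source-filter synthesis over the per-step sensory frames: the excitation
#' per frame is `voicing * glottal pulse train at the (jitter-perturbed) F0
#' plus (1 - voicing + noise_floor) * white noise`, scaled by pressure and a
#' 20 ms linear onset envelope, then filtered through a cascade of three
#' second-order resonators at (F1, F2, F3) with the configured bandwidths.
#' Filter state carries across frame boundaries and pressure/voicing are
#' interpolated per sample, so frame transitions do not click. With
#' `jitter_sigma = 0` or a fixed seed, repeated synthesis is bit-identical.
#'
#' @param aud T x 4 matrix of auditory frames (F0-F3 in Hz).
#' @param som T x 8 matrix of somatosensory frames (place, pressure,
#'   voicing).
#' @param cfg an [audio_config()].
#' @param control_dt control step in ms.
#' @param normalize peak-normalize to \[-1, 1\] (default TRUE; an all-silent
#'   source stays exactly zero).
#' @return numeric waveform of length
#'   `round(T * control_dt * sample_rate / 1000)`.
#' @export
synth_audio <- function(aud, som, cfg = audio_config(), control_dt = 5,
                        normalize = TRUE) {
  aud <- as.matrix(aud); som <- as.matrix(som)
  n_frames <- nrow(aud)
  if (n_frames == 0) stop("empty frame sequence", call. = FALSE)
  if (nrow(som) != n_frames)
    stop("auditory and somatosensory frame counts differ", call. = FALSE)
  fs <- cfg$sample_rate
  spf <- fs * control_dt / 1000           # samples per control frame
  n <- round(n_frames * spf)
  frame_idx <- pmin(floor((seq_len(n) - 1) / spf) + 1, n_frames)

  f0p <- perturb_f0(aud[, 1], cfg$jitter_sigma, cfg$seed + 1000L)
  voiced <- glottal_pulse_train(f0p[frame_idx], fs, n)
  voiced <- voiced / max(abs(voiced), 1e-12)
  noise <- with_seed(cfg$seed + 2000L, rnorm(n))

  centers <- (seq_len(n_frames) - 0.5) * spf
  smooth <- function(v) {
    if (n_frames == 1) return(rep(v, n))
    approx(centers, v, xout = seq_len(n) - 0.5, rule = 2)$y
  }
  pressure <- smooth(som[, 7])
  voicing <- smooth(som[, 8])
  onset <- pmin((seq_len(n) - 0.5) / fs * 1000 / 20, 1)

  src <- pressure * onset *
    (voicing * voiced + ((1 - voicing) + cfg$noise_floor) * noise)
  wave <- resonator_cascade(src, aud[, 2:4, drop = FALSE], frame_idx,
                            cfg$bandwidths, fs)
  if (normalize) {
    peak <- max(abs(wave))
    if (peak > 0) wave <- wave / peak
  }
  wave
}
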