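# Pitch and formant estimation for sustained-vowel recordings, used to turn
# a human (or model) recording into a speech target. Standard signal
# processing only: normalized-autocorrelation pitch and LPC root formants.

.check_mono <- function(wave) {
  if (!is.numeric(wave) || length(wave) == 0)
    stop("input must be a non-empty numeric mono waveform", call. = FALSE)
  if (!is.null(dim(wave)) && length(dim(wave)) > 1 && min(dim(wave)) > 1)
    stop("multi-channel input is not supported", call. = FALSE)
  as.numeric(wave)
}

#' Autocorrelation pitch tracking
#'
#' Frame-based normalized autocorrelation: per 40 ms frame (10 ms hop) the
#' lag maximizing the lag-0-normalized autocorrelation within the period
#' range `[1/f0_ceil, 1/f0_floor]` is chosen and refined by parabolic
#' interpolation. Frames whose peak autocorrelation falls below
#' `ac_threshold` or whose RMS is below the silence threshold are flagged
#' unvoiced (`f0 = 0`).
#'
#' @param wave mono numeric waveform.
#' @param sample_rate sampling rate in Hz, `>= 8000`.
#' @param f0_floor,f0_ceil pitch search range in Hz (defaults 75-500).
#' @param frame_ms,hop_ms analysis frame and hop in ms (defaults 40 / 10).
#' @param ac_threshold voicing threshold on the normalized autocorrelation
#'   peak (default 0.3).
#' @return an object of class `pitch_track`: `times` (frame centers, ms),
#'   `f0` (Hz; 0 = unvoiced), `frame_len`, `hop`.
#' @export
estimate_pitch <- function(wave, sample_rate, f0_floor = 75, f0_ceil = 500,
                           frame_ms = 40, hop_ms = 10, ac_threshold = 0.3) {
  wave <- .check_mono(wave)
  if (sample_rate < 8000)
    stop("sample_rate must be >= 8000 Hz", call. = FALSE)
  flen <- round(frame_ms * sample_rate / 1000)
  hop <- round(hop_ms * sample_rate / 1000)
  if (length(wave) < flen)
    stop("waveform shorter than one analysis frame", call. = FALSE)
  starts <- seq(1, length(wave) - flen + 1, by = hop)
  lmin <- max(2L, floor(sample_rate / f0_ceil))
  lmax <- min(flen - 2L, ceiling(sample_rate / f0_floor))
  # silence threshold: relative to the loudest frame, with an absolute floor
  frame_rms <- vapply(starts, function(s)
    sqrt(mean(wave[s:(s + flen - 1)]^2)), numeric(1))
  silence <- pmax(1e-6, 0.01 * max(frame_rms))

  f0 <- numeric(length(starts))
  np2 <- 2^ceiling(log2(2 * flen))
  for (i in seq_along(starts)) {
    if (frame_rms[i] < silence) next
    x <- wave[starts[i]:(starts[i] + flen - 1)]
    x <- x - mean(x)
    if (sum(x^2) == 0) next
    sp <- fft(c(x, numeric(np2 - flen)))
    ac <- Re(fft(Mod(sp)^2, inverse = TRUE)) / np2
    # unbias the taper (ac[l] sums flen - l products) so the peak location
    # is not pulled toward shorter lags
    lags <- lmin:lmax
    r <- (ac[1 + lags] / (flen - lags)) / (ac[1] / flen)
    if (max(r) < ac_threshold) next
    # a periodic signal has near-equal peaks at every multiple of its
    # period; take the shortest near-maximal lag to avoid octave-down errors
    best <- which(r >= 0.97 * max(r))[1]
    lag <- lmin + best - 1
    # parabolic refinement around the peak
    if (best > 1 && best < length(r)) {
      y1 <- r[best - 1]; y2 <- r[best]; y3 <- r[best + 1]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) lag <- lag + 0.5 * (y1 - y3) / denom
    }
    cand <- sample_rate / lag
    if (cand >= f0_floor && cand <= f0_ceil) f0[i] <- cand
  }
  structure(list(times = (starts - 1 + flen / 2) / sample_rate * 1000,
                 f0 = f0, frame_len = frame_ms, hop = hop_ms),
            class = "pitch_track")
}

#' LPC formant tracking
#'
#' Waveforms above 11025 Hz are resampled down; after pre-emphasis
#' (coefficient 0.97), each 25 ms Hamming-windowed frame (10 ms hop) is fit
#' with a linear-prediction model of order 12 (autocorrelation method).
#' Formants are the angles of the complex prediction-polynomial roots with
#' bandwidth below 400 Hz and frequency in \[90, 5000\] Hz, sorted
#' ascending; frames with fewer than three qualifying roots are flagged
#' invalid.
#'
#' @param wave mono numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param order LPC order (default 12).
#' @param frame_ms,hop_ms analysis frame and hop in ms (defaults 25 / 10).
#' @param preemph pre-emphasis coefficient (default 0.97).
#' @param max_bw bandwidth ceiling for a root to count as a formant (Hz).
#' @param fmin,fmax admissible formant frequency range (Hz).
#' @return an object of class `formant_track`: `times` (ms), `F1`, `F2`,
#'   `F3` (Hz, NA where invalid), `valid` (logical per frame).
#' @export
estimate_formants <- function(wave, sample_rate, order = 12, frame_ms = 25,
                              hop_ms = 10, preemph = 0.97, max_bw = 400,
                              fmin = 90, fmax = 5000) {
  wave <- .check_mono(wave)
  if (sample_rate > 11025) {
    g <- .gcd(11025L, as.integer(round(sample_rate)))
    wave <- as.numeric(signal::resample(wave, 11025L %/% g,
                                        as.integer(round(sample_rate)) %/% g))
    sample_rate <- 11025
  }
  y <- c(wave[1], wave[-1] - preemph * wave[-length(wave)])
  flen <- round(frame_ms * sample_rate / 1000)
  hop <- round(hop_ms * sample_rate / 1000)
  if (length(y) < flen)
    stop("waveform shorter than one analysis frame", call. = FALSE)
  starts <- seq(1, length(y) - flen + 1, by = hop)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, flen - 1) / (flen - 1))

  nfr <- length(starts)
  F1 <- F2 <- F3 <- rep(NA_real_, nfr)
  valid <- logical(nfr)
  for (i in seq_len(nfr)) {
    x <- y[starts[i]:(starts[i] + flen - 1)] * win
    r <- vapply(0:order, function(l)
      sum(x[seq_len(flen - l)] * x[seq_len(flen - l) + l]), numeric(1))
    if (r[1] <= 1e-12) next
    a <- tryCatch(solve(toeplitz(r[1:order]), r[2:(order + 1)]),
                  error = function(e) NULL)
    if (is.null(a)) next
    rts <- polyroot(c(1, -a))      # roots in q = z^{-1}
    poles <- 1 / rts
    freq <- Arg(poles) * sample_rate / (2 * pi)
    bw <- -sample_rate / pi * log(pmin(Mod(poles), 1 - 1e-12))
    keep <- freq > fmin & freq < fmax & bw < max_bw & bw > 0
    fr <- sort(freq[keep])
    if (length(fr) >= 3) {
      F1[i] <- fr[1]; F2[i] <- fr[2]; F3[i] <- fr[3]
      valid[i] <- TRUE
    }
  }
  structure(list(times = (starts - 1 + flen / 2) / sample_rate * 1000,
                 F1 = F1, F2 = F2, F3 = F3, valid = valid),
            class = "formant_track")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Build a speech target from a sustained-vowel recording
#'
#' The extraction pipeline: estimate pitch and formants, take the medians
#' over the voiced / valid frames, and define a single-segment target over
#' the voiced span whose auditory bounds are `median * (1 -/+ tolerance)`
#' per dimension. Pressure and voicing are constrained to \[0.5, 1\]; place
#' dimensions are left unconstrained.
#'
#' @param wave mono numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param name label for the new target.
#' @param tolerance relative half-width of the region bounds (default 0.05).
#' @param control_dt control step of the target in ms.
#' @return a [speech_target()].
#' @export
build_target_from_audio <- function(wave, sample_rate, name,
                                    tolerance = 0.05, control_dt = 5) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  pt <- estimate_pitch(wave, sample_rate)
  voiced <- pt$f0 > 0
  voiced_ms <- sum(voiced) * pt$hop
  if (voiced_ms < 200)
    stop(sprintf("insufficient voiced material: found %g ms, need >= 200 ms",
                 voiced_ms), call. = FALSE)
  ft <- estimate_formants(wave, sample_rate)
  if (!any(ft$valid))
    stop("no valid formant frames in the recording", call. = FALSE)
  med <- c(median(pt$f0[voiced]), median(ft$F1[ft$valid]),
           median(ft$F2[ft$valid]), median(ft$F3[ft$valid]))
  seg <- target_segment(0, voiced_ms,
                        aud_min = med * (1 - tolerance),
                        aud_max = med * (1 + tolerance),
                        som_min = c(rep(0, 6), 0.5, 0.5),
                        som_max = rep(1, 8))
  speech_target(name, list(seg), control_dt = control_dt, interp = "linear")
}
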