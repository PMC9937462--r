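test_that("neutral posture sits at range midpoints; controls pass through", {
  fit <- default_forward_fit()
  x <- c(rep(0, 10), 0.5, 0.7, 0.3)
  fr <- synth_sample(x, fit)
  expect_equal(unname(fr$aud[2:4]),
               (fit$aud_lo[2:4] + fit$aud_hi[2:4]) / 2)  # sigmoid(0) = 0.5
  expect_equal(unname(fr$aud[1]), (fit$aud_lo[1] + fit$aud_hi[1]) / 2)
  expect_equal(unname(fr$som[["pressure"]]), 0.7)
  expect_equal(unname(fr$som[["voicing"]]), 0.3)
  expect_error(synth_sample(rep(0, 12), fit), "length 13")
})

test_that("forward map agrees with an independent scalar evaluation", {
  # scalar-loop oracle: one output dimension at a time, no vectorization
  scalar_forward <- function(x, fit) {
    sig <- function(z) 1 / (1 + exp(-z))
    aud <- numeric(4)
    aud[1] <- fit$aud_lo[1] + (fit$aud_hi[1] - fit$aud_lo[1]) * x[11]
    for (k in 2:4) {
      z <- fit$aud_bias[k]
      for (j in 1:10) z <- z + fit$aud_weights[k, j] * x[j]
      aud[k] <- fit$aud_lo[k] + (fit$aud_hi[k] - fit$aud_lo[k]) * sig(z)
    }
    som <- numeric(8)
    for (i in 1:6) {
      z <- fit$som_bias[i]
      for (j in 1:10) z <- z + fit$som_weights[i, j] * x[j]
      som[i] <- sig(z)
    }
    som[7] <- x[12]; som[8] <- x[13]
    list(aud = aud, som = som)
  }
  set.seed(11)
  for (rep in 1:20) {
    fit <- random_fit()
    x <- random_state(fit)
    got <- synth_sample(x, fit)
    want <- scalar_forward(x, fit)
    expect_equal(unname(got$aud), want$aud, tolerance = 1e-12)
    expect_equal(unname(got$som), want$som, tolerance = 1e-12)
  }
})

test_that("outputs stay inside declared ranges across the state box", {
  fit <- default_forward_fit()
  set.seed(4)
  for (rep in 1:50) {
    fr <- synth_sample(random_state(fit), fit)
    expect_true(all(fr$aud >= fit$aud_lo & fr$aud <= fit$aud_hi))
    expect_true(all(fr$som >= 0 & fr$som <= 1))
  }
})

test_that("Jacobian matches central finite differences", {
  set.seed(7)
  h <- 1e-5
  for (rep in 1:50) {
    fit <- if (rep %% 2) default_forward_fit() else random_fit()
    x <- random_state(fit)
    x <- clamp(x, state_box(fit)$lo + 2 * h, state_box(fit)$hi - 2 * h)
    J <- vt_jacobian(x, fit)
    Jfd <- matrix(0, 12, 13)
    for (j in 1:13) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      fp <- synth_sample(xp, fit); fm <- synth_sample(xm, fit)
      Jfd[, j] <- (c(fp$aud, fp$som) - c(fm$aud, fm$som)) / (2 * h)
    }
    expect_lt(norm(J - Jfd, "F") / norm(J, "F"), 1e-4)
  }
})

test_that("Jacobian structure: zero rows and linear pass-throughs", {
  fit <- default_forward_fit()
  J <- vt_jacobian(initial_state(fit), fit)
  # F0 row: only the f0_ctrl partial, equal to the range width
  expect_equal(J[1, 11], fit$aud_hi[1] - fit$aud_lo[1])
  expect_equal(J[1, -11], rep(0, 12))
  # a zero weight row gives zero shape partials
  fit0 <- fit; fit0$aud_weights[3, ] <- 0
  expect_equal(vt_jacobian(initial_state(fit0), fit0)[3, 1:10], rep(0, 10))
  # pressure and voicing pass-throughs
  expect_equal(J[11, ], c(rep(0, 11), 1, 0))
  expect_equal(J[12, ], c(rep(0, 12), 1))
})

test_that("pitch perturbation is seeded, scaled, and vanishes at sigma 0", {
  f0 <- rep(150, 10000)
  expect_identical(perturb_f0(f0, 0, seed = 3), f0)
  a <- perturb_f0(f0, 0.02, seed = 3)
  b <- perturb_f0(f0, 0.02, seed = 3)
  expect_identical(a, b)
  rel_sd <- sd(a / f0 - 1)
  expect_lt(abs(rel_sd - 0.02) / 0.02, 0.05)
  expect_error(perturb_f0(f0, -0.1, seed = 1), ">= 0")
})

test_that("zero pressure yields an exactly zero waveform", {
  fr <- constant_frames(50, pressure = 0)
  w <- synth_audio(fr$aud, fr$som, audio_config(jitter_sigma = 0),
                   control_dt = 5, normalize = FALSE)
  expect_identical(w, numeric(length(w)))
})

test_that("audio synthesis is bit-identical under a fixed seed", {
  fr <- constant_frames(60)
  cfg <- audio_config(jitter_sigma = 0.01, seed = 42L)
  expect_identical(synth_audio(fr$aud, fr$som, cfg, 5),
                   synth_audio(fr$aud, fr$som, cfg, 5))
  # length contract and normalization
  w <- synth_audio(fr$aud, fr$som, cfg, 5)
  expect_length(w, round(60 * 5 * cfg$sample_rate / 1000))
  expect_lte(max(abs(w)), 1)
})

test_that("voiced source spectrum peaks at the fundamental", {
  fs <- 11025
  src <- glottal_pulse_train(140, fs, 2 * fs)  # 2 s -> 0.5 Hz resolution
  mag <- Mod(fft(src))[1:(fs)]
  peak_hz <- (which.max(mag) - 1) / 2
  expect_lt(abs(peak_hz - 140), 1)
})

test_that("waveform RMS is non-decreasing in pressure", {
  rms <- vapply(c(0.2, 0.5, 0.8, 1.0), function(p) {
    fr <- constant_frames(60, pressure = p)
    w <- synth_audio(fr$aud, fr$som, audio_config(jitter_sigma = 0),
                     control_dt = 5, normalize = FALSE)
    sqrt(mean(w^2))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("per-frame filtering with carried state equals whole-signal filtering", {
  # constant coefficients: chunked recursion must agree exactly with one pass
  set.seed(9)
  n <- 40
  fr <- constant_frames(n)
  cfg <- audio_config(jitter_sigma = 0)
  w_chunked <- synth_audio(fr$aud, fr$som, cfg, 5, normalize = FALSE)
  # reference: same source, one unchunked recursion per resonator
  fs <- cfg$sample_rate
  spf <- fs * 5 / 1000
  ns <- round(n * spf)
  one_frame <- constant_frames(1)
  # single frame of the same length via control_dt = n * 5
  w_whole <- synth_audio(one_frame$aud, one_frame$som, cfg,
                         control_dt = n * 5, normalize = FALSE)
  expect_equal(length(w_chunked), length(w_whole))
  expect_equal(w_chunked, w_whole, tolerance = 1e-12)
})
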