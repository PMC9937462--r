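test_that("no forcing: zero program and zero gains hold the initial state", {
  tg <- unconstrained_target()
  cfg <- run_config(gains = control_gains(alpha_ff = 0, alpha_fb_aud = 0,
                                          alpha_fb_som = 0),
                    deterministic = TRUE)
  tr <- produce(tg, zero_program(tg), cfg, audio = FALSE)
  x0 <- initial_state(cfg$fit)
  expect_true(all(apply(tr$states, 1, function(r) identical(r, x0))))
})

test_that("an unconstrained region generates no errors or feedback", {
  tg <- unconstrained_target()
  cfg <- det_cfg()
  tr <- produce(tg, zero_program(tg), cfg, audio = FALSE)
  expect_equal(max(abs(tr$e_aud)), 0)
  expect_equal(max(abs(tr$e_som)), 0)
  expect_equal(max(abs(tr$u_fb)), 0)
  # training on it returns the program's commands unchanged
  res <- train(tg, 1, cfg, reset = FALSE, keep_traces = FALSE, audio = FALSE)
  expect_equal(res$program$commands, zero_program(tg)$commands)
})

test_that("deterministic mode reproduces a production bit-identically", {
  tg <- quick_target()
  cfg <- det_cfg(seed = 7L)
  tr1 <- produce(tg, zero_program(tg), cfg)
  tr2 <- produce(tg, zero_program(tg), cfg)
  expect_identical(tr1$u, tr2$u)
  expect_identical(tr1$states, tr2$states)
  expect_identical(tr1$waveform, tr2$waveform)
  rng <- diff(range(tr1$u))
  expect_identical(normalized_rmse(tr1$u, tr2$u, max(rng, 1)), 0)
})

test_that("produce validates program/target compatibility", {
  tg <- quick_target()
  short <- motor_program(tg$name, 10, control_dt = tg$control_dt)
  expect_error(produce(tg, short, det_cfg()), "does not match")
  wrong_dt <- motor_program(tg$name, nrow(zero_program(tg)$commands),
                            control_dt = 10)
  expect_error(produce(tg, wrong_dt, det_cfg()), "control_dt differ")
})

test_that("waveform duration equals target duration within one step", {
  tg <- quick_target()
  cfg <- det_cfg()
  tr <- produce(tg, zero_program(tg), cfg)
  dur_ms <- length(tr$waveform) / cfg$audio$sample_rate * 1000
  expect_lt(abs(dur_ms - target_duration(tg)), tg$control_dt)
})

test_that("training reduces auditory error and converges on a fixture", {
  tg <- quick_target()
  res <- train(tg, 8, det_cfg(), reset = TRUE, keep_traces = FALSE,
               audio = FALSE)
  e <- res$summary$mean_abs_e_aud
  expect_true(all(diff(e[1:3]) < 0))
  expect_lt(e[8], 0.35 * e[1])
  expect_equal(res$program$iterations_trained, 8L)
})

test_that("a converged program is stable over further unreset productions", {
  tg <- quick_target()
  cfg <- det_cfg()
  res <- train(tg, 60, cfg, reset = TRUE, keep_traces = FALSE, audio = FALSE)
  more <- train(tg, 20, cfg, reset = FALSE, program = res$program,
                keep_traces = FALSE, audio = FALSE)
  e <- more$summary$mean_abs_e_aud
  # per-iteration summaries stay within 1% of the training signal range
  rng <- res$summary$mean_abs_e_aud[1]
  expect_lt(max(e) - min(e), 0.01 * rng)
})

test_that("WAV files round-trip in both formats", {
  tg <- quick_target(duration_ms = 300)
  cfg <- det_cfg()
  tr <- produce(tg, zero_program(tg), cfg)
  p16 <- withr::local_tempfile(fileext = ".wav")
  save_wav(tr, p16)
  back <- read_wav(p16)
  expect_equal(back$sample_rate, cfg$audio$sample_rate)
  expect_lte(max(abs(back$samples - tr$waveform)), 1 / 32768)
  # float32 read-back is bit-identical after the float cast
  cfg32 <- run_config(audio = audio_config(format = "float32"),
                      deterministic = TRUE)
  tr32 <- produce(tg, zero_program(tg), cfg32)
  p32 <- withr::local_tempfile(fileext = ".wav")
  save_wav(tr32, p32)
  back32 <- read_wav(p32)
  expect_equal(back32$samples, tr32$waveform, tolerance = 1e-7)
  expect_equal(back32$format, "float32")
  # silent trace writes all-zero samples
  silent <- tr
  silent$waveform <- numeric(1000)
  ps <- withr::local_tempfile(fileext = ".wav")
  save_wav(silent, ps)
  expect_identical(read_wav(ps)$samples, numeric(1000))
})

test_that("trace CSV round-trips numerically and is deterministic", {
  tg <- quick_target(duration_ms = 300)
  cfg <- det_cfg()
  tr <- produce(tg, zero_program(tg), cfg, audio = FALSE)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  save_trace(tr, p1)
  df <- read_trace(p1)
  expect_equal(nrow(df), nrow(tr$states))
  expect_identical(matrix(as.matrix(df[, paste0("x", 1:13)]),
                          ncol = 13, dimnames = NULL), tr$states)
  expect_identical(matrix(as.matrix(df[, paste0("e_aud", 1:4)]),
                          ncol = 4, dimnames = NULL), tr$e_aud)
  save_trace(produce(tg, zero_program(tg), cfg, audio = FALSE), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("config files override gains and seeds", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "alpha_fb_aud = 0.5", "tau_aud = 50",
               "deterministic = true", "seed = 9"), path)
  conf <- read_config(path)
  cfg <- config_to_run(conf)
  expect_equal(cfg$gains$alpha_fb_aud, 0.5)
  expect_equal(cfg$gains$tau_aud, 50)
  expect_true(cfg$deterministic)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$audio$jitter_sigma, 0)  # deterministic forces jitter off
  cfg2 <- config_to_run(conf, seed = 3L)
  expect_equal(cfg2$seed, 3L)
})

test_that("forward-fit coefficient files round-trip", {
  fit <- default_forward_fit()
  path <- withr::local_tempfile(fileext = ".fit")
  write_forward_fit(fit, path)
  expect_equal(read_forward_fit(path), fit)
})
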