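#' Run configuration for productions
#'
#' One object bundling everything a production needs besides the target and
#' motor program. `deterministic = TRUE` forces the pitch jitter off; all
#' remaining stochastic components (aspiration noise) are drawn from streams
#' derived from the single master `seed`, so two runs with identical
#' configuration are bit-identical.
#'
#' @param gains a [control_gains()].
#' @param audio an [audio_config()].
#' @param fit a [forward_fit()].
#' @param deterministic force `jitter_sigma = 0`.
#' @param seed master seed; the jitter and noise streams are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(gains = control_gains(), audio = audio_config(),
                       fit = default_forward_fit(), deterministic = FALSE,
                       seed = 1L) {
  if (deterministic) audio$jitter_sigma <- 0
  audio$seed <- as.integer(seed)
  if (audio$sample_rate <= 2 * max(fit$aud_hi))
    stop("sample_rate must exceed twice the highest formant range",
         call. = FALSE)
  structure(list(gains = gains, audio = audio, fit = fit,
                 deterministic = isTRUE(deterministic),
                 seed = as.integer(seed)),
            class = "run_config")
}

.delay_steps <- function(tau, dt) {
  n <- tau / dt
  if (abs(n - round(n)) > 1e-9)
    stop(sprintf("feedback delay %g ms is not an integer multiple of the ",
                 tau), "control step", call. = FALSE)
  as.integer(round(n))
}

#' Run one closed-loop production
#'
#' Simulates the full control loop for one target. At each control step the
#' delayed auditory and somatosensory errors are read from their delay
#' lines, converted into a feedback command through the Jacobian
#' pseudoinverse, combined with the feedforward command
#' (`u = alpha_ff * ff + u_fb`), and integrated into the articulatory state;
#' the forward fit then produces the sensory frames, which are compared
#' against the target region at that time to give the new errors pushed into
#' the delay lines. A second, time-aligned feedback command (computed from
#' the *current* step's error) is recorded for learning, so that
#' [train()] can credit corrections to the step where the error occurred
#' rather than one sensory delay later. Audio is synthesized over the
#' sensory frames after the loop.
#'
#' @param target a [speech_target()].
#' @param program a [motor_program()] whose length matches the target.
#' @param cfg a [run_config()].
#' @param audio synthesize the waveform (default TRUE; [train()] skips it on
#'   intermediate iterations).
#' @return an object of class `production_trace`: per-step matrices
#'   `states` (T x 13), `u_ff`, `u_fb`, `u`, `u_learn` (T x 13), `aud`
#'   (T x 4), `som` (T x 8), `e_aud`, `e_som`, plus `waveform`, `target`,
#'   `seed`, `control_dt` and the `config` snapshot.
#' @export
produce <- function(target, program, cfg = run_config(), audio = TRUE) {
  validate_target(target)
  dt <- target$control_dt
  n_steps <- ceiling(target_duration(target) / dt)
  if (nrow(program$commands) != n_steps)
    stop(sprintf("program length %d does not match target (%d steps)",
                 nrow(program$commands), n_steps), call. = FALSE)
  if (abs(program$control_dt - dt) > 1e-9)
    stop("program and target control_dt differ", call. = FALSE)
  gains <- cfg$gains; fit <- cfg$fit
  n_a <- .delay_steps(gains$tau_aud, dt)
  n_s <- .delay_steps(gains$tau_som, dt)
  box <- state_box(fit)
  dur <- target_duration(target)

  X <- matrix(0, n_steps, 13); AUD <- matrix(0, n_steps, 4)
  SOM <- matrix(0, n_steps, 8)
  Uff <- matrix(0, n_steps, 13); Ufb <- matrix(0, n_steps, 13)
  U <- matrix(0, n_steps, 13); Ulearn <- matrix(0, n_steps, 13)
  Eaud <- matrix(0, n_steps, 4); Esom <- matrix(0, n_steps, 8)

  x <- initial_state(fit)
  for (t in seq_len(n_steps)) {
    e_del <- error_frame(
      if (t > n_a) Eaud[t - n_a, ] else rep(0, 4),
      if (t > n_s) Esom[t - n_s, ] else rep(0, 8))
    J <- vt_jacobian(x, fit)
    u_fb <- feedback_command(e_del, J, gains)
    u_ff <- program$commands[t, ]
    u <- gains$alpha_ff * u_ff + u_fb
    x <- integrate_state(x, u, dt, box)
    fr <- synth_sample(x, fit)
    tb <- target_trajectory(target, min((t - 0.5) * dt, dur))
    e_aud <- region_error(fr$aud, tb$aud_min, tb$aud_max)
    e_som <- region_error(fr$som, tb$som_min, tb$som_max)
    # time-aligned feedback (for learning credit assignment): the Jacobian
    # at the state that generated the error
    J_now <- vt_jacobian(x, fit)
    u_learn <- feedback_command(error_frame(e_aud, e_som), J_now, gains)

    X[t, ] <- x; AUD[t, ] <- fr$aud; SOM[t, ] <- fr$som
    Uff[t, ] <- u_ff; Ufb[t, ] <- u_fb; U[t, ] <- u; Ulearn[t, ] <- u_learn
    Eaud[t, ] <- e_aud; Esom[t, ] <- e_som
  }
  waveform <- if (audio) synth_audio(AUD, SOM, cfg$audio, dt) else NULL
  structure(list(target = target$name, seed = cfg$seed, control_dt = dt,
                 states = X, u_ff = Uff, u_fb = Ufb, u = U, u_learn = Ulearn,
                 aud = AUD, som = SOM, e_aud = Eaud, e_som = Esom,
                 waveform = waveform, config = cfg),
            class = "production_trace")
}

#' Train a motor program on a target
#'
#' The acquisition protocol: optionally reset the feedforward program to
#' zeros, then repeat `produce -> update_program` for `n_iters` iterations,
#' folding each iteration's time-aligned feedback trace into the program
#' with learning rate `lambda_learn`. The per-iteration summary reports the
#' mean absolute auditory (Hz) and somatosensory (unitless) errors over all
#' steps and dimensions.
#'
#' @param target a [speech_target()].
#' @param n_iters number of training iterations, `>= 1`.
#' @param cfg a [run_config()].
#' @param reset zero the program before training (default TRUE).
#' @param program starting [motor_program()]; default a zero program sized to
#'   the target.
#' @param keep_traces return the per-iteration [produce()] traces.
#' @param audio synthesize audio on the final iteration.
#' @return list with `program` (the trained [motor_program()]), `summary`
#'   (data.frame: iteration, mean_abs_e_aud, mean_abs_e_som) and `traces`.
#' @export
train <- function(target, n_iters = 20, cfg = run_config(), reset = TRUE,
                  program = NULL, keep_traces = TRUE, audio = TRUE) {
  if (n_iters < 1) stop("n_iters must be >= 1", call. = FALSE)
  if (is.null(program)) program <- zero_program(target)
  if (reset)
    program <- motor_program(program$name, nrow(program$commands),
                             control_dt = program$control_dt)
  e_aud <- numeric(n_iters); e_som <- numeric(n_iters)
  traces <- if (keep_traces) vector("list", n_iters) else NULL
  for (k in seq_len(n_iters)) {
    tr <- produce(target, program, cfg, audio = audio && k == n_iters)
    e_aud[k] <- mean(abs(tr$e_aud))
    e_som[k] <- mean(abs(tr$e_som))
    program <- update_program(program, tr$u_learn, cfg$gains$lambda_learn)
    if (keep_traces) traces[[k]] <- tr
  }
  list(program = program,
       summary = data.frame(iteration = seq_len(n_iters),
                            mean_abs_e_aud = e_aud, mean_abs_e_som = e_som),
       traces = traces)
}

# Session cache for reproducibly derived built-in programs.
.program_cache <- new.env(parent = emptyenv())

#' Pretrained motor program for a built-in target
#'
#' The shipped targets (except `example`, which deliberately has none) come
#' with a pretrained feedforward program derived reproducibly at run time by
#' the standard acquisition protocol: weight reset followed by 20 training
#' iterations in deterministic mode. Results are cached per session.
#'
#' @param name a built-in target name other than `"example"`.
#' @param cfg a [run_config()]; defaults to deterministic mode with seed 1.
#' @param n_iters training iterations (default 20).
#' @return a [motor_program()].
#' @export
builtin_program <- function(name, cfg = run_config(deterministic = TRUE),
                            n_iters = 20) {
  if (name == "example")
    stop("the 'example' production has no pretrained motor program",
         call. = FALSE)
  key <- paste(name, cfg$seed, n_iters, sep = "/")
  if (!is.null(.program_cache[[key]])) return(.program_cache[[key]])
  fitres <- train(builtin_target(name, cfg$fit), n_iters, cfg,
                  reset = TRUE, keep_traces = FALSE, audio = FALSE)
  .program_cache[[key]] <- fitres$program
  fitres$program
}

#' Write a production's waveform to a WAV file
#'
#' Mono WAV at the configured sample rate and format; the waveform is scaled
#' to peak at most 1 before quantization.
#'
#' @param trace a [produce()] trace with a waveform.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_wav <- function(trace, path) {
  if (is.null(trace$waveform))
    stop("trace has no waveform (produced with audio = FALSE?)",
         call. = FALSE)
  w <- trace$waveform
  peak <- max(abs(w))
  if (peak > 1) w <- w / peak
  write_wav(w, path, sample_rate = trace$config$audio$sample_rate,
            format = trace$config$audio$format)
}

# Fixed column order of the trace CSV.
.trace_cols <- function() {
  c("step", "t_ms",
    paste0("x", 1:13), paste0("u_ff", 1:13), paste0("u_fb", 1:13),
    paste0("u", 1:13),
    "F0", "F1", "F2", "F3", paste0("place", 1:6), "pressure", "voicing",
    paste0("e_aud", 1:4), paste0("e_som", 1:8))
}

#' Save / load a production trace as CSV
#'
#' One row per control step in a fixed, documented column order (`step`,
#' `t_ms`, states `x1..x13`, commands `u_ff*`, `u_fb*`, `u*`, sensory frames
#' `F0..F3`, `place1..6`, `pressure`, `voicing`, errors `e_aud*`, `e_som*`).
#' Values are written at 17 significant digits, so the numeric columns
#' reload to full precision.
#'
#' @param trace a [produce()] trace.
#' @param path file path.
#' @return `read_trace` returns a data.frame; `save_trace` invisibly returns
#'   `path`.
#' @export
save_trace <- function(trace, path) {
  n <- nrow(trace$states)
  m <- cbind(seq_len(n), seq_len(n) * trace$control_dt,
             trace$states, trace$u_ff, trace$u_fb, trace$u,
             trace$aud, trace$som, trace$e_aud, trace$e_som)
  txt <- apply(m, 2, fmt_num)
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1)
  lines <- c(paste(.trace_cols(), collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_trace
#' @export
read_trace <- function(path) {
  read.csv(path, check.names = FALSE)
}
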