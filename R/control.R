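#' Control loop gains, delays and learning parameters
#'
#' @param alpha_ff feedforward gain (dimensionless multiplier on the motor
#'   program readout).
#' @param alpha_fb_aud auditory feedback gain (per second).
#' @param alpha_fb_som somatosensory feedback gain (per second).
#' @param lambda_learn learning rate: fraction of the iteration's feedback
#'   command folded into the motor program after each production.
#' @param lambda_reg pseudoinverse damping (damped least squares); 0 gives
#'   the plain Moore-Penrose pseudoinverse.
#' @param tau_aud,tau_som sensory feedback delays in ms; must be nonnegative
#'   integer multiples of the control step.
#' @return an object of class `control_gains`.
#' @export
control_gains <- function(alpha_ff = 1.0, alpha_fb_aud = 1.0,
                          alpha_fb_som = 0.5, lambda_learn = 1.0,
                          lambda_reg = 1e-4, tau_aud = 100, tau_som = 50) {
  g <- structure(list(alpha_ff = alpha_ff, alpha_fb_aud = alpha_fb_aud,
                      alpha_fb_som = alpha_fb_som,
                      lambda_learn = lambda_learn, lambda_reg = lambda_reg,
                      tau_aud = tau_aud, tau_som = tau_som),
                 class = "control_gains")
  if (any(unlist(g) < 0))
    stop("gains, damping and delays must all be >= 0", call. = FALSE)
  g
}

#' Signed distance toward a target region
#'
#' Zero while `lo <= y <= hi`; `lo - y` below the region and `hi - y` above
#' it, so the error always points from the current value toward the region
#' and is continuous in `y`. Vectorized elementwise over equal-length inputs.
#'
#' @param y sensory value(s).
#' @param lo,hi region bounds, `lo <= hi` elementwise.
#' @return signed error, same length as `y`.
#' @export
region_error <- function(y, lo, hi) {
  if (any(lo > hi)) stop("region bounds require lo <= hi", call. = FALSE)
  ifelse(y < lo, lo - y, ifelse(y > hi, hi - y, 0))
}

#' Damped or Moore-Penrose pseudoinverse
#'
#' With `lambda_reg = 0`, the Moore-Penrose pseudoinverse via singular value
#' decomposition (zeroing singular values below a numerical-rank tolerance);
#' with `lambda_reg > 0`, the damped least-squares inverse
#' `t(J) %*% solve(J %*% t(J) + lambda_reg * I)`.
#'
#' @param J numeric matrix with finite entries.
#' @param lambda_reg damping, `>= 0`.
#' @return the (damped) pseudoinverse, `ncol(J)` x `nrow(J)`.
#' @export
pseudoinverse <- function(J, lambda_reg = 0) {
  J <- as.matrix(J)
  if (any(!is.finite(J)))
    stop("pseudoinverse requires finite entries", call. = FALSE)
  if (lambda_reg > 0)
    return(t(J) %*% solve(J %*% t(J) + lambda_reg * diag(nrow(J))))
  sv <- svd(J)
  tol <- max(dim(J)) * max(sv$d, 0) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Error frame
#'
#' Bundle of the signed auditory (length 4, Hz) and somatosensory (length 8,
#' unitless) region errors at one control step.
#'
#' @param e_aud length-4 auditory error.
#' @param e_som length-8 somatosensory error.
#' @return an object of class `error_frame`.
#' @export
error_frame <- function(e_aud = rep(0, 4), e_som = rep(0, 8)) {
  structure(list(e_aud = as.numeric(e_aud), e_som = as.numeric(e_som)),
            class = "error_frame")
}

#' Feedback motor command from sensory errors
#'
#' The inverse map: each modality's error is pushed through the damped
#' pseudoinverse of its block of the vocal-tract Jacobian, and the two
#' contributions are combined with independent gains:
#' `u_fb = alpha_fb_aud * pinv(J_aud) %*% e_aud +
#'  alpha_fb_som * pinv(J_som) %*% e_som`. Zero error gives a zero command.
#'
#' @param e an [error_frame()].
#' @param J the 12 x 13 Jacobian from [vt_jacobian()] (rows 1-4 auditory,
#'   rows 5-12 somatosensory).
#' @param gains a [control_gains()].
#' @return length-13 motor velocity (state units per second).
#' @export
feedback_command <- function(e, J, gains = control_gains()) {
  if (nrow(J) != length(e$e_aud) + length(e$e_som))
    stop("Jacobian row count does not match error dimensions", call. = FALSE)
  u <- numeric(ncol(J))
  if (any(e$e_aud != 0))
    u <- u + gains$alpha_fb_aud *
      drop(pseudoinverse(J[seq_along(e$e_aud), , drop = FALSE],
                         gains$lambda_reg) %*% e$e_aud)
  if (any(e$e_som != 0))
    u <- u + gains$alpha_fb_som *
      drop(pseudoinverse(J[length(e$e_aud) + seq_along(e$e_som), ,
                           drop = FALSE], gains$lambda_reg) %*% e$e_som)
  u
}

# ---------------------------------------------------------------------------
# Motor programs
# ---------------------------------------------------------------------------

#' Create a motor program
#'
#' The feedforward motor program for a target: a T x 13 matrix of motor
#' velocities (state units per second), one row per control step, where
#' `T = ceiling(duration / control_dt)`. A freshly reset program is the
#' all-zeros matrix.
#'
#' @param name target label the program belongs to.
#' @param n_steps number of control steps T.
#' @param control_dt control step in ms.
#' @param commands optional T x 13 matrix (default all zeros).
#' @param iterations_trained training iteration counter.
#' @return an object of class `motor_program`.
#' @export
motor_program <- function(name, n_steps, control_dt = 5, commands = NULL,
                          iterations_trained = 0L) {
  if (is.null(commands)) commands <- matrix(0, n_steps, 13)
  commands <- as.matrix(commands)
  if (nrow(commands) != n_steps || ncol(commands) != 13)
    stop("motor program commands must be a T x 13 matrix", call. = FALSE)
  if (any(!is.finite(commands)))
    stop("motor program contains non-finite commands", call. = FALSE)
  structure(list(name = as.character(name), commands = commands,
                 control_dt = as.numeric(control_dt),
                 iterations_trained = as.integer(iterations_trained)),
            class = "motor_program")
}

#' @rdname motor_program
#' @param target a [speech_target()]; `zero_program` sizes an all-zeros
#'   program to it.
#' @export
zero_program <- function(target) {
  n <- ceiling(target_duration(target) / target$control_dt)
  motor_program(target$name, n, control_dt = target$control_dt)
}

#' Feedforward command lookup
#'
#' Pure readout of the program's command at one control step (1-based).
#'
#' @param program a [motor_program()].
#' @param step step index in `1..T`.
#' @return length-13 motor velocity.
#' @export
feedforward_command <- function(program, step) {
  n <- nrow(program$commands)
  if (step < 1 || step > n)
    stop(sprintf("step %d out of range 1..%d", step, n), call. = FALSE)
  program$commands[step, ]
}

#' Integrate the articulatory state one control step
#'
#' Euler step `x + u * dt / 1000`, clamped per dimension to the state box
#' after integration (a state pushed against a bound stays at the bound).
#'
#' @param x length-13 articulatory state.
#' @param u length-13 motor velocity (state units per second).
#' @param dt control step in ms.
#' @param box clamping bounds from [state_box()].
#' @return the new state.
#' @export
integrate_state <- function(x, u, dt, box = state_box()) {
  if (any(!is.finite(u)))
    stop("motor command contains non-finite values", call. = FALSE)
  clamp(x + u * dt / 1000, box$lo, box$hi)
}

#' Fold a production's feedback into the motor program
#'
#' Additive per-step incorporation: `commands[t, ] + lambda_learn *
#' fb_trace[t, ]`, with the training counter incremented. A production that
#' stayed inside the target region everywhere has a zero trace, so a learned
#' program at the zero-error fixed point is stable.
#'
#' @param program a [motor_program()].
#' @param fb_trace T x 13 matrix of feedback commands from the production.
#' @param lambda_learn learning rate.
#' @return the updated [motor_program()].
#' @export
update_program <- function(program, fb_trace, lambda_learn = 1.0) {
  fb_trace <- as.matrix(fb_trace)
  if (!all(dim(fb_trace) == dim(program$commands)))
    stop("feedback trace shape does not match the motor program",
         call. = FALSE)
  motor_program(program$name,
                n_steps = nrow(program$commands),
                control_dt = program$control_dt,
                commands = program$commands + lambda_learn * fb_trace,
                iterations_trained = program$iterations_trained + 1L)
}

#' Read / write motor program files
#'
#' Plain-text persistence: a 3-line header (`name`, `control_dt_ms`,
#' `iterations_trained`) followed by one whitespace-separated row of 13
#' command values per control step, written at 17 significant digits so the
#' round trip is exact at full double precision.
#'
#' @param program a [motor_program()].
#' @param path file path.
#' @return `read_program` returns a [motor_program()]; `write_program`
#'   invisibly returns `path`.
#' @export
write_program <- function(program, path) {
  hdr <- c(paste("name", program$name),
           paste("control_dt_ms", fmt_num(program$control_dt)),
           paste("iterations_trained", program$iterations_trained))
  rows <- apply(program$commands, 1,
                function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_program
#' @export
read_program <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("motor program file too short", call. = FALSE)
  name <- strsplit(lines[1], "\\s+")[[1]][2]
  dt <- as.numeric(strsplit(lines[2], "\\s+")[[1]][2])
  iters <- as.integer(strsplit(lines[3], "\\s+")[[1]][2])
  cmds <- do.call(rbind, lapply(lines[-(1:3)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  motor_program(name, nrow(cmds), control_dt = dt, commands = cmds,
                iterations_trained = iters)
}
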