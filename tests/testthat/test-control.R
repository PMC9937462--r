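test_that("region error is zero inside and points toward the region", {
  expect_equal(region_error(5, 4, 6), 0)
  expect_equal(region_error(3, 4, 6), 1)
  expect_equal(region_error(7, 4, 6), -1)
  expect_equal(region_error(c(3, 5, 7), c(4, 4, 4), c(6, 6, 6)),
               c(1, 0, -1))
  expect_error(region_error(5, 6, 4), "lo <= hi")
  # continuity at the region edges
  eps <- 1e-9
  expect_lt(abs(region_error(4 - eps, 4, 6)), 1e-8)
  expect_lt(abs(region_error(6 + eps, 4, 6)), 1e-8)
})

test_that("pseudoinverse: closed forms and Moore-Penrose property", {
  expect_equal(pseudoinverse(diag(3)), diag(3))
  expect_equal(pseudoinverse(diag(c(2, 0))), diag(c(0.5, 0)))
  set.seed(21)
  for (rep in 1:100) {
    J <- matrix(rnorm(sample(2:12, 1) * 13), ncol = 13)
    Jp <- pseudoinverse(J)
    expect_lt(max(abs(J %*% Jp %*% J - J)), 1e-8)
    # independent oracle
    expect_equal(Jp, MASS::ginv(J), tolerance = 1e-8)
  }
  expect_error(pseudoinverse(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("damped pseudoinverse matches its closed form", {
  set.seed(22)
  J <- matrix(rnorm(4 * 13), 4, 13)
  lam <- 0.1
  expect_equal(pseudoinverse(J, lam),
               t(J) %*% solve(J %*% t(J) + lam * diag(4)))
})

test_that("feedback command combines two independent modality solves", {
  set.seed(23)
  gains <- control_gains(alpha_fb_aud = 1.3, alpha_fb_som = 0.6,
                         lambda_reg = 1e-4)
  J <- vt_jacobian(random_state(), default_forward_fit())
  e_aud <- rnorm(4); e_som <- rnorm(8)
  u <- feedback_command(error_frame(e_aud, e_som), J, gains)
  # componentwise oracle: two damped least-squares solves done by hand
  dls <- function(Jb, e) drop(t(Jb) %*%
    solve(Jb %*% t(Jb) + gains$lambda_reg * diag(nrow(Jb)), e))
  expect_equal(u, 1.3 * dls(J[1:4, ], e_aud) + 0.6 * dls(J[5:12, ], e_som),
               tolerance = 1e-10)
  # zero error -> zero command; zero gain gates a modality out
  expect_equal(feedback_command(error_frame(), J, gains), rep(0, 13))
  g0 <- control_gains(alpha_fb_som = 0)
  u1 <- feedback_command(error_frame(e_aud, e_som), J, g0)
  u2 <- feedback_command(error_frame(e_aud, rnorm(8)), J, g0)
  expect_equal(u1, u2)
  expect_error(feedback_command(error_frame(), J[1:10, ], gains),
               "row count")
})

test_that("feedforward lookup is a pure indexed read with range checks", {
  tg <- quick_target()
  pr <- zero_program(tg)
  expect_equal(feedforward_command(pr, 1), rep(0, 13))
  expect_equal(feedforward_command(pr, nrow(pr$commands)), rep(0, 13))
  expect_error(feedforward_command(pr, nrow(pr$commands) + 1), "out of range")
  expect_error(feedforward_command(pr, 0), "out of range")
  # additive update shows up in the lookup
  fb <- matrix(0.3, nrow(pr$commands), 13)
  pr2 <- update_program(pr, fb, lambda_learn = 1)
  expect_equal(feedforward_command(pr2, 5), rep(0.3, 13))
})

test_that("state integration is Euler with post-step clamping", {
  x <- rep(0, 13)
  expect_equal(integrate_state(x, rep(0, 13), 5), x)
  expect_equal(integrate_state(x, rep(1, 13), 5),
               clamp(rep(0.005, 13), state_box()$lo, state_box()$hi))
  hi <- state_box()$hi
  expect_equal(integrate_state(hi, rep(100, 13), 5), hi)  # stays at bound
  expect_error(integrate_state(x, c(rep(0, 12), Inf), 5), "non-finite")
})

test_that("program update: identity on zero trace, counted always", {
  tg <- quick_target()
  pr <- zero_program(tg)
  z <- matrix(0, nrow(pr$commands), 13)
  up <- update_program(pr, z, lambda_learn = 1)
  expect_equal(up$commands, pr$commands)
  expect_equal(up$iterations_trained, 1L)
  fb <- matrix(rnorm(length(z)), nrow(z), 13)
  same <- update_program(pr, fb, lambda_learn = 0)
  expect_equal(same$commands, pr$commands)
  expect_equal(same$iterations_trained, 1L)
  expect_error(update_program(pr, fb[-1, ]), "shape")
})

test_that("motor program files round-trip at full double precision", {
  set.seed(31)
  pr <- motor_program("demo", 17, control_dt = 5,
                      commands = matrix(rnorm(17 * 13), 17, 13),
                      iterations_trained = 4L)
  path <- withr::local_tempfile(fileext = ".prog")
  write_program(pr, path)
  back <- read_program(path)
  expect_identical(back$commands, pr$commands)
  expect_equal(back$name, "demo")
  expect_equal(back$iterations_trained, 4L)
  expect_equal(back$control_dt, 5)
})
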