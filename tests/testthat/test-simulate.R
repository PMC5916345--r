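test_that("reference TAC matches independent stiff ODE integration", {
  skip_if_not_installed("deSolve")
  sched <- frame_schedule("RAC")
  cp_fun <- function(t) eval_plasma(plasma_input(), t)
  # states: C (one-tissue concentration), I (its running integral)
  rhs <- function(t, y, p) {
    list(c(p$K1 * cp_fun(t) - p$k2 * y[1], y[1]))
  }
  bounds <- c(0, sched$start[-1], 60)
  sol <- deSolve::lsoda(c(C = 0, I = 0), bounds, rhs,
                        list(K1 = 0.1, k2 = 0.1),
                        rtol = 1e-10, atol = 1e-12)
  oracle <- diff(sol[, "I"]) / sched$duration
  got <- simulate_reference_tac(K1p = 0.1, k2p = 0.1, schedule = sched)
  expect_lt(max(abs(got$activity - oracle) / oracle), 1e-3)
})

test_that("zero plasma input produces an all-zero reference TAC", {
  z <- plasma_input(A1 = 0, A2 = 0, A3 = 0)
  got <- simulate_reference_tac(z, schedule = frame_schedule("RAC"))
  expect_equal(got$activity, rep(0, 19))
  expect_error(simulate_reference_tac(K1p = 0, schedule = frame_schedule("RAC")))
})

test_that("graphical-exact irreversible TACs are Patlak-linear by construction", {
  tis0 <- simulate_irreversible_tac(ref_fmt, Ki = 0, V = 1)
  expect_equal(tis0$activity, ref_fmt$activity)
  tis <- simulate_irreversible_tac(ref_fmt, Ki = 0.015, V = 0.5)
  # Patlak transform is exactly linear at every frame, not just late ones
  x <- striatakit:::patlak_ref_integral(ref_fmt) / ref_fmt$activity
  y <- tis$activity / ref_fmt$activity
  fitline <- 0.5 + 0.015 * x
  expect_lt(max(abs(y - fitline)), 1e-12)
  expect_error(simulate_irreversible_tac(ref_fmt, Ki = -1), ">= 0")
})

test_that("compartmental TAC reaches the ODE-oracle Patlak slope", {
  skip_if_not_installed("deSolve")
  K1 <- 0.1; k2 <- 0.05; k3 <- 0.01
  tis <- simulate_irreversible_tac(ref_fmt, mode = "compartmental",
                                   K1 = K1, k2 = k2, k3 = k3)
  rc <- striatakit:::tac_continuous(ref_fmt)
  cr_fun <- stats::approxfun(rc$t, rc$values, rule = 2)
  rhs <- function(t, y, p) {
    list(c(K1 * cr_fun(t) - (k2 + k3) * y[1], k3 * y[1], cr_fun(t)))
  }
  sol <- deSolve::lsoda(c(C1 = 0, C2 = 0, Icr = 0), seq(0, 90, 0.5), rhs,
                        NULL, rtol = 1e-10, atol = 1e-12)
  late <- sol[, "time"] >= 60
  xo <- sol[late, "Icr"] / cr_fun(sol[late, "time"])
  yo <- (sol[late, "C1"] + sol[late, "C2"]) / cr_fun(sol[late, "time"])
  oracle_slope <- stats::coef(stats::lm(yo ~ xo))[2]
  fit <- patlak_fit(tis, ref_fmt, t_star = 60)
  expect_lt(abs(fit$Ki - oracle_slope) / oracle_slope, 0.02)
  # and both approach the asymptotic K1 k3 / (k2 + k3)
  expect_lt(abs(fit$Ki - K1 * k3 / (k2 + k3)) / (K1 * k3 / (k2 + k3)), 0.05)
})

test_that("SRTM forward model is exact at BPnd = 0 and linear in the input", {
  same <- simulate_srtm_tac(ref_rac, R1 = 1, k2 = 0.3, BPnd = 0)
  expect_equal(same$activity, ref_rac$activity, tolerance = 1e-12)
  a <- simulate_srtm_tac(ref_rac, R1 = 1.2, k2 = 0.3, BPnd = 2)
  ref2 <- tac(ref_rac$schedule, 2 * ref_rac$activity)
  b <- simulate_srtm_tac(ref2, R1 = 1.2, k2 = 0.3, BPnd = 2)
  expect_equal(b$activity, 2 * a$activity, tolerance = 1e-12)
  expect_error(simulate_srtm_tac(ref_rac, R1 = 0), "R1")
})

test_that("SRTM forward model matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  R1 <- 1; k2 <- 0.3; BPnd <- 2
  k2a <- k2 / (1 + BPnd)
  rc <- striatakit:::tac_continuous(ref_rac)
  cr_fun <- stats::approxfun(rc$t, rc$values, rule = 2)
  # Z = Cr (x) exp(-k2a t); W = running integral of the tissue curve
  rhs <- function(t, y, p) {
    list(c(cr_fun(t) - k2a * y[1],
           R1 * cr_fun(t) + (k2 - R1 * k2a) * y[1]))
  }
  sched <- ref_rac$schedule
  bounds <- c(0, sched$start[-1], 60)
  sol <- deSolve::lsoda(c(Z = 0, W = 0), bounds, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  oracle <- diff(sol[, "W"]) / sched$duration
  got <- simulate_srtm_tac(ref_rac, R1, k2, BPnd)
  expect_lt(max(abs(got$activity - oracle) / oracle), 1e-3)
})

test_that("frame noise follows the frame-weighted model and is reproducible", {
  expect_equal(add_frame_noise(ref_rac, 0)$activity, ref_rac$activity)
  n1 <- add_frame_noise(ref_rac, 0.5, seed = 11)
  n2 <- add_frame_noise(ref_rac, 0.5, seed = 11)
  expect_identical(n1$activity, n2$activity)
  expect_error(add_frame_noise(ref_rac, -1), ">= 0")
  # Monte-Carlo check of the per-frame SD formula on one frame
  frame1 <- ref_rac$activity[1]
  dur1 <- ref_rac$schedule$duration[1]
  draws <- withr::with_seed(99, {
    replicate(1e4, add_frame_noise(ref_rac, 1)$activity[1])
  })
  expect_lt(abs(stats::sd(draws) / sqrt(frame1 / dur1) - 1), 0.02)
})
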