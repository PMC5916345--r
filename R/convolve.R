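# Numerical core shared by the TAC simulators and the SRTM basis builder.
#
# All continuous-time operations live on a uniform internal grid (default
# 0.1 min).  Convolution with an exponential kernel is computed by an exact
# exponential integrator for piecewise-linear signals: the only discretisation
# error is the piecewise-linear representation of the input itself, so forward
# simulation and fitting that share the same representation are mutually
# consistent to machine precision.

# default internal grid step (minutes)
.DT_INTERNAL <- 0.1

time_grid <- function(schedule, dt = .DT_INTERNAL) {
  n <- round(end_time(schedule) / dt)
  dt * (0:n)
}

# y(t_i) = int_0^{t_i} x(s) exp(-k (t_i - s)) ds for x piecewise linear on a
# uniform grid with step dt.  k = 0 gives the cumulative trapezoid integral.
conv_exp <- function(x, dt, k) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  if (k < 0) stop("rate constant must be >= 0")
  kdt <- k * dt
  if (kdt < 1e-8) {
    # series limit (trapezoid when k = 0)
    E0 <- dt * (1 - kdt / 2 + kdt^2 / 6)
    E1 <- dt^2 / 2 * (1 - 2 * kdt / 3 + kdt^2 / 4)
    a <- exp(-kdt)
  } else {
    a <- exp(-kdt)
    E0 <- (1 - a) / k
    E1 <- (1 - (1 + kdt) * a) / k^2
  }
  c1 <- E1 / dt          # weight on x_{i-1}
  c2 <- E0 - E1 / dt     # weight on x_i
  w <- c1 * x[-n] + c2 * x[-1]
  y <- stats::filter(w, a, method = "recursive")
  c(0, as.numeric(y))
}

cum_trapz <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((x[-n] + x[-1]) / 2 * dt))
}

# frame-average a fine-grid signal: trapezoid integral over each frame divided
# by the frame duration.  Frame boundaries must align with the grid.
frame_average <- function(values, t, schedule) {
  dt <- t[2] - t[1]
  vapply(seq_len(nrow(schedule)), function(i) {
    i0 <- round(schedule$start[i] / dt) + 1L
    i1 <- round((schedule$start[i] + schedule$duration[i]) / dt) + 1L
    seg <- values[i0:i1]
    m <- length(seg)
    (sum(seg) - (seg[1] + seg[m]) / 2) * dt / schedule$duration[i]
  }, numeric(1))
}

# dense frames x grid-points matrix W with W %*% v == frame_average(v); lets
# a whole basis matrix be frame-averaged in one product
frame_avg_matrix <- function(schedule, t) {
  dt <- t[2] - t[1]
  W <- matrix(0, nrow(schedule), length(t))
  for (i in seq_len(nrow(schedule))) {
    i0 <- round(schedule$start[i] / dt) + 1L
    i1 <- round((schedule$start[i] + schedule$duration[i]) / dt) + 1L
    w <- rep(dt, i1 - i0 + 1L)
    w[c(1L, length(w))] <- dt / 2
    W[i, i0:i1] <- w / schedule$duration[i]
  }
  W
}

# Canonical continuous reconstruction of a frame-level TAC: piecewise-linear
# with nodes at the frame boundaries, starting from (0, 0), with node values
# chosen so that the frame-duration average over every frame reproduces the
# frame datum exactly ((v_i + v_{i+1})/2 = a_i, solved by forward recursion).
# Every operation that needs a continuous curve (SRTM forward model and basis
# functions, compartmental simulation) uses this same reconstruction, which
# keeps forward simulation and fitting mutually consistent: the frame average
# of the reconstruction IS the frame data.
tac_continuous <- function(x, dt = .DT_INTERNAL) {
  stopifnot(inherits(x, "tac"))
  n <- nrow(x$schedule)
  bounds <- c(0, x$schedule$start[-1], end_time(x$schedule))
  v <- numeric(n + 1)
  for (i in seq_len(n)) v[i + 1] <- 2 * x$activity[i] - v[i]
  t <- time_grid(x$schedule, dt)
  list(t = t, values = stats::approx(bounds, v, xout = t, rule = 2)$y)
}
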