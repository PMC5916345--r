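#' Log-spaced theta3 grid for basis-function SRTM
#'
#' @param n number of grid points (default 128).
#' @param theta3_min,theta3_max grid bounds in 1/min (defaults 0.006 and 0.6,
#'   bracketing plausible apparent efflux rates `k2a` for reversible D2/3
#'   ligands).
#' @return Sorted numeric vector of `n` log-spaced rates.
#' @export
theta3_grid <- function(n = 128, theta3_min = 0.006, theta3_max = 0.6) {
  stopifnot(n >= 1, theta3_min > 0, theta3_max > theta3_min)
  exp(seq(log(theta3_min), log(theta3_max), length.out = n))
}

# Frame-averaged basis functions B(theta) = C_r (x) exp(-theta t) for a set of
# theta values, built from the canonical continuous reconstruction of the
# reference TAC.  Shared by srtm_fit and the voxelwise map fitter.
srtm_basis_set <- function(ref, theta3 = theta3_grid(), dt = .DT_INTERNAL) {
  stopifnot(inherits(ref, "tac"))
  if (length(theta3) == 0L || any(theta3 <= 0) || is.unsorted(theta3)) {
    stop("theta3 grid must be nonempty, positive and sorted")
  }
  rc <- tac_continuous(ref)
  step <- rc$t[2] - rc$t[1]
  W <- frame_avg_matrix(ref$schedule, rc$t)
  Bgrid <- vapply(theta3, function(th) conv_exp(rc$values, step, th),
                  numeric(length(rc$t)))
  list(
    refF = ref$activity, B = W %*% Bgrid, theta3 = theta3,
    rc = rc, dt = step, W = W, schedule = ref$schedule
  )
}

# Weighted 2-parameter linear solve for every theta on the grid; returns the
# best grid node (ties broken toward the smallest theta3).
srtm_grid_solve <- function(y, basis, w) {
  r <- basis$refF
  B <- basis$B
  a11 <- sum(w * r * r)
  a12 <- colSums(w * r * B)
  a22 <- colSums(w * B * B)
  c1 <- sum(w * r * y)
  c2 <- colSums(w * B * y)
  det <- a11 * a22 - a12^2
  scale <- a11 * a22
  bad <- !is.finite(det) | det <= .Machine$double.eps * pmax(scale, 1)
  if (all(bad)) stop("singular SRTM design (is the reference TAC all zero?)")
  th1 <- (a22 * c1 - a12 * c2) / det
  th2 <- (a11 * c2 - a12 * c1) / det
  rss <- sum(w * y * y) - th1 * c1 - th2 * c2
  rss[bad] <- Inf
  j <- which.min(rss) # first minimum -> smallest theta3 on exact ties
  list(j = j, theta1 = th1[j], theta2 = th2[j], rss = max(rss[j], 0))
}

# 2-parameter solve at a single (possibly off-grid) theta3.
srtm_solve_at <- function(y, basis, w, theta) {
  b <- as.numeric(basis$W %*% conv_exp(basis$rc$values, basis$dt, theta))
  r <- basis$refF
  a11 <- sum(w * r * r); a12 <- sum(w * r * b); a22 <- sum(w * b * b)
  c1 <- sum(w * r * y); c2 <- sum(w * b * y)
  det <- a11 * a22 - a12^2
  if (!is.finite(det) || det <= .Machine$double.eps * max(a11 * a22, 1)) {
    return(list(theta1 = NA_real_, theta2 = NA_real_, rss = Inf))
  }
  th1 <- (a22 * c1 - a12 * c2) / det
  th2 <- (a11 * c2 - a12 * c1) / det
  list(theta1 = th1, theta2 = th2,
       rss = max(sum(w * y * y) - th1 * c1 - th2 * c2, 0))
}

resolve_weights <- function(weights, schedule) {
  if (is.null(weights)) return(rep(1, nrow(schedule)))
  if (is.character(weights)) {
    weights <- match.arg(weights, c("uniform", "frame_duration"))
    return(switch(weights,
      uniform = rep(1, nrow(schedule)),
      frame_duration = schedule$duration
    ))
  }
  weights <- as.numeric(weights)
  if (length(weights) != nrow(schedule) || any(!is.finite(weights)) ||
      any(weights < 0)) {
    stop("weights must be nonnegative, one per frame")
  }
  weights
}

#' Basis-function simplified reference tissue model (SRTM) fit
#'
#' Fits the SRTM operational equation to a target TAC using a reference-region
#' TAC and a basis-function search: for each candidate apparent efflux rate
#' \eqn{\theta_3 = k_{2a}} the basis
#' \eqn{B_{\theta_3}(t) = C_r \otimes e^{-\theta_3 t}} (frame-averaged) is
#' built and the weighted linear least-squares problem
#' \eqn{C_t \approx \theta_1 C_r + \theta_2 B_{\theta_3}} is solved; the
#' \eqn{\theta_3} minimising weighted RSS wins (exact ties go to the smallest
#' \eqn{\theta_3}, the smoother solution). Parameters are reported as
#' \eqn{R_1 = \theta_1}, \eqn{k_2 = \theta_2 + \theta_1 \theta_3} and
#' \eqn{BP_{ND} = k_2/\theta_3 - 1}, the non-displaceable binding potential
#' \eqn{BP_{ND} = f_{ND} B_{avail} / K_D}.
#'
#' By default a local continuous refinement of \eqn{\theta_3} (golden-section
#' search between the grid neighbours of the best node) follows the grid
#' search, removing the grid-resolution floor on `BPnd`; set
#' `refine = FALSE` for the pure grid estimator.
#'
#' @param tissue target [tac()].
#' @param ref reference [tac()] on the identical schedule.
#' @param theta3 candidate grid, see [theta3_grid()].
#' @param weights `NULL`/`"uniform"` (default), `"frame_duration"`, or a
#'   nonnegative numeric vector (one per frame).
#' @param refine logical; continuous theta3 refinement after the grid search.
#' @return Object of class `srtm`: `R1`, `k2` (1/min), `theta3` (1/min),
#'   `BPnd`, `rss`, plus fitted values and inputs for the methods.
#' @seealso [simulate_srtm_tac()] for the forward model, [percent_change()]
#'   for the drug-challenge release statistic.
#' @examples
#' ref <- simulate_reference_tac(schedule = frame_schedule("RAC"))
#' tis <- simulate_srtm_tac(ref, R1 = 1, k2 = 0.3, BPnd = 2.19)
#' fit <- srtm_fit(tis, ref)
#' coef(fit)
#' @export
srtm_fit <- function(tissue, ref, theta3 = theta3_grid(), weights = NULL,
                     refine = TRUE) {
  stopifnot(inherits(tissue, "tac"), inherits(ref, "tac"))
  if (!same_schedule(tissue$schedule, ref$schedule)) {
    stop("tissue and reference schedules differ")
  }
  basis <- srtm_basis_set(ref, theta3)
  w <- resolve_weights(weights, ref$schedule)
  fit <- srtm_fit_engine(tissue$activity, basis, w, refine)
  fit$tissue <- tissue
  fit$ref <- ref
  fit
}

# Engine used by srtm_fit and the voxelwise map fitter (basis precomputed
# once per reference TAC).
srtm_fit_engine <- function(y, basis, w, refine = TRUE) {
  g <- srtm_grid_solve(y, basis, w)
  theta <- basis$theta3[g$j]
  th1 <- g$theta1; th2 <- g$theta2; rss <- g$rss
  if (refine && length(basis$theta3) > 1L) {
    lo <- basis$theta3[max(g$j - 1L, 1L)]
    hi <- basis$theta3[min(g$j + 1L, length(basis$theta3))]
    if (hi > lo) {
      opt <- stats::optimize(
        function(th) srtm_solve_at(y, basis, w, th)$rss,
        lower = lo, upper = hi, tol = 1e-10
      )
      if (opt$objective < rss) {
        s <- srtm_solve_at(y, basis, w, opt$minimum)
        theta <- opt$minimum; th1 <- s$theta1; th2 <- s$theta2; rss <- s$rss
      }
    }
  }
  k2 <- th2 + th1 * theta
  fitted <- th1 * basis$refF +
    th2 * as.numeric(basis$W %*% conv_exp(basis$rc$values, basis$dt, theta))
  structure(
    list(
      R1 = th1, k2 = k2, theta3 = theta, BPnd = k2 / theta - 1,
      rss = rss, weights = w, fitted = fitted, schedule = basis$schedule
    ),
    class = "srtm"
  )
}

#' @export
print.srtm <- function(x, digits = 4, ...) {
  cat("Basis-function SRTM fit\n")
  cat(sprintf("  R1     = %.*g\n", digits, x$R1))
  cat(sprintf("  k2     = %.*g 1/min\n", digits, x$k2))
  cat(sprintf("  theta3 = %.*g 1/min\n", digits, x$theta3))
  cat(sprintf("  BPnd   = %.*g\n", digits, x$BPnd))
  cat(sprintf("  RSS    = %.*g\n", digits, x$rss))
  invisible(x)
}

#' @export
coef.srtm <- function(object, ...) {
  c(R1 = object$R1, k2 = object$k2, theta3 = object$theta3,
    BPnd = object$BPnd)
}

#' @export
summary.srtm <- function(object, ...) object

#' @export
predict.srtm <- function(object, ...) object$fitted

#' @export
residuals.srtm <- function(object, ...) {
  if (is.null(object$tissue)) return(NULL)
  object$tissue$activity - object$fitted
}

#' @export
plot.srtm <- function(x, ...) {
  mid <- x$schedule$mid
  graphics::plot(mid, x$tissue$activity, pch = 19,
                 xlab = "time (min)", ylab = "activity",
                 main = sprintf("SRTM fit (BPnd = %.3g)", x$BPnd), ...)
  graphics::lines(mid, x$fitted, col = "firebrick")
  if (!is.null(x$ref)) graphics::lines(mid, x$ref$activity, col = "grey50", lty = 2)
  invisible(x)
}
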