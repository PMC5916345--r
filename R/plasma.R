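#' Tri-exponential bolus plasma input function
#'
#' A Feng-style model of the arterial concentration after a bolus injection:
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'   + A_3 e^{-\lambda_3 t}}
#' It is zero at `t = 0`, rises sharply to a peak and decays tri-exponentially.
#' The reference-tissue analyses in this package never see the plasma curve --
#' it exists only so the synthetic generator can produce realistic reference
#' TACs -- so its absolute scale is arbitrary.
#'
#' @param A1,A2,A3 amplitudes (default Feng values; `A1` in conc/min, `A2`,
#'   `A3` in conc units).
#' @param lambda1,lambda2,lambda3 decay rates in 1/min, `lambda1 > lambda2 >
#'   lambda3 > 0`.
#' @return A `plasma_input` object, callable via [eval_plasma()].
#' @examples
#' cp <- plasma_input()
#' eval_plasma(cp, c(0, 1, 10))
#' @export
plasma_input <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                         lambda1 = 4.134, lambda2 = 0.1191, lambda3 = 0.0104) {
  if (any(c(lambda1, lambda2, lambda3) <= 0)) stop("decay rates must be > 0")
  structure(
    list(A = c(A1, A2, A3), lambda = c(lambda1, lambda2, lambda3)),
    class = "plasma_input"
  )
}

#' Evaluate a plasma input at arbitrary times
#'
#' @param input a [plasma_input()].
#' @param t times in minutes, `>= 0`.
#' @return Concentrations at `t` (0 at `t = 0`, decaying to 0 at infinity).
#' @export
eval_plasma <- function(input, t) {
  stopifnot(inherits(input, "plasma_input"))
  if (any(t < 0)) stop("t must be >= 0")
  A <- input$A; l <- input$lambda
  (A[1] * t - A[2] - A[3]) * exp(-l[1] * t) +
    A[2] * exp(-l[2] * t) + A[3] * exp(-l[3] * t)
}

#' @export
print.plasma_input <- function(x, ...) {
  cat("Tri-exponential bolus plasma input\n")
  cat("  A      =", paste(signif(x$A, 5), collapse = ", "), "\n")
  cat("  lambda =", paste(signif(x$lambda, 5), collapse = ", "), "1/min\n")
  invisible(x)
}
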