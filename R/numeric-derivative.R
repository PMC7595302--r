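#' Finite-difference derivative oracle
#'
#' Central-difference gradient (\code{order = 1}) or full finite-difference
#' Hessian (\code{order = 2}) of a scalar-valued function, with a relative
#' step per coordinate. Intended as an independent check of the analytic
#' derivatives in tests and diagnostics, not as a production differentiator.
#'
#' Steps default to \code{1e-6 * max(1, |x_j|)} for the gradient and
#' \code{1e-4 * max(1, |x_j|)} for the Hessian (nested central differences).
#'
#' @param f function of a numeric vector returning a finite scalar.
#' @param x numeric vector at which to differentiate.
#' @param order 1 (gradient) or 2 (Hessian).
#' @param step relative step size; default depends on \code{order}.
#' @return length-d gradient vector or d x d Hessian matrix.
#' @export
numeric_derivative <- function(f, x, order = 1, step = NULL) {
  stopifnot(order %in% c(1, 2))
  d <- length(x)
  if (is.null(step)) step <- if (order == 1) 1e-6 else 1e-4
  h <- step * pmax(1, abs(x))
  fx <- f(x)
  if (!is.finite(fx)) stop("non-finite function value at 'x'")
  if (order == 1) {
    grad <- numeric(d)
    for (j in seq_len(d)) {
      e <- numeric(d); e[j] <- h[j]
      fp <- f(x + e); fm <- f(x - e)
      if (!is.finite(fp) || !is.finite(fm))
        stop("non-finite function value near 'x'")
      grad[j] <- (fp - fm) / (2 * h[j])
    }
    return(grad)
  }
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    ej <- numeric(d); ej[j] <- h[j]
    H[j, j] <- (f(x + ej) - 2 * fx + f(x - ej)) / h[j]^2
    if (j < d) for (k in (j + 1):d) {
      ek <- numeric(d); ek[k] <- h[k]
      H[j, k] <- (f(x + ej + ek) - f(x + ej - ek) -
                  f(x - ej + ek) + f(x - ej - ek)) / (4 * h[j] * h[k])
      H[k, j] <- H[j, k]
    }
  }
  H
}
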