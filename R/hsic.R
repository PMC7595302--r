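#' Hilbert-Schmidt Independence Criterion
#'
#' Biased empirical HSIC estimator between paired samples:
#' \deqn{\mathrm{HSIC} = \frac{1}{n^2}\mathrm{Tr}(KHLH)}
#' with K, L the Gram matrices of X and Y and \eqn{H = I - \frac1n 11^\top}
#' the centering matrix. The state object caches the centered matrices
#' \eqn{A = HLH} and \eqn{B = HKH} used by the derivative formulas.
#'
#' @param X n x d_x sample matrix (vectors are treated as one column).
#' @param Y n x d_y sample matrix.
#' @param specK,specL kernel specs for the two sides; default RBF with the
#'   median heuristic scale per variable.
#' @return object of class \code{hsic_state}: \code{value}, \code{X},
#'   \code{Y}, \code{specK}, \code{specL}, \code{K}, \code{L}, \code{A},
#'   \code{B}.
#' @export
hsic <- function(X, Y, specK = NULL, specL = NULL) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1) else as_mat(X)
  Y <- if (is.null(dim(Y))) matrix(Y, ncol = 1) else as_mat(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("'X' and 'Y' must have the same number of rows")
  if (n < 2) stop("need at least 2 samples")
  if (is.null(specK)) specK <- kernel_spec("rbf", gamma = median_heuristic(X))
  if (is.null(specL)) specL <- kernel_spec("rbf", gamma = median_heuristic(Y))
  K <- gram_matrix(specK, X, X)
  L <- gram_matrix(specL, Y, Y)
  H <- diag(n) - matrix(1 / n, n, n)
  A <- H %*% L %*% H
  B <- H %*% K %*% H
  value <- sum(K * t(A)) / n^2   # Tr(K A)
  structure(list(value = value, X = X, Y = Y, specK = specK, specL = specL,
                 K = K, L = L, A = A, B = B),
            class = "hsic_state")
}

#' @export
print.hsic_state <- function(x, ...) {
  cat(sprintf("<hsic_state> n = %d, d_x = %d, d_y = %d, HSIC = %g\n",
              nrow(x$X), ncol(x$X), ncol(x$Y), x$value))
  invisible(x)
}

#' Analytic HSIC gradient with respect to the samples
#'
#' Per-sample, per-feature derivatives of the HSIC value. The elementwise
#' form is \deqn{\frac{\partial \mathrm{HSIC}}{\partial x_i^q} =
#' \frac{2}{n^2} A_i\, \partial_q k(x_i)} (row i of A = HLH contracted with
#' the kernel gradient vector at \eqn{x_i}); it applies to any
#' differentiable kernel. For the RBF kernel the equivalent trace form
#' \deqn{-\frac{2}{\sigma^2 n^2}\mathrm{Tr}(HLH (K \circ M^q))}
#' is also available (\eqn{[M^q]_{ij} = x_i^q - x_j^q} on row i, zero
#' elsewhere; \eqn{\gamma = 1/(2\sigma^2)}); the two code paths agree and
#' are cross-checked in the test suite.
#'
#' @param state an \code{hsic_state}.
#' @param wrt differentiate with respect to \code{"X"} or \code{"Y"}.
#' @param method \code{"elementwise"} (any kernel) or \code{"trace"}
#'   (RBF only, literal trace evaluation).
#' @return n x d matrix of partial derivatives.
#' @export
hsic_gradient <- function(state, wrt = c("X", "Y"),
                          method = c("elementwise", "trace")) {
  wrt <- match.arg(wrt)
  method <- match.arg(method)
  Z <- if (wrt == "X") state$X else state$Y
  spec <- if (wrt == "X") state$specK else state$specL
  Cmat <- if (wrt == "X") state$A else state$B  # terms not depending on Z
  n <- nrow(Z); d <- ncol(Z)
  if (method == "trace") {
    if (spec$family != "rbf")
      stop("the trace form is defined for the RBF kernel only")
    Kz <- if (wrt == "X") state$K else state$L
    sigma2 <- 1 / (2 * spec$gamma)
    out <- matrix(0, n, d)
    for (q in seq_len(d)) {
      diffs <- outer(Z[, q], Z[, q], "-")
      for (i in seq_len(n)) {
        Mq <- matrix(0, n, n)
        Mq[i, ] <- diffs[i, ]
        out[i, q] <- -2 / (sigma2 * n^2) * sum(Cmat * t(Kz * Mq))
      }
    }
    return(out)
  }
  G <- gram_gradient(spec, Z, Z)  # [i, j, q] = d k(z_i, z_j) / d z_i^q
  out <- matrix(0, n, d)
  for (q in seq_len(d))
    out[, q] <- 2 / n^2 * rowSums(Cmat * G[, , q])
  out
}

#' HSIC sensitivity vector field
#'
#' Per-sample derivative vectors of HSIC with respect to both variables and
#' the modulus of the concatenated field,
#' \eqn{|S|_i = \|(\mathrm{d}X_i, \mathrm{d}Y_i)\|_2}, summarizing how much
#' each sample pair influences the dependence estimate.
#'
#' @param state an \code{hsic_state}.
#' @return object of class \code{hsic_field}: \code{Sx}, \code{Sy},
#'   \code{modulus}.
#' @export
sensitivity_field <- function(state) {
  Sx <- hsic_gradient(state, "X")
  Sy <- hsic_gradient(state, "Y")
  structure(list(Sx = Sx, Sy = Sy,
                 modulus = sqrt(rowSums(Sx^2) + rowSums(Sy^2))),
            class = "hsic_field")
}

#' @export
print.hsic_field <- function(x, ...) {
  cat(sprintf("<hsic_field> n = %d, mean |S| = %g, max |S| = %g\n",
              nrow(x$Sx), mean(x$modulus), max(x$modulus)))
  invisible(x)
}

#' Gradient flow on HSIC
#'
#' Moves the samples by explicit Euler steps along (maximize) or against
#' (minimize) the HSIC gradient, recording the HSIC value at every
#' iteration. Kernel scales are computed once at the start and frozen during
#' the flow by default (refreshing the bandwidth each step changes the
#' objective between steps); set \code{refresh_bandwidth = TRUE} to re-apply
#' the median heuristic every iteration.
#'
#' @param X0,Y0 initial paired samples.
#' @param specK,specL kernel specs; default median-heuristic RBF at t = 0.
#' @param step step size in gradient units; \code{"auto"} uses
#'   \code{0.05 * data scale / max |gradient|} at t = 0.
#' @param iters number of iterations.
#' @param direction \code{"maximize"} or \code{"minimize"} dependence.
#' @param move which block to update: \code{"both"}, \code{"X"} or
#'   \code{"Y"}.
#' @param refresh_bandwidth recompute median-heuristic scales each step.
#' @return object of class \code{hsic_flow}: \code{X}, \code{Y} (final),
#'   \code{hsic_trace} (length iters + 1, value before each update and
#'   after the last), \code{step}.
#' @export
hsic_flow <- function(X0, Y0, specK = NULL, specL = NULL, step = "auto",
                      iters = 50, direction = c("maximize", "minimize"),
                      move = c("both", "X", "Y"),
                      refresh_bandwidth = FALSE) {
  direction <- match.arg(direction)
  move <- match.arg(move)
  stopifnot(iters >= 1)
  X <- if (is.null(dim(X0))) matrix(X0, ncol = 1) else as_mat(X0)
  Y <- if (is.null(dim(Y0))) matrix(Y0, ncol = 1) else as_mat(Y0)
  if (is.null(specK)) specK <- kernel_spec("rbf", gamma = median_heuristic(X))
  if (is.null(specL)) specL <- kernel_spec("rbf", gamma = median_heuristic(Y))
  sgn <- if (direction == "maximize") 1 else -1
  st <- hsic(X, Y, specK, specL)
  if (identical(step, "auto")) {
    g0 <- max(abs(hsic_gradient(st, "X")), abs(hsic_gradient(st, "Y")))
    scale <- mean(c(apply(X, 2, stats::sd), apply(Y, 2, stats::sd)))
    step <- if (g0 > 0) 0.05 * scale / g0 else 1
  }
  stopifnot(is.numeric(step), step >= 0)
  trace <- numeric(iters + 1)
  trace[1] <- st$value
  for (t in seq_len(iters)) {
    if (move %in% c("both", "X")) X <- X + sgn * step * hsic_gradient(st, "X")
    if (move %in% c("both", "Y")) Y <- Y + sgn * step * hsic_gradient(st, "Y")
    if (refresh_bandwidth) {
      specK <- kernel_spec("rbf", gamma = median_heuristic(X))
      specL <- kernel_spec("rbf", gamma = median_heuristic(Y))
    }
    st <- hsic(X, Y, specK, specL)
    if (!is.finite(st$value)) stop("HSIC diverged during the flow")
    trace[t + 1] <- st$value
  }
  structure(list(X = X, Y = Y, hsic_trace = trace, step = step,
                 direction = direction),
            class = "hsic_flow")
}

#' @export
print.hsic_flow <- function(x, ...) {
  cat(sprintf("<hsic_flow> %s, %d iterations, HSIC %g -> %g\n",
              x$direction, length(x$hsic_trace) - 1,
              x$hsic_trace[1], x$hsic_trace[length(x$hsic_trace)]))
  invisible(x)
}
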