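#' Kernel evaluation and analytic derivatives
#'
#' \code{kernel_value} evaluates \eqn{k(x,y)} for a pair of points;
#' \code{kernel_gradient} returns the gradient with respect to the FIRST
#' argument, \eqn{[\partial k/\partial x^j]_j}; \code{kernel_hessian} the full
#' \eqn{d \times d} matrix of second partials \eqn{\partial^2 k /
#' \partial x^j \partial x^k}, constructed exactly symmetric.
#'
#' Derivatives are always taken with respect to the first argument; for the
#' stationary families (rbf, ard) derivatives with respect to the second
#' argument are the negatives, for the dot-product families they follow from
#' exchanging the roles of \code{x} and \code{y}.
#'
#' Note on the ARD family: its gradient is
#' \eqn{-((x^j-y^j)/\lambda_j^2)\,k(x,y)} and its second partial
#' \eqn{(((x^j-y^j)^2/\lambda_j^4) - 1/\lambda_j^2)\,k(x,y)}, i.e. the signs
#' follow from differentiating the kernel itself (verified against finite
#' differences); some published tables drop the minus signs.
#'
#' @param spec a \code{\link{kernel_spec}}.
#' @param x,y numeric vectors of equal length d.
#' @return \code{kernel_value}: scalar; \code{kernel_gradient}: length-d
#'   vector; \code{kernel_hessian}: symmetric d x d matrix.
#' @examples
#' sp <- kernel_spec("rbf", gamma = 0.5)
#' kernel_value(sp, c(1, 0), c(0, 1))
#' kernel_gradient(sp, c(1, 0), c(0, 1))
#' @export
kernel_value <- function(spec, x, y) {
  check_pair(spec, x, y)
  switch(spec$family,
    linear = sum(x * y),
    poly   = (spec$gamma * sum(x * y) + spec$c0)^spec$degree,
    rbf    = exp(-spec$gamma * sum((x - y)^2)),
    tanh   = tanh(spec$gamma * sum(x * y) + spec$c0),
    ard    = spec$nu^2 * exp(-0.5 * sum(((x - y) / spec$lengthscales)^2)))
}

#' @rdname kernel_value
#' @export
kernel_gradient <- function(spec, x, y) {
  check_pair(spec, x, y)
  g <- spec$gamma
  switch(spec$family,
    linear = as.numeric(y),
    poly   = g * spec$degree * y * (g * sum(x * y) + spec$c0)^(spec$degree - 1),
    rbf    = -2 * g * (x - y) * exp(-g * sum((x - y)^2)),
    tanh   = {
      u <- g * sum(x * y) + spec$c0
      g * y / cosh(u)^2
    },
    ard    = {
      k <- kernel_value(spec, x, y)
      -((x - y) / spec$lengthscales^2) * k
    })
}

#' @rdname kernel_value
#' @export
kernel_hessian <- function(spec, x, y) {
  check_pair(spec, x, y)
  d <- length(x); g <- spec$gamma
  H <- switch(spec$family,
    linear = matrix(0, d, d),
    poly   = {
      p <- spec$degree
      base <- g * sum(x * y) + spec$c0
      if (p < 2) matrix(0, d, d)
      else (p - 1) * p * g^2 * tcrossprod(y) * base^(p - 2)
    },
    rbf    = {
      k <- exp(-g * sum((x - y)^2))
      u <- x - y
      4 * g^2 * tcrossprod(u) * k - diag(2 * g * k, d)
    },
    tanh   = {
      u <- g * sum(x * y) + spec$c0
      -2 * g^2 * tcrossprod(y) * tanh(u) / cosh(u)^2
    },
    ard    = {
      k <- kernel_value(spec, x, y)
      w <- (x - y) / spec$lengthscales^2
      tcrossprod(w) * k - diag(k / spec$lengthscales^2, d)
    })
  (H + t(H)) / 2  # enforce exact symmetry against round-off
}

#' Higher-order unmixed RBF partial derivatives
#'
#' Computes \eqn{\partial^m k/\partial (x^j)^m} for the RBF kernel through the
#' Faa di Bruno identity applied to \eqn{k = f(g)} with \eqn{f = \exp} and
#' \eqn{g = -\gamma\|x-y\|^2}: since \eqn{\partial g/\partial x^j =
#' -2\gamma(x^j - y^j)}, \eqn{\partial^2 g/\partial (x^j)^2 = -2\gamma} and all
#' higher derivatives of g vanish, the identity collapses to a sum over pairs
#' \eqn{(t_1, t_2)} with \eqn{t_1 + 2 t_2 = m}:
#' \deqn{\partial^m_j k = k \sum_{t_1 + 2t_2 = m}
#'   \frac{m!}{t_1!\, t_2!\, 2^{t_2}} (g')^{t_1} (g'')^{t_2}.}
#'
#' @param spec an RBF \code{\link{kernel_spec}}.
#' @param x,y numeric vectors of equal length.
#' @param j feature index (1-based).
#' @param m derivative order, a positive integer.
#' @return scalar m-th partial derivative.
#' @export
rbf_mth_partial <- function(spec, x, y, j, m) {
  check_pair(spec, x, y)
  if (spec$family != "rbf")
    stop("rbf_mth_partial requires an RBF kernel spec")
  if (m < 1 || m != round(m)) stop("'m' must be a positive integer")
  if (j < 1 || j > length(x)) stop("feature index 'j' out of range")
  g <- spec$gamma
  k <- exp(-g * sum((x - y)^2))
  gp <- -2 * g * (x[j] - y[j])  # g'
  gpp <- -2 * g                 # g''
  total <- 0
  for (t2 in 0:(m %/% 2)) {
    t1 <- m - 2 * t2
    coef <- factorial(m) / (factorial(t1) * factorial(t2) * 2^t2)
    total <- total + coef * gp^t1 * gpp^t2
  }
  k * total
}

## pairwise squared Euclidean distances between rows of X and rows of Y
sqdist <- function(X, Y) {
  sx <- rowSums(X^2); sy <- rowSums(Y^2)
  D <- outer(sx, sy, "+") - 2 * tcrossprod(X, Y)
  D[D < 0] <- 0
  D
}

as_mat <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

check_gram_input <- function(spec, X, Y) {
  if (!inherits(spec, "kernel_spec")) stop("'spec' must be a kernel_spec")
  if (ncol(X) != ncol(Y))
    stop("'X' and 'Y' must have the same number of columns")
  if (spec$family == "ard" && length(spec$lengthscales) != ncol(X))
    stop("ARD lengthscale count does not match data dimension")
  invisible(TRUE)
}

#' Gram matrix
#'
#' Builds the matrix of kernel evaluations \eqn{[K]_{ij} = k(X_i, Y_j)}
#' between the rows of two sample matrices.
#'
#' @param spec a \code{\link{kernel_spec}}.
#' @param X numeric matrix n x d.
#' @param Y numeric matrix m x d (defaults to \code{X}).
#' @return n x m matrix.
#' @export
gram_matrix <- function(spec, X, Y = X) {
  X <- as_mat(X); Y <- as_mat(Y)
  check_gram_input(spec, X, Y)
  g <- spec$gamma
  switch(spec$family,
    linear = tcrossprod(X, Y),
    poly   = (g * tcrossprod(X, Y) + spec$c0)^spec$degree,
    rbf    = exp(-g * sqdist(X, Y)),
    tanh   = tanh(g * tcrossprod(X, Y) + spec$c0),
    ard    = {
      L <- spec$lengthscales
      Xs <- sweep(X, 2, L, "/"); Ys <- sweep(Y, 2, L, "/")
      spec$nu^2 * exp(-0.5 * sqdist(Xs, Ys))
    })
}

#' Stacked Gram derivative tensors
#'
#' \code{gram_gradient} returns the first-derivative tensor with slice
#' \code{[i, l, j]} equal to \eqn{\partial k(x_i, a_l)/\partial x_i^j}
#' (derivative with respect to the evaluation point), so contracting slice j
#' with a coefficient vector over anchors gives the j-th component of an
#' expansion gradient. \code{gram_second_partial} holds the unmixed second
#' partials \eqn{\partial^2 k(x_i, a_l)/\partial (x_i^j)^2} in the same
#' layout. The tensor layout (evaluation point, anchor, feature) is fixed.
#'
#' @param spec a \code{\link{kernel_spec}}.
#' @param Xeval evaluation points, n x d matrix.
#' @param anchors anchor points, m x d matrix.
#' @return numeric array of dimension c(n, m, d).
#' @export
gram_gradient <- function(spec, Xeval, anchors) {
  X <- as_mat(Xeval); A <- as_mat(anchors)
  check_gram_input(spec, X, A)
  n <- nrow(X); m <- nrow(A); d <- ncol(X)
  g <- spec$gamma
  out <- array(0, dim = c(n, m, d))
  K <- gram_matrix(spec, X, A)
  base <- switch(spec$family,
    poly = (g * tcrossprod(X, A) + spec$c0)^(spec$degree - 1),
    tanh = 1 / cosh(g * tcrossprod(X, A) + spec$c0)^2,
    NULL)
  for (j in seq_len(d)) {
    out[, , j] <- switch(spec$family,
      linear = matrix(A[, j], n, m, byrow = TRUE),
      poly   = g * spec$degree * base *
               matrix(A[, j], n, m, byrow = TRUE),
      rbf    = -2 * g * outer(X[, j], A[, j], "-") * K,
      tanh   = g * base * matrix(A[, j], n, m, byrow = TRUE),
      ard    = -(outer(X[, j], A[, j], "-") / spec$lengthscales[j]^2) * K)
  }
  out
}

#' @rdname gram_gradient
#' @export
gram_second_partial <- function(spec, Xeval, anchors) {
  X <- as_mat(Xeval); A <- as_mat(anchors)
  check_gram_input(spec, X, A)
  n <- nrow(X); m <- nrow(A); d <- ncol(X)
  g <- spec$gamma
  out <- array(0, dim = c(n, m, d))
  K <- gram_matrix(spec, X, A)
  if (spec$family == "linear") return(out)
  base <- switch(spec$family,
    poly = if (spec$degree >= 2)
      (g * tcrossprod(X, A) + spec$c0)^(spec$degree - 2) else NULL,
    tanh = {
      u <- g * tcrossprod(X, A) + spec$c0
      tanh(u) / cosh(u)^2
    },
    NULL)
  for (j in seq_len(d)) {
    out[, , j] <- switch(spec$family,
      poly = if (is.null(base)) matrix(0, n, m) else
        (spec$degree - 1) * spec$degree * g^2 *
        matrix(A[, j]^2, n, m, byrow = TRUE) * base,
      rbf  = {
        Dj <- outer(X[, j], A[, j], "-")
        2 * g * (2 * g * Dj^2 - 1) * K
      },
      tanh = -2 * g^2 * matrix(A[, j]^2, n, m, byrow = TRUE) * base,
      ard  = {
        Dj <- outer(X[, j], A[, j], "-")
        lj <- spec$lengthscales[j]
        (Dj^2 / lj^4 - 1 / lj^2) * K
      })
  }
  out
}
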