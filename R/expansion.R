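#' Kernel expansion
#'
#' The universal object every kernel method here reduces to: a function
#' \deqn{f(x) = \sum_{i=1}^n \alpha_i k(x, x_i) + b} determined by a kernel
#' spec, a set of anchor points and a coefficient vector. GP/KRR predictive
#' means, SVM decision functions, Parzen and KECA densities are all instances
#' with a particular \eqn{\alpha}.
#'
#' @param spec a \code{\link{kernel_spec}}.
#' @param anchors n x d matrix of anchor (training) points.
#' @param alpha numeric coefficient vector of length n.
#' @param bias scalar offset b (contributes zero to every derivative).
#' @return object of class \code{kernel_expansion}.
#' @export
kernel_expansion <- function(spec, anchors, alpha, bias = 0) {
  stopifnot(inherits(spec, "kernel_spec"))
  anchors <- as_mat(anchors)
  alpha <- as.numeric(alpha)
  if (nrow(anchors) != length(alpha))
    stop("'alpha' length must equal the number of anchor rows")
  if (!all(is.finite(anchors))) stop("non-finite anchors")
  if (!all(is.finite(alpha))) stop("non-finite coefficients")
  stopifnot(is.numeric(bias), length(bias) == 1L, is.finite(bias))
  structure(list(spec = spec, anchors = anchors, alpha = alpha, bias = bias),
            class = "kernel_expansion")
}

#' @export
print.kernel_expansion <- function(x, ...) {
  cat(sprintf("<kernel_expansion> %s kernel, %d anchors, d = %d, bias = %g\n",
              x$spec$family, nrow(x$anchors), ncol(x$anchors), x$bias))
  invisible(x)
}

eval_matrix <- function(X, d) {
  if (is.null(dim(X))) X <- matrix(X, ncol = d, byrow = TRUE)
  X <- as_mat(X)
  if (ncol(X) != d) stop("evaluation points have wrong dimension")
  X
}

#' Evaluate a kernel expansion
#'
#' @param object a \code{\link{kernel_expansion}}.
#' @param newdata evaluation points: a vector of length d or a matrix with d
#'   columns.
#' @param ... unused.
#' @return numeric vector of f values, one per evaluation point.
#' @export
predict.kernel_expansion <- function(object, newdata, ...) {
  X <- eval_matrix(newdata, ncol(object$anchors))
  drop(gram_matrix(object$spec, X, object$anchors) %*% object$alpha) +
    object$bias
}

#' Derivatives of a kernel expansion
#'
#' All derivatives are linear in the coefficients and reduce to contractions
#' of the Gram-derivative tensors with \eqn{\alpha}:
#' \code{expansion_gradient} gives \eqn{\nabla f(x) = (\nabla K)^\top \alpha},
#' \code{expansion_hessian} the d x d curvature matrix,
#' \code{expansion_laplacian} the sum of unmixed second partials (equal to
#' the trace of the Hessian) and \code{expansion_partial} the m-th unmixed
#' partial with respect to one feature (orders above 2 are available for the
#' RBF family via \code{\link{rbf_mth_partial}}). The bias contributes zero
#' throughout.
#'
#' @param expn a \code{\link{kernel_expansion}}.
#' @param x a single evaluation point (vector) or, for
#'   \code{expansion_gradient} and \code{expansion_laplacian}, a matrix of
#'   points (rows).
#' @param j feature index for \code{expansion_partial}.
#' @param m derivative order for \code{expansion_partial}.
#' @return \code{expansion_gradient}: a d-vector (or n x d matrix for matrix
#'   input); \code{expansion_hessian}: d x d matrix;
#'   \code{expansion_laplacian}: scalar (or n-vector);
#'   \code{expansion_partial}: scalar.
#' @export
expansion_gradient <- function(expn, x) {
  X <- eval_matrix(x, ncol(expn$anchors))
  G <- gram_gradient(expn$spec, X, expn$anchors)
  out <- vapply(seq_len(dim(G)[3]),
                function(j) drop(G[, , j, drop = FALSE][, , 1] %*% expn$alpha),
                numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X))
  if (is.null(dim(x)) && nrow(X) == 1L) drop(out) else out
}

#' @rdname expansion_gradient
#' @export
expansion_hessian <- function(expn, x) {
  x <- as.numeric(x)
  d <- ncol(expn$anchors)
  if (length(x) != d) stop("evaluation point has wrong dimension")
  spec <- expn$spec
  if (spec$family == "rbf") {
    # vectorized over anchors: H = 4 g^2 D' diag(w) D - 2 g sum(w) I,
    # with D_i = x - a_i and w_i = alpha_i k(x, a_i)
    D <- sweep(expn$anchors, 2, x, FUN = function(a, b) b - a)
    k <- exp(-spec$gamma * rowSums(D^2))
    w <- expn$alpha * k
    H <- 4 * spec$gamma^2 * crossprod(D * w, D) -
      diag(2 * spec$gamma * sum(w), d)
  } else if (spec$family == "ard") {
    D <- sweep(expn$anchors, 2, x, FUN = function(a, b) b - a)
    Dw <- sweep(D, 2, spec$lengthscales^2, "/")
    k <- spec$nu^2 * exp(-0.5 * rowSums(sweep(D, 2, spec$lengthscales, "/")^2))
    w <- expn$alpha * k
    H <- crossprod(Dw * w, Dw) - diag(sum(w) / spec$lengthscales^2, d)
  } else {
    H <- matrix(0, d, d)
    for (i in seq_len(nrow(expn$anchors)))
      H <- H + expn$alpha[i] * kernel_hessian(spec, x, expn$anchors[i, ])
  }
  (H + t(H)) / 2
}

#' @rdname expansion_gradient
#' @export
expansion_laplacian <- function(expn, x) {
  X <- eval_matrix(x, ncol(expn$anchors))
  S <- gram_second_partial(expn$spec, X, expn$anchors)
  per_feature <- vapply(seq_len(dim(S)[3]),
                        function(j) drop(S[, , j, drop = FALSE][, , 1] %*%
                                           expn$alpha),
                        numeric(nrow(X)))
  out <- rowSums(matrix(per_feature, nrow = nrow(X)))
  if (is.null(dim(x)) && nrow(X) == 1L) out[1] else out
}

#' @rdname expansion_gradient
#' @export
expansion_partial <- function(expn, x, j, m = 1) {
  x <- as.numeric(x)
  d <- ncol(expn$anchors)
  if (length(x) != d) stop("evaluation point has wrong dimension")
  if (j < 1 || j > d) stop("feature index out of range")
  if (m < 1) stop("'m' must be >= 1")
  n <- nrow(expn$anchors)
  per_anchor <- if (m == 1) {
    vapply(seq_len(n),
           function(i) kernel_gradient(expn$spec, x, expn$anchors[i, ])[j], 0)
  } else if (m == 2) {
    vapply(seq_len(n),
           function(i) kernel_hessian(expn$spec, x, expn$anchors[i, ])[j, j], 0)
  } else {
    if (expn$spec$family != "rbf")
      stop("orders m > 2 are supported for the RBF family only")
    vapply(seq_len(n),
           function(i) rbf_mth_partial(expn$spec, x, expn$anchors[i, ], j, m),
           0)
  }
  sum(per_anchor * expn$alpha)
}

#' Sensitivity map of a kernel expansion
#'
#' Empirical sensitivity summaries of the squared gradient of f over an
#' evaluation set: the feature sensitivity
#' \deqn{s_j = \frac1n \sum_i (\partial f(x_i)/\partial x^j)^2}
#' and the point sensitivity
#' \deqn{q_i = \frac1d \sum_j (\partial f(x_i)/\partial x^j)^2.}
#' The two summaries share all squared derivatives, so
#' \eqn{n \sum_j s_j = d \sum_i q_i} holds as an algebraic identity.
#'
#' @param expn a \code{\link{kernel_expansion}}.
#' @param Xeval evaluation points (defaults to the expansion anchors).
#' @return object of class \code{sensitivity_report}: a list with
#'   \code{feature_sensitivity} (length d), \code{point_sensitivity}
#'   (length n_eval) and \code{eval_points}.
#' @export
sensitivity_map <- function(expn, Xeval = expn$anchors) {
  X <- eval_matrix(Xeval, ncol(expn$anchors))
  if (nrow(X) == 0L) stop("empty evaluation set")
  G <- expansion_gradient(expn, X)
  G <- matrix(G, nrow = nrow(X))
  sensitivity_report(G^2, X)
}

## shared constructor: G2 = matrix of squared partial derivatives (n x d)
sensitivity_report <- function(G2, X) {
  structure(list(feature_sensitivity = colMeans(G2),
                 point_sensitivity = rowMeans(G2),
                 eval_points = X),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>", length(x$point_sensitivity), "points,",
      length(x$feature_sensitivity), "features\n")
  cat("  feature sensitivities s:",
      paste(signif(x$feature_sensitivity, 4), collapse = ", "), "\n")
  cat("  point sensitivity q: mean", signif(mean(x$point_sensitivity), 4),
      " max", signif(max(x$point_sensitivity), 4), "\n")
  invisible(x)
}

#' Export a sensitivity report as a delimited table
#'
#' Writes one row per evaluation point with its coordinates and point
#' sensitivity; feature sensitivities go to a commented header line.
#'
#' @param report a \code{sensitivity_report}.
#' @param path output CSV path.
#' @return invisibly, the data frame written.
#' @export
write_sensitivity <- function(report, path) {
  df <- as.data.frame(report$eval_points)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$point_sensitivity <- report$point_sensitivity
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_sensitivity: ",
                    paste(format(report$feature_sensitivity, digits = 12),
                          collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Function-norm and derivative-norm quadratic forms
#'
#' For an expansion with coefficients \eqn{\alpha} and Gram / Gram-derivative
#' matrices built at the evaluation points, returns the four quadratic forms
#' \eqn{\|f\|_H^2 = \alpha^\top K \alpha},
#' \eqn{\|f\|_2^2 = \alpha^\top K^\top K \alpha},
#' \eqn{\|\nabla f\|_2^2 = \alpha^\top (\nabla K)^\top (\nabla K) \alpha} and
#' \eqn{\|\nabla^2 f\|_2^2 = \alpha^\top (\nabla^2 K)^\top (\nabla^2 K)
#' \alpha}, with the derivative matrices stacked feature-wise ((n d) x n) so
#' the forms are defined for any d. The RKHS norm requires the evaluation
#' points to coincide in number with the anchors (it is the native quadratic
#' form in \eqn{\alpha}); it is reported as \code{NA} otherwise.
#'
#' @param expn a \code{\link{kernel_expansion}}.
#' @param Xeval evaluation points (defaults to the anchors).
#' @return list with elements \code{rkhs}, \code{l2}, \code{grad},
#'   \code{curv} (each a squared norm).
#' @export
derivative_norms <- function(expn, Xeval = expn$anchors) {
  X <- eval_matrix(Xeval, ncol(expn$anchors))
  a <- expn$alpha
  K <- gram_matrix(expn$spec, X, expn$anchors)
  G <- gram_gradient(expn$spec, X, expn$anchors)
  S <- gram_second_partial(expn$spec, X, expn$anchors)
  Ka <- drop(K %*% a)
  Ga <- vapply(seq_len(dim(G)[3]),
               function(j) drop(G[, , j, drop = FALSE][, , 1] %*% a),
               numeric(nrow(X)))
  Sa <- vapply(seq_len(dim(S)[3]),
               function(j) drop(S[, , j, drop = FALSE][, , 1] %*% a),
               numeric(nrow(X)))
  list(rkhs = if (nrow(X) == length(a)) sum(a * Ka) else NA_real_,
       l2   = sum(Ka^2),
       grad = sum(Ga^2),
       curv = sum(Sa^2))
}
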