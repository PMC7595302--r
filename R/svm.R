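#' Binary soft-margin SVM
#'
#' Fits the standard C-SVM dual
#' \deqn{\min_\alpha \tfrac12 \alpha^\top (yy^\top \circ K)\alpha -
#'   1^\top\alpha, \quad 0 \le \alpha_i \le C, \; y^\top\alpha = 0,}
#' via the interior-point QP solver \code{kernlab::ipop}. The decision
#' function is the kernel expansion
#' \eqn{f(x) = \sum_i y_i \alpha_i k(x, x_i) + b}; the bias is recovered
#' from the free support vectors (or from the KKT interval midpoint when
#' none are free).
#'
#' @param X n x d input matrix.
#' @param y labels in \{-1, +1\}.
#' @param spec a \code{\link{kernel_spec}}; default RBF with median-heuristic
#'   scale.
#' @param C box constraint, positive.
#' @param tol support-vector threshold relative to C.
#' @return object of class \code{svm_model}: the decision
#'   \code{\link{kernel_expansion}} (coefficients \eqn{y_i\alpha_i}, bias b),
#'   plus \code{alpha}, \code{labels}, \code{sv_mask}, \code{C}.
#' @export
svm_fit <- function(X, y, spec = NULL, C = 1, tol = 1e-6) {
  X <- as_mat(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), C > 0)
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(spec)) spec <- kernel_spec("rbf", gamma = median_heuristic(X))
  n <- nrow(X)
  K <- gram_matrix(spec, X, X)
  Q <- (y %o% y) * K
  sol <- kernlab::ipop(c = matrix(-1, n, 1), H = Q + diag(1e-8, n),
                       A = matrix(y, 1, n), b = 0,
                       l = matrix(0, n, 1), u = matrix(C, n, 1),
                       r = 0, sigf = 9, maxiter = 80)
  alpha <- pmin(pmax(as.numeric(kernlab::primal(sol)), 0), C)
  f0 <- drop(K %*% (alpha * y))  # decision values without bias
  sv_tol <- tol * C
  free <- alpha > sv_tol & alpha < C - sv_tol
  if (any(free)) {
    b <- mean(y[free] - f0[free])
  } else {
    # KKT interval: y_i(f0_i + b) >= 1 for alpha = 0, <= 1 for alpha = C
    bnd <- y - f0   # b bound values; role depends on label/alpha status
    lo_set <- (alpha <= sv_tol & y > 0) | (alpha >= C - sv_tol & y < 0)
    hi_set <- (alpha <= sv_tol & y < 0) | (alpha >= C - sv_tol & y > 0)
    lo <- if (any(lo_set)) max(bnd[lo_set]) else -Inf
    hi <- if (any(hi_set)) min(bnd[hi_set]) else Inf
    b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else 0
  }
  structure(list(expansion = kernel_expansion(spec, X, alpha * y, bias = b),
                 alpha = alpha, labels = y, sv_mask = alpha > sv_tol,
                 C = C),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %s kernel, n = %d, C = %g, support vectors = %d\n",
              x$expansion$spec$family, length(x$alpha), x$C, sum(x$sv_mask)))
  invisible(x)
}

#' SVM decision values and the tanh-masked decision
#'
#' \code{decision_value} evaluates \eqn{f(x) = \sum_i y_i\alpha_i k(x,x_i) +
#' b}; \code{masked_value} applies the differentiable surrogate of the sign
#' mask, \eqn{g(x) = \tanh(f(x))}, which shares its sign with f so the
#' predicted label is unchanged.
#'
#' @param model a fitted \code{svm_model}.
#' @param x evaluation point(s).
#' @return numeric vector of decision (resp. masked) values.
#' @export
decision_value <- function(model, x) {
  predict(model$expansion, x)
}

#' @rdname decision_value
#' @export
masked_value <- function(model, x) {
  tanh(decision_value(model, x))
}

#' @rdname decision_value
#' @param ... unused.
#' @param object a fitted \code{svm_model}.
#' @param newdata evaluation point(s).
#' @export
predict.svm_model <- function(object, newdata, ...) {
  sign(decision_value(object, newdata))
}

#' Gradient of the masked SVM decision
#'
#' Product-rule decomposition of
#' \eqn{\partial \tanh(f(x))/\partial x^j = (1 - g^2(x))\,\partial
#' f(x)/\partial x^j}: the scalar mask factor \eqn{1 - \tanh^2(f(x))}
#' (maximal on the decision boundary, vanishing deep inside either class)
#' times the kernel-expansion gradient of f.
#'
#' @param model a fitted \code{svm_model}.
#' @param x a single evaluation point.
#' @return list with \code{gradient} (full masked gradient),
#'   \code{mask_factor} (scalar) and \code{kernel_gradient} (gradient of f).
#' @export
masked_gradient <- function(model, x) {
  f <- decision_value(model, x)
  kg <- expansion_gradient(model$expansion, x)
  mf <- 1 - tanh(f)^2
  list(gradient = mf * kg, mask_factor = mf, kernel_gradient = kg)
}

#' Mask / kernel / composite sensitivity decomposition
#'
#' Point and feature sensitivities of the three components of the masked
#' decision derivative over an evaluation set: the kernel part
#' \eqn{\partial f}, the mask factor \eqn{1 - g^2} (a scalar field, treated
#' as a per-point squared weight applied uniformly over features), and the
#' composite product. The composite point sensitivity concentrates along the
#' decision boundary, where the mask factor is largest.
#'
#' @param model a fitted \code{svm_model}.
#' @param Xeval evaluation points (default: training points).
#' @return list of three \code{sensitivity_report}s: \code{mask},
#'   \code{kernel}, \code{composite}.
#' @export
margin_sensitivity <- function(model, Xeval = model$expansion$anchors) {
  X <- eval_matrix(Xeval, ncol(model$expansion$anchors))
  if (nrow(X) == 0L) stop("empty evaluation set")
  f <- decision_value(model, X)
  G <- matrix(expansion_gradient(model$expansion, X), nrow = nrow(X))
  mf <- 1 - tanh(f)^2
  d <- ncol(X)
  list(mask = sensitivity_report(matrix(mf^2, nrow(X), d), X),
       kernel = sensitivity_report(G^2, X),
       composite = sensitivity_report((mf * G)^2, X))
}

#' Cross-validated SVM hyperparameter selection
#'
#' k-fold grid search over (C, gamma) for the RBF kernel, selecting the pair
#' with the highest mean held-out accuracy, then refitting on all data.
#'
#' @param X,y training data as in \code{\link{svm_fit}}.
#' @param C_grid candidate box constraints.
#' @param gamma_grid candidate RBF scales; default scales the median
#'   heuristic by 1/4, 1, 4.
#' @param folds number of folds.
#' @param seed seed controlling the fold assignment.
#' @return fitted \code{svm_model} with attributes \code{cv_accuracy},
#'   \code{cv_C}, \code{cv_gamma}.
#' @export
svm_fit_cv <- function(X, y, C_grid = c(0.1, 1, 10, 100),
                       gamma_grid = NULL, folds = 3, seed = 1) {
  X <- as_mat(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(gamma_grid)) gamma_grid <- median_heuristic(X) * c(0.25, 1, 4)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  best <- list(acc = -Inf)
  for (C in C_grid) for (g in gamma_grid) {
    acc <- 0
    ok <- TRUE
    for (fo in seq_len(folds)) {
      tr <- fold_id != fo
      if (length(unique(y[tr])) < 2) { ok <- FALSE; break }
      m <- tryCatch(svm_fit(X[tr, , drop = FALSE], y[tr],
                            kernel_spec("rbf", gamma = g), C = C),
                    error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      pred <- predict(m, X[!tr, , drop = FALSE])
      acc <- acc + mean(pred == y[!tr]) / folds
    }
    if (ok && acc > best$acc) best <- list(acc = acc, C = C, gamma = g)
  }
  if (!is.finite(best$acc)) stop("cross-validation failed on every grid point")
  model <- svm_fit(X, y, kernel_spec("rbf", gamma = best$gamma), C = best$C)
  attr(model, "cv_accuracy") <- best$acc
  attr(model, "cv_C") <- best$C
  attr(model, "cv_gamma") <- best$gamma
  model
}
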