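#' Parzen (kernel) density estimate as a kernel expansion
#'
#' The Parzen window estimate
#' \deqn{\hat p(x) = \frac1n \sum_{i=1}^n \kappa_\sigma(x, x_i)}
#' with the Gaussian density kernel \eqn{\kappa_\sigma(x,y) =
#' (2\pi\sigma^2)^{-d/2}\exp(-\|x-y\|^2/(2\sigma^2))}, represented internally
#' as an RBF kernel expansion with \eqn{\gamma = 1/(2\sigma^2)} and
#' coefficients \eqn{\alpha_i = (2\pi\sigma^2)^{-d/2}/n}, so all expansion
#' derivative machinery applies directly to the density.
#'
#' @param X n x d sample matrix.
#' @param sigma isotropic bandwidth; default is the mean of the per-dimension
#'   Silverman rule values.
#' @return object of class \code{density_model} with \code{mode = "parzen"}.
#' @export
parzen_fit <- function(X, sigma = NULL) {
  X <- as_mat(X)
  if (is.null(sigma)) sigma <- silverman_bw(X)
  stopifnot(is.finite(sigma), sigma > 0)
  n <- nrow(X); d <- ncol(X)
  const <- (2 * pi * sigma^2)^(-d / 2)
  spec <- kernel_spec("rbf", sigma = sigma)
  structure(list(expansion = kernel_expansion(spec, X, rep(const / n, n)),
                 mode = "parzen", sigma = sigma, rank = n,
                 eigvecs = NULL, eigvals = NULL, selection = NULL),
            class = "density_model")
}

#' Per-dimension Silverman bandwidth, averaged to an isotropic value
#'
#' \eqn{\sigma_j = (4/(d+2))^{1/(d+4)} n^{-1/(d+4)} \mathrm{sd}(x^j)};
#' the isotropic bandwidth is the mean over dimensions.
#'
#' @param X sample matrix.
#' @return positive scalar.
#' @export
silverman_bw <- function(X) {
  X <- as_mat(X)
  n <- nrow(X); d <- ncol(X)
  f <- (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
  mean(f * apply(X, 2, stats::sd))
}

#' Eigendecomposition-restricted density estimate (KECA-style)
#'
#' Restricts the Parzen estimate to r components of the eigendecomposition
#' of the un-centered Gram matrix \eqn{K = E D E^\top} of the density
#' kernel: with \eqn{E_r} the retained eigenvectors, the coefficient vector
#' becomes \eqn{\alpha = \frac1n E_r E_r^\top 1_n} (the 1/n keeps the
#' \eqn{r = n} case identical to the Parzen estimate; for \eqn{r < n} the
#' restricted density is a smoothed, in general unnormalized,
#' approximation). Components are retained either by eigenvalue
#' (\code{selection = "variance"}) or by their information-potential
#' (Renyi entropy) contribution \eqn{d_i (e_i^\top 1_n)^2}
#' (\code{selection = "entropy"}, the KECA ranking).
#'
#' @param X n x d sample matrix.
#' @param r number of retained components, 1 <= r <= n.
#' @param selection \code{"entropy"} or \code{"variance"}.
#' @param sigma bandwidth as in \code{\link{parzen_fit}}.
#' @return object of class \code{density_model} with \code{mode = "keca"}.
#' @export
keca_fit <- function(X, r, selection = c("entropy", "variance"),
                     sigma = NULL) {
  X <- as_mat(X)
  selection <- match.arg(selection)
  n <- nrow(X)
  if (r < 1 || r > n) stop("'r' must be between 1 and n")
  if (is.null(sigma)) sigma <- silverman_bw(X)
  base <- parzen_fit(X, sigma)
  K <- gram_matrix(base$expansion$spec, X, X)  # un-centered Gram
  eig <- eigen(K, symmetric = TRUE)
  E <- eig$vectors; dvals <- eig$values
  score <- switch(selection,
    variance = dvals,
    entropy  = dvals * drop(crossprod(E, rep(1, n)))^2)
  keep <- order(score, decreasing = TRUE)[seq_len(r)]
  Er <- E[, keep, drop = FALSE]
  const <- (2 * pi * sigma^2)^(-ncol(X) / 2)
  alpha <- const / n * drop(Er %*% crossprod(Er, rep(1, n)))
  structure(list(expansion = kernel_expansion(base$expansion$spec, X, alpha),
                 mode = "keca", sigma = sigma, rank = as.integer(r),
                 eigvecs = Er, eigvals = dvals[keep], selection = selection),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> %s, n = %d, d = %d, sigma = %g",
              x$mode, nrow(x$expansion$anchors), ncol(x$expansion$anchors),
              x$sigma))
  if (x$mode == "keca")
    cat(sprintf(", rank = %d (%s selection)", x$rank, x$selection))
  cat("\n")
  invisible(x)
}

#' Evaluate a fitted density model
#'
#' @param object a \code{density_model}.
#' @param newdata evaluation point(s).
#' @param ... unused.
#' @return density values.
#' @export
predict.density_model <- function(object, newdata, ...) {
  predict(object$expansion, newdata)
}

#' Density-ridge score
#'
#' A point lies on the \code{ridge_dim}-dimensional ridge (principal curve
#' for \code{ridge_dim = 1}) of the density when the density gradient is
#' orthogonal to the trailing Hessian eigenvectors. The score is
#' \eqn{\|V(x)^\top \nabla \hat p(x)\|} where the columns of V(x) are
#' \code{d - ridge_dim} eigenvectors of the density Hessian at x. By default
#' (\code{eigvec_rule = "smallest"}, the density-ridge convention) V holds
#' the eigenvectors with the smallest, most negative, eigenvalues — the
#' directions across the ridge; \code{eigvec_rule = "largest"} reproduces
#' the alternative top-eigenvector reading.
#'
#' @param model a \code{density_model}.
#' @param x a single evaluation point.
#' @param ridge_dim ridge dimensionality, 1 <= ridge_dim < d.
#' @param eigvec_rule which Hessian eigenvectors to project onto.
#' @param scale \code{"log"} (default) scores the gradient and Hessian of
#'   \eqn{\log \hat p}; \code{"density"} uses \eqn{\hat p} itself. The two
#'   share the same zero set (log is monotone), but the log-density Hessian
#'   stays negative definite across the flanks of a Gaussian-like crest, so
#'   percentile thresholds on the score do not pick up spurious
#'   inflection-zone points in the tails — the usual convention in the
#'   principal-curve literature.
#' @return list with \code{score} (>= 0), \code{eigvals} (of the projection
#'   eigenvectors) and \code{qualifies} (all projection eigenvalues < 0).
#' @export
ridge_score <- function(model, x, ridge_dim = 1,
                        eigvec_rule = c("smallest", "largest"),
                        scale = c("log", "density")) {
  eigvec_rule <- match.arg(eigvec_rule)
  scale <- match.arg(scale)
  d <- ncol(model$expansion$anchors)
  if (ridge_dim < 1 || ridge_dim >= d)
    stop("'ridge_dim' must satisfy 1 <= ridge_dim < d")
  g <- expansion_gradient(model$expansion, x)
  H <- expansion_hessian(model$expansion, x)
  if (scale == "log") {
    p <- predict(model$expansion, x)
    p <- max(p, .Machine$double.xmin)
    g <- g / p
    H <- H / p - tcrossprod(g)
  }
  eig <- eigen(H, symmetric = TRUE)  # eigenvalues in decreasing order
  idx <- if (eigvec_rule == "smallest") {
    seq(ridge_dim + 1, d)        # trailing (most negative)
  } else {
    seq_len(d - ridge_dim)       # leading
  }
  V <- eig$vectors[, idx, drop = FALSE]
  list(score = sqrt(sum(drop(crossprod(V, g))^2)),
       eigvals = eig$values[idx],
       qualifies = all(eig$values[idx] < 0))
}

#' Extract density-ridge points from an evaluation set
#'
#' Scores every evaluation point with \code{\link{ridge_score}} and retains
#' those with score at most \code{epsilon} (default: the 5th percentile of
#' the scores). Under the default eigenvector rule a point must additionally
#' have negative trailing Hessian eigenvalues to qualify (it sits on a
#' density crest, not in a valley). Retained points are ordered along the
#' curve via \code{\link{order_curve}}.
#'
#' @param model a \code{density_model}.
#' @param Xeval candidate points (rows); typically the sample itself.
#' @param ridge_dim ridge dimensionality.
#' @param epsilon score threshold; \code{NULL} for the 5th percentile.
#' @param eigvec_rule,scale passed to \code{\link{ridge_score}}.
#' @param k neighbors for the ordering graph.
#' @return object of class \code{ridge_result}: \code{ridge_points},
#'   \code{ridge_scores} (all scores), \code{retained} (logical),
#'   \code{epsilon}, \code{ordering} (Dijkstra distances and component
#'   labels for the retained points).
#' @export
extract_ridge <- function(model, Xeval, ridge_dim = 1, epsilon = NULL,
                          eigvec_rule = c("smallest", "largest"), k = 5,
                          scale = c("log", "density")) {
  eigvec_rule <- match.arg(eigvec_rule)
  scale <- match.arg(scale)
  X <- eval_matrix(Xeval, ncol(model$expansion$anchors))
  stopifnot(is.null(epsilon) || epsilon > 0)
  n <- nrow(X)
  scores <- numeric(n); quals <- logical(n)
  for (i in seq_len(n)) {
    rs <- ridge_score(model, X[i, ], ridge_dim, eigvec_rule, scale)
    scores[i] <- rs$score
    quals[i] <- rs$qualifies
  }
  if (is.null(epsilon)) epsilon <- stats::quantile(scores, 0.05, names = FALSE)
  retained <- scores <= epsilon
  if (eigvec_rule == "smallest") retained <- retained & quals
  if (!any(retained)) {
    warning("no evaluation point passes the ridge threshold")
    ordering <- list(distance = numeric(0), component = integer(0))
  } else {
    ordering <- order_curve(X[retained, , drop = FALSE], k = k)
  }
  structure(list(ridge_points = X[retained, , drop = FALSE],
                 ridge_scores = scores, retained = retained,
                 epsilon = epsilon, ordering = ordering),
            class = "ridge_result")
}

#' @export
print.ridge_result <- function(x, ...) {
  cat(sprintf("<ridge_result> %d / %d points retained (epsilon = %g)\n",
              sum(x$retained), length(x$retained), x$epsilon))
  invisible(x)
}

#' Order points along a curve by graph shortest-path distance
#'
#' Builds a mutual k-nearest-neighbor graph over the points with Euclidean
#' edge weights, picks per connected component an endpoint (a vertex of
#' maximal graph eccentricity) and returns the Dijkstra shortest-path
#' distance of every point from that endpoint, together with the component
#' label. Used to color/order ridge points along the principal curve.
#'
#' @param points m x d matrix.
#' @param k neighborhood size.
#' @return list with \code{distance} (length m) and \code{component}
#'   (integer labels).
#' @export
order_curve <- function(points, k = 5) {
  P <- as_mat(points)
  m <- nrow(P)
  if (m == 0L) stop("at least one point required")
  if (m == 1L) return(list(distance = 0, component = 1L))
  D <- as.matrix(stats::dist(P))
  kk <- min(k, m - 1)
  nn <- t(apply(D, 1, function(row) order(row)[2:(kk + 1)]))
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) adj[i, nn[i, ]] <- TRUE
  adj <- adj & t(adj)  # mutual kNN
  W <- ifelse(adj, D, 0)
  gr <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  comp <- igraph::components(gr)$membership
  dist_out <- rep(NA_real_, m)
  for (cid in unique(comp)) {
    vs <- which(comp == cid)
    if (length(vs) == 1L) { dist_out[vs] <- 0; next }
    sub <- igraph::induced_subgraph(gr, vs)
    dmat <- igraph::distances(sub, algorithm = "dijkstra")
    ecc <- apply(dmat, 1, max)
    start <- which.max(ecc)
    dist_out[vs] <- dmat[start, ]
  }
  list(distance = dist_out, component = as.integer(comp))
}
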