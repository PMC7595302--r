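#' Kernel specification
#'
#' Constructs a validated description of a kernel function: the family plus
#' its hyperparameters. Five families are supported:
#' \describe{
#'   \item{linear}{\eqn{k(x,y) = x^\top y}}
#'   \item{poly}{\eqn{k(x,y) = (\gamma x^\top y + c_0)^p}}
#'   \item{rbf}{\eqn{k(x,y) = \exp(-\gamma \|x-y\|^2)}}
#'   \item{tanh}{\eqn{k(x,y) = \tanh(\gamma x^\top y + c_0)}}
#'   \item{ard}{\eqn{k(x,y) = \nu^2 \exp(-\frac12 \sum_d ((x_d-y_d)/\lambda_d)^2)}}
#' }
#' The RBF scale may be given either as \code{gamma} or as a bandwidth
#' \code{sigma}; the two are related by \eqn{\gamma = 1/(2\sigma^2)} and the
#' value is stored internally as \code{gamma}.
#'
#' @param family one of \code{"linear"}, \code{"poly"}, \code{"rbf"},
#'   \code{"tanh"}, \code{"ard"}.
#' @param gamma positive scale parameter (poly/rbf/tanh).
#' @param sigma alternative RBF bandwidth; mutually exclusive with
#'   \code{gamma}.
#' @param c0 offset (poly/tanh).
#' @param degree positive integer polynomial degree.
#' @param nu positive amplitude of the ARD kernel.
#' @param lengthscales vector of positive per-feature lengthscales (ARD).
#' @return an object of class \code{kernel_spec}.
#' @examples
#' kernel_spec("rbf", gamma = 0.5)
#' kernel_spec("ard", nu = 1, lengthscales = c(1, 2))
#' @export
kernel_spec <- function(family = c("linear", "poly", "rbf", "tanh", "ard"),
                        gamma = NULL, sigma = NULL, c0 = 1, degree = 2L,
                        nu = 1, lengthscales = NULL) {
  family <- match.arg(family)
  if (!is.null(gamma) && !is.null(sigma))
    stop("supply either 'gamma' or 'sigma', not both")
  if (!is.null(sigma)) {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma > 0)
    gamma <- 1 / (2 * sigma^2)
  }
  if (is.null(gamma)) gamma <- 1
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (family %in% c("poly", "rbf", "tanh") && gamma <= 0)
    stop("'gamma' must be positive for family '", family, "'")
  if (family == "poly") {
    if (degree < 1 || degree != round(degree))
      stop("'degree' must be a positive integer")
    degree <- as.integer(degree)
  }
  if (family == "ard") {
    if (is.null(lengthscales))
      stop("family 'ard' requires 'lengthscales'")
    stopifnot(is.numeric(lengthscales), all(is.finite(lengthscales)),
              all(lengthscales > 0))
    stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu), nu > 0)
  }
  stopifnot(is.numeric(c0), length(c0) == 1L, is.finite(c0))
  structure(list(family = family, gamma = gamma, c0 = c0,
                 degree = as.integer(degree), nu = nu,
                 lengthscales = lengthscales),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec>", x$family, "\n")
  pars <- switch(x$family,
    linear = character(0),
    poly   = sprintf("gamma=%g, c0=%g, degree=%d", x$gamma, x$c0, x$degree),
    rbf    = sprintf("gamma=%g (sigma=%g)", x$gamma, sqrt(1 / (2 * x$gamma))),
    tanh   = sprintf("gamma=%g, c0=%g", x$gamma, x$c0),
    ard    = sprintf("nu=%g, lengthscales=[%s]", x$nu,
                     paste(signif(x$lengthscales, 4), collapse = ", ")))
  if (length(pars)) cat("  ", pars, "\n")
  invisible(x)
}

## shared input checks for pairwise kernel evaluation
check_pair <- function(spec, x, y) {
  if (!inherits(spec, "kernel_spec")) stop("'spec' must be a kernel_spec")
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite entries in 'x' or 'y'")
  if (spec$family == "ard" && length(spec$lengthscales) != length(x))
    stop("ARD lengthscale count (", length(spec$lengthscales),
         ") does not match data dimension (", length(x), ")")
  invisible(TRUE)
}

#' Median-heuristic RBF scale
#'
#' Sets \eqn{\gamma = 1/(2\,\mathrm{median}^2)} of the pairwise Euclidean
#' distances of the rows of \code{X}, a standard default for RBF bandwidths.
#'
#' @param X numeric matrix (rows = samples).
#' @return positive scalar gamma.
#' @export
median_heuristic <- function(X) {
  X <- as.matrix(X)
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m^2)
}

#' Serialize / deserialize a kernel spec as YAML
#'
#' @param spec a \code{kernel_spec}.
#' @param path file path; for \code{kernel_spec_to_yaml} omit to return the
#'   YAML string.
#' @return \code{kernel_spec_to_yaml}: the YAML string (invisibly when written
#'   to a file); \code{kernel_spec_from_yaml}: a \code{kernel_spec}.
#' @export
kernel_spec_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  lst <- Filter(Negate(is.null), unclass(spec))
  txt <- yaml::as.yaml(lst)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname kernel_spec_to_yaml
#' @export
kernel_spec_from_yaml <- function(path) {
  lst <- yaml::yaml.load_file(path)
  if (!is.null(lst$sigma) && is.null(lst$gamma)) {
    kernel_spec(lst$family, sigma = lst$sigma,
                c0 = lst$c0 %||% 1, degree = lst$degree %||% 2L,
                nu = lst$nu %||% 1, lengthscales = lst$lengthscales)
  } else {
    kernel_spec(lst$family, gamma = lst$gamma,
                c0 = lst$c0 %||% 1, degree = lst$degree %||% 2L,
                nu = lst$nu %||% 1, lengthscales = lst$lengthscales)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
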