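#' Synthetic 1-D regression data at controlled SNR
#'
#' Generates a clean 1-D signal plus additive white Gaussian noise whose
#' variance is set from the requested signal-to-noise ratio,
#' \eqn{\mathrm{SNR} = 10 \log_{10}(\sigma_y^2/\sigma_n^2)}, with
#' \eqn{\sigma_y^2} the empirical variance of the clean signal. Available
#' signals: \code{"sin3pix"} (\eqn{\sin(3\pi x)} on [0, 1]), \code{"smooth"}
#' (a squared-exponential bump) and \code{"composite"} (sinusoid plus ramp).
#'
#' @param name signal name.
#' @param n sample count.
#' @param snr_db requested SNR in dB; \code{Inf} for noiseless.
#' @param seed integer seed, or \code{NULL} to draw from the current RNG
#'   stream.
#' @param design \code{"uniform"} draws x from U(0, 1); \code{"grid"} uses n
#'   equally spaced points (no near-duplicate inputs, so unregularized
#'   interpolation stays numerically meaningful).
#' @return list with \code{x}, \code{y} (noisy), \code{y_clean},
#'   \code{noise_var}.
#' @export
sim_regression_1d <- function(name = c("sin3pix", "smooth", "composite"),
                              n = 100, snr_db = 20, seed = NULL,
                              design = c("uniform", "grid")) {
  name <- match.arg(name)
  design <- match.arg(design)
  stopifnot(n >= 1, is.finite(snr_db) || is.infinite(snr_db))
  with_seed(seed, {
    x <- if (design == "grid") seq(0, 1, length.out = n)
         else stats::runif(n, 0, 1)
    y_clean <- switch(name,
      sin3pix   = sin(3 * pi * x),
      smooth    = exp(-(x - 0.5)^2 / 0.02),
      composite = sin(4 * pi * x) + 2 * x)
    sig_var <- stats::var(y_clean)
    noise_var <- if (is.infinite(snr_db)) 0 else sig_var / 10^(snr_db / 10)
    y <- y_clean + stats::rnorm(n, 0, sqrt(noise_var))
    list(x = x, y = y, y_clean = y_clean, noise_var = noise_var)
  })
}

#' Synthetic 2-D binary classification toys
#'
#' Balanced two-class problems in the plane with labels in \{-1, +1\}:
#' \code{"moons"} (two interleaving half circles), \code{"circles"} (two
#' concentric rings, inner radius 0.5, outer 1) and \code{"ellipsoids"} (two
#' overlapping anisotropic Gaussian clouds).
#'
#' @param name dataset name.
#' @param n total sample count (split as evenly as possible).
#' @param noise Gaussian jitter standard deviation.
#' @param seed integer seed, or \code{NULL}.
#' @return list with \code{X} (n x 2) and \code{y} (+-1).
#' @export
sim_classification_2d <- function(name = c("moons", "circles", "ellipsoids"),
                                  n = 200, noise = 0.1, seed = NULL) {
  name <- match.arg(name)
  stopifnot(n >= 2)
  n1 <- ceiling(n / 2); n2 <- n - n1
  with_seed(seed, {
    if (name == "moons") {
      t1 <- stats::runif(n1, 0, pi); t2 <- stats::runif(n2, 0, pi)
      X <- rbind(cbind(cos(t1), sin(t1)),
                 cbind(1 - cos(t2), 0.5 - sin(t2)))
    } else if (name == "circles") {
      t1 <- stats::runif(n1, 0, 2 * pi); t2 <- stats::runif(n2, 0, 2 * pi)
      X <- rbind(0.5 * cbind(cos(t1), sin(t1)),
                 1.0 * cbind(cos(t2), sin(t2)))
    } else {
      X <- rbind(cbind(stats::rnorm(n1, -0.5, 1.2), stats::rnorm(n1, 0, 0.4)),
                 cbind(stats::rnorm(n2,  0.5, 0.4), stats::rnorm(n2, 0, 1.2)))
    }
    if (noise > 0 && name != "ellipsoids")
      X <- X + matrix(stats::rnorm(2 * n, 0, noise), ncol = 2)
    list(X = X, y = c(rep(1, n1), rep(-1, n2)))
  })
}

#' Synthetic 2-D manifold density toys
#'
#' Point clouds concentrated on low-dimensional structures, used by the
#' density-ridge examples: \code{"ring"} (radius \code{r0} with radial
#' Gaussian jitter), \code{"arc"} (upper half of the ring) and
#' \code{"blobs"} (three-component Gaussian mixture).
#'
#' @param name dataset name.
#' @param n sample count.
#' @param noise jitter standard deviation.
#' @param seed integer seed, or \code{NULL}.
#' @param r0 ring/arc radius.
#' @return n x 2 matrix.
#' @export
sim_density_2d <- function(name = c("arc", "ring", "blobs"), n = 300,
                           noise = 0.1, seed = NULL, r0 = 1) {
  name <- match.arg(name)
  stopifnot(n >= 2)
  with_seed(seed, {
    if (name %in% c("ring", "arc")) {
      th <- stats::runif(n, 0, if (name == "ring") 2 * pi else pi)
      r <- r0 + stats::rnorm(n, 0, noise)
      cbind(r * cos(th), r * sin(th))
    } else {
      centers <- matrix(c(-1, 0, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
      id <- sample.int(3, n, replace = TRUE)
      centers[id, ] + matrix(stats::rnorm(2 * n, 0, 0.2 + noise), ncol = 2)
    }
  })
}

#' Synthetic paired samples with controlled dependence
#'
#' Bivariate toys for dependence estimation: \code{"sinusoid"}
#' (\eqn{y = \sin(\omega x) + } noise), \code{"noisy_ring"} (points on a
#' circle, so x and y are nonlinearly associated), \code{"line_clusters"}
#' (two clusters along the identity line) and \code{"near_independent"}
#' (independent Gaussian draws).
#'
#' @param name dataset name.
#' @param n sample count.
#' @param noise noise standard deviation.
#' @param seed integer seed, or \code{NULL}.
#' @param omega sinusoid frequency.
#' @return list with numeric vectors \code{x} and \code{y}.
#' @export
sim_dependence_pair <- function(name = c("sinusoid", "noisy_ring",
                                         "line_clusters", "near_independent"),
                                n = 200, noise = 0.1, seed = NULL,
                                omega = 2) {
  name <- match.arg(name)
  stopifnot(n >= 2)
  with_seed(seed, {
    switch(name,
      sinusoid = {
        x <- stats::runif(n, -2, 2)
        list(x = x, y = sin(omega * x) + stats::rnorm(n, 0, noise))
      },
      noisy_ring = {
        th <- stats::runif(n, 0, 2 * pi)
        r <- 1 + stats::rnorm(n, 0, noise)
        list(x = r * cos(th), y = r * sin(th))
      },
      line_clusters = {
        c1 <- stats::rnorm(n, ifelse(stats::runif(n) < 0.5, -1, 1), 0.3)
        list(x = c1 + stats::rnorm(n, 0, noise),
             y = c1 + stats::rnorm(n, 0, noise))
      },
      near_independent = list(x = stats::rnorm(n), y = stats::rnorm(n)))
  })
}

#' Piecewise-linear two-input regression surface
#'
#' The surface \eqn{y = a x_1 + b x_2} on \eqn{x \sim U([-20, 20]^2)} whose
#' slope in each coordinate switches at zero: \eqn{a = 5} where
#' \eqn{x_1 > 0} and \eqn{a = 1} where \eqn{x_1 \le 0}; \eqn{b = 1}
#' everywhere. The function is continuous at the origin. Used to check that
#' feature sensitivities of a fitted model recover the squared-slope ratio.
#'
#' @param n sample count.
#' @param seed integer seed, or \code{NULL}.
#' @param noise_sd optional additive Gaussian noise on the targets.
#' @return list with \code{X} (n x 2), \code{y} (noisy),
#'   \code{y_clean}.
#' @export
sim_piecewise_surface <- function(n = 200, seed = NULL, noise_sd = 0) {
  stopifnot(n >= 1)
  with_seed(seed, {
    X <- matrix(stats::runif(2 * n, -20, 20), ncol = 2)
    y_clean <- piecewise_surface_value(X)
    y <- y_clean + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    list(X = X, y = y, y_clean = y_clean)
  })
}

#' @rdname sim_piecewise_surface
#' @param X n x 2 matrix of input locations.
#' @export
piecewise_surface_value <- function(X) {
  X <- as_mat(X)
  a <- ifelse(X[, 1] > 0, 5, 1)
  a * X[, 1] + X[, 2]
}
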