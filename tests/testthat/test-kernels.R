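test_that("kernel values match their closed forms and symmetry", {
  expect_equal(kernel_value(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_value(kernel_spec("rbf", gamma = 3), c(1, 2), c(1, 2)), 1)
  expect_equal(kernel_value(kernel_spec("poly", gamma = 1, c0 = 1, degree = 2),
                            c(1, 0), c(1, 0)), 4)
  set.seed(11)
  for (fam in all_families) {
    spec <- random_spec(fam)
    x <- runif(5, -2, 2); y <- runif(5, -2, 2)
    expect_equal(kernel_value(spec, x, y), kernel_value(spec, y, x),
                 tolerance = 1e-14)
  }
  # rbf bounded in (0, 1], ard in (0, nu^2]
  set.seed(12)
  spr <- kernel_spec("rbf", gamma = 0.8)
  spa <- kernel_spec("ard", nu = 1.5, lengthscales = runif(5, 0.5, 2))
  for (i in 1:20) {
    x <- runif(5, -3, 3); y <- runif(5, -3, 3)
    v <- kernel_value(spr, x, y)
    expect_true(v > 0 && v <= 1)
    va <- kernel_value(spa, x, y)
    expect_true(va > 0 && va <= 1.5^2 + 1e-15)
  }
})

test_that("input contracts are enforced", {
  sp <- kernel_spec("rbf", gamma = 1)
  expect_error(kernel_value(sp, c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(kernel_value(sp, c(1, NA), c(1, 2)), "finite")
  expect_error(kernel_spec("rbf", gamma = -1), "positive")
  expect_error(kernel_spec("ard"), "lengthscales")
  expect_error(kernel_value(kernel_spec("ard", lengthscales = c(1, 1)),
                            1:3, 4:6), "dimension")
  expect_error(kernel_spec("poly", degree = 1.5), "integer")
})

test_that("analytic gradients match finite differences for all families", {
  set.seed(21)
  for (fam in all_families) {
    spec <- random_spec(fam)
    worst <- 0
    for (i in 1:200) {
      x <- runif(5, -2, 2); y <- runif(5, -2, 2)
      ag <- kernel_gradient(spec, x, y)
      ng <- numeric_derivative(function(z) kernel_value(spec, z, y), x)
      worst <- max(worst, max(abs(ag - ng) / pmax(1, abs(ng))))
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("analytic Hessians match nested finite differences and are symmetric", {
  set.seed(22)
  for (fam in all_families) {
    spec <- random_spec(fam)
    for (i in 1:25) {
      x <- runif(5, -2, 2); y <- runif(5, -2, 2)
      H <- kernel_hessian(spec, x, y)
      expect_identical(max(abs(H - t(H))), 0)  # constructed symmetric
      Hn <- numeric_derivative(function(z) kernel_value(spec, z, y), x,
                               order = 2)
      expect_lt(max(abs(H - Hn)), 1e-4)
    }
  }
  # fixed closed-form cases
  expect_equal(kernel_hessian(kernel_spec("linear"), c(1, 2), c(3, 4)),
               matrix(0, 2, 2))
  H <- kernel_hessian(kernel_spec("rbf", gamma = 1.3), c(0.4, -1), c(0.4, -1))
  expect_equal(H, diag(-2 * 1.3, 2))
})

test_that("stationary kernels are antisymmetric and translation invariant", {
  set.seed(23)
  for (fam in c("rbf", "ard")) {
    spec <- random_spec(fam)
    for (i in 1:20) {
      x <- runif(5, -2, 2); y <- runif(5, -2, 2); c0 <- runif(5, -1, 1)
      expect_equal(kernel_gradient(spec, x, y), -kernel_gradient(spec, y, x),
                   tolerance = 1e-12)
      expect_equal(kernel_value(spec, x + c0, y + c0),
                   kernel_value(spec, x, y), tolerance = 1e-12)
      expect_equal(kernel_gradient(spec, x + c0, y + c0),
                   kernel_gradient(spec, x, y), tolerance = 1e-12)
    }
  }
})

test_that("higher-order RBF partials follow the composite-exponential recursion", {
  sp <- kernel_spec("rbf", gamma = 1)
  set.seed(24)
  # m = 1, 2 equal the closed-form gradient/Hessian entries exactly
  for (i in 1:20) {
    x <- runif(3, -2, 2); y <- runif(3, -2, 2)
    j <- sample(3, 1)
    expect_equal(rbf_mth_partial(sp, x, y, j, 1),
                 kernel_gradient(sp, x, y)[j], tolerance = 1e-12)
    expect_equal(rbf_mth_partial(sp, x, y, j, 2),
                 kernel_hessian(sp, x, y)[j, j], tolerance = 1e-12)
  }
  # m = 3, 4 against values frozen from symbolic differentiation of
  # exp(-gamma (x - y)^2)
  expect_equal(rbf_mth_partial(sp, 0.7, 0, 1, 3), 3.4650148855070575,
               tolerance = 1e-8)
  expect_equal(rbf_mth_partial(sp, 0.7, 0, 1, 4), -4.703990505105619,
               tolerance = 1e-8)
  sp2 <- kernel_spec("rbf", gamma = 0.5)
  expect_equal(rbf_mth_partial(sp2, 1.3, 0.4, 1, 3), 1.3146112942020531,
               tolerance = 1e-8)
  expect_equal(rbf_mth_partial(sp2, 1.3, 0.4, 1, 4), -0.8029733825925176,
               tolerance = 1e-8)
  expect_error(rbf_mth_partial(kernel_spec("linear"), 1, 2, 1, 1), "RBF")
  expect_error(rbf_mth_partial(sp, 1, 2, 1, 0), "positive integer")
})

test_that("Gram matrices agree with per-pair evaluation and are PSD", {
  set.seed(25)
  X <- matrix(runif(15, -2, 2), 5, 3)
  Y <- matrix(runif(12, -2, 2), 4, 3)
  for (fam in all_families) {
    spec <- random_spec(fam, d = 3)
    K <- gram_matrix(spec, X, Y)
    for (i in 1:5) for (j in 1:4)
      expect_equal(K[i, j], kernel_value(spec, X[i, ], Y[j, ]),
                   tolerance = 1e-12)
  }
  # PSD families: smallest eigenvalue of a 50-point rbf Gram
  Z <- matrix(runif(100, -2, 2), 50, 2)
  Kz <- gram_matrix(kernel_spec("rbf", gamma = 1), Z, Z)
  expect_gte(min(eigen(Kz, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(diag(Kz), rep(1, 50))
})

test_that("Gram derivative tensors match per-pair kernel derivatives", {
  set.seed(26)
  X <- matrix(runif(12, -2, 2), 4, 3)
  A <- matrix(runif(18, -2, 2), 6, 3)
  for (fam in all_families) {
    spec <- random_spec(fam, d = 3)
    G <- gram_gradient(spec, X, A)
    S <- gram_second_partial(spec, X, A)
    for (i in 1:4) for (l in 1:6) {
      kg <- kernel_gradient(spec, X[i, ], A[l, ])
      kh <- kernel_hessian(spec, X[i, ], A[l, ])
      expect_equal(G[i, l, ], kg, tolerance = 1e-12)
      expect_equal(S[i, l, ], diag(kh), tolerance = 1e-12)
    }
  }
  # linear kernel: gradient slices constant in the evaluation point
  Gl <- gram_gradient(kernel_spec("linear"), X, A)
  for (j in 1:3)
    expect_equal(Gl[, , j], matrix(A[, j], 4, 6, byrow = TRUE))
  # rbf: self-fibres vanish
  Gr <- gram_gradient(kernel_spec("rbf", gamma = 1), X, X)
  for (i in 1:4) expect_equal(Gr[i, i, ], rep(0, 3))
})

test_that("numeric_derivative handles simple analytic cases", {
  expect_equal(numeric_derivative(function(z) sum(z^2), 3), 6,
               tolerance = 1e-6)
  expect_equal(numeric_derivative(function(z) 5, c(1, 2)), c(0, 0))
  expect_error(numeric_derivative(function(z) NaN, 1), "non-finite")
})

test_that("median heuristic and yaml round-trip behave", {
  set.seed(27)
  X <- matrix(rnorm(40), 20, 2)
  g <- median_heuristic(X)
  m <- median(dist(X))
  expect_equal(g, 1 / (2 * m^2))
  sp <- kernel_spec("ard", nu = 1.2, lengthscales = c(0.5, 2))
  f <- tempfile(fileext = ".yaml")
  kernel_spec_to_yaml(sp, f)
  sp2 <- kernel_spec_from_yaml(f)
  expect_equal(sp, sp2)
  # sigma spelling maps to gamma
  writeLines("family: rbf\nsigma: 2.0", f)
  expect_equal(kernel_spec_from_yaml(f)$gamma, 1 / 8)
})
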