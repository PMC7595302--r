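test_that("Parzen densities are normalized proper pdfs", {
  set.seed(61)
  # single 1-D sample: one normalized bump
  m1 <- parzen_fit(matrix(0.3), sigma = 0.5)
  expect_equal(predict(m1, 0.3), 1 / sqrt(2 * pi * 0.25), tolerance = 1e-12)
  # 1-D grid quadrature close to 1
  x <- rnorm(80)
  pm <- parzen_fit(matrix(x, ncol = 1))
  grid <- seq(min(x) - 4, max(x) + 4, length.out = 2000)
  expect_equal(sum(predict(pm, grid)) * diff(grid)[1], 1, tolerance = 0.01)
  # 2-D grid quadrature
  X2 <- matrix(rnorm(160, sd = 0.7), ncol = 2)
  pm2 <- parzen_fit(X2)
  gx <- seq(-4, 4, length.out = 120)
  G <- as.matrix(expand.grid(gx, gx))
  expect_equal(sum(predict(pm2, G)) * diff(gx)[1]^2, 1, tolerance = 0.01)
  # nonnegative everywhere
  expect_true(all(predict(pm2, matrix(runif(2000, -5, 5), ncol = 2)) >= 0))
})

test_that("full-rank eigendecomposition density reduces to Parzen", {
  set.seed(62)
  for (i in 1:3) {
    n <- sample(20:60, 1)
    X <- matrix(rnorm(2 * n), ncol = 2)
    km <- keca_fit(X, r = n)
    pm <- parzen_fit(X, sigma = km$sigma)
    pts <- matrix(rnorm(200), ncol = 2)
    expect_lt(max(abs(predict(km, pts) - predict(pm, pts))), 1e-10)
  }
})

test_that("entropy selection maximizes the information-potential sum", {
  set.seed(63)
  X <- matrix(rnorm(14), ncol = 2)  # n = 7, exhaustive check feasible
  n <- nrow(X)
  km <- keca_fit(X, r = 3, selection = "entropy")
  K <- gram_matrix(km$expansion$spec, X, X)
  eig <- eigen(K, symmetric = TRUE)
  contrib <- eig$values * drop(crossprod(eig$vectors, rep(1, n)))^2
  best <- max(combn(n, 3, function(idx) sum(contrib[idx])))
  # the selected subset attains the exhaustive-search optimum
  sel_sum <- sum(sort(contrib, decreasing = TRUE)[1:3])
  expect_equal(sel_sum, best, tolerance = 1e-10)
  # and the fitted model used exactly that ranking
  expect_equal(sort(km$eigvals), sort(eig$values[order(contrib,
               decreasing = TRUE)[1:3]]), tolerance = 1e-10)
})

test_that("rank-1 variance-selected density on one cluster is unimodal", {
  set.seed(64)
  X <- matrix(rnorm(100, sd = 0.5), ncol = 2)
  km <- keca_fit(X, r = 1, selection = "variance")
  g <- seq(-2, 2, length.out = 60)
  p <- matrix(predict(km, as.matrix(expand.grid(g, g))), 60, 60)
  # count strict interior local maxima on the grid
  n_max <- 0
  for (i in 2:59) for (j in 2:59) {
    nb <- p[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (p[i, j] == max(nb) && sum(nb == max(nb)) == 1) n_max <- n_max + 1
  }
  expect_equal(n_max, 1)
})

test_that("ridge scores vanish at modes and match a finite-difference pipeline", {
  set.seed(65)
  X <- sim_density_2d("ring", n = 120, noise = 0.08, seed = 65)
  dm <- parzen_fit(X)
  # finite-difference oracle on the raw density, same eigenvector rule
  x0 <- X[7, ] * 0.95
  g_fd <- numeric_derivative(function(z) predict(dm, z), x0)
  H_fd <- numeric_derivative(function(z) predict(dm, z), x0, order = 2)
  v <- eigen(H_fd, symmetric = TRUE)$vectors[, 2]
  rs <- ridge_score(dm, x0, ridge_dim = 1, scale = "density")
  expect_equal(rs$score, abs(sum(v * g_fd)), tolerance = 1e-5)
  expect_gte(rs$score, 0)
  # at a local maximum the gradient, hence the score, vanishes
  mode_guess <- optim(X[1, ], function(z) -predict(dm, z))$par
  rs_mode <- ridge_score(dm, mode_guess, 1, scale = "density")
  expect_lt(rs_mode$score, 1e-4)
  # density symmetric about the x1 axis: on the axis the gradient is exactly
  # radial, so the score against the orthogonal eigenvector vanishes
  Xi <- as.matrix(expand.grid(seq(-2, 2, 0.5), seq(-2, 2, 0.5)))
  di <- parzen_fit(Xi, sigma = 0.6)
  g <- expansion_gradient(di$expansion, c(1.2, 0))
  expect_lt(abs(g[2]), 1e-12)
  H <- expansion_hessian(di$expansion, c(1.2, 0))
  ev <- eigen(H, symmetric = TRUE)$vectors
  v_orth <- ev[, which.max(abs(ev[2, ]))]  # eigenvector along x2
  expect_lt(abs(sum(v_orth * g)), 1e-12)
})

test_that("ridge extraction recovers the major axis of an elongated Gaussian", {
  fracs <- vapply(1:3, function(s) {
    set.seed(s)
    X <- cbind(rnorm(1000, 0, 3), rnorm(1000, 0, 0.5))
    dm <- parzen_fit(X)
    rr <- extract_ridge(dm, X, ridge_dim = 1)
    mean(abs(rr$ridge_points[, 2]) < 0.5)
  }, 0)
  expect_true(all(fracs >= 0.9))
})

test_that("ridge thresholding and ordering behave at the extremes", {
  set.seed(67)
  X <- sim_density_2d("arc", n = 200, noise = 0.05, seed = 67)
  dm <- parzen_fit(X)
  rr_all <- extract_ridge(dm, X, ridge_dim = 1, epsilon = Inf,
                          eigvec_rule = "largest")
  expect_equal(nrow(rr_all$ridge_points), 200)  # epsilon = Inf keeps all
  rr <- extract_ridge(dm, X, ridge_dim = 1)
  expect_true(all(rr$ridge_scores[rr$retained] <= rr$epsilon))
  # retained arc points form a connected path under the mutual 5-NN graph
  expect_true(length(unique(rr$ordering$component)) <= 2)
  expect_true(all(rr$ordering$distance >= 0))
  expect_warning(extract_ridge(dm, X, ridge_dim = 1, epsilon = 1e-300),
                 "no evaluation point")
})

test_that("curve ordering reproduces exact shortest-path distances", {
  # collinear equally spaced points: distances 0, h, 2h, ...
  oc <- order_curve(cbind(seq(0, 2.5, 0.5), 0), k = 2)
  expect_equal(oc$distance, seq(0, 2.5, 0.5))
  expect_equal(order_curve(matrix(c(1, 2), 1, 2))$distance, 0)
  # Floyd-Warshall oracle on a small random set
  set.seed(68)
  P <- matrix(runif(16), 8, 2)
  oc8 <- order_curve(P, k = 3)
  D <- as.matrix(dist(P))
  kk <- 3
  adj <- matrix(FALSE, 8, 8)
  for (i in 1:8) adj[i, order(D[i, ])[2:(kk + 1)]] <- TRUE
  adj <- adj & t(adj)
  W <- ifelse(adj, D, Inf); diag(W) <- 0
  for (k in 1:8) for (i in 1:8) for (j in 1:8)
    W[i, j] <- min(W[i, j], W[i, k] + W[k, j])
  comp1 <- which(oc8$component == oc8$component[1])
  # distances from the chosen endpoint agree with the all-pairs oracle
  start <- comp1[which.min(abs(oc8$distance[comp1]))]
  expect_equal(oc8$distance[comp1], W[start, comp1], tolerance = 1e-12)
})

test_that("ridge scores are scale equivariant in rank order", {
  set.seed(69)
  X <- sim_density_2d("ring", n = 150, noise = 0.08, seed = 69)
  dm1 <- parzen_fit(X, sigma = 0.3)
  dm2 <- parzen_fit(X * 10, sigma = 3)  # data and bandwidth jointly scaled
  s1 <- vapply(1:50, function(i) ridge_score(dm1, X[i, ], 1)$score, 0)
  s2 <- vapply(1:50, function(i) ridge_score(dm2, 10 * X[i, ], 1)$score, 0)
  expect_equal(spearman(s1, s2), 1)
})
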