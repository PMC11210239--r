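test_that("soft thresholding is the l1 proximal operator", {
  expect_equal(soft_threshold(0.3, 0.5), 0)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  z <- c(-3, -0.2, 0, 0.2, 3)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(z, 1), c(-2, 0, 0, 0, 2))
  expect_error(soft_threshold(1, -0.1), ">= 0")
})

test_that("PLS initialization recovers the leading singular pair", {
  # noiseless rank-1 pair: exact fixed point
  set.seed(2)
  u0 <- rnorm(12); a <- rnorm(6); b <- rnorm(5)
  X <- outer(u0, a); Y <- outer(u0, b)
  init <- pls_initialize(X, Y, seed = 1)
  expect_gte(abs(sum(init$g * a / sqrt(sum(a^2)))), 0.9999)
  expect_gte(abs(sum(init$d * b / sqrt(sum(b^2)))), 0.9999)
  expect_equal(sqrt(sum(init$g^2)), 1)
  expect_equal(sqrt(sum(init$d^2)), 1)
  expect_equal(init$u, as.numeric(X %*% init$g))

  # random matrices: dense SVD of X'Y as oracle
  for (s in 1:5) {
    X <- rand_std(6, 4, seed = 40 + s)
    Y <- rand_std(6, 3, seed = 80 + s)
    init <- pls_initialize(X, Y, seed = s)
    sv <- svd(crossprod(X, Y))
    expect_gte(abs(sum(init$g * sv$u[, 1])), 0.999)
    expect_gte(abs(sum(init$d * sv$v[, 1])), 0.999)
  }
})

test_that("coordinate update matches hand evaluation and its limits", {
  # crafted so t_g = cov_scale * X'Yd = (1.0, 0.1)
  X <- rbind(c(2, 0.2), c(0, 0))
  Y <- rbind(c(1, 0), c(0, 0))
  d <- c(1, 0)
  cfg <- solver_config(lambda1 = 0.4, beta1 = 0, gamma1 = 0, delta1 = 0.5)
  g <- update_g(X, Y, d, g = c(0, 0), L1 = NULL, config = cfg)
  expect_equal(g, c(1, 0))  # soft((1, .1), .4)/(2*.5) = (.6, 0), then unit norm

  # full shrinkage returns the zero vector
  cfg_big <- solver_config(lambda1 = 10, beta1 = 0)
  expect_equal(update_g(X, Y, d, c(0, 0), NULL, cfg_big), c(0, 0))

  # penalty-free limit: direction proportional to X'v, the plain PLS step
  set.seed(6)
  X <- rand_std(8, 5, seed = 6); Y <- rand_std(8, 4, seed = 7)
  d <- rnorm(4); d <- d / sqrt(sum(d^2))
  cfg0 <- solver_config(lambda1 = 0, beta1 = 0, delta1 = 0.5)
  step <- as.numeric(crossprod(X, Y %*% d))
  expect_equal(update_g(X, Y, d, rep(0, 5), NULL, cfg0),
               step / sqrt(sum(step^2)))
})

test_that("update_d is the mirror of update_g", {
  set.seed(12)
  X <- rand_std(8, 5, seed = 21); Y <- rand_std(8, 4, seed = 22)
  L1 <- build_knn_hypergraph(t(X), k = 2)$laplacian
  L2 <- build_knn_hypergraph(t(Y), k = 2)$laplacian
  g <- rnorm(5); g <- g / sqrt(sum(g^2))
  d <- rnorm(4); d <- d / sqrt(sum(d^2))
  cfg <- solver_config(lambda1 = 0.2, lambda2 = 0.2, beta1 = 0.3, beta2 = 0.3,
                       cov_scale = "1/n")
  # updating d on (X, Y) equals updating "g" on the swapped problem (Y, X)
  swapped <- solver_config(lambda1 = 0.2, beta1 = 0.3, cov_scale = "1/n")
  expect_equal(update_d(X, Y, g, d, L2, cfg),
               update_g(Y, X, g, d, L2, swapped))
})

test_that("objective matches the explicit normalized pairwise graph sum", {
  set.seed(31)
  for (s in 1:5) {
    X <- rand_std(5, 4, seed = 60 + s)
    Y <- rand_std(5, 3, seed = 90 + s)
    hx <- build_knn_hypergraph(t(X), k = 2)
    hy <- build_knn_hypergraph(t(Y), k = 2)
    g <- rnorm(4); d <- rnorm(3)
    cfg <- solver_config(lambda1 = 0.3, lambda2 = 0.2, beta1 = 0.7, beta2 = 0.4,
                         gamma1 = 0.1, gamma2 = 0.2)
    got <- hr_objective(X, Y, g, d, hx$laplacian, hy$laplacian, cfg)
    want <- -(1 / 4) * as.numeric(t(g) %*% crossprod(X, Y) %*% d) +
      0.7 * pairwise_graph_penalty(g, hx$similarity, hx$vertex_degrees) +
      0.4 * pairwise_graph_penalty(d, hy$similarity, hy$vertex_degrees) +
      0.3 * sum(abs(g)) + 0.2 * sum(abs(d)) +
      0.1 * sum(g^2) + 0.2 * sum(d^2)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # every term vanishes at the origin
  expect_equal(hr_objective(rand_std(5, 4, 1), rand_std(5, 3, 2),
                            rep(0, 4), rep(0, 3)), 0)
})

test_that("solver reduces to the leading singular pair without penalties", {
  for (s in 1:6) {
    X <- rand_std(20, 30, seed = 100 + s)
    Y <- rand_std(20, 25, seed = 200 + s)
    cfg <- solver_config(lambda1 = 1e-6, lambda2 = 1e-6, beta1 = 0, beta2 = 0,
                         seed = s)
    fit <- fit_component(X, Y, config = cfg)
    sv <- svd(crossprod(X, Y))
    expect_gte(abs(sum(fit$g * sv$u[, 1])), 0.999)
    expect_gte(abs(sum(fit$d * sv$v[, 1])), 0.999)
    expect_equal(fit$u, as.numeric(X %*% fit$g))
    expect_equal(fit$v, as.numeric(Y %*% fit$d))
  }
})

test_that("objective trace is non-increasing and weights stay on the sphere", {
  set.seed(44)
  for (s in 1:10) {
    X <- rand_std(15, 12, seed = 300 + s)
    Y <- rand_std(15, 10, seed = 400 + s)
    L1 <- build_knn_hypergraph(t(X), k = 2)$laplacian
    L2 <- build_knn_hypergraph(t(Y), k = 2)$laplacian
    cfg <- solver_config(lambda1 = 0.1, lambda2 = 0.1, beta1 = 0.1, beta2 = 0.1,
                         seed = s)
    fit <- suppressWarnings(fit_component(X, Y, L1, L2, cfg))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    expect_equal(sqrt(sum(fit$g^2)), 1)
    expect_equal(sqrt(sum(fit$d^2)), 1)
  }
})

test_that("updates are sign-equivariant and the objective is sign-invariant", {
  X <- rand_std(10, 6, seed = 55); Y <- rand_std(10, 5, seed = 56)
  L1 <- build_knn_hypergraph(t(X), k = 2)$laplacian
  cfg <- solver_config(lambda1 = 0.2, beta1 = 0.2)
  g <- rnorm(6); g <- g / sqrt(sum(g^2))
  d <- rnorm(5); d <- d / sqrt(sum(d^2))
  expect_equal(update_g(X, Y, -d, -g, L1, cfg), -update_g(X, Y, d, g, L1, cfg))
  L2 <- build_knn_hypergraph(t(Y), k = 2)$laplacian
  expect_equal(hr_objective(X, Y, -g, -d, L1, L2, cfg),
               hr_objective(X, Y, g, d, L1, L2, cfg))
})

test_that("over-shrinkage is flagged as a degenerate component", {
  X <- rand_std(10, 6, seed = 70); Y <- rand_std(10, 5, seed = 71)
  cfg <- solver_config(lambda1 = 50, lambda2 = 50, beta1 = 0, beta2 = 0, seed = 1)
  expect_warning(fit <- fit_component(X, Y, config = cfg), "degenerate")
  expect_true(fit$degenerate)
  expect_true(all(fit$g == 0))
})

test_that("solver configuration validates its constants", {
  expect_error(solver_config(lambda1 = -1), ">= 0")
  expect_error(solver_config(delta1 = 0), "> 0")
  expect_error(solver_config(tol = 0), "> 0")
  expect_error(solver_config(n_modules = 0), ">= 1")
  expect_equal(solver_config()$threshold, 1)
  expect_equal(solver_config()$n_modules, 20)
  expect_equal(solver_config()$knn_k, 2)
})
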