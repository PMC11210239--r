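test_that("feature membership follows the z-score rule with default T = 1", {
  expect_equal(formals(select_features)$threshold, 1)

  w <- c(0.9, rep(0.05, 9))
  sel <- select_features(w)
  expect_equal(sel$indices, 1L)
  expect_equal(sel$z[1], (0.9 - mean(w)) / sd(w))  # ~2.85
  expect_gt(sel$z[1], 2.8)

  expect_warning(sel0 <- select_features(rep(0.3, 5)), "constant")
  expect_length(sel0$indices, 0)

  # two-sided by default, literal one-sided rule behind the flag
  w2 <- c(5, -5, 0, 0, 0, 0)
  expect_equal(select_features(w2)$indices, c(1L, 2L))
  expect_equal(select_features(w2, one_sided = TRUE)$indices, 1L)
})

test_that("sample membership combines the normalized latent scores", {
  u <- c(3, 0, 0, 0, 0, 0); v <- c(4, 0, 0, 0, 0, 0)
  expect_equal(select_samples(u, v)$indices, 1L)

  # u = v: the combined score is determined by u alone
  set.seed(8)
  u <- rnorm(10)
  expect_equal(select_samples(u, u)$indices,
               which(abs(scale(u / sqrt(sum(u^2)) * 2)[, 1]) > 1))

  expect_warning(s0 <- select_samples(rep(0, 5), rnorm(5)), "zero latent")
  expect_length(s0$indices, 0)
  expect_warning(sc <- select_samples(rep(1, 5), rep(1, 5)), "constant")
  expect_length(sc$indices, 0)

  # raw thresholding variant skips the z-scoring
  u <- c(10, 1, 1, 1); v <- c(10, 1, 1, 1)
  raw <- select_samples(u, v, zscore = FALSE)
  expect_equal(raw$indices, 1L)
  expect_equal(raw$score, u / sqrt(sum(u^2)) + v / sqrt(sum(v^2)))
})

test_that("rank-one deflation removes the module signal exactly", {
  X <- rbind(c(1, 2), c(3, 4)); u <- c(1, 1)
  df <- deflate(X, u)
  expect_equal(df$loading, c(2, 3))
  expect_equal(df$residual, rbind(c(-1, -1), c(1, 1)))
  expect_lt(max(abs(crossprod(df$residual, u))), 1e-10)

  set.seed(14)
  X <- matrix(rnorm(30), 6, 5); u <- rnorm(6)
  expect_lt(max(abs(crossprod(deflate(X, u)$residual, u))), 1e-10)
  expect_lt(max(abs(deflate(outer(u, rnorm(5)), u)$residual)), 1e-12)
  expect_error(deflate(X, rep(0, 6)), "zero latent")
})

test_that("module correlation and error match direct evaluation", {
  u <- rnorm(8)
  expect_equal(module_pcc(u, u), 1)
  expect_equal(module_pcc(u, -u), -1)
  # frozen from the direct formula: cov = 1.5, sd = 1, sqrt(7/3)
  expect_equal(module_pcc(c(1, 2, 3), c(1, 2, 4)), 1.5 / sqrt(7 / 3))
  expect_equal(round(module_pcc(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  expect_warning(expect_true(is.na(module_pcc(c(1, 1, 1), c(1, 2, 3)))),
                 "zero-variance")

  X <- diag(2); u <- c(1, 1); xl <- c(0.5, 0.5)
  expect_equal(module_error(X, X, u, u, xl, xl), 2)
  expect_equal(module_error(X, X, u, u, xl, xl, convention = "symmetric"), 2)
  # quadratic form: doubling the residuals quadruples the error
  X2 <- X + (X - outer(u, xl))  # residual doubled around the same rank-1 signal
  expect_equal(module_error(X2, X, u, u, xl, xl),
               4 * 1 + 1)
  # exact rank-1 reconstruction has zero error
  set.seed(15)
  u <- rnorm(6); a <- rnorm(4); b <- rnorm(3)
  expect_equal(module_error(outer(u, a), outer(u, b), u, u, a, b), 0)
})

test_that("module extraction recovers planted orthogonal co-modules", {
  sim <- simulate_paired_omics(n_samples = 80, p_features = 120, q_features = 100,
                               n_modules = 2, support_x = 10, support_y = 10,
                               snr = 2, seed = 5)
  cfg <- solver_config(seed = 5, n_modules = 2)
  fit <- extract_modules(sim$X, sim$Y, cfg)
  for (k in 1:2) {
    jac_x <- sapply(fit$modules, function(m)
      length(intersect(m$x_features$index, sim$truth$supports_x[[k]])) /
        length(union(m$x_features$index, sim$truth$supports_x[[k]])))
    expect_gte(max(jac_x), 0.8)
  }
  ev <- evaluate_recovery(fit, sim$truth)
  expect_gte(ev$mean_f1, 0.8)
})

test_that("deflation telescopes and successive scores are orthogonal", {
  sim <- simulate_paired_omics(50, 60, 55, 2, 8, 8, snr = 2, seed = 3)
  cfg <- solver_config(lambda1 = 0.05, lambda2 = 0.05, beta1 = 0.05,
                       beta2 = 0.05, seed = 1, n_modules = 5)
  fit <- suppressWarnings(extract_modules(sim$X, sim$Y, cfg))
  live <- Filter(function(m) !m$degenerate, fit$modules)
  rec <- Reduce(`+`, lapply(live, function(m)
    outer(m$component$u, m$component$x_loading)))
  expect_lt(max(abs(fit$X - rec - fit$X_residual)), 1e-8)
  U <- sapply(live, function(m) m$component$u)
  G <- crossprod(U)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("extraction defaults to 20 modules and stops early on rank collapse", {
  expect_equal(solver_config()$n_modules, 20)

  # K = 1 equals a single component fit
  sim <- simulate_paired_omics(40, 30, 25, 1, 6, 6, snr = 2, seed = 9)
  cfg <- solver_config(seed = 9, n_modules = 1)
  fit1 <- extract_modules(sim$X, sim$Y, cfg)
  Xs <- standardize_columns(sim$X); Ys <- standardize_columns(sim$Y)
  L1 <- build_knn_hypergraph(t(Xs), k = 2)$laplacian
  L2 <- build_knn_hypergraph(t(Ys), k = 2)$laplacian
  comp <- fit_component(Xs, Ys, L1, L2, cfg)
  expect_equal(fit1$modules[[1]]$component$g, comp$g)
  expect_equal(nrow(fit1$summary), 1)

  # exactly rank-2 data cannot yield 5 modules
  set.seed(16)
  U <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  X <- U %*% matrix(rnorm(2 * 10), 2, 10)
  Y <- U %*% matrix(rnorm(2 * 8), 2, 8)
  cfg <- solver_config(lambda1 = 0.01, lambda2 = 0.01, beta1 = 0, beta2 = 0,
                       seed = 2, n_modules = 5, tol = 1e-10)
  expect_warning(fit <- extract_modules(X, Y, cfg, graph = "none",
                                        standardize = FALSE),
                 "exhausted|converge")
  expect_lt(nrow(fit$summary), 5)
})

test_that("pure-noise modules correlate less than planted ones", {
  pccs <- sapply(1:6, function(s) {
    noise <- simulate_paired_omics(50, 40, 35, n_modules = 0, snr = 0,
                                   seed = 500 + s)
    planted <- simulate_paired_omics(50, 40, 35, n_modules = 1, support_x = 8,
                                     support_y = 8, snr = 1, seed = 600 + s)
    cfg <- solver_config(lambda1 = 0.1, lambda2 = 0.1, seed = s, n_modules = 1)
    f0 <- suppressWarnings(extract_modules(noise$X, noise$Y, cfg))
    f1 <- suppressWarnings(extract_modules(planted$X, planted$Y, cfg))
    c(noise = abs(f0$summary$pcc[1]), planted = abs(f1$summary$pcc[1]))
  })
  expect_lt(mean(pccs["noise", ]), mean(pccs["planted", ]))
})

test_that("grid search scores combinations by mean module correlation", {
  sim <- simulate_paired_omics(50, 40, 35, 1, 8, 8, snr = 2, seed = 21)
  cfg <- solver_config(seed = 21)
  single <- grid_search(sim$X, sim$Y, cfg,
                        lambda1_grid = 0.1, lambda2_grid = 0.1,
                        beta1_grid = 0.5, beta2_grid = 0.5,
                        search_modules = 1)
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best_config$lambda1, 0.1)
  expect_equal(single$best_score, single$table$mean_abs_pcc[1])

  gs <- suppressWarnings(
    grid_search(sim$X, sim$Y, cfg,
                lambda1_grid = c(0.05, 0.5), lambda2_grid = 0.1,
                beta1_grid = c(0.05, 0.5), beta2_grid = 0.1,
                search_modules = 1))
  expect_equal(nrow(gs$table), 4)
  expect_gte(gs$best_score, median(gs$table$mean_abs_pcc, na.rm = TRUE))
  # deterministic given the seed
  gs2 <- suppressWarnings(
    grid_search(sim$X, sim$Y, cfg,
                lambda1_grid = c(0.05, 0.5), lambda2_grid = 0.1,
                beta1_grid = c(0.05, 0.5), beta2_grid = 0.1,
                search_modules = 1))
  expect_identical(gs$table, gs2$table)
})
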