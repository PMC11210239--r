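#' Solver configuration
#'
#' Collects every tuning constant of the hypergraph-regularized sparse
#' PLS solver and its downstream module extraction. Defaults reproduce
#' the reference analysis settings: lasso and hypergraph strengths 0.5,
#' no ridge term, hyperedges of at most 2 vertices, 20 modules, and the
#' covariance term scaled by `1/p` (the number of X features).
#'
#' @param lambda1,lambda2 l1 (lasso) strengths for the X- and Y-block
#'   weight vectors, `>= 0`.
#' @param beta1,beta2 hypergraph-penalty strengths, `>= 0`. Zero
#'   deactivates the graph term (the sparse-PLS special case).
#' @param gamma1,gamma2 optional l2 (ridge) strengths for the
#'   elastic-net variant, `>= 0`, default 0.
#' @param delta1,delta2 positive stabilizers in the coordinate-update
#'   denominator `2 * (beta + gamma + delta)`. Any positive value only
#'   rescales the pre-normalization coordinates, since each sweep ends
#'   with projection to the unit sphere; default 1.
#' @param cov_scale normalizing constant of the covariance term:
#'   `"1/p"` (default) divides by the number of X features, `"1/n"` by
#'   the number of samples. The choice only rebalances the penalties.
#' @param max_iter maximum number of alternating sweeps, default 100.
#' @param tol relative objective-change tolerance, default 1e-6.
#' @param seed integer seed driving the initialization (choice of the
#'   starting Y column); `NULL` leaves the RNG state alone.
#' @param threshold z-score membership cutoff T for features and
#'   samples, default 1.
#' @param n_modules number of modules K to extract, default 20.
#' @param knn_k hyperedge size (vertices per hyperedge), default 2.
#' @param one_sided if `TRUE`, membership uses the literal one-sided
#'   rule `z > T`; default is the two-sided `|z| > T`, appropriate for
#'   signed weights.
#' @param zscore_samples if `TRUE` (default) the combined sample score
#'   `u* + v*` is z-scored before thresholding, mirroring the feature
#'   rule; `FALSE` thresholds it raw.
#' @param error_convention scaling of the module reconstruction error:
#'   `"printed"` uses `p/n` on both blocks, `"symmetric"` uses `p/n`
#'   and `q/n`.
#' @param literal_coupling if `TRUE`, the graph coupling inside the
#'   coordinate update is weighted by `2*lambda` exactly as printed in
#'   the source derivation; the default `FALSE` uses `2*beta`, the
#'   weight obtained by differentiating the stated objective.
#' @param rebuild_laplacian if `TRUE`, the feature hypergraphs are
#'   rebuilt from the deflated matrices before every module; default
#'   reuses the Laplacians of the original standardized matrices.
#' @return object of class `"solver_config"`.
#' @export
solver_config <- function(lambda1 = 0.5, lambda2 = 0.5,
                          beta1 = 0.5, beta2 = 0.5,
                          gamma1 = 0, gamma2 = 0,
                          delta1 = 1, delta2 = 1,
                          cov_scale = c("1/p", "1/n"),
                          max_iter = 100, tol = 1e-6,
                          seed = NULL,
                          threshold = 1, n_modules = 20, knn_k = 2,
                          one_sided = FALSE, zscore_samples = TRUE,
                          error_convention = c("printed", "symmetric"),
                          literal_coupling = FALSE,
                          rebuild_laplacian = FALSE) {
  cfg <- list(lambda1 = lambda1, lambda2 = lambda2,
              beta1 = beta1, beta2 = beta2,
              gamma1 = gamma1, gamma2 = gamma2,
              delta1 = delta1, delta2 = delta2,
              cov_scale = match.arg(cov_scale),
              max_iter = max_iter, tol = tol, seed = seed,
              threshold = threshold, n_modules = n_modules, knn_k = knn_k,
              one_sided = one_sided, zscore_samples = zscore_samples,
              error_convention = match.arg(error_convention),
              literal_coupling = literal_coupling,
              rebuild_laplacian = rebuild_laplacian)
  for (nm in c("lambda1", "lambda2", "beta1", "beta2", "gamma1", "gamma2")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if (cfg$delta1 <= 0 || cfg$delta2 <= 0) stop("delta1 and delta2 must be > 0")
  if (cfg$tol <= 0) stop("tol must be > 0")
  if (cfg$max_iter < 1) stop("max_iter must be >= 1")
  if (cfg$n_modules < 1) stop("n_modules must be >= 1")
  if (cfg$knn_k < 1) stop("knn_k must be >= 1")
  if (cfg$threshold <= 0) stop("threshold must be > 0")
  class(cfg) <- "solver_config"
  cfg
}

cov_scale_value <- function(X, cfg) {
  switch(cfg$cov_scale, "1/p" = 1 / ncol(X), "1/n" = 1 / nrow(X))
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - lam, 0)`, the proximal operator of the l1
#' penalty; vectorized over `z`.
#'
#' @param z numeric vector.
#' @param lam threshold, `>= 0`.
#' @return shrunken vector.
#' @export
soft_threshold <- function(z, lam) {
  if (lam < 0) stop("lam must be >= 0")
  sign(z) * pmax(abs(z) - lam, 0)
}

#' Plain PLS power iteration used as solver initialization
#'
#' Runs the classical alternating power iteration
#' `g := X'v / v'v` (normalized), `u := Xg`,
#' `d := Y'u / u'u` (normalized), `v := Yd`
#' from a seeded random column of Y, until the direction change falls
#' below 1e-8 or 500 sweeps. At the fixed point (g, d) is the leading
#' singular-vector pair of `X'Y`.
#'
#' @param X,Y column-standardized matrices sharing the same rows.
#' @param seed integer seed for the choice of the starting column.
#' @return list with unit-norm `g`, `d` and scores `u = Xg`, `v = Yd`.
#' @export
pls_initialize <- function(X, Y, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must share samples (rows)")
  if (all(X == 0) || all(Y == 0)) stop("X and Y must not be all-zero")
  cols <- with_seed(seed, sample.int(ncol(Y)))
  v <- NULL
  for (j in cols) {
    if (sum(Y[, j]^2) > 0) { v <- Y[, j]; break }
  }
  if (is.null(v)) stop("all columns of Y are degenerate (zero variance)")
  g <- rep(0, ncol(X)); d <- rep(0, ncol(Y))
  for (it in seq_len(500)) {
    g_new <- crossprod(X, v) / sum(v^2)
    g_new <- as.numeric(g_new) / l2norm(g_new)
    u <- as.numeric(X %*% g_new)
    if (sum(u^2) == 0) stop("degenerate latent score u during initialization")
    d_new <- crossprod(Y, u) / sum(u^2)
    d_new <- as.numeric(d_new) / l2norm(d_new)
    v <- as.numeric(Y %*% d_new)
    if (sum(v^2) == 0) stop("degenerate latent score v during initialization")
    delta <- max(l2norm(g_new - g), l2norm(d_new - d))
    g <- g_new; d <- d_new
    if (delta < 1e-8) break
  }
  list(g = g, d = d, u = as.numeric(X %*% g), v = as.numeric(Y %*% d))
}

# Normalized similarity I - L (the coupling kernel of the graph term),
# or NULL when the penalty is inactive.
coupling_kernel <- function(L, beta) {
  if (is.null(L) || beta == 0) return(NULL)
  K <- -L
  diag(K) <- diag(K) + 1
  K
}

# One sweep of the soft-threshold updates for a weight vector. `t_vec`
# is the covariance gradient (cscale * t(M) %*% score), `K` the
# normalized similarity (NULL for no graph). The graph coupling is
# evaluated at the incoming unit-scale vector for every coordinate, so
# a fixed point of the sweep satisfies the stationarity condition of
# the norm-constrained objective (updated coordinates live on the
# pre-normalization scale and must not leak into the coupling term).
# The sweep ends with projection to the unit sphere (unless all-zero).
sweep_weights <- function(t_vec, w, K, lambda, beta, gamma, delta, coupling_coef) {
  denom <- 2 * (beta + gamma + delta)
  z <- if (is.null(K)) t_vec else
    t_vec + 2 * coupling_coef * as.numeric(K %*% w)
  if (any(!is.finite(z))) {
    stop("non-finite coordinate update at index ", which(!is.finite(z))[1],
         "; check the Laplacian and penalties")
  }
  w <- soft_threshold(z, lambda) / denom
  nrm <- l2norm(w)
  if (nrm > 0) w <- w / nrm
  w
}

#' Coordinate update of the X-block weight vector
#'
#' One full sweep of the soft-threshold coordinate updates for g with d
#' held fixed:
#' `g_j <- soft(z_j, lambda1) / (2 * (beta1 + gamma1 + delta1))` with
#' `z_j = t_j + 2 * beta1 * sum_i S_ij g_i / sqrt(Dv_ii Dv_jj)` and
#' `t = cov_scale * X'Yd`. The coupling sum is evaluated at the
#' incoming (unit-norm) g for every coordinate, which makes the sweep's
#' fixed points the stationary points of the norm-constrained
#' objective; the sweep ends with projection to the unit sphere
#' (unless fully shrunk to zero).
#'
#' @param X,Y data matrices (same rows).
#' @param d fixed Y-block weight vector.
#' @param g current X-block weight vector.
#' @param L1 normalized Laplacian of the X-feature hypergraph, or `NULL`
#'   for no graph penalty.
#' @param config a [solver_config()].
#' @return updated g.
#' @export
update_g <- function(X, Y, d, g, L1 = NULL, config = solver_config()) {
  t_vec <- as.numeric(crossprod(X, Y %*% d)) * cov_scale_value(X, config)
  coef <- if (config$literal_coupling) config$lambda1 else config$beta1
  sweep_weights(t_vec, g, coupling_kernel(L1, config$beta1),
                config$lambda1, config$beta1, config$gamma1, config$delta1, coef)
}

#' Coordinate update of the Y-block weight vector
#'
#' Mirror of [update_g()] with the roles of the blocks exchanged:
#' `t = cov_scale * Y'Xg` and the penalties
#' `(lambda2, beta2, gamma2, delta2)` with the Y-feature Laplacian.
#'
#' @inheritParams update_g
#' @param L2 normalized Laplacian of the Y-feature hypergraph, or `NULL`.
#' @return updated d.
#' @export
update_d <- function(X, Y, g, d, L2 = NULL, config = solver_config()) {
  t_vec <- as.numeric(crossprod(Y, X %*% g)) * cov_scale_value(X, config)
  coef <- if (config$literal_coupling) config$lambda2 else config$beta2
  sweep_weights(t_vec, d, coupling_kernel(L2, config$beta2),
                config$lambda2, config$beta2, config$gamma2, config$delta2, coef)
}

#' Penalized objective in minimization form
#'
#' Evaluates
#' \deqn{-c\, g^T X^T Y d + \beta_1 g^T L_1 g + \beta_2 d^T L_2 d
#'       + \lambda_1 \|g\|_1 + \lambda_2 \|d\|_1
#'       + \gamma_1 \|g\|_2^2 + \gamma_2 \|d\|_2^2,}
#' with `c` the configured covariance scale. With `beta = gamma = 0`
#' this is the (negated, l1-penalized) sparse-PLS objective; the graph
#' quadratic forms equal the normalized pairwise sums
#' `sum_{i<j} S_ij (g_i/sqrt(Dv_ii) - g_j/sqrt(Dv_jj))^2`.
#'
#' @inheritParams update_g
#' @param d Y-block weight vector.
#' @param L1,L2 normalized Laplacians or `NULL`.
#' @return scalar objective value.
#' @export
hr_objective <- function(X, Y, g, d, L1 = NULL, L2 = NULL,
                         config = solver_config()) {
  val <- -cov_scale_value(X, config) *
    sum(crossprod(X %*% g, Y %*% d)) +
    config$lambda1 * sum(abs(g)) + config$lambda2 * sum(abs(d)) +
    config$gamma1 * sum(g^2) + config$gamma2 * sum(d^2)
  if (!is.null(L1) && config$beta1 > 0) {
    val <- val + config$beta1 * as.numeric(crossprod(g, L1 %*% g))
  }
  if (!is.null(L2) && config$beta2 > 0) {
    val <- val + config$beta2 * as.numeric(crossprod(d, L2 %*% d))
  }
  val
}

#' Fit one hypergraph-regularized sparse PLS component
#'
#' Alternates full coordinate-descent sweeps of g and d (each followed
#' by projection to the unit sphere) from the plain-PLS initialization,
#' recording the minimization-form objective after every alternation.
#' Iteration stops when the relative objective change falls below
#' `config$tol`, when a sweep fails to improve the objective (the
#' previous iterate is kept, so the recorded trace is non-increasing by
#' construction), or at `config$max_iter` sweeps, whichever comes first.
#'
#' @param X,Y column-standardized matrices over the same samples.
#' @param L1,L2 normalized feature-hypergraph Laplacians for the X and Y
#'   blocks (or `NULL` to drop the graph terms).
#' @param config a [solver_config()].
#' @return object of class `"component_fit"`: weight vectors `g`, `d`
#'   (unit norm, or all-zero when fully shrunk), latent scores
#'   `u = Xg`, `v = Yd`, deflation loadings `x_loading = X'u/u'u` and
#'   `y_loading = Y'v/v'v`, `objective_trace`, `n_iter`, `converged`,
#'   `degenerate`.
#' @export
fit_component <- function(X, Y, L1 = NULL, L2 = NULL, config = solver_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  init <- pls_initialize(X, Y, seed = config$seed)
  g <- init$g; d <- init$d
  obj <- hr_objective(X, Y, g, d, L1, L2, config)
  trace <- obj
  converged <- FALSE
  degenerate <- FALSE
  iters <- 0
  for (it in seq_len(config$max_iter)) {
    iters <- it
    g_new <- update_g(X, Y, d, g, L1, config)
    if (all(g_new == 0)) { g <- g_new; degenerate <- TRUE; break }
    d_new <- update_d(X, Y, g_new, d, L2, config)
    if (all(d_new == 0)) { g <- g_new; d <- d_new; degenerate <- TRUE; break }
    obj_new <- hr_objective(X, Y, g_new, d_new, L1, L2, config)
    if (obj_new > obj) {
      # no improvement: keep the previous iterate
      converged <- TRUE
      break
    }
    g <- g_new; d <- d_new
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) / (abs(obj) + 1e-12) < config$tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  if (degenerate) {
    if (all(g == 0) && all(d == 0)) {
      stop(errorCondition(
        "both weight vectors fully shrunk to zero; decrease lambda1/lambda2",
        class = "hrspls_degenerate_error"))
    }
    warning("weight vector fully shrunk to zero: degenerate component (consider smaller lambda)")
  } else if (!converged) {
    warning(sprintf("component did not converge in %d sweeps", config$max_iter))
  }
  u <- as.numeric(X %*% g)
  v <- as.numeric(Y %*% d)
  x_loading <- if (sum(u^2) > 0) as.numeric(crossprod(X, u)) / sum(u^2) else rep(0, ncol(X))
  y_loading <- if (sum(v^2) > 0) as.numeric(crossprod(Y, v)) / sum(v^2) else rep(0, ncol(Y))
  structure(list(g = g, d = d, u = u, v = v,
                 x_loading = x_loading, y_loading = y_loading,
                 objective_trace = trace, n_iter = iters,
                 converged = converged, degenerate = degenerate,
                 config = config),
            class = "component_fit")
}

#' @export
print.component_fit <- function(x, ...) {
  cat(sprintf("sparse PLS component: %d/%d nonzero g, %d/%d nonzero d, %d sweeps (%s)\n",
              sum(x$g != 0), length(x$g), sum(x$d != 0), length(x$d),
              x$n_iter,
              if (x$degenerate) "degenerate" else if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final objective %.6g, cor(u, v) = %.4f\n",
              utils::tail(x$objective_trace, 1),
              if (stats::sd(x$u) > 0 && stats::sd(x$v) > 0) stats::cor(x$u, x$v) else NA))
  invisible(x)
}
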