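#' Select module features by z-scoring a weight vector
#'
#' Standardizes the weights to z-scores `(w - mean(w)) / sd(w)` and
#' keeps the indices whose score exceeds the membership threshold T
#' (`|z| > T` by default; `z > T` when `one_sided`). The default
#' threshold is `T = 1`.
#'
#' @param weights numeric weight vector (length >= 2).
#' @param threshold positive membership cutoff T.
#' @param one_sided use the one-sided rule `z > T`.
#' @return list with `indices` (integer) and `z` (z-scores of all
#'   weights). A constant weight vector has no usable z-scores and
#'   yields an empty selection with a warning.
#' @export
select_features <- function(weights, threshold = 1, one_sided = FALSE) {
  if (length(weights) < 2) stop("need at least 2 weights")
  if (threshold <= 0) stop("threshold must be > 0")
  s <- stats::sd(weights)
  if (s == 0) {
    warning("constant weight vector: no features selected")
    return(list(indices = integer(0), z = rep(0, length(weights))))
  }
  z <- (weights - mean(weights)) / s
  idx <- if (one_sided) which(z > threshold) else which(abs(z) > threshold)
  list(indices = as.integer(idx), z = as.numeric(z))
}

#' Select module samples from the latent scores
#'
#' Normalizes both latent score vectors to unit l2 norm, forms the
#' combined score `s = u* + v*`, z-scores it (unless `zscore = FALSE`,
#' which thresholds s raw) and applies the same membership rule as
#' [select_features()].
#'
#' @param u,v latent score vectors of equal length (n samples).
#' @param threshold positive membership cutoff T.
#' @param one_sided use `score > T` instead of `|score| > T`.
#' @param zscore z-score the combined vector before thresholding.
#' @return list with `indices` and `score` (the thresholded vector).
#' @export
select_samples <- function(u, v, threshold = 1, one_sided = FALSE,
                           zscore = TRUE) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (length(u) < 2) stop("need at least 2 samples")
  nu <- l2norm(u); nv <- l2norm(v)
  if (nu == 0 || nv == 0) {
    warning("zero latent score vector: no samples selected")
    return(list(indices = integer(0), score = rep(0, length(u))))
  }
  s <- u / nu + v / nv
  if (zscore) {
    sds <- stats::sd(s)
    if (sds == 0) {
      warning("constant combined score: no samples selected")
      return(list(indices = integer(0), score = rep(0, length(u))))
    }
    s <- (s - mean(s)) / sds
  }
  idx <- if (one_sided) which(s > threshold) else which(abs(s) > threshold)
  list(indices = as.integer(idx), score = as.numeric(s))
}

#' Rank-one deflation of a data block
#'
#' Removes the component signal from a matrix:
#' `loading = X'u / u'u`, `residual = X - u loading'`. The residual is
#' orthogonal to u by construction.
#'
#' @param X data matrix.
#' @param u latent score vector (nonzero).
#' @return list with `residual` and `loading`.
#' @export
deflate <- function(X, u) {
  uu <- sum(u^2)
  if (uu == 0) stop("cannot deflate with a zero latent score vector")
  loading <- as.numeric(crossprod(X, u)) / uu
  list(residual = X - outer(as.numeric(u), loading), loading = loading)
}

#' Pearson correlation of the two latent scores of a module
#'
#' `cov(u, v) / (sd(u) sd(v))`, the module-coherence measure. Returns
#' `NA` with a warning when either score has zero variance.
#'
#' @param u,v latent score vectors (length >= 3).
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
module_pcc <- function(u, v) {
  if (length(u) != length(v) || length(u) < 3) stop("u and v must share length >= 3")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("zero-variance latent score: module correlation undefined")
    return(NA_real_)
  }
  stats::cor(u, v)
}

#' Module reconstruction error
#'
#' Weighted sum of squared residual entries after removing the module's
#' rank-one signal from both blocks:
#' `p/n * sum((X - u x_loading')^2) + p/n * sum((Y - v y_loading')^2)`
#' under the default `"printed"` convention; `"symmetric"` weights the
#' Y term by `q/n` instead.
#'
#' @param X,Y data blocks (same rows).
#' @param u,v latent score vectors.
#' @param x_loading,y_loading deflation loadings.
#' @param convention `"printed"` or `"symmetric"`.
#' @return nonnegative scalar.
#' @export
module_error <- function(X, Y, u, v, x_loading, y_loading,
                         convention = c("printed", "symmetric")) {
  convention <- match.arg(convention)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  rx <- X - outer(as.numeric(u), as.numeric(x_loading))
  ry <- Y - outer(as.numeric(v), as.numeric(y_loading))
  wy <- if (convention == "printed") p / n else q / n
  (p / n) * sum(rx^2) + wy * sum(ry^2)
}

empty_module <- function(index, comp = NULL) {
  list(index = index,
       x_features = data.frame(id = character(0), index = integer(0),
                               weight = numeric(0), z_score = numeric(0)),
       y_features = data.frame(id = character(0), index = integer(0),
                               weight = numeric(0), z_score = numeric(0)),
       samples = data.frame(id = character(0), index = integer(0),
                            combined_score = numeric(0)),
       pcc = NA_real_, module_error = NA_real_,
       component = comp, degenerate = TRUE)
}

ids_or_index <- function(nms, prefix, n) {
  if (is.null(nms)) paste0(prefix, seq_len(n)) else nms
}

#' Extract successive co-modules from a paired omics dataset
#'
#' The full pipeline for one parameter setting: standardize both blocks,
#' build the feature hypergraph Laplacians, then repeat `n_modules`
#' times: fit a component, select member features and samples by
#' z-score thresholding, record the module correlation `cor(u, v)` and
#' reconstruction error, and deflate both blocks by the component's
#' rank-one signal. A component whose weight vector is fully shrunk to
#' zero yields an empty module and the blocks are passed on undeflated.
#'
#' @param X,Y numeric matrices, samples x features, over the same
#'   samples (rows aligned). Standardized internally unless
#'   `standardize = FALSE`.
#' @param config a [solver_config()].
#' @param graph `"hypergraph"` (default), `"simple"` for the
#'   simple-graph baseline Laplacian, or `"none"` to drop the graph
#'   penalty.
#' @param L1,L2 optional precomputed Laplacians, overriding `graph`.
#' @param standardize z-score the columns first (recommended; the
#'   z-score membership rule and distance-based neighbourhoods assume
#'   comparable feature scales).
#' @return object of class `"hrspls_modules"`: list of per-module
#'   records (selected features with weights and z-scores, samples with
#'   combined scores, `pcc`, `module_error`, the underlying component
#'   fit) plus a `summary` data frame with one row per module.
#' @export
extract_modules <- function(X, Y, config = solver_config(),
                            graph = c("hypergraph", "simple", "none"),
                            L1 = NULL, L2 = NULL, standardize = TRUE) {
  graph <- match.arg(graph)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must share samples (rows)")
  if (standardize) {
    X <- standardize_columns(X)
    Y <- standardize_columns(Y)
  }
  x_ids <- ids_or_index(colnames(X), "x", ncol(X))
  y_ids <- ids_or_index(colnames(Y), "y", ncol(Y))
  s_ids <- ids_or_index(rownames(X), "sample", nrow(X))

  use_graph <- graph != "none" && (config$beta1 > 0 || config$beta2 > 0)
  build_lap <- function(M) {
    switch(graph,
           hypergraph = build_knn_hypergraph(t(M), k = config$knn_k)$laplacian,
           simple = build_knn_graph_laplacian(t(M), k = config$knn_k)$laplacian)
  }
  if (use_graph && is.null(L1)) L1 <- build_lap(X)
  if (use_graph && is.null(L2)) L2 <- build_lap(Y)
  if (!use_graph) { L1 <- NULL; L2 <- NULL }

  Xc <- X; Yc <- Y
  modules <- vector("list", config$n_modules)
  n_extracted <- config$n_modules
  for (kk in seq_len(config$n_modules)) {
    if (max(abs(Xc)) < 1e-10 || max(abs(Yc)) < 1e-10) {
      warning(sprintf("data exhausted after %d module(s); stopping early", kk - 1))
      n_extracted <- kk - 1
      break
    }
    cfg_k <- config
    if (!is.null(config$seed)) cfg_k$seed <- config$seed + kk - 1
    if (use_graph && config$rebuild_laplacian && kk > 1) {
      L1 <- build_lap(Xc)
      L2 <- build_lap(Yc)
    }
    comp <- tryCatch(
      fit_component(Xc, Yc, L1 = L1, L2 = L2, config = cfg_k),
      hrspls_degenerate_error = function(e) NULL)
    if (is.null(comp) || comp$degenerate) {
      modules[[kk]] <- empty_module(kk, comp)
      next
    }
    fx <- select_features(comp$g, config$threshold, config$one_sided)
    fy <- select_features(comp$d, config$threshold, config$one_sided)
    ss <- select_samples(comp$u, comp$v, config$threshold,
                         config$one_sided, config$zscore_samples)
    modules[[kk]] <- list(
      index = kk,
      x_features = data.frame(id = x_ids[fx$indices], index = fx$indices,
                              weight = comp$g[fx$indices],
                              z_score = fx$z[fx$indices]),
      y_features = data.frame(id = y_ids[fy$indices], index = fy$indices,
                              weight = comp$d[fy$indices],
                              z_score = fy$z[fy$indices]),
      samples = data.frame(id = s_ids[ss$indices], index = ss$indices,
                           combined_score = ss$score[ss$indices]),
      pcc = module_pcc(comp$u, comp$v),
      module_error = module_error(Xc, Yc, comp$u, comp$v,
                                  comp$x_loading, comp$y_loading,
                                  config$error_convention),
      component = comp, degenerate = FALSE)
    Xc <- deflate(Xc, comp$u)$residual
    Yc <- deflate(Yc, comp$v)$residual
  }
  modules <- modules[seq_len(n_extracted)]

  summary_df <- do.call(rbind, lapply(modules, function(m) {
    data.frame(module_index = m$index,
               n_x_features = nrow(m$x_features),
               n_y_features = nrow(m$y_features),
               n_samples = nrow(m$samples),
               pcc = m$pcc,
               module_error = m$module_error,
               objective = if (is.null(m$component) || m$degenerate) NA_real_ else
                 utils::tail(m$component$objective_trace, 1),
               converged = if (is.null(m$component) || m$degenerate) NA else
                 m$component$converged)
  }))
  if (is.null(summary_df)) {
    summary_df <- data.frame(module_index = integer(0), n_x_features = integer(0),
                             n_y_features = integer(0), n_samples = integer(0),
                             pcc = numeric(0), module_error = numeric(0),
                             objective = numeric(0), converged = logical(0))
  }
  structure(list(modules = modules, summary = summary_df, config = config,
                 graph = graph, x_ids = x_ids, y_ids = y_ids,
                 sample_ids = s_ids,
                 X_residual = Xc, Y_residual = Yc, X = X, Y = Y),
            class = "hrspls_modules")
}

#' @export
print.hrspls_modules <- function(x, ...) {
  cat(sprintf("%d extracted co-module(s) (%s graph penalty)\n",
              length(x$modules), x$graph))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Hyperparameter grid search scored by mean module correlation
#'
#' Runs [extract_modules()] for every combination of the supplied
#' penalty grids (and hyperedge sizes), scores each combination by the
#' mean absolute module correlation `|cor(u, v)|` over its
#' non-degenerate modules, and returns the best combination together
#' with the full score table. The default grids are
#' `c(0.01, 0.05, 0.1, 0.5, 1)` for each of the four penalties (625
#' combinations); `search_modules` caps the number of modules fitted
#' per combination so the search stays tractable, after which the
#' winning configuration can be refit at full depth.
#'
#' @param X,Y paired data matrices.
#' @param config base [solver_config()]; its seed makes the search
#'   deterministic.
#' @param lambda1_grid,lambda2_grid,beta1_grid,beta2_grid numeric grids.
#' @param knn_k_grid integer grid of hyperedge sizes.
#' @param search_modules number of modules fitted per combination.
#' @param graph graph penalty kind, as in [extract_modules()].
#' @return list with `best_config` (a [solver_config()]), `best_score`,
#'   and `table` (one row per combination: parameters and mean
#'   absolute module correlation).
#' @export
grid_search <- function(X, Y, config = solver_config(),
                        lambda1_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                        lambda2_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                        beta1_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                        beta2_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                        knn_k_grid = config$knn_k,
                        search_modules = 3,
                        graph = c("hypergraph", "simple", "none")) {
  graph <- match.arg(graph)
  combos <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid,
                        beta1 = beta1_grid, beta2 = beta2_grid,
                        knn_k = knn_k_grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) == 0) stop("empty hyperparameter grid")
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xs <- standardize_columns(X); Ys <- standardize_columns(Y)
  lap_cache <- list()
  laps_for_k <- function(k) {
    key <- as.character(k)
    if (is.null(lap_cache[[key]])) {
      lap_cache[[key]] <<- switch(graph,
        hypergraph = list(L1 = build_knn_hypergraph(t(Xs), k = k)$laplacian,
                          L2 = build_knn_hypergraph(t(Ys), k = k)$laplacian),
        simple = list(L1 = build_knn_graph_laplacian(t(Xs), k = k)$laplacian,
                      L2 = build_knn_graph_laplacian(t(Ys), k = k)$laplacian),
        none = list(L1 = NULL, L2 = NULL))
    }
    lap_cache[[key]]
  }
  scores <- rep(NA_real_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- config
    cfg$lambda1 <- combos$lambda1[i]; cfg$lambda2 <- combos$lambda2[i]
    cfg$beta1 <- combos$beta1[i]; cfg$beta2 <- combos$beta2[i]
    cfg$knn_k <- combos$knn_k[i]
    cfg$n_modules <- search_modules
    laps <- laps_for_k(cfg$knn_k)
    fit <- suppressWarnings(
      extract_modules(Xs, Ys, cfg, graph = graph,
                      L1 = laps$L1, L2 = laps$L2, standardize = FALSE))
    pccs <- fit$summary$pcc[!is.na(fit$summary$pcc)]
    if (length(pccs) > 0) scores[i] <- mean(abs(pccs))
  }
  if (all(is.na(scores))) {
    stop("all grid combinations produced only degenerate modules; revise the grid")
  }
  combos$mean_abs_pcc <- scores
  best <- which.max(scores)
  best_config <- config
  best_config$lambda1 <- combos$lambda1[best]
  best_config$lambda2 <- combos$lambda2[best]
  best_config$beta1 <- combos$beta1[best]
  best_config$beta2 <- combos$beta2[best]
  best_config$knn_k <- combos$knn_k[best]
  list(best_config = best_config, best_score = scores[best], table = combos)
}
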