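#' Baseline method specification
#'
#' The comparison methods are nested restrictions of the same solver:
#' `"pls"` zeroes every penalty, `"spls"` keeps only the lasso terms,
#' `"snpls"` swaps the hypergraph Laplacian for the simple-graph
#' Laplacian of the mutualized kNN adjacency, and `"hrspls"` is the
#' full hypergraph-regularized fit.
#'
#' @param method one of `"pls"`, `"spls"`, `"snpls"`, `"hrspls"`.
#' @param config base [solver_config()]; penalties are restricted
#'   according to the method.
#' @return list with `method`, restricted `config` and `graph_kind`.
#' @export
baseline_spec <- function(method = c("pls", "spls", "snpls", "hrspls"),
                          config = solver_config()) {
  method <- match.arg(method)
  cfg <- config
  graph_kind <- switch(method,
    pls = { cfg$lambda1 <- 0; cfg$lambda2 <- 0
            cfg$beta1 <- 0; cfg$beta2 <- 0
            cfg$gamma1 <- 0; cfg$gamma2 <- 0; "none" },
    spls = { cfg$beta1 <- 0; cfg$beta2 <- 0
             cfg$gamma1 <- 0; cfg$gamma2 <- 0; "none" },
    snpls = "simple",
    hrspls = "hypergraph")
  list(method = method, config = cfg, graph_kind = graph_kind)
}

#' Fit a baseline method
#'
#' Runs the module-extraction pipeline under the restricted
#' configuration of [baseline_spec()].
#'
#' @param X,Y paired data matrices.
#' @param method baseline name, see [baseline_spec()].
#' @param config base [solver_config()].
#' @return an `"hrspls_modules"` object.
#' @export
fit_baseline <- function(X, Y, method = c("pls", "spls", "snpls", "hrspls"),
                         config = solver_config()) {
  spec <- baseline_spec(method, config)
  extract_modules(X, Y, spec$config,
                  graph = switch(spec$graph_kind, none = "none",
                                 simple = "simple", hypergraph = "hypergraph"))
}

#' Compare methods on one dataset
#'
#' Fits each requested method and tabulates, per method, the mean
#' module reconstruction error, the mean absolute module correlation
#' (over non-degenerate modules) and the objective value, reported as
#' the sum of the final per-module objectives.
#'
#' @param X,Y paired data matrices.
#' @param methods character vector of baseline names.
#' @param config base [solver_config()].
#' @return list with `table` (one row per method) and `fits` (the
#'   underlying `"hrspls_modules"` objects, named by method).
#' @export
compare_methods <- function(X, Y, methods = c("pls", "spls", "snpls", "hrspls"),
                            config = solver_config()) {
  if (length(methods) < 1) stop("need at least one method")
  fits <- lapply(methods, function(m) fit_baseline(X, Y, m, config))
  names(fits) <- methods
  table <- do.call(rbind, lapply(methods, function(m) {
    s <- fits[[m]]$summary
    data.frame(method = m,
               mean_module_error = mean(s$module_error, na.rm = TRUE),
               mean_module_correlation = mean(abs(s$pcc), na.rm = TRUE),
               objective_value = sum(s$objective, na.rm = TRUE))
  }))
  list(table = table, fits = fits)
}
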