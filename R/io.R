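#' Read a delimited omics matrix
#'
#' Reads a TSV/CSV with a header row and an identifier column and
#' returns a numeric matrix in samples x features orientation,
#' whichever way the file is stored on disk. Duplicate identifiers,
#' non-numeric cells and empty files are distinct errors; missing
#' values error by default or are imputed by the feature mean.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows of the file are samples
#'   (default), `"features"` if rows are features (the matrix is
#'   transposed after reading).
#' @param sep field delimiter; `"auto"` lets the reader sniff it.
#' @param missing `"error"` (default) or `"impute_mean"`.
#' @param name optional label (e.g. `"expression"`), stored as an
#'   attribute.
#' @return numeric matrix, samples in rows, with dimnames.
#' @export
read_omics_matrix <- function(path, orientation = c("samples", "features"),
                              sep = "auto", missing = c("error", "impute_mean"),
                              name = NULL) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2) stop("no data rows/columns in ", path)
  row_ids <- as.character(dt[[1]])
  dup <- row_ids[duplicated(row_ids)]
  if (length(dup) > 0) stop("duplicate row identifier(s) in ", path, ": ",
                            paste(unique(dup), collapse = ", "))
  col_ids <- colnames(dt)[-1]
  dupc <- col_ids[duplicated(col_ids)]
  if (length(dupc) > 0) stop("duplicate column identifier(s) in ", path, ": ",
                             paste(unique(dupc), collapse = ", "))
  vals <- dt[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) stop("non-numeric column(s) in ", path, ": ",
                     paste(utils::head(col_ids[bad], 5), collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- row_ids
  if (orientation == "features") m <- t(m)
  if (anyNA(m)) {
    if (missing == "error") {
      stop(sum(is.na(m)), " missing value(s) in ", path,
           "; use missing = \"impute_mean\" to impute")
    }
    n_imp <- sum(is.na(m))
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
    message("imputed ", n_imp, " missing value(s) by feature means in ", path)
  }
  if (nrow(m) < 3 || ncol(m) < 2) {
    stop("matrix from ", path, " needs >= 3 samples and >= 2 features ",
         "(check the orientation flag)")
  }
  if (!is.null(name)) attr(m, "name") <- name
  m
}

#' Write an omics matrix as TSV
#'
#' Samples in rows, an `id` first column, full precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_omics_matrix <- function(m, path) {
  dt <- data.table::data.table(id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Align two omics matrices on their shared samples
#'
#' Intersects row identifiers, reorders Y to X's order and drops
#' unmatched samples with a message.
#'
#' @param X,Y matrices with sample identifiers as rownames.
#' @return list with aligned `X` and `Y`.
#' @export
align_samples <- function(X, Y) {
  if (is.null(rownames(X)) || is.null(rownames(Y))) {
    if (nrow(X) != nrow(Y)) stop("matrices lack sample ids and differ in rows")
    return(list(X = X, Y = Y))
  }
  common <- intersect(rownames(X), rownames(Y))
  if (length(common) < 3) stop("fewer than 3 shared samples between X and Y")
  dropped <- (nrow(X) - length(common)) + (nrow(Y) - length(common))
  if (dropped > 0) message("dropped ", dropped, " unmatched sample row(s)")
  list(X = X[common, , drop = FALSE], Y = Y[common, , drop = FALSE])
}

#' Write module-extraction results as TSV files
#'
#' Produces `modules.tsv` (module_index, omics, feature_id, weight,
#' z_score), `samples.tsv` (module_index, sample_id, combined_score)
#' and `summary.tsv` (one row per module).
#'
#' @param fit an `"hrspls_modules"` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_module_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- do.call(rbind, lapply(fit$modules, function(m) {
    rbind(
      if (nrow(m$x_features) > 0)
        data.frame(module_index = m$index, omics = "X",
                   feature_id = m$x_features$id,
                   weight = m$x_features$weight,
                   z_score = m$x_features$z_score),
      if (nrow(m$y_features) > 0)
        data.frame(module_index = m$index, omics = "Y",
                   feature_id = m$y_features$id,
                   weight = m$y_features$weight,
                   z_score = m$y_features$z_score))
  }))
  if (is.null(feats)) {
    feats <- data.frame(module_index = integer(0), omics = character(0),
                        feature_id = character(0), weight = numeric(0),
                        z_score = numeric(0))
  }
  samp <- do.call(rbind, lapply(fit$modules, function(m) {
    if (nrow(m$samples) > 0)
      data.frame(module_index = m$index, sample_id = m$samples$id,
                 combined_score = m$samples$combined_score)
  }))
  if (is.null(samp)) {
    samp <- data.frame(module_index = integer(0), sample_id = character(0),
                       combined_score = numeric(0))
  }
  paths <- file.path(dir, c("modules.tsv", "samples.tsv", "summary.tsv"))
  data.table::fwrite(feats, paths[1], sep = "\t")
  data.table::fwrite(samp, paths[2], sep = "\t")
  data.table::fwrite(fit$summary, paths[3], sep = "\t")
  invisible(paths)
}

#' Run the full pipeline from files to result files
#'
#' Reads and aligns the two matrices, optionally grid-searches the
#' penalties, extracts modules and writes `modules.tsv`,
#' `samples.tsv`, `summary.tsv` (and `gridsearch.tsv` when searching)
#' plus `run_metadata.json` into `out_dir`. Identical inputs, config
#' and seed produce identical outputs; on error, partial outputs are
#' removed and the error is rethrown.
#'
#' @param x_path,y_path input matrix files.
#' @param out_dir output directory.
#' @param config a [solver_config()].
#' @param orientation orientation of both input files, as in
#'   [read_omics_matrix()].
#' @param graph graph penalty kind.
#' @param gridsearch run [grid_search()] first and refit the winning
#'   configuration at full depth.
#' @param grids optional named list of grids
#'   (`lambda1`, `lambda2`, `beta1`, `beta2`, `knn_k`) for the search.
#' @param search_modules modules per combination during the search.
#' @return invisibly, the `"hrspls_modules"` fit.
#' @export
run_pipeline <- function(x_path, y_path, out_dir,
                         config = solver_config(),
                         orientation = c("samples", "features"),
                         graph = c("hypergraph", "simple", "none"),
                         gridsearch = FALSE, grids = NULL,
                         search_modules = 3) {
  orientation <- match.arg(orientation)
  graph <- match.arg(graph)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  result <- tryCatch({
    X <- read_omics_matrix(x_path, orientation = orientation, name = "X")
    Y <- read_omics_matrix(y_path, orientation = orientation, name = "Y")
    al <- align_samples(X, Y)
    cfg <- config
    if (gridsearch) {
      g <- function(nm, default) if (!is.null(grids[[nm]])) grids[[nm]] else default
      gs <- grid_search(al$X, al$Y, config = config,
                        lambda1_grid = g("lambda1", c(0.01, 0.05, 0.1, 0.5, 1)),
                        lambda2_grid = g("lambda2", c(0.01, 0.05, 0.1, 0.5, 1)),
                        beta1_grid = g("beta1", c(0.01, 0.05, 0.1, 0.5, 1)),
                        beta2_grid = g("beta2", c(0.01, 0.05, 0.1, 0.5, 1)),
                        knn_k_grid = g("knn_k", config$knn_k),
                        search_modules = search_modules, graph = graph)
      gpath <- file.path(out_dir, "gridsearch.tsv")
      data.table::fwrite(gs$table, gpath, sep = "\t")
      written <- c(written, gpath)
      cfg <- gs$best_config
      cfg$n_modules <- config$n_modules
    }
    fit <- extract_modules(al$X, al$Y, cfg, graph = graph)
    written <- c(written, write_module_results(fit, out_dir))
    meta <- file.path(out_dir, "run_metadata.json")
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("hrspls")),
           x_path = x_path, y_path = y_path,
           n_samples = nrow(al$X), p_features = ncol(al$X),
           q_features = ncol(al$Y),
           graph = graph, gridsearch = gridsearch,
           parameters = cfg[!vapply(cfg, is.null, logical(1))],
           n_modules_extracted = length(fit$modules),
           n_converged = sum(fit$summary$converged, na.rm = TRUE)),
      meta, auto_unbox = TRUE, digits = NA)
    written <- c(written, meta)
    fit
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(result)
}
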