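# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. `seed = NULL` leaves the
# RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

l2norm <- function(x) sqrt(sum(x^2))

#' Column-standardize a matrix
#'
#' Centers every column to mean zero and scales it to unit standard
#' deviation. Constant columns cannot be scaled and are dropped with a
#' warning; both weight z-scoring and distance-based neighbourhood graphs
#' assume features live on a comparable scale, so fitting routines call
#' this before any other computation.
#'
#' @param x numeric matrix (samples in rows).
#' @return standardized matrix, possibly with fewer columns.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("matrix must be numeric")
  if (any(!is.finite(x))) stop("matrix contains non-finite values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant column(s): %s",
                    sum(sds == 0),
                    paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) < 2) stop("fewer than 2 non-constant columns remain")
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}
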