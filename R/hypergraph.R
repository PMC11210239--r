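#' k-nearest-neighbour hypergraphs over omics features
#'
#' A hypergraph generalizes a graph by letting an edge (a "hyperedge")
#' join any number of vertices. Here vertices are the features of one
#' omics block and one hyperedge is grown around every feature: the edge
#' centred on feature j contains j itself plus its `k - 1` nearest
#' neighbour features, measured on z-scored feature profiles. The derived
#' similarity matrix and normalized Laplacian feed the solver's
#' smoothness penalty, which encourages features sharing hyperedges to
#' receive similar weights.
#'
#' The structure is encoded by an N x M binary incidence matrix H
#' (H\[i, e\] = 1 iff vertex i belongs to hyperedge e), a positive edge
#' weight vector w, the weighted vertex degrees Dv (row sums of H
#' weighted by w), the edge degrees De (vertices per edge), the vertex
#' similarity
#' \deqn{S = H W D_e^{-1} H^T,}
#' and the normalized Laplacian
#' \deqn{L = I - D_v^{-1/2} S D_v^{-1/2}.}
#' S is symmetric and nonnegative with row sums equal to the vertex
#' degrees, so L is symmetric positive semidefinite and annihilates
#' \eqn{D_v^{1/2} 1}.
#'
#' @param profiles numeric matrix, N features x n samples (one row per
#'   vertex). Each row is z-scored before distances are computed;
#'   constant rows cannot be z-scored and enter as-is with a warning.
#' @param k maximum number of vertices per hyperedge (the centre feature
#'   plus `k - 1` neighbours), `1 <= k <= N`. `k = 1` yields singleton
#'   edges and hence a zero Laplacian: allowed, but flagged as
#'   degenerate regularization.
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (distance `1 - cor` between profiles).
#' @param edge_weights `"uniform"` (all 1, default) or `"heat"`
#'   (`exp(-mean pairwise squared distance within the edge / sigma^2)`).
#' @param sigma bandwidth for heat weights; defaults to the mean of all
#'   pairwise profile distances.
#' @return object of class `"hypergraph"`: a list with `incidence`,
#'   `edge_weights`, `vertex_degrees`, `edge_degrees`, `similarity`,
#'   `laplacian`, `n_vertices`, `n_edges`, `k`, `metric`.
#' @examples
#' set.seed(1)
#' hg <- build_knn_hypergraph(matrix(rnorm(40), 8, 5), k = 3)
#' hg$incidence
#' range(eigen(hg$laplacian, symmetric = TRUE, only.values = TRUE)$values)
#' @export
build_knn_hypergraph <- function(profiles, k = 2,
                                 metric = c("euclidean", "correlation"),
                                 edge_weights = c("uniform", "heat"),
                                 sigma = NULL) {
  metric <- match.arg(metric)
  edge_weights <- match.arg(edge_weights)
  profiles <- as.matrix(profiles)
  if (any(!is.finite(profiles))) stop("profiles contain non-finite values")
  N <- nrow(profiles)
  if (N < 2 || ncol(profiles) < 2) stop("need at least 2 features and 2 samples")
  if (k < 1 || k > N) stop(sprintf("k must be in [1, %d], got %s", N, k))
  if (k == 1) {
    warning("k = 1 builds singleton hyperedges: the Laplacian is zero and the hypergraph penalty is inactive")
  }

  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant feature profile(s); distances for them use the raw profile",
                    sum(sds == 0)))
  }
  z <- profiles
  ok <- sds > 0
  z[ok, ] <- (profiles[ok, , drop = FALSE] -
                rowMeans(profiles[ok, , drop = FALSE])) / sds[ok]

  dmat <- switch(metric,
    euclidean  = as.matrix(stats::dist(z)),
    correlation = 1 - stats::cor(t(z)))
  if (any(!is.finite(dmat))) {
    # correlation with a constant (raw) profile is undefined; treat as maximal
    dmat[!is.finite(dmat)] <- max(dmat[is.finite(dmat)], 2)
  }

  H <- matrix(0, N, N)
  for (j in seq_len(N)) {
    members <- j
    if (k > 1) {
      others <- setdiff(seq_len(N), j)
      # ascending distance, ties broken by ascending feature index
      ord <- others[order(dmat[others, j], others)]
      members <- c(j, ord[seq_len(k - 1)])
    }
    H[members, j] <- 1
  }
  rownames(H) <- rownames(profiles)

  w <- rep(1, N)
  if (edge_weights == "heat") {
    if (is.null(sigma)) sigma <- mean(dmat[upper.tri(dmat)])
    if (sigma <= 0) sigma <- 1
    w <- vapply(seq_len(N), function(j) {
      m <- which(H[, j] == 1)
      if (length(m) < 2) return(1)
      dd <- dmat[m, m]
      exp(-mean(dd[upper.tri(dd)]^2) / sigma^2)
    }, numeric(1))
  }

  hg <- structure(list(incidence = H, edge_weights = w,
                       n_vertices = N, n_edges = N,
                       k = k, metric = metric),
                  class = "hypergraph")
  similarity_and_laplacian(hg)
}

#' Populate the similarity matrix and normalized Laplacian of a hypergraph
#'
#' Computes the degree matrices, the vertex similarity
#' `S = H W De^-1 H^T` and the normalized Laplacian
#' `L = I - Dv^-1/2 S Dv^-1/2` from the incidence matrix and edge
#' weights. Called by [build_knn_hypergraph()]; exposed so that
#' hand-built incidence structures can be completed the same way.
#'
#' @param hg a `"hypergraph"` object (or list) with at least `incidence`
#'   and `edge_weights`.
#' @return the hypergraph with `vertex_degrees`, `edge_degrees`,
#'   `similarity` and `laplacian` filled in.
#' @export
similarity_and_laplacian <- function(hg) {
  H <- as.matrix(hg$incidence)
  w <- hg$edge_weights
  if (is.null(H) || is.null(w)) stop("incidence and edge_weights must be populated")
  if (!all(H %in% c(0, 1))) stop("incidence entries must be 0 or 1")
  de <- colSums(H)
  if (any(de == 0)) stop("every hyperedge must contain at least one vertex")
  if (any(w <= 0)) stop("edge weights must be positive")
  dv <- as.numeric(H %*% w)
  if (any(dv == 0)) {
    stop("isolated vertex (degree 0) at index ",
         paste(utils::head(which(dv == 0), 5), collapse = ", "),
         ": increase k or prune the feature")
  }
  S <- H %*% (w / de * t(H))
  S <- (S + t(S)) / 2
  L <- diag(nrow(H)) - S / sqrt(outer(dv, dv))
  L <- (L + t(L)) / 2
  hg$vertex_degrees <- dv
  hg$edge_degrees <- de
  hg$similarity <- S
  hg$laplacian <- L
  if (is.null(hg$n_vertices)) hg$n_vertices <- nrow(H)
  if (is.null(hg$n_edges)) hg$n_edges <- ncol(H)
  class(hg) <- "hypergraph"
  hg
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("kNN hypergraph: %d vertices, %d hyperedges (k = %s, %s metric)\n",
              x$n_vertices, x$n_edges,
              if (is.null(x$k)) "?" else x$k,
              if (is.null(x$metric)) "custom" else x$metric))
  invisible(x)
}

#' Normalized Laplacian of a mutualized kNN simple graph
#'
#' Builds the simple-graph analogue of [build_knn_hypergraph()] for the
#' graph-regularized baseline: vertices i and j are adjacent (weight 1)
#' iff j is among the `k - 1` nearest neighbours of i or vice versa, on
#' z-scored profiles. Returns `I - D^-1/2 A D^-1/2`; `k` counts vertices
#' the same way as the hypergraph (centre plus `k - 1` neighbours) so
#' that the two constructions couple the same feature pairs at equal k.
#'
#' @inheritParams build_knn_hypergraph
#' @return list with `adjacency` and `laplacian`.
#' @export
build_knn_graph_laplacian <- function(profiles, k = 2,
                                      metric = c("euclidean", "correlation")) {
  hg <- build_knn_hypergraph(profiles, k = k, metric = metric)
  H <- hg$incidence
  N <- nrow(H)
  A <- matrix(0, N, N)
  for (j in seq_len(N)) {
    nb <- setdiff(which(H[, j] == 1), j)
    A[j, nb] <- 1
    A[nb, j] <- 1
  }
  deg <- rowSums(A)
  denom <- sqrt(outer(deg, deg))
  denom[denom == 0] <- 1
  L <- diag(N) - A / denom
  L <- (L + t(L)) / 2
  list(adjacency = A, laplacian = L)
}

#' Write hypergraph matrices to disk
#'
#' Serializes the incidence matrix as a sparse triplet TSV
#' (`vertex_id`, `edge_id`, `value`) and, optionally, the similarity and
#' Laplacian as dense TSVs.
#'
#' @param hg hypergraph object.
#' @param incidence_path path for the triplet TSV.
#' @param similarity_path,laplacian_path optional paths for dense TSVs.
#' @return invisibly, the paths written.
#' @export
write_hypergraph <- function(hg, incidence_path,
                             similarity_path = NULL, laplacian_path = NULL) {
  idx <- which(hg$incidence == 1, arr.ind = TRUE)
  ids <- rownames(hg$incidence)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(hg$incidence)))
  trip <- data.table::data.table(vertex_id = ids[idx[, 1]],
                                 edge_id = paste0("e", idx[, 2]),
                                 value = 1)
  data.table::fwrite(trip, incidence_path, sep = "\t")
  written <- incidence_path
  for (nm in c("similarity", "laplacian")) {
    path <- if (nm == "similarity") similarity_path else laplacian_path
    if (!is.null(path)) {
      data.table::fwrite(data.table::as.data.table(hg[[nm]]), path, sep = "\t")
      written <- c(written, path)
    }
  }
  invisible(written)
}
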