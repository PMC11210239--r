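# Shared fixtures and independent oracles, all generated in code.

# Seeded standardized Gaussian matrix.
rand_std <- function(n, p, seed) {
  set.seed(seed)
  standardize_columns(matrix(rnorm(n * p), n, p))
}

# Independent second implementation of the graph penalty as the explicit
# normalized pairwise sum sum_{i<j} S_ij (w_i/sqrt(dv_i) - w_j/sqrt(dv_j))^2.
pairwise_graph_penalty <- function(w, S, dv) {
  total <- 0
  l <- sqrt(dv)
  for (i in seq_along(w)) {
    for (j in seq_along(w)) {
      if (i < j) total <- total + S[i, j] * (w[i] / l[i] - w[j] / l[j])^2
    }
  }
  total
}

# Exhaustive minimization of the penalized objective over unit vectors
# g(theta), d(phi) on an angular grid (p = q = 2 only).
angular_min_objective <- function(X, Y, L1, L2, cfg, step_deg = 0.5) {
  th <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  G <- rbind(cos(th), sin(th))
  cscale <- if (cfg$cov_scale == "1/p") 1 / ncol(X) else 1 / nrow(X)
  cross <- -cscale * t(G) %*% crossprod(X, Y) %*% G
  pen_g <- cfg$beta1 * colSums(G * (L1 %*% G)) +
    cfg$lambda1 * colSums(abs(G)) + cfg$gamma1
  pen_d <- cfg$beta2 * colSums(G * (L2 %*% G)) +
    cfg$lambda2 * colSums(abs(G)) + cfg$gamma2
  min(sweep(sweep(cross, 1, pen_g, "+"), 2, pen_d, "+"))
}

# Brute-force neighbour sets from the full distance matrix (oracle for
# the kNN hyperedge construction; ties by ascending index).
brute_force_edges <- function(profiles, k) {
  z <- t(scale(t(profiles)))
  d <- as.matrix(dist(z))
  lapply(seq_len(nrow(profiles)), function(j) {
    others <- setdiff(seq_len(nrow(profiles)), j)
    ord <- others[order(d[others, j], others)]
    sort(c(j, ord[seq_len(k - 1)]))
  })
}

# Exhaustive planted-to-extracted matching: enumerates every injective
# assignment and returns the one maximizing the total Jaccard index.
exhaustive_match <- function(ext_supports, truth_sets) {
  K <- length(truth_sets); M <- length(ext_supports)
  jac <- function(a, b) {
    if (length(a) == 0 && length(b) == 0) return(0)
    length(intersect(a, b)) / length(union(a, b))
  }
  cand <- utils::combn(M, K, simplify = FALSE)
  best <- NULL; best_score <- -Inf
  for (sel in cand) {
    perm_list <- if (K == 1) list(sel) else {
      out <- list()
      rec <- function(prefix, rest) {
        if (length(rest) == 0) out[[length(out) + 1]] <<- prefix
        else for (r in rest) rec(c(prefix, r), setdiff(rest, r))
      }
      rec(integer(0), sel)
      out
    }
    for (pm in perm_list) {
      score <- sum(vapply(seq_len(K), function(k)
        jac(ext_supports[[pm[k]]], truth_sets[[k]]), numeric(1)))
      if (score > best_score) { best_score <- score; best <- pm }
    }
  }
  list(assignment = best, score = best_score)
}
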