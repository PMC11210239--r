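#' Simulate paired omics matrices with planted co-modules
#'
#' Generates two blocks sharing sparse latent factors:
#' `X = sum_k s_x u_k g_k' + E_x` and `Y = sum_k s_y u_k d_k' + E_y`,
#' where the `u_k` are orthonormal sample scores, `g_k`/`d_k` are zero
#' outside randomly chosen disjoint supports with unit-norm positive
#' blocks (so features sharing a support are mutually correlated and
#' nearest-neighbour hyperedges align with the planted structure), and
#' the noise is i.i.d. Gaussian (optionally scaled Student-t for
#' heavier tails). The signal scale `s` is set so that the mean
#' per-entry signal variance over the support equals `snr * noise_sd^2`:
#' `s = noise_sd * sqrt(snr * n * m)` for support size m. `snr = 0`
#' plants supports but no signal (a pure-noise null with bookkeeping).
#'
#' @param n_samples,p_features,q_features dimensions (n >= 4).
#' @param n_modules number of planted co-modules (0 for pure noise).
#' @param support_x,support_y features per planted module in each block.
#' @param snr per-entry signal-to-noise variance ratio, `>= 0`.
#' @param noise_sd Gaussian noise standard deviation, `> 0`.
#' @param noise `"gaussian"` (default) or `"t"` (scaled to unit
#'   variance, `df` degrees of freedom).
#' @param df degrees of freedom for t noise.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return list with `X`, `Y` (dimnamed matrices) and `truth`, a
#'   `"synthetic_truth"` object holding `supports_x`, `supports_y`
#'   (lists of index vectors), `latent_scores` (n x K orthonormal),
#'   `loadings_x`, `loadings_y` (sparse weight vectors), the signal
#'   scales and all generator parameters.
#' @export
simulate_paired_omics <- function(n_samples = 100, p_features = 300,
                                  q_features = 250, n_modules = 1,
                                  support_x = 15, support_y = 15,
                                  snr = 2, noise_sd = 1,
                                  noise = c("gaussian", "t"), df = 4,
                                  seed = NULL) {
  noise <- match.arg(noise)
  if (n_samples < 4) stop("need n_samples >= 4")
  if (snr < 0 || noise_sd <= 0) stop("snr must be >= 0 and noise_sd > 0")
  if (n_modules * support_x > p_features || n_modules * support_y > q_features) {
    stop("planted supports exceed the feature dimension")
  }
  if (n_modules > n_samples) stop("cannot plant more modules than samples")
  with_seed(seed, {
    K <- n_modules
    draw_noise <- function(n, p) {
      e <- switch(noise,
                  gaussian = stats::rnorm(n * p),
                  t = stats::rt(n * p, df = df) / sqrt(df / (df - 2)))
      matrix(noise_sd * e, n, p)
    }
    X <- draw_noise(n_samples, p_features)
    Y <- draw_noise(n_samples, q_features)
    supports_x <- list(); supports_y <- list()
    loadings_x <- list(); loadings_y <- list()
    U <- matrix(numeric(0), n_samples, 0)
    s_x <- s_y <- numeric(0)
    if (K > 0) {
      U <- qr.Q(qr(matrix(stats::rnorm(n_samples * K), n_samples, K)))
      pool_x <- sample.int(p_features, K * support_x)
      pool_y <- sample.int(q_features, K * support_y)
      s_x <- rep(noise_sd * sqrt(snr * n_samples * support_x), K)
      s_y <- rep(noise_sd * sqrt(snr * n_samples * support_y), K)
      for (k in seq_len(K)) {
        sx <- sort(pool_x[((k - 1) * support_x + 1):(k * support_x)])
        sy <- sort(pool_y[((k - 1) * support_y + 1):(k * support_y)])
        gk <- rep(0, p_features); dk <- rep(0, q_features)
        wx <- stats::runif(support_x, 0.8, 1.2)
        wy <- stats::runif(support_y, 0.8, 1.2)
        gk[sx] <- wx / l2norm(wx)
        dk[sy] <- wy / l2norm(wy)
        X <- X + s_x[k] * outer(U[, k], gk)
        Y <- Y + s_y[k] * outer(U[, k], dk)
        supports_x[[k]] <- sx; supports_y[[k]] <- sy
        loadings_x[[k]] <- gk; loadings_y[[k]] <- dk
      }
    }
    dimnames(X) <- list(paste0("sample_", seq_len(n_samples)),
                        paste0("x_", seq_len(p_features)))
    dimnames(Y) <- list(paste0("sample_", seq_len(n_samples)),
                        paste0("y_", seq_len(q_features)))
    truth <- structure(list(n_samples = n_samples, p_features = p_features,
                            q_features = q_features, n_planted = K,
                            supports_x = supports_x, supports_y = supports_y,
                            latent_scores = U,
                            loadings_x = loadings_x, loadings_y = loadings_y,
                            signal_scale_x = s_x, signal_scale_y = s_y,
                            snr = snr, noise_sd = noise_sd, noise = noise,
                            seed = seed),
                       class = "synthetic_truth")
    list(X = X, Y = Y, truth = truth)
  })
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

prf <- function(sel, truth_set) {
  tp <- length(intersect(sel, truth_set))
  precision <- if (length(sel) > 0) tp / length(sel) else 0
  recall <- if (length(truth_set) > 0) tp / length(truth_set) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Score extracted modules against a planted truth
#'
#' Greedily matches each planted co-module to the extracted module with
#' the largest Jaccard index of the combined (X and Y) feature supports
#' (ties broken by extracted-module index, each extracted module used
#' at most once), then reports per planted module the support
#' precision/recall/F1 for each block, the absolute correlation between
#' the matched latent scores and the planted scores, and the matched
#' module's correlation `cor(u, v)`.
#'
#' @param modules an `"hrspls_modules"` object (or its list of modules).
#' @param truth a `"synthetic_truth"` from [simulate_paired_omics()].
#' @return list with `per_module` (data frame, one row per planted
#'   module) and means `mean_f1`, `mean_latent_cor`, `mean_pcc`.
#'   `mean_f1` averages the X- and Y-side F1; `mean_latent_cor`
#'   averages `|cor(u, u_true)|` and `|cor(v, u_true)|`.
#' @export
evaluate_recovery <- function(modules, truth) {
  if (inherits(modules, "hrspls_modules")) modules <- modules$modules
  K <- truth$n_planted
  if (K < 1) stop("truth contains no planted modules")
  p <- truth$p_features
  ext_supports <- lapply(modules, function(m) {
    c(m$x_features$index, p + m$y_features$index)
  })
  used <- rep(FALSE, length(modules))
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    tset <- c(truth$supports_x[[k]], p + truth$supports_y[[k]])
    jac <- vapply(seq_along(modules), function(i) {
      if (used[i]) -1 else jaccard(ext_supports[[i]], tset)
    }, numeric(1))
    best <- if (length(jac) > 0) which.max(jac) else NA_integer_
    if (is.na(best) || jac[best] < 0) {
      rows[[k]] <- data.frame(planted = k, matched = NA_integer_,
                              jaccard = 0,
                              precision_x = 0, recall_x = 0, f1_x = 0,
                              precision_y = 0, recall_y = 0, f1_y = 0,
                              latent_cor_u = 0, latent_cor_v = 0, pcc = NA_real_)
      next
    }
    used[best] <- TRUE
    m <- modules[[best]]
    px <- prf(m$x_features$index, truth$supports_x[[k]])
    py <- prf(m$y_features$index, truth$supports_y[[k]])
    ut <- truth$latent_scores[, k]
    cu <- if (!is.null(m$component) && stats::sd(m$component$u) > 0)
      abs(stats::cor(m$component$u, ut)) else 0
    cv <- if (!is.null(m$component) && stats::sd(m$component$v) > 0)
      abs(stats::cor(m$component$v, ut)) else 0
    rows[[k]] <- data.frame(planted = k, matched = m$index,
                            jaccard = jac[best],
                            precision_x = px["precision"], recall_x = px["recall"],
                            f1_x = px["f1"],
                            precision_y = py["precision"], recall_y = py["recall"],
                            f1_y = py["f1"],
                            latent_cor_u = cu, latent_cor_v = cv,
                            pcc = m$pcc)
  }
  per_module <- do.call(rbind, rows)
  rownames(per_module) <- NULL
  list(per_module = per_module,
       mean_f1 = mean((per_module$f1_x + per_module$f1_y) / 2),
       mean_latent_cor = mean((per_module$latent_cor_u + per_module$latent_cor_v) / 2),
       mean_pcc = mean(abs(per_module$pcc), na.rm = TRUE))
}

#' Write a simulated dataset to disk
#'
#' Writes `X.tsv` and `Y.tsv` (samples x features with an `id` header
#' column) and `truth.json` (supports, parameters, seed) into `dir`.
#'
#' @param sim result of [simulate_paired_omics()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- file.path(dir, "X.tsv"); py <- file.path(dir, "Y.tsv")
  write_omics_matrix(sim$X, px)
  write_omics_matrix(sim$Y, py)
  tr <- sim$truth
  pj <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(n_samples = tr$n_samples, p_features = tr$p_features,
         q_features = tr$q_features, n_planted = tr$n_planted,
         supports_x = tr$supports_x, supports_y = tr$supports_y,
         latent_scores = tr$latent_scores,
         signal_scale_x = tr$signal_scale_x, signal_scale_y = tr$signal_scale_y,
         snr = tr$snr, noise_sd = tr$noise_sd, noise = tr$noise,
         seed = tr$seed),
    pj, auto_unbox = TRUE, digits = NA)
  invisible(c(px, py, pj))
}

#' Read a planted truth back from truth.json
#'
#' @param path path to a `truth.json` written by [write_simulation()].
#' @return a `"synthetic_truth"` object.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$supports_x <- lapply(seq_len(tr$n_planted), function(k)
    as.integer(if (is.list(tr$supports_x)) tr$supports_x[[k]] else tr$supports_x[k, ]))
  tr$supports_y <- lapply(seq_len(tr$n_planted), function(k)
    as.integer(if (is.list(tr$supports_y)) tr$supports_y[[k]] else tr$supports_y[k, ]))
  tr$latent_scores <- matrix(unlist(tr$latent_scores),
                             nrow = tr$n_samples, ncol = tr$n_planted)
  class(tr) <- "synthetic_truth"
  tr
}
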