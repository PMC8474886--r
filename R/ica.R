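#' Consensus independent component analysis of an expression matrix
#'
#' Runs fixed-point ICA (negentropy maximization with the log-cosh
#' contrast, after PCA whitening) `n_runs` times, each from a random
#' orthonormal initialization on a bootstrap resample of the genes, pools
#' the estimated components across runs, clusters them by absolute Pearson
#' correlation of their gene weights, and averages each stable cluster into
#' a consensus component. A cluster is stable when the fraction of runs
#' contributing to it reaches `stability_threshold`. The gene bootstrap is
#' what gives stability its meaning: genuine sources are re-estimated
#' almost unchanged on every resample, whereas directions fitted to noise
#' depend on the particular genes drawn and fail to recur.
#' Consensus weights are standardized per component (mean 0, sd 1) with the
#' sign convention that each component's largest-magnitude gene weight is
#' positive. Activity scores (the mixing matrix) are the least-squares
#' coefficients of each centered sample profile on the consensus weights.
#'
#' Components are ordered by decreasing stability, so reported stability is
#' monotone non-increasing.
#'
#' @param x An [expression_matrix()]: complete, nonzero-variance genes.
#' @param n_components Number of components per run (whitening dimension);
#'   at most `min(genes, samples)` and at most the numerical rank of the
#'   centered matrix. At most this many consensus components are returned.
#' @param n_runs Number of independent ICA runs (at least 2).
#' @param stability_threshold Minimum fraction of runs a consensus cluster
#'   must appear in.
#' @param seed Seed governing all randomness (initializations).
#' @param cor_threshold Absolute Pearson correlation at which two run
#'   estimates are considered the same component.
#' @param maxit,tol Fixed-point iteration controls.
#' @return List with `components` (class `metica_components`: `weights`
#'   genes x K, `stability`, `dataset_label`) and `mixing` (class
#'   `metica_mixing`: `activities` samples x K).
#' @export
decompose <- function(x, n_components, n_runs = 25,
                      stability_threshold = 0.5, seed = 1,
                      cor_threshold = 0.9, maxit = 200, tol = 1e-6) {
  stopifnot(inherits(x, "metica_expr"))
  v <- x$values
  n_genes <- nrow(v)
  k <- as.integer(n_components)
  if (k < 2 || k > min(dim(v))) {
    stop("n_components must lie in [2, min(genes, samples)]")
  }
  if (n_runs < 2) stop("n_runs must be at least 2")

  # Double centering: gene-centering removes the common mean expression
  # profile (otherwise recovered as a spurious stable component);
  # sample-centering makes the gene-space covariance well-defined for
  # whitening.
  xc <- v - rowMeans(v)
  xc <- sweep(xc, 2, colMeans(xc))
  sv <- svd(xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) {
    stop(sprintf("n_components (%d) exceeds the matrix rank (%d)", k, rank))
  }
  # Whitened gene-space representation: columns have mean 0, covariance I
  # over genes.
  z <- sv$u[, seq_len(k), drop = FALSE] * sqrt(n_genes - 1)

  runs <- with_seed(seed, {
    out <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      w0 <- matrix(stats::rnorm(k * k), k, k)
      idx <- sample.int(n_genes, n_genes, replace = TRUE)
      est <- tryCatch({
        w_hat <- fastica_symmetric(z[idx, , drop = FALSE], w0,
                                   maxit = maxit, tol = tol)
        standardize_cols(z %*% w_hat)
      }, error = function(e) NULL)
      if (is.null(est)) {
        message("ICA run ", r, " failed and was discarded")
      }
      out[[r]] <- est
    }
    out
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (sum(ok) < 2) stop("fewer than 2 ICA runs survived")
  runs <- runs[ok]
  run_id <- rep(seq_along(runs), each = k)
  pool <- do.call(cbind, runs)        # genes x (k * n_ok), standardized

  cl <- cluster_run_components(pool, run_id, n_runs = n_runs,
                               cor_threshold = cor_threshold)
  keep <- cl$stability >= stability_threshold
  if (!any(keep)) stop("no consensus component reached the stability ",
                       "threshold")
  ord <- order(-cl$stability[keep])
  centroids <- cl$centroids[, keep, drop = FALSE][, ord, drop = FALSE]
  stability <- cl$stability[keep][ord]
  if (ncol(centroids) > k) {
    centroids <- centroids[, seq_len(k), drop = FALSE]
    stability <- stability[seq_len(k)]
  }
  weights <- apply_sign_convention(standardize_cols(centroids))
  comp_ids <- sprintf("TC%d", seq_len(ncol(weights)))
  dimnames(weights) <- list(rownames(v), comp_ids)
  names(stability) <- comp_ids

  comps <- structure(list(weights = weights, stability = stability,
                          dataset_label = x$dataset_label),
                     class = "metica_components")
  a <- solve(crossprod(weights), crossprod(weights, xc))
  activities <- t(a)
  dimnames(activities) <- list(colnames(v), comp_ids)
  mixing <- structure(list(activities = activities,
                           sample_ids = colnames(v),
                           component_ids = comp_ids),
                      class = "metica_mixing")
  list(components = comps, mixing = mixing)
}

# Symmetric (parallel) fixed-point ICA with the log-cosh contrast on a
# whitened genes x k matrix. Returns the k x k orthonormal unmixing
# matrix.
fastica_symmetric <- function(z, w0, maxit = 200, tol = 1e-6) {
  n <- nrow(z)
  w <- orthonormalize(w0)
  for (it in seq_len(maxit)) {
    s <- z %*% w
    g <- tanh(s)
    w1 <- crossprod(z, g) / n -
      sweep(w, 2, colMeans(1 - g^2), "*")
    w1 <- orthonormalize(w1)
    delta <- max(abs(abs(colSums(w1 * w)) - 1))
    w <- w1
    if (!is.finite(delta)) stop("ICA iteration diverged")
    if (delta < tol) break
  }
  w
}

# Symmetric decorrelation: W (W'W)^(-1/2).
orthonormalize <- function(w) {
  e <- eigen(crossprod(w), symmetric = TRUE)
  if (min(e$values) < .Machine$double.eps * max(e$values)) {
    stop("degenerate unmixing matrix")
  }
  w %*% (e$vectors %*% (t(e$vectors) / sqrt(e$values)))
}

# Greedy centroid clustering of pooled run components by absolute Pearson
# correlation. Returns sign-aligned centroids and per-cluster stability
# (fraction of distinct runs contributing).
cluster_run_components <- function(pool, run_id, n_runs, cor_threshold) {
  n <- nrow(pool)
  ac <- abs(crossprod(pool)) / (n - 1)   # columns standardized
  m <- ncol(pool)
  remaining <- rep(TRUE, m)
  centroids <- list()
  stability <- numeric()
  while (any(remaining)) {
    idx <- which(remaining)
    hits <- rowSums(ac[idx, idx, drop = FALSE] >= cor_threshold)
    seed_i <- idx[which.max(hits)]
    members <- idx[ac[seed_i, idx] >= cor_threshold]
    signs <- sign(crossprod(pool[, seed_i], pool[, members, drop = FALSE]))
    signs[signs == 0] <- 1
    centroid <- as.vector(pool[, members, drop = FALSE] %*% t(signs)) /
      length(members)
    centroids[[length(centroids) + 1]] <- centroid
    stability <- c(stability,
                   length(unique(run_id[members])) / n_runs)
    remaining[members] <- FALSE
  }
  list(centroids = do.call(cbind, centroids), stability = stability)
}

#' @export
print.metica_components <- function(x, ...) {
  cat(sprintf("<metica_components '%s'> %d genes x %d components\n",
              x$dataset_label, nrow(x$weights), ncol(x$weights)))
  cat("stability:", paste(sprintf("%.2f", x$stability), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.metica_mixing <- function(x, ...) {
  cat(sprintf("<metica_mixing> %d samples x %d components\n",
              nrow(x$activities), ncol(x$activities)))
  invisible(x)
}

#' Project samples onto consensus components
#'
#' Estimates activity scores for (possibly new) samples as the
#' least-squares coefficients of each centered sample profile on the
#' component weight matrix, restricted to the genes shared between the
#' components and the expression matrix. At least half of the component
#' genes must be present.
#'
#' @param components A `metica_components` object.
#' @param x An [expression_matrix()].
#' @return A `metica_mixing` object (`activities`: samples x components).
#' @export
project_activities <- function(components, x) {
  stopifnot(inherits(components, "metica_components"),
            inherits(x, "metica_expr"))
  w <- components$weights
  shared <- intersect(rownames(w), rownames(x$values))
  frac <- length(shared) / nrow(w)
  if (frac < 0.5) {
    stop(sprintf("only %.1f%% of component genes present in the ",
                 100 * frac), "expression matrix (need >= 50%)")
  }
  if (frac < 1) {
    message(sprintf("projecting on %d/%d shared genes (%.1f%%)",
                    length(shared), nrow(w), 100 * frac))
  }
  ws <- w[shared, , drop = FALSE]
  xs <- x$values[shared, , drop = FALSE]
  xs <- sweep(xs, 2, colMeans(xs))
  a <- solve(crossprod(ws), crossprod(ws, xs))
  activities <- t(a)
  dimnames(activities) <- list(colnames(x$values), colnames(w))
  structure(list(activities = activities,
                 sample_ids = colnames(x$values),
                 component_ids = colnames(w)),
            class = "metica_mixing")
}

#' Suggest a component count from the PCA spectrum
#'
#' Returns the smallest number of principal components whose cumulative
#' explained variance reaches `variance_target`, a pragmatic default for
#' choosing the whitening dimension of [decompose()].
#'
#' @param x An [expression_matrix()].
#' @param variance_target Cumulative variance fraction to reach.
#' @return Integer component count.
#' @export
suggest_k <- function(x, variance_target = 0.8) {
  stopifnot(inherits(x, "metica_expr"))
  if (variance_target <= 0 || variance_target > 1) {
    stop("variance_target must lie in (0, 1]")
  }
  xc <- sweep(x$values, 2, colMeans(x$values))
  d2 <- svd(xc, nu = 0, nv = 0)$d^2
  as.integer(which(cumsum(d2) / sum(d2) >= variance_target)[1])
}
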