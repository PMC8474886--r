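#' Consensus clustering of gene-set enrichment profiles
#'
#' Collapses redundant gene sets by resampled hierarchical clustering of
#' their enrichment profiles (rows of the enrichment matrix). In each of
#' `reps` resamplings, `ceiling(p_item * n_sets)` sets and
#' `ceiling(p_feature * n_components)` components are drawn without
#' replacement; the sampled sets are clustered on the distance
#' 1 - Pearson correlation (average linkage) and cut at every k in
#' `2..maxK`. The consensus for a pair of sets at a given k is the number
#' of times they co-clustered divided by the number of times they were
#' co-sampled. Final per-k assignments come from hierarchical clustering
#' of 1 - consensus; the cluster count is chosen by [choose_k()] on the
#' per-k areas under the consensus CDF.
#'
#' @param enrichment A `metica_enrichment` (or plain sets x components
#'   matrix with dimnames).
#' @param maxK Largest cluster count examined (must be below the number of
#'   sets).
#' @param reps Number of resamplings (at least 2).
#' @param p_item,p_feature Row / column subsampling fractions.
#' @param seed Seed for the resampling stream.
#' @param delta_threshold Relative CDF-area change below which additional
#'   clusters are considered uninformative (passed to [choose_k()]).
#' @return Object of class `metica_consensus`: `assignment` (named cluster
#'   labels at `chosen_k`), `assignments` (per-k label matrix), `consensus`
#'   (list of per-k consensus matrices), `cdf_area` (named per-k),
#'   `chosen_k`, `parameters`.
#' @export
consensus_cluster <- function(enrichment, maxK = 15, reps = 100,
                              p_item = 0.8, p_feature = 0.8, seed = 1,
                              delta_threshold = 0.01) {
  z <- if (inherits(enrichment, "metica_enrichment")) {
    enrichment$z
  } else enrichment
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  n_sets <- nrow(z)
  n_feat <- ncol(z)
  if (n_sets < 3) stop("need at least 3 gene sets")
  if (maxK >= n_sets) stop("maxK must be smaller than the number of sets")
  if (reps < 2) stop("reps must be at least 2")
  n_item <- ceiling(p_item * n_sets)
  n_col <- max(2, ceiling(p_feature * n_feat))
  maxK <- min(maxK, n_item - 1)
  ks <- 2:maxK

  co <- lapply(ks, function(k) matrix(0, n_sets, n_sets))
  names(co) <- ks
  tries <- matrix(0, n_sets, n_sets)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      for (try in 1:20) {
        rows <- sort(sample.int(n_sets, n_item))
        cols <- sample.int(n_feat, n_col)
        sub <- z[rows, cols, drop = FALSE]
        if (nrow(unique(sub)) >= 2) break   # redraw degenerate resamples
      }
      cc <- suppressWarnings(stats::cor(t(sub)))
      cc[!is.finite(cc)] <- 0
      hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
      tries[rows, rows] <- tries[rows, rows] + 1
      for (k in ks) {
        lab <- stats::cutree(hc, k = k)
        same <- outer(lab, lab, "==")
        co[[as.character(k)]][rows, rows] <-
          co[[as.character(k)]][rows, rows] + same
      }
    }
  })
  never <- tries == 0 & row(tries) != col(tries)
  if (any(never)) {
    warning(sum(never) / 2, " set pair(s) never co-sampled; their ",
            "consensus is set to 0")
  }
  consensus <- lapply(co, function(m) {
    cm <- ifelse(tries > 0, m / pmax(tries, 1), 0)
    diag(cm) <- 1
    cm <- (cm + t(cm)) / 2
    dimnames(cm) <- list(rownames(z), rownames(z))
    cm
  })
  cdf_area <- vapply(consensus, consensus_cdf_area, numeric(1))
  names(cdf_area) <- ks
  assignments <- sapply(ks, function(k) {
    hc <- stats::hclust(stats::as.dist(1 - consensus[[as.character(k)]]),
                        method = "average")
    stats::cutree(hc, k = k)
  })
  dimnames(assignments) <- list(rownames(z), ks)
  chosen_k <- choose_k(cdf_area, delta_threshold = delta_threshold)
  structure(list(
    assignment = assignments[, as.character(chosen_k)],
    assignments = assignments,
    consensus = consensus,
    cdf_area = cdf_area,
    chosen_k = chosen_k,
    parameters = list(maxK = maxK, reps = reps, p_item = p_item,
                      p_feature = p_feature, seed = seed,
                      delta_threshold = delta_threshold,
                      linkage = "average", distance = "pearson")),
    class = "metica_consensus")
}

# Area under the empirical CDF of the upper-triangle consensus values,
# evaluated as the mean of the CDF on a fixed 100-point grid in [0, 1].
consensus_cdf_area <- function(cm) {
  vals <- cm[upper.tri(cm)]
  grid <- seq(0, 1, length.out = 100)
  mean(stats::ecdf(vals)(grid))
}

#' Choose the cluster count by the relative change in CDF area
#'
#' The area under the consensus CDF grows with k; the chosen k is the last
#' one before the relative gain drops below `delta_threshold`. Formally,
#' with `A(k)` the per-k areas, `delta(2) = A(2)` and
#' `delta(k) = (A(k) - A(k-1)) / A(k)` for k >= 3 (the relative change of
#' the attained area); the function returns the smallest k for which
#' `delta(k + 1) < delta_threshold`. If no k qualifies, the largest k is
#' returned with a warning.
#'
#' @param cdf_area Numeric vector of areas for k = 2..maxK (names optional).
#' @param delta_threshold Relative-change cutoff.
#' @return Integer cluster count.
#' @export
choose_k <- function(cdf_area, delta_threshold = 0.01) {
  if (length(cdf_area) < 3) stop("need areas for at least 3 values of k")
  ks <- as.integer(names(cdf_area) %||% seq(2, length.out =
                                              length(cdf_area)))
  if (any(is.na(ks))) ks <- seq(2L, length.out = length(cdf_area))
  a <- as.numeric(cdf_area)
  delta <- c(a[1], diff(a) / a[-1])
  qual <- which(delta[-1] < delta_threshold)   # delta(k+1) below threshold
  if (length(qual) == 0) {
    warning("no k reached a relative CDF-area change below ",
            delta_threshold, "; returning maxK")
    return(ks[length(ks)])
  }
  ks[qual[1]]
}

#' @export
print.metica_consensus <- function(x, ...) {
  cat(sprintf("<metica_consensus> %d sets, k = 2..%d, chosen k = %d\n",
              nrow(x$assignments), max(as.integer(colnames(x$assignments))),
              x$chosen_k))
  invisible(x)
}
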