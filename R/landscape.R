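#' Cluster samples into metabolic subtypes
#'
#' Hierarchically clusters samples on the distance 1 - Pearson correlation
#' of their activity profiles with Ward linkage (the `ward.D2`
#' squared-update recurrence), then sweeps cut heights in ascending order
#' and keeps the first height at which the smallest resulting cluster
#' reaches `min_cluster_size` samples.
#'
#' @param mixing A `metica_mixing` (or samples x components matrix),
#'   typically restricted to the metabolic components.
#' @param min_cluster_size Smallest admissible subtype size.
#' @param sweep Numeric `c(from, to, by)` for the cut-height sweep. Ward
#'   heights depend on sample count and separation, so the sweep range may
#'   need widening for large panels.
#' @return Object of class `metica_subtypes`: `assignment` (named subtype
#'   labels), `cut_height`, `n_subtypes`, `min_cluster_size`, `hclust`.
#' @export
subtype_samples <- function(mixing, min_cluster_size = 50,
                            sweep = c(0, 8, 0.2)) {
  a <- if (inherits(mixing, "metica_mixing")) mixing$activities else mixing
  stopifnot(is.matrix(a), !is.null(rownames(a)))
  if (nrow(a) < 2 * min_cluster_size) {
    stop("need at least 2 * min_cluster_size samples")
  }
  if (any(apply(a, 1, stats::sd) == 0)) {
    stop("constant activity row(s): correlation distance undefined")
  }
  d <- stats::as.dist(1 - stats::cor(t(a)))
  hc <- stats::hclust(d, method = "ward.D2")
  heights <- seq(sweep[1], sweep[2], by = sweep[3])
  for (h in heights) {
    labels <- stats::cutree(hc, h = h)
    if (min(table(labels)) >= min_cluster_size) {
      assignment <- stats::setNames(sprintf("MS%d", labels), rownames(a))
      return(structure(list(assignment = assignment, cut_height = h,
                            n_subtypes = length(unique(labels)),
                            min_cluster_size = min_cluster_size,
                            hclust = hc),
                       class = "metica_subtypes"))
    }
  }
  stop("no cut height in the sweep yields a smallest cluster of ",
       min_cluster_size, " samples; widen the sweep or reduce ",
       "min_cluster_size")
}

#' @export
print.metica_subtypes <- function(x, ...) {
  cat(sprintf("<metica_subtypes> %d subtypes at height %.2f (min size %d)\n",
              x$n_subtypes, x$cut_height, min(table(x$assignment))))
  invisible(x)
}

#' Median component activity per subtype
#'
#' The subtype characterization table: median activity score of every
#' component within every subtype.
#'
#' @param mixing A `metica_mixing` (or samples x components matrix).
#' @param assignment Named subtype labels (e.g. from [subtype_samples()]).
#' @return Matrix subtypes x components of median activities.
#' @export
subtype_medians <- function(mixing, assignment) {
  a <- if (inherits(mixing, "metica_mixing")) mixing$activities else mixing
  if (inherits(assignment, "metica_subtypes")) {
    assignment <- assignment$assignment
  }
  a <- a[names(assignment), , drop = FALSE]
  t(sapply(split(seq_along(assignment), assignment), function(idx) {
    apply(a[idx, , drop = FALSE], 2, stats::median)
  }))
}

#' Explained variance of components per sample and per group
#'
#' For each sample, the fraction of its activity captured by each
#' component: the squared mixing weight divided by the sample's sum of
#' squared weights (rows sum to one). Group summaries (per study, tissue,
#' or any sample annotation) are means over member samples; a component
#' whose maximum group mean exceeds `flag_threshold` is flagged as a
#' putative batch or tissue effect.
#'
#' @param mixing A `metica_mixing` (or samples x components matrix).
#' @param groups Optional named vector mapping samples to groups.
#' @param flag_threshold Group-mean explained-variance fraction above which
#'   a component is flagged (reporting convention: 0.10).
#' @return Object of class `metica_ev`: `per_sample` (rows sum to 1),
#'   `per_group` (or `NULL`), `max_group_ev`, `flagged`, `excluded`
#'   (all-zero samples).
#' @export
explained_variance <- function(mixing, groups = NULL,
                               flag_threshold = 0.10) {
  a <- if (inherits(mixing, "metica_mixing")) mixing$activities else mixing
  stopifnot(is.matrix(a), !is.null(rownames(a)))
  ss <- rowSums(a^2)
  excluded <- rownames(a)[ss == 0]
  if (length(excluded)) {
    warning(length(excluded), " all-zero activity row(s) excluded from ",
            "explained variance")
    a <- a[ss > 0, , drop = FALSE]
    ss <- ss[ss > 0]
  }
  ev <- a^2 / ss
  per_group <- max_group <- flagged <- NULL
  if (!is.null(groups)) {
    groups <- groups[rownames(ev)]
    if (anyNA(groups)) stop("missing group label for some samples")
    per_group <- t(sapply(split(rownames(ev), groups), function(ids) {
      colMeans(ev[ids, , drop = FALSE])
    }))
    max_group <- apply(per_group, 2, max)
    flagged <- max_group > flag_threshold
  }
  structure(list(per_sample = ev, per_group = per_group,
                 max_group_ev = max_group, flagged = flagged,
                 excluded = excluded, flag_threshold = flag_threshold),
            class = "metica_ev")
}

#' Spearman association screen of component activities against features
#'
#' Correlates every component's activity scores with every feature column
#' (drug IC50 values, immune cell fractions, ...) using [spearman_t()] on
#' pairwise-complete observations. Cells with fewer than `min_pairs`
#' complete pairs, or with a constant feature on the complete pairs, are
#' recorded as undefined and never flagged.
#'
#' @param mixing A `metica_mixing` (or samples x components matrix).
#' @param features Numeric matrix or data frame, samples in rows (matched
#'   to the mixing matrix by row name); may contain missing values.
#' @param threshold Absolute rho above which an association is flagged
#'   (drug-screen convention: 0.2).
#' @param min_pairs Minimum complete pairs per cell.
#' @return Data frame with one row per (component, feature): `component`,
#'   `feature`, `rho`, `p`, `n`, `flagged`.
#' @export
associate <- function(mixing, features, threshold = 0.2, min_pairs = 4) {
  a <- if (inherits(mixing, "metica_mixing")) mixing$activities else mixing
  f <- as.matrix(features)
  shared <- intersect(rownames(a), rownames(f))
  if (length(shared) < min_pairs) {
    stop("fewer than min_pairs samples shared between activities and ",
         "features")
  }
  a <- a[shared, , drop = FALSE]
  f <- f[shared, , drop = FALSE]
  out <- expand.grid(component = colnames(a), feature = colnames(f),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rho <- out$p <- NA_real_
  out$n <- NA_integer_
  out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    xa <- a[, out$component[i]]
    xf <- f[, out$feature[i]]
    ok <- is.finite(xa) & is.finite(xf)
    out$n[i] <- sum(ok)
    if (sum(ok) < min_pairs) next
    if (stats::sd(xf[ok]) == 0 || stats::sd(xa[ok]) == 0) next
    sp <- spearman_t(xa[ok], xf[ok])
    out$rho[i] <- sp$rho
    out$p[i] <- sp$p
    out$flagged[i] <- abs(sp$rho) > threshold
  }
  out
}
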