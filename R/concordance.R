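#' Top genes of a component
#'
#' Genes whose absolute standardized weight strictly exceeds `threshold`
#' (by convention 3, roughly three standard deviations of the weight
#' distribution).
#'
#' @param components A `metica_components` object (or weight matrix).
#' @param component Component ID (or column index).
#' @param threshold Absolute weight cutoff.
#' @return Character vector of gene IDs.
#' @export
top_genes <- function(components, component, threshold = 3) {
  w <- if (inherits(components, "metica_components")) {
    components$weights
  } else components
  v <- w[, component]
  names(v)[abs(v) > threshold]
}

#' Permutation p-value for the overlap of two top-gene lists
#'
#' Draws two random gene sets of the observed sizes (each without
#' replacement, independently of each other) from the shared gene universe
#' and counts how often their overlap reaches the observed one. The
#' p-value uses the add-one permutation estimator
#' `(b + 1) / (n_perm + 1)`, which cannot be zero. The exact hypergeometric
#' upper tail is available as a fast alternative and converges to the
#' permutation estimate.
#'
#' @param n_top_a,n_top_b Sizes of the two top-gene lists.
#' @param n_overlap Observed overlap.
#' @param universe_size Number of genes in the shared universe.
#' @param n_perm Number of random draws.
#' @param seed Seed for the draws.
#' @param method `"permutation"` (default) or `"hypergeometric"`.
#' @return Single p-value in (0, 1].
#' @export
overlap_pvalue <- function(n_top_a, n_top_b, n_overlap, universe_size,
                           n_perm = 10000, seed = 1,
                           method = c("permutation", "hypergeometric")) {
  method <- match.arg(method)
  assert_positive_int(c(n_top_a, n_top_b, universe_size), "sizes")
  assert_positive_int(n_overlap, "n_overlap", allow_zero = TRUE)
  if (n_top_a > universe_size || n_top_b > universe_size) {
    stop("top-gene list larger than the universe")
  }
  if (n_overlap > min(n_top_a, n_top_b)) {
    stop("n_overlap exceeds the smaller list")
  }
  if (n_overlap < n_top_a + n_top_b - universe_size) {
    stop("n_overlap impossible for these sizes")
  }
  if (method == "hypergeometric") {
    return(stats::phyper(n_overlap - 1, n_top_a,
                         universe_size - n_top_a, n_top_b,
                         lower.tail = FALSE))
  }
  # Canonical size order keeps the estimate symmetric in the two lists.
  n1 <- min(n_top_a, n_top_b)
  n2 <- max(n_top_a, n_top_b)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      a <- sample.int(universe_size, n2)
      bb <- sample.int(universe_size, n1)
      if (sum(bb %in% a) >= n_overlap) h <- h + 1L
    }
    h
  })
  (hits + 1) / (n_perm + 1)
}

#' Spearman correlation with the t-distribution p-value
#'
#' Spearman's rho on average-ranked data with the approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom for
#' the two-sided p-value. For `|rho| = 1` the approximation degenerates;
#' the p-value is reported as 0 with `below_approximation = TRUE`.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @return List with `rho`, `p`, `t`, `n`, `below_approximation`.
#' @export
spearman_t <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    return(list(rho = sign(rho), p = 0, t = sign(rho) * Inf, n = n,
                below_approximation = TRUE))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2), t = t, n = n,
       below_approximation = FALSE)
}

#' Cross-dataset concordance of metabolic components
#'
#' Evaluates every pair of selected components between two datasets. Both
#' weight matrices are restricted to the shared gene universe and
#' re-standardized; top genes are the shared-universe genes with absolute
#' weight above `top_threshold`. A pair is concordant when the Spearman
#' correlation of the overlapping top genes' weights satisfies
#' `|rho| > rho_threshold` at `p < p_threshold`, given that the top-gene
#' overlap itself is significant (permutation `p < p_threshold`). Pairs
#' with fewer than 4 overlapping top genes have no defined correlation and
#' are recorded as non-concordant with a reason.
#'
#' @param components_a,components_b `metica_components` for two datasets.
#' @param mtcs_a,mtcs_b Component IDs to compare (e.g. `mtc_ids` of
#'   [select_mtcs()]); `NULL` compares all components.
#' @param top_threshold Absolute weight cutoff for top genes.
#' @param rho_threshold,p_threshold Concordance rule thresholds.
#' @param n_perm Draws for the overlap permutation null.
#' @param seed Master seed; each pair derives its own stream, symmetric in
#'   the pair.
#' @param overlap_method Passed to [overlap_pvalue()].
#' @return Data frame of class `metica_concordance` with one row per pair:
#'   `mtc_a`, `mtc_b`, `dataset_a`, `dataset_b`, `n_top_a`, `n_top_b`,
#'   `n_overlap`, `overlap_p`, `rho`, `rho_p`, `concordant`, `reason`.
#' @export
call_concordance <- function(components_a, components_b,
                             mtcs_a = NULL, mtcs_b = NULL,
                             top_threshold = 3, rho_threshold = 0.5,
                             p_threshold = 0.05, n_perm = 10000, seed = 1,
                             overlap_method = "permutation") {
  stopifnot(inherits(components_a, "metica_components"),
            inherits(components_b, "metica_components"))
  shared <- intersect(rownames(components_a$weights),
                      rownames(components_b$weights))
  if (length(shared) < 4) stop("shared gene universe too small")
  wa <- standardize_cols(components_a$weights[shared, , drop = FALSE])
  wb <- standardize_cols(components_b$weights[shared, , drop = FALSE])
  mtcs_a <- mtcs_a %||% colnames(wa)
  mtcs_b <- mtcs_b %||% colnames(wb)
  u <- length(shared)

  rows <- vector("list", length(mtcs_a) * length(mtcs_b))
  i <- 0
  for (ca in mtcs_a) {
    ta <- names(which(abs(wa[, ca]) > top_threshold))
    for (cb in mtcs_b) {
      tb <- names(which(abs(wb[, cb]) > top_threshold))
      ov <- intersect(ta, tb)
      pair_seed <- derive_seed(seed, paste(sort(c(
        paste(components_a$dataset_label, ca),
        paste(components_b$dataset_label, cb))), collapse = "|"))
      op <- overlap_pvalue(length(ta), length(tb), length(ov), u,
                           n_perm = n_perm, seed = pair_seed,
                           method = overlap_method)
      if (length(ov) >= 4) {
        sp <- spearman_t(wa[ov, ca], wb[ov, cb])
        rho <- sp$rho
        rho_p <- sp$p
        conc <- abs(rho) > rho_threshold && rho_p < p_threshold &&
          op < p_threshold
        reason <- if (conc) "" else "below threshold"
      } else {
        rho <- NA_real_
        rho_p <- NA_real_
        conc <- FALSE
        reason <- "fewer than 4 overlapping top genes"
      }
      i <- i + 1
      rows[[i]] <- data.frame(
        mtc_a = ca, mtc_b = cb,
        dataset_a = components_a$dataset_label,
        dataset_b = components_b$dataset_label,
        n_top_a = length(ta), n_top_b = length(tb),
        n_overlap = length(ov), overlap_p = op,
        rho = rho, rho_p = rho_p, concordant = conc, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metica_concordance", class(out))
  out
}

#' Summarize concordance calls across datasets
#'
#' @param pairs One or more concordance tables from [call_concordance()]
#'   (rbind-compatible), jointly covering every dataset pair of interest.
#' @return List with `per_dataset` (data frame: dataset, n_mtcs,
#'   n_concordant, fraction of that dataset's components concordant with at
#'   least one component elsewhere) and `n_concordant_all_datasets` (number
#'   of components concordant with at least one component in every other
#'   dataset).
#' @export
concordance_summary <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  long <- rbind(
    data.frame(dataset = pairs$dataset_a, mtc = pairs$mtc_a,
               other = pairs$dataset_b, concordant = pairs$concordant,
               stringsAsFactors = FALSE),
    data.frame(dataset = pairs$dataset_b, mtc = pairs$mtc_b,
               other = pairs$dataset_a, concordant = pairs$concordant,
               stringsAsFactors = FALSE))
  key <- paste(long$dataset, long$mtc)
  any_conc <- tapply(long$concordant, key, any)
  ds <- vapply(strsplit(names(any_conc), " "), `[[`, character(1), 1)
  per_dataset <- do.call(rbind, lapply(unique(ds), function(d) {
    hit <- any_conc[ds == d]
    data.frame(dataset = d, n_mtcs = length(hit),
               n_concordant = sum(hit),
               fraction_concordant = mean(hit),
               stringsAsFactors = FALSE)
  }))
  n_datasets <- length(unique(c(pairs$dataset_a, pairs$dataset_b)))
  conc_other <- tapply(long$concordant & TRUE,
                       paste(long$dataset, long$mtc, long$other), any)
  parts <- strsplit(names(conc_other), " ")
  comp_key <- vapply(parts, function(p) paste(p[1], p[2]), character(1))
  all_ds <- tapply(conc_other, comp_key, function(v) {
    all(v) && length(v) == n_datasets - 1
  })
  list(per_dataset = per_dataset,
       n_concordant_all_datasets = sum(all_ds))
}
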