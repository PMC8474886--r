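#' Welch t-to-Z gene-set enrichment of a weight vector
#'
#' Compares the component weights of the genes inside a set against the
#' weights of all other genes with the two-sample Welch t-test for unequal
#' variances, then transforms the two-sided p-value into a signed Z-score
#' (`z = sign(t) * qnorm(1 - p/2)`) so that enrichment scores are
#' comparable across gene sets of different sizes. `|z|` is clamped at 40
#' to keep scores finite when p underflows double precision; the
#' transformation is computed in log space so ordering is preserved far
#' beyond that point.
#'
#' @param weights Named numeric vector of per-gene weights.
#' @param members Character vector of member gene IDs; members absent from
#'   `weights` are ignored.
#' @return List with `t`, `df` (Welch–Satterthwaite), `p` (two-sided), `z`,
#'   `n_in`, `n_out`.
#' @examples
#' welch_z(stats::setNames(c(1, 2, 3, 4, 5, 6), letters[1:6]),
#'         c("a", "b", "c"))
#' @export
welch_z <- function(weights, members) {
  if (is.null(names(weights))) stop("`weights` must be named by gene ID")
  inset <- names(weights) %in% members
  n_in <- sum(inset)
  n_out <- sum(!inset)
  if (n_in < 2 || n_out < 2) {
    stop("need at least 2 member and 2 non-member genes among the weights")
  }
  win <- weights[inset]
  wout <- weights[!inset]
  res <- welch_z_stats(mean(win), stats::var(win), n_in,
                       mean(wout), stats::var(wout), n_out)
  c(res, list(n_in = n_in, n_out = n_out))
}

# Vectorized core of the Welch t -> Z transform. All arguments may be
# vectors of equal length.
welch_z_stats <- function(m1, v1, n1, m2, v2, n2, z_clamp = 40) {
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
              (m1 - m2) / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  log_half_p <- stats::pt(-abs(t), df, log.p = TRUE)
  p <- pmin(2 * exp(log_half_p), 1)
  z <- sign(t) * stats::qnorm(log_half_p, lower.tail = FALSE, log.p = TRUE)
  z <- pmax(pmin(z, z_clamp), -z_clamp)
  z[t == 0] <- 0
  list(t = t, df = df, p = p, z = z)
}

#' Enrichment of every component against every gene set
#'
#' Applies [welch_z()] per (gene set, component) pair. The gene universe is
#' the set of genes carrying component weights; set members outside it are
#' ignored. Sets with fewer than 2 members (or fewer than 2 non-members) in
#' the universe are skipped and reported in the `skipped` field.
#'
#' @param components A `metica_components` object (or a plain genes x K
#'   weight matrix with dimnames).
#' @param gene_sets A [gene_set_collection()].
#' @return Object of class `metica_enrichment`: `z` (sets x components),
#'   `n_in`/`n_out` per set, `skipped` (named reasons), `component_ids`,
#'   `set_ids`.
#' @export
enrich_all <- function(components, gene_sets) {
  w <- if (inherits(components, "metica_components")) {
    components$weights
  } else components
  stopifnot(is.matrix(w), !is.null(rownames(w)), !is.null(colnames(w)))
  stopifnot(inherits(gene_sets, "metica_genesets"))
  universe <- rownames(w)
  n_genes <- length(universe)
  if (length(gene_sets$sets) == 0) stop("empty gene-set collection")

  tot_sum <- colSums(w)
  tot_sq <- colSums(w^2)

  z <- matrix(NA_real_, length(gene_sets$sets), ncol(w),
              dimnames = list(names(gene_sets$sets), colnames(w)))
  n_in <- n_out <- integer(length(gene_sets$sets))
  skipped <- character()
  for (i in seq_along(gene_sets$sets)) {
    members <- intersect(gene_sets$sets[[i]], universe)
    k <- length(members)
    if (k < 2 || n_genes - k < 2) {
      skipped[names(gene_sets$sets)[i]] <-
        sprintf("%d member(s) in universe", k)
      next
    }
    win <- w[members, , drop = FALSE]
    s1 <- colSums(win)
    q1 <- colSums(win^2)
    m1 <- s1 / k
    v1 <- (q1 - k * m1^2) / (k - 1)
    n2 <- n_genes - k
    m2 <- (tot_sum - s1) / n2
    v2 <- (tot_sq - q1 - n2 * m2^2) / (n2 - 1)
    v1 <- pmax(v1, 0)
    v2 <- pmax(v2, 0)
    st <- welch_z_stats(m1, v1, k, m2, v2, n2)
    z[i, ] <- st$z
    n_in[i] <- k
    n_out[i] <- n2
  }
  keep <- !rownames(z) %in% names(skipped)
  if (!any(keep)) stop("no gene set overlaps the component gene universe")
  if (length(skipped)) {
    message(length(skipped), " gene set(s) skipped (too few genes in the ",
            "universe)")
  }
  structure(list(z = z[keep, , drop = FALSE],
                 n_in = stats::setNames(n_in[keep],
                                        rownames(z)[keep]),
                 n_out = stats::setNames(n_out[keep],
                                         rownames(z)[keep]),
                 skipped = skipped,
                 set_ids = rownames(z)[keep],
                 component_ids = colnames(z)),
            class = "metica_enrichment")
}

#' @export
print.metica_enrichment <- function(x, ...) {
  cat(sprintf("<metica_enrichment> %d sets x %d components (%d skipped)\n",
              nrow(x$z), ncol(x$z), length(x$skipped)))
  invisible(x)
}
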