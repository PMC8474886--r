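#' Select metabolic transcriptional components per gene-set cluster
#'
#' Applies two top-3 rules per cluster of gene sets and takes the union:
#' rule A (`max_single_set`) ranks components by the maximum absolute
#' enrichment score over the cluster's sets; rule B (`max_cluster_mean`)
#' ranks by the absolute mean of the signed scores over the cluster's sets
#' (so a component with cancelling positive and negative enrichment within
#' a cluster is excluded by rule B even though rule A may select it). Ties
#' are broken by component order.
#'
#' The signed-mean reading of rule B is the default; set
#' `rule_b = "mean_of_abs"` to rank by the mean of absolute scores
#' instead.
#'
#' @param enrichment A `metica_enrichment` (or sets x components matrix).
#' @param assignment Named vector mapping each set of the enrichment matrix
#'   to a cluster label (e.g. the `assignment` of [consensus_cluster()]).
#'   Sets of the enrichment matrix absent from `assignment` are ignored;
#'   a cluster with no set present in the matrix is an error.
#' @param n_top Components selected per rule per cluster.
#' @param rule_b Interpretation of the cluster-mean rule.
#' @return Object of class `metica_mtc`: `mtc_ids` and a `provenance` data
#'   frame (component, cluster, rule, score).
#' @export
select_mtcs <- function(enrichment, assignment, n_top = 3,
                        rule_b = c("abs_of_mean", "mean_of_abs")) {
  rule_b <- match.arg(rule_b)
  z <- if (inherits(enrichment, "metica_enrichment")) {
    enrichment$z
  } else enrichment
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  assignment <- assignment[names(assignment) %in% rownames(z)]
  if (length(assignment) == 0) {
    stop("no set of the assignment is present in the enrichment matrix")
  }
  clusters <- split(names(assignment), assignment)
  if (any(lengths(clusters) == 0)) {
    stop("cluster with zero sets: assignment inconsistent with enrichment")
  }
  prov <- list()
  for (cl in names(clusters)) {
    zc <- z[clusters[[cl]], , drop = FALSE]
    score_a <- apply(abs(zc), 2, max)
    score_b <- if (rule_b == "abs_of_mean") {
      abs(colMeans(zc))
    } else {
      colMeans(abs(zc))
    }
    for (rule in c("max_single_set", "max_cluster_mean")) {
      sc <- if (rule == "max_single_set") score_a else score_b
      top <- order(-sc)[seq_len(min(n_top, length(sc)))]
      prov[[length(prov) + 1]] <- data.frame(
        component = colnames(z)[top], cluster = cl, rule = rule,
        score = sc[top], stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  prov <- do.call(rbind, prov)
  mtc_ids <- colnames(z)[colnames(z) %in% prov$component]
  structure(list(mtc_ids = mtc_ids, provenance = prov),
            class = "metica_mtc")
}

#' @export
print.metica_mtc <- function(x, ...) {
  cat(sprintf("<metica_mtc> %d components selected over %d clusters\n",
              length(x$mtc_ids), length(unique(x$provenance$cluster))))
  invisible(x)
}

#' Count enriched gene sets per component
#'
#' @param enrichment A `metica_enrichment` (or sets x components matrix).
#' @param threshold Absolute enrichment score a set must exceed (strictly)
#'   to count; the reporting convention uses 3.
#' @return Named integer vector, one count per component.
#' @export
count_enriched_sets <- function(enrichment, threshold = 3) {
  if (threshold <= 0) stop("threshold must be positive")
  z <- if (inherits(enrichment, "metica_enrichment")) {
    enrichment$z
  } else enrichment
  colSums(abs(z) > threshold)
}
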